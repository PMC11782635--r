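# fedlhe

Privacy-preserving federated learning for two-class pathology-image
classification, simulated end to end on one machine. Clients train a small
residual convolutional classifier on local benign/malignant image shards and
upload **encrypted** parameter updates; the server aggregates ciphertexts by
sample-size-weighted federated averaging (FedAvrg) without ever seeing an
individual client's weights.

The package is aimed at researchers studying secure-aggregation protocols
who need a complete, deterministic, desk-scale testbed rather than a
production system.

## What is inside

* **Key generation** in the classic two-prime form: primes `a`, `b`,
  modulus `n = ab`, totient `ω(n) = (a−1)(b−1)`, public exponent `i`,
  private exponent `k = i⁻¹ mod ω(n)`.
* **Additive homomorphic layer** over the same modulus: `c = (1+mn)·rⁿ mod
  n²`, so `dec(c₁·c₂) = (m₁+m₂) mod n` exactly. Decryption is per-prime CRT,
  which works for *every* distinct odd prime pair (including ones where the
  textbook decryption constant does not exist).
* **Fixed-point codec** (scale `2¹⁶`, clip 8, offset-binary negatives) and
  **coefficient batching** of parameter vectors into 64-slot packed
  ciphertexts.
* **FedAvrg** with the per-coordinate guarantee
  `|encrypted − plaintext| ≤ C/(2·scale·N)` for `C` clients and `N` total
  samples.
* A **4-round, 64-bit XOR/XNOR/swap block transform** (Feistel-placed
  feed-function, counter-mode payloads) for the prediction request channel,
  plus RSA-style session-key wrapping with `(i, k)`.
* A **surrogate residual CNN** (backbone/neck/head, ~5k parameters) with
  deterministic base-R training, **magnitude-based hidden-layer pruning**
  and transfer fine-tuning at learning rate 0.0032.
* A **synthetic histopathology-like generator**: two classes at the
  2480:5429 benign:malignant ratio, magnification tags 40×–400×, YOLO-format
  bounding boxes, stratified 80/10/10 splits and the five-client non-IID
  hospital scenario.
* A **CLI** (`inst/cli/fedlhe.R`) with `generate-data`, `run-federated`,
  `run-centralized`, `prune` and `report` subcommands.

The cryptography re-implements a described research construction and makes
**no security claims**.

## Worked example

```r
library(fedlhe)

bundle <- generate_dataset(2000, benign_fraction = 2480/7909,
                           image_size = 64, seed = 1)
print(bundle)
#> Synthetic dataset bundle
#>   train: 1602 images (503 benign / 1099 malignant)
#>   val  :  199 images (62 benign / 137 malignant)
#>   test :  199 images (62 benign / 137 malignant)

fit <- fedl(bundle, fedl_config(rounds = 10, local_epochs = 2,
                                encryption = TRUE, seed = 1))
print(fit)
#> Federated two-class classifier (FedAvrg with encrypted aggregation)
#>   clients: 5 (sizes 304/348/218/218/184)
#>   rounds run: 10 x 2 local epoch(s), batch 32, lr 0.01
#>   final global validation accuracy: 0.9849 (loss 0.0848)
#>   parameters: 5057  |  key modulus: 11314090182999859753
```

The printed validation accuracy is the global model's accuracy on the shared
validation split after the last communication round; the key modulus is the
product of the two freshly drawn 32-bit primes under which every client
update was encrypted. `summary(fit)` tabulates per-round global and
per-client metrics, `plot(fit)` draws the round trajectories, `coef(fit)`
returns the aggregated parameter vector, and `predict(fit, bundle$test)`
scores new images.

Small pieces compose directly:

```r
kp <- he_keygen(5, 11, pub_exponent = 7)   # n = 55, omega = 40, k = 23
he_decrypt(he_add(he_encrypt(30, kp), he_encrypt(30, kp)), kp)
#> [1] 5        # (30 + 30) mod 55
```

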