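---
title: "Methods: encrypted federated learning for two-class pathology images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encrypted federated learning for two-class pathology images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Hospitals hold benign/malignant image collections they cannot pool. Federated
learning trains a shared classifier by exchanging only model parameters, but
the parameter updates themselves still leak information about the local data.
`fedlhe` simulates, in a single process, a federation in which every client's
update is encrypted before upload and the server aggregates *ciphertexts*:
the server learns the weighted average of the client models and nothing about
any individual client's weights.

The package covers the full experimental loop: a synthetic two-class
histopathology-like image generator with magnification tags and YOLO-format
bounding boxes; non-IID client sharding; a small residual convolutional
surrogate classifier; sample-size-weighted federated averaging (FedAvrg) over
an additively homomorphic encryption layer with fixed-point coding and
coefficient batching; a 4-round XOR/XNOR/swap block transform for request
payloads; and magnitude-based hidden-layer pruning with transfer
fine-tuning.

## Key generation and the additive encryption layer

Key generation follows the classic two-prime construction: distinct odd
primes $a$ and $b$ give the modulus $n = ab$ and totient
$\omega(n) = (a-1)(b-1)$; a public exponent $i$ with $1 < i < \omega(n)$ and
$\gcd(i, \omega(n)) = 1$ yields the private exponent
$k = i^{-1} \bmod \omega(n)$. The exponent pair $(i, k)$ is multiplicative,
so it cannot serve the additive aggregation directly; the package keeps it
for wrapping the symmetric session keys of the request channel
(`wrap_session_key()`), exactly as an RSA-style transport key would be used.

Aggregation instead uses an additive layer over the *same* modulus:
plaintexts $m \in [0, n)$ encrypt as

$$c = (1 + mn)\, r^{\,n} \bmod n^2, \qquad r \twoheadleftarrow [1, n),\ \gcd(r, n) = 1,$$

so ciphertext multiplication adds plaintexts:
$\mathrm{dec}(c_1 c_2 \bmod n^2) = (m_1 + m_2) \bmod n$. Encryption is
randomized; equal plaintexts give distinct ciphertexts.

Decryption deliberately avoids the textbook constant
$\mu = \omega^{-1} \bmod n$, which does not exist whenever
$\gcd(n, \omega(n)) \neq 1$ (for example $a = 5$, $b = 11$: $\gcd(55, 40) =
5$). Instead the plaintext is recovered per prime with
$L_p(u) = (u-1)/p$ applied to $c^{\,p-1} \bmod p^2$ and the two residues are
combined by the Chinese Remainder Theorem. The per-prime constants
$h_p = L_p\big((1+n)^{p-1} \bmod p^2\big)^{-1} \bmod p$ always exist for
distinct odd primes, so *every* admissible key pair from the keygen above is
usable — including small classroom primes.

**Supported range.** All big-integer arithmetic is exact 128-bit modular
arithmetic (shift-and-add multiplication; deterministic Miller–Rabin), so
the modulus is limited to $n < 2^{64}$, i.e. primes of at most 32 bits.
That is ample for the package's purpose — demonstrating and testing the
construction — and nothing here is production cryptography: random numbers
come from R's seedable RNG and no operation is constant-time.

## Fixed-point coding and the quantization error bound

Model weights are reals; the message space is $[0, n)$. The codec clips to
$[-B, B]$ (default $B = 8$, far beyond where trained weights live), scales by
$s = 2^{16}$, rounds, and shifts by the offset $\lfloor Bs \rceil$ so
negatives become non-negative (offset binary). Under aggregation each client
$i$ quantizes its *pre-scaled* vector,
$v_i = \mathrm{round}(n_i w_i s) + n_i \cdot \mathrm{offset}$, with $n_i$ its
integer sample count. The server adds ciphertexts only, decrypts the sum,
divides by $N = \sum_i n_i$ and unshifts. Because each coordinate of each
client contributes at most $\tfrac12$ a rounding quantum *once*, the
aggregate deviates from exact plaintext FedAvrg by at most

$$\frac{C}{2 s N} \quad \text{per coordinate, for } C \text{ clients},$$

about $10^{-7}$ at the default scales. The codec's `headroom` must cover
$N$ (not just $C$) because of the pre-scaling; `fedl()` sizes it
automatically and `encrypted_aggregate()` refuses to aggregate beyond it
rather than risk modular wraparound.

## Coefficient batching

Encrypting every parameter separately is the dominant cost, so parameter
vectors are packed: $n_s = 64$ values become the coefficients of
$P(X) = \sum_j x_j X^j$ in $\mathbb{Z}_q[X]/(X^{n_s}+1)$ and travel as one
grouped ciphertext object. Since the aggregation needs *addition only*,
packed ciphertexts are realized as grouped coefficient-wise additive
ciphertexts; polynomial multiplication (and hence negacyclic reduction,
rotations, or true CRT slot semantics) is never required and not
implemented. The plaintext modulus $q$ is the smallest prime exceeding
`headroom * (2*offset + 1)`, so aggregated sums cannot wrap; decoding
reduces modulo $q$. Packing cuts the number of ciphertext objects per
parameter vector from $P$ to $\lceil P/64 \rceil$.

## The block transform for request payloads

Prediction requests and responses travel under a 64-bit, 4-round symmetric
transform. The state is four 16-bit quarters. Round keys derive from the two
64-bit keys: odd rounds XOR $K_1$ with a fixed round constant, even rounds
XNOR $K_2$ with it. Each round (i) mixes the state with the round key (XOR on
odd rounds, XNOR on even), (ii) feeds quarter 0 through the add–rotate–xor
function `f_function()` into quarter 1 — the Feistel position, so `F` need
not be invertible — and (iii) permutes the quarters
$(q_0,q_1,q_2,q_3) \to (q_2,q_3,q_1,q_0)$. Every step is an involution or a
tracked permutation, so decryption applies the exact inverses in reverse
order and round-trips *every* input. The same round structure instantiates
at 4-bit quarters (a 16-bit state), which the tests invert exhaustively over
all 65,536 states. Payloads of arbitrary byte length use counter mode with
an explicit nonce, which keeps equal plaintexts from producing equal
ciphertexts; the construction carries no security claim.

## Federated averaging

Each communication round broadcasts the global parameter vector; every
selected client trains locally for $G$ epochs (Adam, binary cross entropy,
batch 32, learning rate 0.01) and uploads its last-epoch weights; the server
computes $\sum_i (n_i/N)\, w_i$ — through the encrypted path by default —
and redistributes. All clients participate every round by default
(`client_fraction` enables random selection, floor rule with a minimum of
one). The plaintext average is computed anchored at the first update,
$w_1 + \sum_{i\ge2} (n_i/N)(w_i - w_1)$, so that averaging identical vectors
is *bit-exact*; permutation invariance then holds to floating-point
rounding (~1e-16 relative), which the tests assert at 1e-12.

The number of participating clients is configurable; the default is five,
matching the heterogeneous five-hospital scenario the shard specification
encodes. Which round's weights count as "best" is a genuinely open choice:
`fedl()` keeps the final round's weights by default and offers
`best_weights = "best_val"`, logging both so the two conventions can be
compared.

## The surrogate classifier

Every quantity the framework reports is a classification metric (accuracy,
BCE loss, precision/recall/F1), so the surrogate is a classifier, not a
detector: a fixed 4×4 average-pool stem to a 16×16 grid with inputs centred
at 0, one 3×3 convolution into 8 channels, eight prunable residual blocks
$y = x + \mathrm{relu}(\mathrm{conv}_{3\times3}(x))$ (the backbone), a
global-average-pool plus 16-unit dense neck, and a single sigmoid head
(~5,000 parameters). Residual branches initialize at a quarter of the He
scale and the head at a quarter of Xavier so the stacked skip sums start
well-conditioned — with plain He initialization the sigmoid is born
saturated and the first epochs are wasted escaping it. All tensor algebra is
im2col matrix multiplication in base R; training is exactly reproducible
from the seed. YOLO-format annotations are still generated, written and
read, keeping fixture fidelity with detector-style corpora.

Backbone freezing (`freeze_backbone()`) exists for the transfer fine-tuning
stage after pruning; federated rounds train and share the full parameter
vector by default, which keeps the shared vector's length constant across
rounds and makes the single-client and identical-client equivalences exact.

## Hidden-layer pruning

Whole-layer pruning needs a concrete, testable criterion; the package uses
the smallest-assumption magnitude rule: the score
of a layer is the mean absolute weight of its tensor; eligible layers are
the residual blocks outside protected sections (the head is always
protected); every eligible layer scoring below the threshold $\tau$ is
removed in ascending-score order (ties: shallower layer first), up to a cap.
Removal clears the keep-flag; the skip connection routes around the block,
so pruning an all-zero block leaves the forward function pointwise
identical — the property the tests verify bit-exactly. Raising $\tau$ prunes
supersets (monotonicity). Fine-tuning freezes the backbone and retrains at
the transfer learning rate 0.0032, recording the before/after assessment.

## The synthetic corpus and its sharding

The generator emulates the *structure* of a two-class, four-magnification
microscopy corpus, not its histology: benign images have 1–3 small, round,
regular blobs on a pink textured background; malignant images have 4–9
larger, eccentric, ragged blobs, darker and with higher chroma variance.
Blob scale grows with the magnification tag (40×/100×/200×/400×, drawn at
the per-class mix of the emulated corpus), every blob yields a normalized
bounding box, and pixels land on the 8-bit grid so PNG round-trips are
bit-exact. The default benign fraction is 2480/5429-malignant (0.3136
benign). The classes are deliberately well separated — a small classifier
exceeds 90% validation accuracy within 10 epochs — because the package's
claims are about the *protocol* (encryption, aggregation, partitioning,
pruning), not about image difficulty. Passing tests therefore demonstrate
correctness of the machinery, and nothing about performance on real
histopathology: real stain variation, texture, class overlap and label
noise are all absent.

Splits are stratified 80/10/10 with floors (at the emulated corpus size
7,909 this gives 6,329/790/790); the minority class takes the floor at
generation. The five-client non-IID scenario is encoded numerically:
client 1 benign-majority (0.7), client 2 malignant-majority (benign 0.2),
client 3 balanced low-magnification only, client 4 balanced
high-magnification only, client 5 half-size and highly unbalanced (benign
0.85), client sizes otherwise equal at the largest feasible base size.
Exact skew fractions and full coverage of the train split are mutually
infeasible (the benign and malignant demands imply different base sizes),
so the partitioner makes exact stratified draws and returns the leftover
images in an explicit `unassigned` pool; shards plus that pool account for
the train split exactly, and shards are pairwise disjoint. Clients
oversample their minority class by seeded augmentation (90° rotations,
flips, ±10% central scaling, boxes transformed consistently) before
training, mirroring local augmentation ahead of encryption.

## Numerical choices and degenerate inputs

* Tolerances: encrypted-vs-plain aggregation is asserted at the analytic
  bound $C/(2sN)$, never looser; homomorphic arithmetic and block
  round-trips are asserted exactly.
* BCE is reported with probabilities clamped to $[10^{-12}, 1-10^{-12}]$;
  gradients use the exact $(p - y)$ form.
* Degenerate metric denominators (no predicted positives, etc.) return 0
  and are flagged rather than NaN.
* Single-class shards warn and train (BCE remains defined).
* Zero rounds / zero epochs are no-ops with empty histories.
* Checkpoints and key files are plain text at 17 significant digits, which
  round-trips IEEE doubles exactly.

## Problem sizes used by the test-suite and acceptance script

Unit tests run on 100–800-image corpora at 16–32 px. The end-to-end check
uses the package's standard desk-scale experiment: 2,000 images at 64×64,
five non-IID clients, 10 rounds × 2 local epochs with encryption on, three
seeds — sizes chosen so the whole loop (including ~250,000 Paillier-style
encryptions per run) completes in minutes on one CPU while still exercising
every component at meaningful scale. A full-scale profile (640×640 inputs,
100 epochs) is expressible in the configuration but is not part of the
default runs.

## Known limitations

* No security analysis: the HE layer and block transform re-implement a
  described construction for study; keys are small, RNG is not
  cryptographic, timing is not constant.
* The modulus is capped below $2^{64}$ (no arbitrary-precision dependency).
* The surrogate is a classifier; bounding-box regression heads, anchors and
  multi-scale necks are out of scope, as is training on real corpora
  (BreakHis-style two-class image archives are supported only through the
  documented directory loader, untested against real data).
* Batching implements coefficient packing with addition only — not CRT slot
  semantics under multiplication.
* The federation is a single-process simulation; no networking, stragglers,
  asynchrony, differential privacy or secure multi-party computation.
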