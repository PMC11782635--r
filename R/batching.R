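# Coefficient batching: many plaintext values ride in one packed object as
# the coefficients of P(X) = x_0 + x_1 X + ... + x_{n-1} X^{n-1} over
# Z_q[X]/(X^n + 1). Only slot-wise addition is ever needed by the federated
# aggregation, so packed ciphertexts are realized as grouped coefficient-wise
# additive ciphertexts; homomorphic addition then acts slot-wise exactly.

#' Construct a slot vector
#'
#' @param x Integer slot values, already reduced modulo `q`.
#' @param slot_count Number of slots `n`; a power of two.
#' @param q Plaintext modulus.
#' @return Object of class `slot_vector`.
#' @export
slot_vector <- function(x, slot_count = 64, q = default_plain_modulus()) {
  if (slot_count < 1 || bitwAnd(slot_count, slot_count - 1L) != 0)
    stop("slot_count must be a power of two")
  if (length(x) > slot_count)
    stop("vector of length ", length(x), " exceeds ", slot_count,
         " slots; chunk it with packed_encrypt()")
  x <- c(as.numeric(x), rep(0, slot_count - length(x)))
  if (any(x < 0) || any(x != trunc(x)) || any(x >= q))
    stop("slot values must be integers in [0, q)")
  structure(list(slots = x, slot_count = slot_count, q = q),
            class = "slot_vector")
}

#' Smallest prime plaintext modulus with aggregation headroom
#'
#' The default accommodates `headroom` summands of values up to `max_value`
#' without wraparound: the smallest prime exceeding `headroom * (max_value
#' + 1)`.
#' @param headroom Number of summands (clients).
#' @param max_value Largest slot value before aggregation.
#' @export
default_plain_modulus <- function(headroom = 5, max_value = 2^16) {
  cand <- headroom * (max_value + 1) + 1
  if (cand %% 2 == 0) cand <- cand + 1
  while (!cpp_is_prime(sprintf("%.0f", cand))) cand <- cand + 2
  cand
}

#' Encode slots as a packed polynomial and back
#'
#' Coefficient packing: slot `j` becomes the coefficient of `X^j`.
#' `decode(encode(v))` is the identity; decoding reduces coefficients mod
#' `q`, so decoding the sum of two packed polynomials yields the slot-wise
#' modular sums.
#'
#' @param slots A [slot_vector()].
#' @return `encode`: object of class `packed_poly`; `decode`: `slot_vector`.
#' @export
encode <- function(slots) {
  stopifnot(inherits(slots, "slot_vector"))
  structure(list(coef = slots$slots, slot_count = slots$slot_count,
                 q = slots$q), class = "packed_poly")
}

#' @rdname encode
#' @param p A `packed_poly`.
#' @export
decode <- function(p) {
  stopifnot(inherits(p, "packed_poly"))
  slot_vector(p$coef %% p$q, p$slot_count, p$q)
}

#' Encrypt a packed polynomial (or a long vector, chunked)
#'
#' A numeric vector longer than `slot_count` is split into
#' `ceiling(length / slot_count)` chunks, each encoded and encrypted; order
#' is preserved on decryption.
#'
#' @param x A `packed_poly`, `slot_vector`, or numeric vector of
#'   non-negative integers below `q`.
#' @param key An `he_keypair` (public part suffices).
#' @param slot_count,q Packing geometry, used when `x` is a bare vector.
#' @return Object of class `packed_ct`.
#' @export
packed_encrypt <- function(x, key, slot_count = 64,
                           q = default_plain_modulus()) {
  if (inherits(x, "slot_vector")) x <- encode(x)
  if (inherits(x, "packed_poly")) {
    slot_count <- x$slot_count; q <- x$q
    vec <- x$coef
    len <- length(vec)
  } else {
    vec <- as.numeric(x)
    if (any(vec < 0) || any(vec != trunc(vec)) || any(vec >= q))
      stop("values must be integers in [0, q)")
    len <- length(vec)
  }
  n_chunks <- max(1L, as.integer(ceiling(len / slot_count)))
  chunks <- vector("list", n_chunks)
  for (jc in seq_len(n_chunks)) {
    lo <- (jc - 1) * slot_count + 1
    hi <- min(jc * slot_count, len)
    coefs <- if (lo > len) numeric(0) else vec[lo:hi]
    coefs <- c(coefs, rep(0, slot_count - length(coefs)))
    chunks[[jc]] <- he_encrypt(coefs, key)
  }
  structure(list(chunks = chunks, slot_count = slot_count, q = q,
                 length = len, n = he_modulus(key)), class = "packed_ct")
}

#' Slot-wise homomorphic addition of packed ciphertexts
#'
#' @param C1,C2 `packed_ct` objects with identical geometry and key.
#' @export
packed_add <- function(C1, C2) {
  stopifnot(inherits(C1, "packed_ct"), inherits(C2, "packed_ct"))
  if (C1$slot_count != C2$slot_count || C1$q != C2$q)
    stop("packed ciphertexts have mismatched slot_count or plaintext modulus")
  if (C1$n != C2$n) stop("packed ciphertexts are under different keys")
  if (C1$length != C2$length)
    stop("packed ciphertexts encode vectors of different lengths")
  chunks <- mapply(he_add, C1$chunks, C2$chunks, SIMPLIFY = FALSE)
  structure(list(chunks = chunks, slot_count = C1$slot_count, q = C1$q,
                 length = C1$length, n = C1$n), class = "packed_ct")
}

#' Decrypt a packed ciphertext back to its slot values
#'
#' Coefficients are reduced modulo `q` after decryption, so sums that stayed
#' below the carrier message space reduce to the slot-wise modular sums.
#' @param C A `packed_ct`.
#' @param key The `he_keypair`.
#' @param reduce Reduce mod `q` (default). With `reduce = FALSE` the raw
#'   integer sums are returned, which the aggregation path uses.
#' @export
packed_decrypt <- function(C, key, reduce = TRUE) {
  stopifnot(inherits(C, "packed_ct"))
  vals <- unlist(lapply(C$chunks, function(ch) he_decrypt(ch, key)))
  if (is.character(vals)) stop("decrypted packed values exceed 2^53")
  vals <- vals[seq_len(C$length)]
  if (reduce) vals %% C$q else vals
}

#' Number of ciphertext objects used per parameter vector
#' @param length Vector length.
#' @param slot_count Slots per packed ciphertext.
#' @export
packed_count <- function(length, slot_count = 64) {
  max(1L, as.integer(ceiling(length / slot_count)))
}
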