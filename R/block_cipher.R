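# 4-round 64-bit diffusion transform: XOR, XNOR, quarter swapping and an F
# feed-function in Feistel position. The state is four 16-bit quarters; odd
# rounds mix with K1-derived keys by XOR, even rounds with K2-derived keys by
# XNOR; each round feeds quarter 0 through F into quarter 1 and then permutes
# the quarters. All steps are exact involutions or tracked permutations, so
# decryption applies the inverses in reverse order. A width-parameterized
# variant (4-bit quarters, 16-bit state) supports exhaustive verification.
#
# This is a faithful re-implementation of a described research construction;
# it carries no security claim and must not be used as production crypto.

# Round constants: fixed "nothing up my sleeve" words (first 16 hex digits of
# the golden ratio and sqrt(2), split into quarters), masked to the width.
.bc_round_consts <- function(width) {
  full <- matrix(c(
    0x9E37, 0x79B9, 0x7F4A, 0x7C15,
    0x6A09, 0xE667, 0xF3BC, 0xC908,
    0xBB67, 0xAE85, 0x84CA, 0xA73B,
    0x3C6E, 0xF372, 0xFE94, 0xF82B), 4, 4, byrow = TRUE)
  mask <- bitwShiftL(1L, width) - 1L
  matrix(bitwAnd(as.integer(full), mask), 4, 4)
}

bc_mask <- function(width) bitwShiftL(1L, width) - 1L

rotl <- function(x, r, width) {
  r <- r %% width
  if (r == 0) return(bitwAnd(x, bc_mask(width)))
  bitwAnd(bitwOr(bitwShiftL(x, r), bitwShiftR(x, width - r)), bc_mask(width))
}

xnor <- function(a, b, width) bitwXor(bitwXor(a, b), bc_mask(width))

# Accept a key as 4 width-bit words, a single hex string, or a numeric < 2^53.
key_words <- function(key, width = 16) {
  mask <- bc_mask(width)
  if (is.character(key) && length(key) == 1) {
    hx <- gsub("^0[xX]", "", key)
    if (!grepl("^[0-9a-fA-F]{1,16}$", hx)) stop("key must be up to 16 hex digits")
    hx <- formatC(hx, width = 16, flag = "0")
    w <- strtoi(substring(hx, c(1, 5, 9, 13), c(4, 8, 12, 16)), 16L)
    return(bitwAnd(w, mask))
  }
  if (is.numeric(key) && length(key) == 4) return(bitwAnd(as.integer(key), mask))
  if (is.numeric(key) && length(key) == 1) {
    v <- key
    w <- integer(4)
    for (j in 4:1) { w[j] <- v %% 65536; v <- v %/% 65536 }
    return(bitwAnd(as.integer(w), mask))
  }
  stop("key must be 4 words, a hex string, or a single number")
}

#' Derive the 4-round key schedule from the two 64-bit keys
#'
#' Round keys for odd rounds come from `K1` XOR a fixed round constant; for
#' even rounds from the XNOR of `K2` with the constant. The schedule is a
#' pure function of `(K1, K2)`.
#'
#' @param K1,K2 64-bit keys: a hex string (up to 16 digits), four 16-bit
#'   words, or a numeric below `2^53`.
#' @param width Quarter width in bits: 16 for the real cipher, 4 for the
#'   reduced exhaustive variant.
#' @return Object of class `bc_schedule`: a 4x4 integer matrix of round-key
#'   quarters plus the width.
#' @export
derive_round_keys <- function(K1, K2, width = 16) {
  k1 <- key_words(K1, width); k2 <- key_words(K2, width)
  rc <- .bc_round_consts(width)
  rk <- matrix(0L, 4, 4)
  for (r in 1:4) {
    rk[r, ] <- if (r %% 2 == 1) bitwXor(k1, rc[r, ])
               else xnor(k2, rc[r, ], width)
  }
  structure(list(round_keys = rk, width = width), class = "bc_schedule")
}

#' The F feed-function of the round transform
#'
#' An add-rotate-xor mix of a quarter with a round-key quarter. Total over
#' the full domain and deterministic; it sits in Feistel position, so it
#' need not be invertible.
#'
#' @param q,rk Integer vectors of `width`-bit words.
#' @param width Word width in bits.
#' @export
f_function <- function(q, rk, width = 16) {
  m <- bc_mask(width) + 1L
  t1 <- (q + rk) %% m
  t2 <- bitwXor(rotl(t1, 5, width), rotl(q, 11, width))
  (t2 + rotl(rk, 3, width)) %% m
}

.bc_perm <- c(3L, 4L, 2L, 1L)      # (q0,q1,q2,q3) -> (q2,q3,q1,q0)
.bc_perm_inv <- c(4L, 3L, 1L, 2L)

as_block_matrix <- function(blocks, width) {
  if (is.matrix(blocks)) {
    stopifnot(ncol(blocks) == 4)
    m <- blocks
  } else {
    stopifnot(length(blocks) == 4)
    m <- matrix(as.integer(blocks), 1, 4)
  }
  mask <- bc_mask(width)
  if (any(m < 0) || any(m > mask))
    stop("block quarters must be in [0, 2^width)")
  storage.mode(m) <- "integer"
  m
}

#' Encrypt / decrypt 64-bit blocks
#'
#' Each block is four `width`-bit quarters. Every round XORs (odd rounds) or
#' XNORs (even rounds) the state with the round key, applies the Feistel step
#' `q1 <- q1 XOR F(q0, rk)`, and permutes the quarters
#' `(q0,q1,q2,q3) -> (q2,q3,q1,q0)`. [decrypt_block()] applies the exact
#' inverses in reverse order, so `decrypt_block(encrypt_block(x))` is the
#' identity on every input.
#'
#' @param blocks A length-4 integer vector (one block) or an n x 4 matrix.
#' @param ks A schedule from [derive_round_keys()].
#' @return Same shape as the input.
#' @export
encrypt_block <- function(blocks, ks) {
  stopifnot(inherits(ks, "bc_schedule"))
  w <- ks$width
  s <- as_block_matrix(blocks, w)
  for (r in 1:4) {
    rk <- ks$round_keys[r, ]
    for (j in 1:4) {
      s[, j] <- if (r %% 2 == 1) bitwXor(s[, j], rk[j])
                else xnor(s[, j], rk[j], w)
    }
    s[, 2] <- bitwXor(s[, 2], f_function(s[, 1], rk[4], w))
    s <- s[, .bc_perm, drop = FALSE]
  }
  if (is.matrix(blocks)) s else s[1, ]
}

#' @rdname encrypt_block
#' @export
decrypt_block <- function(blocks, ks) {
  stopifnot(inherits(ks, "bc_schedule"))
  w <- ks$width
  s <- as_block_matrix(blocks, w)
  for (r in 4:1) {
    rk <- ks$round_keys[r, ]
    s <- s[, .bc_perm_inv, drop = FALSE]
    s[, 2] <- bitwXor(s[, 2], f_function(s[, 1], rk[4], w))
    for (j in 1:4) {
      s[, j] <- if (r %% 2 == 1) bitwXor(s[, j], rk[j])
                else xnor(s[, j], rk[j], w)
    }
  }
  if (is.matrix(blocks)) s else s[1, ]
}

# ---- payload (counter mode) --------------------------------------------

raw_to_words <- function(bytes) {
  n <- length(bytes)
  pad <- (-n) %% 2
  b <- as.integer(c(bytes, raw(pad)))
  matrix(b, ncol = 2, byrow = TRUE) %*% c(256L, 1L)
}

words_to_raw <- function(words) {
  as.raw(rbind(words %/% 256L, words %% 256L))
}

keystream_words <- function(ks, nonce, n_blocks) {
  if (n_blocks == 0) return(matrix(integer(0), 0, 4))
  ctr <- seq_len(n_blocks) - 1L
  blocks <- cbind(rep(nonce[1], n_blocks), rep(nonce[2], n_blocks),
                  ctr %/% 65536L, ctr %% 65536L)
  blocks <- matrix(bitwAnd(as.integer(blocks), bc_mask(ks$width)),
                   n_blocks, 4)
  encrypt_block(blocks, ks)
}

#' Encrypt / decrypt an arbitrary byte payload
#'
#' Counter-mode chaining over 64-bit blocks with an explicit nonce: the block
#' transform encrypts `(nonce, counter)` blocks and the resulting keystream
#' is XORed onto the bytes. Decryption regenerates the keystream from the
#' stored nonce and recovers the exact byte sequence.
#'
#' @param data A raw vector (any length, including empty).
#' @param ks Schedule from [derive_round_keys()] (width 16).
#' @param nonce_seed Integer seed from which the 32-bit nonce is drawn.
#' @return Object of class `bc_payload` with fields `nonce`, `n_bytes`,
#'   `pad_length` and the ciphered `blocks`.
#' @export
encrypt_payload <- function(data, ks, nonce_seed) {
  stopifnot(is.raw(data), inherits(ks, "bc_schedule"), ks$width == 16)
  nonce <- with_seed(nonce_seed, sample.int(65536L, 2) - 1L)
  n_bytes <- length(data)
  n_blocks <- ceiling(n_bytes / 8)
  pad <- n_blocks * 8 - n_bytes
  padded <- c(data, raw(pad))
  words <- matrix(raw_to_words(padded), ncol = 4, byrow = TRUE)
  ksw <- keystream_words(ks, nonce, n_blocks)
  enc <- matrix(bitwXor(as.integer(words), as.integer(ksw)), n_blocks, 4)
  structure(list(nonce = nonce, n_bytes = n_bytes, pad_length = pad,
                 blocks = enc), class = "bc_payload")
}

#' @rdname encrypt_payload
#' @param payload A `bc_payload`.
#' @export
decrypt_payload <- function(payload, ks) {
  stopifnot(inherits(payload, "bc_payload"), inherits(ks, "bc_schedule"))
  n_blocks <- nrow(payload$blocks)
  if (payload$pad_length >= 8 || payload$pad_length < 0 ||
      n_blocks * 8 - payload$pad_length != payload$n_bytes)
    stop("corrupt payload: block count and byte length disagree")
  ksw <- keystream_words(ks, payload$nonce, n_blocks)
  words <- matrix(bitwXor(as.integer(payload$blocks), as.integer(ksw)),
                  n_blocks, 4)
  bytes <- words_to_raw(as.integer(t(words)))
  bytes[seq_len(payload$n_bytes)]
}

#' Serialize a payload to a plain-text file and back
#'
#' Format: header `fedlhe-payload <nonce1> <nonce2> <pad> <n_blocks>`, then
#' one block of four words per line.
#' @param payload A `bc_payload`.
#' @param path File path.
#' @export
write_payload <- function(payload, path) {
  hdr <- sprintf("fedlhe-payload %d %d %d %d", payload$nonce[1],
                 payload$nonce[2], payload$pad_length, nrow(payload$blocks))
  body <- apply(payload$blocks, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_payload
#' @export
read_payload <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(sub("^fedlhe-payload ", "", lines[1]), " ")[[1]])
  if (!startsWith(lines[1], "fedlhe-payload") || length(hdr) != 4)
    stop("not a payload file: ", path)
  n_blocks <- hdr[4]
  if (length(lines) - 1 != n_blocks)
    stop("truncated payload: expected ", n_blocks, " blocks, found ",
         length(lines) - 1)
  blocks <- if (n_blocks == 0) matrix(integer(0), 0, 4) else
    do.call(rbind, lapply(lines[-1], function(l)
      as.integer(strsplit(l, " ", fixed = TRUE)[[1]])))
  structure(list(nonce = hdr[1:2], n_bytes = n_blocks * 8 - hdr[3],
                 pad_length = hdr[3], blocks = blocks), class = "bc_payload")
}

# ---- exponent-key wrapping (request channel) ---------------------------

#' Wrap and unwrap a session key with the RSA-form exponent pair
#'
#' The key-generation exponents `(i, k)` form a multiplicative pair modulo
#' `n`; the request channel uses them to wrap the symmetric session keys of
#' the block transform: `wrap = s^i mod n`, `s = wrap^k mod n`.
#'
#' @param session_key Integer in `[2, n)` (numeric or decimal string).
#' @param key An `he_keypair`.
#' @export
wrap_session_key <- function(session_key, key) {
  stopifnot(inherits(key, "he_keypair"))
  s <- as_decimal(session_key, "session key")
  if (!dec_lt(s, key$n)) stop("session key must be below n")
  cpp_mod_pow(s, key$i, key$n)
}

#' @rdname wrap_session_key
#' @param wrapped Output of `wrap_session_key`.
#' @export
unwrap_session_key <- function(wrapped, key) {
  stopifnot(inherits(key, "he_keypair"))
  cpp_mod_pow(as_decimal(wrapped, "wrapped key"), key$k, key$n)
}
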