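#' @useDynLib fedlhe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- decimal-string plumbing -------------------------------------------

# Coerce numerics / strings to canonical decimal strings. Numerics must be
# non-negative integers representable exactly in a double (< 2^53).
as_decimal <- function(x, what = "value") {
  if (is.character(x)) {
    if (any(!grepl("^[0-9]+$", x)))
      stop(what, " must be a non-negative integer (decimal string)")
    return(sub("^0+(?=.)", "", x, perl = TRUE))
  }
  if (is.numeric(x)) {
    if (any(!is.finite(x)) || any(x < 0) || any(x != trunc(x)))
      stop(what, " must be a non-negative integer")
    if (any(x >= 2^53))
      stop(what, " exceeds 2^53; pass it as a decimal string")
    return(sprintf("%.0f", x))
  }
  stop(what, " must be numeric or a decimal string")
}

dec_to_num <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  n[nchar(x) > 15 & !is.na(n) & n >= 2^53] <- NA_real_
  n
}

dec_lt <- function(a, b) {
  # a < b on canonical decimal strings
  na <- nchar(a); nb <- nchar(b)
  ifelse(na != nb, na < nb, a < b)
}

# ---- key generation (Steps 1-5) ----------------------------------------

#' Generate a homomorphic-encryption key pair from two odd primes
#'
#' Follows the five-step RSA-form key generation: choose distinct odd primes
#' `a` and `b`, set `n = a*b` and the Euler totient `omega = (a-1)*(b-1)`,
#' pick a public exponent `i` with `1 < i < omega` and `gcd(i, omega) = 1`,
#' and compute the private exponent `k = i^-1 mod omega`. The exponent pair
#' `(i, k)` is carried for the request channel (see [wrap_session_key()]);
#' the additive encrypt/add/decrypt layer ([he_encrypt()], [he_add()],
#' [he_decrypt()]) operates over the same modulus `n` with ciphertexts in
#' `[0, n^2)`, so homomorphic addition holds exactly.
#'
#' Either supply both primes explicitly, or supply `bit_length` to draw them
#' deterministically from R's RNG (seed with `set.seed()` or the `seed`
#' argument). Supported modulus range is `n < 2^64` (primes of at most 32
#' bits); the implementation is research-grade, not production cryptography.
#'
#' @param prime_a,prime_b Distinct odd primes (numeric or decimal string).
#' @param pub_exponent Public exponent `i`; chosen automatically if `NULL`.
#' @param bit_length Bits per generated prime (4..32) when primes are drawn.
#' @param seed Optional integer seed used when drawing primes.
#' @param min_bits Minimum admissible size of the modulus: `n >= 2^min_bits`.
#' @return An object of class `he_keypair` with fields `a`, `b`, `n`,
#'   `omega`, `i`, `k` (decimal strings) and `public_key`/`private_key`
#'   sub-lists.
#' @examples
#' kp <- he_keygen(5, 11, pub_exponent = 7)
#' kp$n      # "55"
#' kp$k      # "23"
#' @export
he_keygen <- function(prime_a = NULL, prime_b = NULL, pub_exponent = NULL,
                      bit_length = NULL, seed = NULL, min_bits = 4) {
  if (is.null(prime_a) != is.null(prime_b))
    stop("supply both primes or neither")
  if (is.null(prime_a)) {
    if (is.null(bit_length))
      stop("supply either explicit primes or a bit_length to draw them")
    if (bit_length < 4 || bit_length > 32)
      stop("bit_length per prime must be in [4, 32]")
    if (!is.null(seed)) set.seed(seed)
    prime_a <- cpp_gen_prime(as.integer(bit_length))
    repeat {
      prime_b <- cpp_gen_prime(as.integer(bit_length))
      if (prime_b != prime_a) break
    }
  }
  a <- as_decimal(prime_a, "prime_a")
  b <- as_decimal(prime_b, "prime_b")
  for (p in c(a, b)) {
    if (!cpp_is_prime(p))
      stop("not a prime: ", p)
  }
  if (a == b) stop("primes must be distinct, got a = b = ", a)
  if (a == "2" || b == "2") stop("primes must be odd")
  n <- big_mul_small(a, b)
  omega <- big_mul_small(dec_sub1(a), dec_sub1(b))
  if (dec_lt(n, as_decimal(2^min_bits)))
    stop("modulus n = ", n, " is below the configured minimum 2^", min_bits)
  if (is.null(pub_exponent)) {
    i <- pick_pub_exponent(omega)
  } else {
    i <- as_decimal(pub_exponent, "pub_exponent")
    if (!dec_lt("1", i) || !dec_lt(i, omega))
      stop("public exponent must satisfy 1 < i < omega = ", omega)
    g <- cpp_gcd(i, omega)
    if (g != "1")
      stop("public exponent ", i, " is not coprime with omega = ", omega,
           ": gcd = ", g)
  }
  k <- cpp_modinv(i, omega)
  if (identical(k, ""))
    stop("exponent not invertible modulo omega")
  structure(list(
    a = a, b = b, n = n, omega = omega, i = i, k = k,
    public_key = list(i = i, n = n),
    private_key = list(k = k, n = n, a = a, b = b)
  ), class = "he_keypair")
}

# n = a*b and omega = (a-1)(b-1) both fit in u128; reuse the C mulmod with a
# huge modulus so the product is computed exactly.
big_mul_small <- function(a, b) {
  cpp_mod_mul(a, b, "340282366920938463463374607431768211455")
}

dec_sub1 <- function(x) {
  # x - 1 for a positive decimal string
  n <- dec_to_num(x)
  if (!is.na(n)) return(sprintf("%.0f", n - 1))
  d <- as.integer(strsplit(x, "")[[1]])
  j <- length(d)
  while (d[j] == 0) { d[j] <- 9; j <- j - 1 }
  d[j] <- d[j] - 1
  sub("^0+(?=.)", "", paste(d, collapse = ""), perl = TRUE)
}

pick_pub_exponent <- function(omega) {
  if (dec_lt("65537", omega) && cpp_gcd("65537", omega) == "1")
    return("65537")
  i <- 3
  repeat {
    is <- as_decimal(i)
    if (!dec_lt(is, omega)) stop("no admissible public exponent below omega")
    if (cpp_gcd(is, omega) == "1") return(is)
    i <- i + 2
  }
}

#' @export
print.he_keypair <- function(x, ...) {
  cat("Homomorphic key pair\n")
  cat("  modulus n :", x$n, "\n")
  cat("  omega(n)  :", x$omega, "\n")
  cat("  public  K1: (i =", x$i, ", n)\n")
  cat("  private K2: (k =", x$k, ", n)\n")
  invisible(x)
}

# ---- additive encrypt / add / decrypt ----------------------------------

he_modulus <- function(key) {
  if (inherits(key, "he_keypair")) return(key$n)
  if (is.list(key) && !is.null(key$n)) return(key$n)
  stop("not a homomorphic key")
}

#' Encrypt integer plaintexts additively
#'
#' Plaintexts live in the message space `[0, n)`. Encryption is randomized
#' (R's RNG), so equal plaintexts yield distinct ciphertexts with
#' overwhelming probability; decryption of a sum of ciphertexts returns the
#' modular sum of the plaintexts.
#'
#' @param m Plaintexts: non-negative integers (numeric `< 2^53` or decimal
#'   strings up to `n - 1`).
#' @param key An `he_keypair` or its `public_key` element (needs `n`).
#' @return Object of class `he_ciphertext`: decimal strings with the
#'   modulus attached.
#' @seealso [he_decrypt()], [he_add()], [he_sum()]
#' @export
he_encrypt <- function(m, key) {
  n <- he_modulus(key)
  ms <- as_decimal(m, "plaintext")
  bad <- !dec_lt(ms, n)
  if (any(bad))
    stop("plaintext ", ms[which(bad)[1]],
         " is outside the message space [0, n) with n = ", n)
  # with the factors at hand, exponentiate per prime (RSA-CRT style);
  # identical ciphertexts for identical nonces, just faster
  ct <- if (inherits(key, "he_keypair"))
    cpp_he_encrypt_crt(ms, key$a, key$b)
  else cpp_he_encrypt(ms, n)
  structure(ct, n = n, class = "he_ciphertext")
}

#' Decrypt ciphertexts
#'
#' @param cts `he_ciphertext` vector.
#' @param key `he_keypair` (or its `private_key`, which carries the primes).
#' @param as `"auto"` returns numerics when every plaintext fits exactly in
#'   a double, `"character"` always returns decimal strings.
#' @export
he_decrypt <- function(cts, key, as = c("auto", "character")) {
  as <- match.arg(as)
  priv <- if (inherits(key, "he_keypair")) key$private_key else key
  if (is.null(priv$a) || is.null(priv$b))
    stop("decryption needs the private key (prime factors)")
  n <- big_mul_small(priv$a, priv$b)
  cn <- attr(cts, "n")
  if (!is.null(cn) && cn != n)
    stop("key mismatch: ciphertext modulus ", cn,
         " differs from the key's modulus ", n)
  out <- cpp_he_decrypt(unclass(cts), priv$a, priv$b)
  if (as == "character") return(out)
  num <- dec_to_num(out)
  if (anyNA(num)) out else num
}

#' Homomorphic addition of ciphertexts
#'
#' `decrypt(he_add(E(m1), E(m2))) == (m1 + m2) mod n`, computed without any
#' decryption. Both operands must be encrypted under the same modulus.
#' @param c1,c2 `he_ciphertext` vectors of equal length (or length 1, which
#'   is recycled).
#' @export
he_add <- function(c1, c2) {
  n1 <- attr(c1, "n"); n2 <- attr(c2, "n")
  if (is.null(n1) || is.null(n2)) stop("operands must be he_ciphertext objects")
  if (n1 != n2)
    stop("ciphertexts were produced under different keys (n = ", n1,
         " vs n = ", n2, ")")
  a <- unclass(c1); b <- unclass(c2)
  if (length(a) != length(b)) {
    if (length(a) == 1) a <- rep(a, length(b))
    else if (length(b) == 1) b <- rep(b, length(a))
    else stop("ciphertext vectors differ in length")
  }
  structure(cpp_he_add(a, b, n1), n = n1, class = "he_ciphertext")
}

#' Fold a sequence of ciphertexts with homomorphic addition
#'
#' @param cs A list of `he_ciphertext` vectors (all under the same key).
#' @export
he_sum <- function(cs) {
  if (!is.list(cs) || length(cs) == 0)
    stop("he_sum needs a non-empty list of ciphertexts")
  acc <- cs[[1]]
  if (length(cs) > 1)
    for (j in 2:length(cs)) acc <- he_add(acc, cs[[j]])
  acc
}

#' @export
print.he_ciphertext <- function(x, ...) {
  cat("he_ciphertext:", length(x), "value(s) mod n^2, n =", attr(x, "n"), "\n")
  show <- utils::head(unclass(x), 3)
  cat(" ", paste(substr(show, 1, 24), "..."), sep = "\n  ")
  invisible(x)
}

# ---- fixed-point codec --------------------------------------------------

#' Fixed-point codec for real-valued model weights
#'
#' Bridges real-valued parameter updates into the integer message space.
#' Values are clipped to `[-clip, clip]`, scaled by `2^scale_bits`, rounded,
#' and shifted by an offset so negatives map to non-negative integers
#' (offset-binary). `headroom` is the maximum number of quantized summands
#' the aggregation may add before the codec range could be exceeded.
#'
#' @param scale_bits Power-of-two scale exponent; scale is `2^scale_bits`.
#' @param clip Symmetric clip bound on the encoded reals.
#' @param headroom Maximum number of summands (defaults to 5 clients).
#' @return Object of class `fp_codec`.
#' @export
fp_codec <- function(scale_bits = 16, clip = 8, headroom = 5) {
  stopifnot(scale_bits > 0, clip > 0, headroom >= 1)
  structure(list(
    scale_bits = scale_bits,
    scale = 2^scale_bits,
    clip = clip,
    headroom = headroom,
    offset = round(clip * 2^scale_bits)
  ), class = "fp_codec")
}

#' Quantize reals into the integer message space
#'
#' @param w Numeric vector.
#' @param codec An [fp_codec()].
#' @return Integer-valued numeric vector in `[0, 2*clip*scale]`; attribute
#'   `clipped` counts coordinates that hit the clip bound.
#' @export
fp_quantize <- function(w, codec) {
  stopifnot(inherits(codec, "fp_codec"))
  clipped <- sum(abs(w) > codec$clip)
  wc <- pmin(pmax(w, -codec$clip), codec$clip)
  structure(round(wc * codec$scale) + codec$offset, clipped = clipped)
}

#' Invert [fp_quantize()]
#' @param v Quantized integer vector.
#' @param codec An [fp_codec()].
#' @export
fp_dequantize <- function(v, codec) {
  stopifnot(inherits(codec, "fp_codec"))
  (as.numeric(v) - codec$offset) / codec$scale
}

# Does the codec's worst-case aggregated sum fit below the message bound n?
codec_fits <- function(codec, n) {
  worst <- codec$headroom * (2 * codec$offset)
  n_num <- dec_to_num(n)
  if (!is.na(n_num)) return(worst < n_num)
  TRUE  # n >= 2^53 dwarfs any desk-scale codec range
}

# ---- key / ciphertext serialization ------------------------------------

#' Write and read key files
#'
#' Keys serialize as plain structured text, one `field value` pair per line
#' (fields `a b n omega i k`), bit-exact across platforms.
#' @param key An `he_keypair`.
#' @param path File path.
#' @export
write_he_key <- function(key, path) {
  stopifnot(inherits(key, "he_keypair"))
  writeLines(sprintf("%s %s", c("a", "b", "n", "omega", "i", "k"),
                     c(key$a, key$b, key$n, key$omega, key$i, key$k)), path)
  invisible(path)
}

#' @rdname write_he_key
#' @export
read_he_key <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, " ", fixed = TRUE)
  vals <- stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
  need <- c("a", "b", "n", "omega", "i", "k")
  if (!all(need %in% names(vals)))
    stop("malformed key file: missing field(s) ",
         paste(setdiff(need, names(vals)), collapse = ", "))
  he_keygen(vals[["a"]], vals[["b"]], pub_exponent = vals[["i"]])
}

#' Write and read ciphertext payload files
#'
#' Length-prefixed big-integer sequences as plain text: a header line
#' `fedlhe-ct <n> <count>` followed by one decimal ciphertext per line.
#' @param cts An `he_ciphertext` vector.
#' @param path File path.
#' @export
write_ciphertexts <- function(cts, path) {
  stopifnot(inherits(cts, "he_ciphertext"))
  writeLines(c(sprintf("fedlhe-ct %s %d", attr(cts, "n"), length(cts)),
               unclass(cts)), path)
  invisible(path)
}

#' @rdname write_ciphertexts
#' @export
read_ciphertexts <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (length(hdr) != 3 || hdr[1] != "fedlhe-ct")
    stop("not a ciphertext payload file: ", path)
  count <- as.integer(hdr[3])
  body <- lines[-1]
  if (length(body) != count)
    stop("truncated ciphertext payload: expected ", count, " values, found ",
         length(body))
  structure(body, n = hdr[2], class = "he_ciphertext")
}
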