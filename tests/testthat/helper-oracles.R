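# Independent oracles used across the suite. These are deliberately naive
# (schoolbook digit arithmetic, brute-force searches) and share no code with
# the package's arithmetic paths.

# -- big-decimal arithmetic on digit vectors ------------------------------

.digits <- function(s) as.integer(strsplit(s, "")[[1]])
.undigits <- function(d) {
  s <- paste(d, collapse = "")
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  s
}

dec_cmp_oracle <- function(a, b) {
  a <- sub("^0+(?=.)", "", a, perl = TRUE)
  b <- sub("^0+(?=.)", "", b, perl = TRUE)
  if (nchar(a) != nchar(b)) return(sign(nchar(a) - nchar(b)))
  if (a == b) 0L else if (a < b) -1L else 1L
}

dec_add_oracle <- function(a, b) {
  da <- rev(.digits(a)); db <- rev(.digits(b))
  n <- max(length(da), length(db))
  da <- c(da, rep(0L, n - length(da)))
  db <- c(db, rep(0L, n - length(db)))
  out <- integer(n + 1)
  carry <- 0L
  for (j in seq_len(n)) {
    s <- da[j] + db[j] + carry
    out[j] <- s %% 10L
    carry <- s %/% 10L
  }
  out[n + 1] <- carry
  .undigits(rev(out))
}

dec_sub_oracle <- function(a, b) {  # a >= b
  da <- rev(.digits(a)); db <- rev(.digits(b))
  db <- c(db, rep(0L, length(da) - length(db)))
  out <- integer(length(da))
  borrow <- 0L
  for (j in seq_along(da)) {
    s <- da[j] - db[j] - borrow
    if (s < 0) { s <- s + 10L; borrow <- 1L } else borrow <- 0L
    out[j] <- s
  }
  .undigits(rev(out))
}

# (m1 + m2) mod n for m1, m2 < n
dec_mod_add_oracle <- function(m1, m2, n) {
  s <- dec_add_oracle(m1, m2)
  if (dec_cmp_oracle(s, n) >= 0) s <- dec_sub_oracle(s, n)
  s
}

# Exact decimal string of an integer-valued double (also above 2^53).
dec_of <- function(x) sprintf("%.0f", x)

# Draw an integer-valued double uniformly below frac * n_num (n as numeric).
rand_big_below <- function(n_num, frac = 0.999) {
  dec_of(floor(stats::runif(1) * frac * n_num))
}

# -- brute-force modular inverse -----------------------------------------

brute_force_inverse <- function(i, omega) {
  for (d in seq_len(omega)) {
    if ((i * d) %% omega == 1) return(d)
  }
  NA_integer_
}

small_primes <- c(5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L, 41L, 43L,
                  47L, 53L, 59L, 61L, 67L, 71L, 73L, 79L, 83L, 89L, 97L)

# -- lightweight image fixtures ------------------------------------------

# A stub image set with 1x1 pixels: cheap enough for split/partition tests
# at corpus-scale n.
stub_image_set <- function(labels, mags = NULL) {
  n <- length(labels)
  if (is.null(mags)) mags <- rep(40L, n)
  imgs <- lapply(seq_len(n), function(j)
    fedlhe:::new_synth_image(array(0.5, c(1, 1, 3)), labels[j], mags[j],
                             matrix(numeric(0), 0, 5), sprintf("s%05d", j)))
  fedlhe:::new_image_set(imgs)
}

# A small, well-separated dataset bundle shared by slow-ish tests.
tiny_bundle <- function(n = 160, image_size = 32, seed = 7) {
  generate_dataset(n, image_size = image_size, seed = seed)
}
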