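# Internal helpers shared across modules.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a sub-seed below 2^31 from a master seed and a stream label.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  acc <- 0
  for (p in parts) acc <- (acc * 1000003 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(acc %% 2147483629 + 1)
}

# Sample an H x W x C array at source coordinates (index space) bilinearly.
bilinear_sample <- function(x, ys, xs) {
  d <- dim(x)
  was2d <- length(d) == 2
  if (was2d) { x <- array(x, c(d, 1)); d <- dim(x) }
  h <- d[1]; w <- d[2]; ch <- d[3]
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ys - y0, 0), 1)
  fx <- pmin(pmax(xs - x0, 0), 1)
  th <- length(ys); tw <- length(xs)
  wy <- matrix(fy, th, tw); wx <- matrix(fx, th, tw, byrow = TRUE)
  out <- array(0, c(th, tw, ch))
  for (k in seq_len(ch)) {
    plane <- x[, , k]
    out[, , k] <- plane[y0, x0, drop = FALSE] * (1 - wy) * (1 - wx) +
      plane[y0, x1, drop = FALSE] * (1 - wy) * wx +
      plane[y1, x0, drop = FALSE] * wy * (1 - wx) +
      plane[y1, x1, drop = FALSE] * wy * wx
  }
  if (was2d) out[, , 1] else out
}

# Bilinear resize to th x tw, mapping pixel centres to pixel centres.
bilinear_resize <- function(x, th, tw = th) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  ys <- (seq_len(th) - 0.5) * h / th + 0.5
  xs <- (seq_len(tw) - 0.5) * w / tw + 0.5
  bilinear_sample(x, ys, xs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x) sprintf("%.10g", x)
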