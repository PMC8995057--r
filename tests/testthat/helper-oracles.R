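# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive each quantity by the most literal method
# available, so they share no code path with the implementation.

# Exhaustive Otsu: between-class variance evaluated at every candidate
# threshold by direct partitioning of the pixel vector.
oracle_otsu <- function(img) {
  v <- as.integer(round(as.numeric(img)))
  cands <- sort(unique(v))
  cands <- cands[-length(cands)]
  best_t <- NA_integer_
  best_bcv <- -Inf
  n <- length(v)
  for (t in cands) {
    c0 <- v[v <= t]; c1 <- v[v > t]
    if (!length(c0) || !length(c1)) next
    bcv <- (length(c0) / n) * (length(c1) / n) * (mean(c0) - mean(c1))^2
    if (bcv > best_bcv + 1e-12) {
      best_bcv <- bcv
      best_t <- t
    }
  }
  best_t
}

# Brute-force Euclidean distance to the nearest silver pixel center.
oracle_distmap <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  sil <- which(m == 1L, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m)))
    out[r, cc] <- sqrt(min((sil[, 1] - r)^2 + (sil[, 2] - cc)^2))
  out
}

# Components minus holes via flood labelling: foreground components under
# `conn`, minus enclosed background components under the dual connectivity.
oracle_euler <- function(fg, conn = 4) {
  fg <- matrix(as.logical(fg), nrow(fg), ncol(fg))
  n_fg <- nanomef::label_components(fg, conn)$n
  dual <- if (conn == 4) 8 else 4
  # pad background so the outside is a single component, never a hole
  bg <- !fg
  pad <- matrix(TRUE, nrow(bg) + 2, ncol(bg) + 2)
  pad[2:(nrow(bg) + 1), 2:(ncol(bg) + 1)] <- bg
  n_bg <- nanomef::label_components(pad, dual)$n
  as.integer(n_fg - (n_bg - 1L))
}

# Strip class and attributes down to a plain integer matrix.
plain_mat <- function(m) matrix(as.integer(m), nrow(m), ncol(m))

# Fresh scratch directory per test.
withr_like_tempdir <- function() {
  d <- tempfile("nanomef-test-")
  dir.create(d, recursive = TRUE)
  d
}

# A blobby random mask for topology / distance tests.
random_blob_mask <- function(n = 64, p = 0.45, sigma = 1.5, seed = 1,
                             pixel_size = 2) {
  set.seed(seed)
  raw <- matrix(rbinom(n * n, 1, p), n, n)
  sm <- as.matrix(EBImage::gblur(raw, sigma = sigma))
  binary_mask(matrix(as.integer(sm > p), n, n), pixel_size = pixel_size)
}

# Two silver slabs separated by a vertical gap stripe of width w px.
stripe_mask <- function(w, height = 40, slab = 10, pixel_size = 1) {
  m <- matrix(1L, height, 2 * slab + w)
  m[, (slab + 1):(slab + w)] <- 0L
  binary_mask(m, pixel_size = pixel_size)
}
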