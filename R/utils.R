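# Internal helpers: seed derivation, array smoothing, clipping.

# Derive a reproducible sub-seed from a root seed and a stream name, so
# each generator draws from its own named stream and adding a generator
# never perturbs existing ones. Kept below 2^31 - 1.
.deriveSeed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 69069 + h * 2654435 + 1) %% 2147483647)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Separable 3D Gaussian smoothing with zero padding at the borders.
# Kernel truncated at 3 sigma. Used to turn binary phantoms into
# segmentation-like probability maps.
.gaussianSmooth3D <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(arr, perm)
    dm <- dim(m)
    dim(m) <- c(dm[1], dm[2] * dm[3])
    n <- dm[1]
    # banded convolution as a matrix product (zero padding outside)
    K <- matrix(0, n, n)
    for (j in seq_len(2 * rad + 1)) {
      off <- j - rad - 1L
      idx <- seq_len(n)
      src <- idx + off
      keep <- src >= 1L & src <= n
      K[cbind(idx[keep], src[keep])] <- K[cbind(idx[keep], src[keep])] + k[j]
    }
    m <- K %*% m
    dim(m) <- dm
    arr <- aperm(m, order(perm))
  }
  arr
}

# Collapse trailing singleton axes so 4D files with a degenerate fourth
# axis load as 3D; errors if more than 3 non-singleton axes remain.
.squeezeTo3D <- function(arr) {
  d <- dim(arr)
  if (is.null(d)) stop("input has no dimensions")
  while (length(d) > 3L && d[length(d)] == 1L) d <- d[-length(d)]
  if (length(d) > 3L)
    stop(sprintf("volume has %d non-squeezable axes; expected 3",
                 length(d)))
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))
  dim(arr) <- d
  arr
}
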