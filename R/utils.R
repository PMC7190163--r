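# internal numeric helpers shared by the filtering, segmentation and
# rendering code

# normalised 1-D Gaussian kernel; radius = ceiling(truncate * sigma)
gaussian_kernel1d <- function(sigma, truncate = 4) {
  stopifnot(sigma > 0, truncate > 0)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# reflect indices into 1..n ("abcd" -> "dcba|abcd|dcba"), vectorised
reflect_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  j0 <- (j - 1L) %% (2L * n)
  j0 <- ifelse(j0 >= n, 2L * n - 1L - j0, j0)
  as.integer(j0 + 1L)
}

# convolve an array along one axis with kernel k, reflect boundary.
# Implemented as a dense banded-matrix product on the unfolded array:
# exact, vectorised, and fast at the image sizes this package works at.
convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  n <- d[axis]
  if (n == 1L) return(a)
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in seq_along(k)) {
    src <- reflect_index(seq_len(n) + (o - 1L - r), n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + k[o]
  }
  perm <- c(axis, setdiff(seq_along(d), axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, nrow = n)
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

# separable Gaussian smoothing of a 2-D or 3-D array; sigma is recycled
# per axis, sigma = 0 or axis extent 1 skips that axis
gaussian_smooth <- function(a, sigma, truncate = 4) {
  d <- dim(a)
  nd <- length(d)
  sigma <- rep_len(sigma, nd)
  for (ax in seq_len(nd)) {
    if (sigma[ax] > 0 && d[ax] > 1L) {
      a <- convolve_axis(a, gaussian_kernel1d(sigma[ax], truncate), ax)
    }
  }
  a
}

# named scalar checks used by the parameter constructors
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
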