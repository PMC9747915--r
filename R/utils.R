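# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed; keeps every derived
# seed strictly below 2^31 so it remains a valid R integer.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Column z-score; constant columns map to 0 rather than NaN.
zscore <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
}

# Shift a 3D array by integer offsets (dx, dy, dz), padding with `fill`.
# shift_array(a, d)[i] == a[i - d] where defined.
shift_array <- function(a, d, fill = NA) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dm[ax]
    if (abs(d[ax]) >= n) return(out)
    if (d[ax] >= 0) {
      dst[[ax]] <- (1L + d[ax]):n
      src[[ax]] <- 1L:(n - d[ax])
    } else {
      dst[[ax]] <- 1L:(n + d[ax])
      src[[ax]] <- (1L - d[ax]):n
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable 3D Gaussian smoothing with per-axis sigma in voxel units.
# Zero sigma on an axis leaves that axis untouched. Border handled by
# kernel renormalization (no padding bias).
gaussian_smooth3 <- function(a, sigma_vox) {
  stopifnot(length(sigma_vox) == 3L, all(sigma_vox >= 0))
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    num <- array(0, dim(a))
    den <- array(0, dim(a))
    ones <- array(1, dim(a))
    d <- c(0L, 0L, 0L)
    for (j in seq_along(k)) {
      d[ax] <- j - r - 1L
      num <- num + k[j] * shift_array(a, d, fill = 0)
      den <- den + k[j] * shift_array(ones, d, fill = 0)
    }
    a <- num / den
  }
  a
}

# The 13 unique 3D direction vectors (one per +/- pair), rows (dx, dy, dz).
directions13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  unname(g[keep, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
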