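# Internal numerical utilities shared across modules.
#
# Geometry is carried in mm at the interface level (file and SimNIBS
# convention); every physical computation converts to SI meters on entry.

#' @keywords internal
MU0 <- 4 * pi * 1e-7   # vacuum permeability, H/m

MM_TO_M <- 1e-3

# Row-wise cross product of two n x 3 matrices.
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(x) sqrt(rowSums(x * x))

as_matrix3 <- function(x, what = "points") {
  if (is.null(dim(x))) {
    if (length(x) == 3L) x <- matrix(x, nrow = 1L)
    else stop(sprintf("'%s' must be an n x 3 matrix", what))
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("'%s' must be an n x 3 matrix", what))
  storage.mode(x) <- "double"
  x
}

# Pairwise field sums between observers and weighted point sources.
#
# obs, src: n x 3 and m x 3 positions in meters.  W: m x (3R) matrix holding R
# stacked 3-column weight blocks (one per realization/mode).  Returns, per
# request,
#   inv:   S_inv[i, ]  = sum_j W_j / |obs_i - src_j|
#   cross: S_cross[i,] = sum_j W_j x (obs_i - src_j) / |obs_i - src_j|^3
# both as n x (3R) matrices.  No physical prefactors are applied here.
# Accumulation is chunked over both observers and sources and kept in double
# precision.  If min_dist (m) is given, any observer-source pair closer than
# it raises an error.
pair_field_sums <- function(obs, src, W, want_inv = TRUE, want_cross = TRUE,
                            min_dist = NULL, chunk_obs = 2048L,
                            chunk_src = 8192L) {
  n <- nrow(obs); m <- nrow(src)
  ncolW <- ncol(W)
  if (ncolW %% 3L != 0L) stop("weight matrix must have 3R columns")
  R <- ncolW %/% 3L
  ix <- seq(1L, ncolW, by = 3L); iy <- ix + 1L; iz <- ix + 2L

  S_inv <- if (want_inv) matrix(0, n, ncolW) else NULL
  P <- if (want_cross) matrix(0, n, ncolW) else NULL  # sum K3 * W
  Q <- if (want_cross) matrix(0, n, ncolW) else NULL  # sum K3 * (W x src)

  CW <- NULL
  if (want_cross) {
    # cross(W_j, src_j) per source, per realization block
    CW <- matrix(0, m, ncolW)
    CW[, ix] <- W[, iy] * src[, 3] - W[, iz] * src[, 2]
    CW[, iy] <- W[, iz] * src[, 1] - W[, ix] * src[, 3]
    CW[, iz] <- W[, ix] * src[, 2] - W[, iy] * src[, 1]
  }

  for (o0 in seq(1L, n, by = chunk_obs)) {
    o1 <- min(o0 + chunk_obs - 1L, n)
    oi <- o0:o1
    ox <- obs[oi, 1]; oy <- obs[oi, 2]; oz <- obs[oi, 3]
    for (s0 in seq(1L, m, by = chunk_src)) {
      s1 <- min(s0 + chunk_src - 1L, m)
      si <- s0:s1
      dx <- outer(ox, src[si, 1], "-")
      dy <- outer(oy, src[si, 2], "-")
      dz <- outer(oz, src[si, 3], "-")
      d2 <- dx * dx + dy * dy + dz * dz
      if (!is.null(min_dist) && any(d2 < min_dist^2))
        stop(sprintf("observer within %.3g m of a source point (min distance %.3g m)",
                     min_dist, sqrt(min(d2))))
      Kinv <- 1 / sqrt(d2)
      if (want_inv)
        S_inv[oi, ] <- S_inv[oi, ] + Kinv %*% W[si, , drop = FALSE]
      if (want_cross) {
        K3 <- Kinv / d2
        P[oi, ] <- P[oi, ] + K3 %*% W[si, , drop = FALSE]
        Q[oi, ] <- Q[oi, ] + K3 %*% CW[si, , drop = FALSE]
      }
    }
  }

  out <- list()
  if (want_inv) out$inv <- S_inv
  if (want_cross) {
    S_cross <- matrix(0, n, ncolW)
    S_cross[, ix] <- P[, iy] * obs[, 3] - P[, iz] * obs[, 2] - Q[, ix]
    S_cross[, iy] <- P[, iz] * obs[, 1] - P[, ix] * obs[, 3] - Q[, iy]
    S_cross[, iz] <- P[, ix] * obs[, 2] - P[, iy] * obs[, 1] - Q[, iz]
    out$cross <- S_cross
  }
  out
}

# Lightweight content checksum used to tie session components together.
light_hash <- function(x) {
  r <- serialize(x, NULL, xdr = TRUE)
  v <- as.integer(r)
  # 2 x 32-bit rolling checksums over the byte stream
  n <- length(v)
  w1 <- sum(v * (seq_len(n) %% 251L)) %% 2147483647
  w2 <- sum(v * (seq_len(n) %% 509L)) %% 2147483629
  sprintf("%d-%d-%d", n, w1, w2)
}

# Run an expression with a temporary RNG substream derived from `seed`,
# restoring the caller's RNG state afterwards.
with_substream <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Sub-seed for realization i of master seed `seed`; the i-th draw of a
# sequential stream, hence independent of how many realizations are requested.
substream_seeds <- function(seed, n) {
  with_substream(seed, sample.int(.Machine$integer.max - 1L, n))
}
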