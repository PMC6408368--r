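# thin-plate spline kernel U(r) = r^2 log r (natural log), U(0) = 0
tps_kernel <- function(r) {
  out <- r * 0
  pos <- r > 0
  out[pos] <- r[pos]^2 * log(r[pos])
  out
}

# full (k+3) x (k+3) TPS system matrix [[K P][P' 0]] for a source config
tps_system_matrix <- function(source) {
  k <- nrow(source)
  D <- as.matrix(stats::dist(source))
  K <- tps_kernel(D)
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  L
}

#' Fit a thin-plate-spline warp between two landmark configurations
#'
#' Exact interpolating warp with kernel `U(r) = r^2 log(r)` (natural log,
#' `U(0) = 0`): the unique map sending every source landmark to its target
#' that minimizes integral bending energy. The affine part absorbs
#' translation, rotation and uniform/shear linear trends; the non-affine
#' weights satisfy the side conditions (they sum to zero and are orthogonal
#' to the source coordinates).
#'
#' @param source,target `k x 2` matrices, `k >= 3`, source landmarks not all
#'   collinear and without duplicates.
#' @return Object of class `tps_warp`: `source`, `target`, `affine` (3 x 2:
#'   intercept, x, y coefficients per output coordinate), `weights` (`k x 2`),
#'   and `bending_energy` (`sum(weights * K %*% weights)`, non-negative, zero
#'   iff the map is affine).
#' @export
tps_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  k <- nrow(source)
  if (k < 3L) stop("need at least 3 landmarks")
  if (!identical(dim(source), dim(target))) stop("source/target dimension mismatch")
  if (anyDuplicated(source)) stop("duplicated source landmarks: singular system")
  if (qr(center_config(source))$rank < 2L) stop("collinear source landmarks: singular system")
  L <- tps_system_matrix(source)
  rhs <- rbind(target, matrix(0, 3L, 2L))
  sol <- tryCatch(solve(L, rhs), error = function(e) {
    stop("singular thin-plate-spline system")
  })
  W <- sol[seq_len(k), , drop = FALSE]
  A <- sol[k + 1:3, , drop = FALSE]
  K <- L[seq_len(k), seq_len(k)]
  be <- sum(W * (K %*% W))
  if (be < 0 && be > -1e-9) be <- 0
  structure(
    list(source = source, target = target, affine = A, weights = W,
         bending_energy = be),
    class = "tps_warp"
  )
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("<tps_warp> %d landmarks, bending energy %.6g\n",
              nrow(x$source), x$bending_energy))
  invisible(x)
}

#' Evaluate a thin-plate-spline warp at query points
#'
#' @param warp A [tps_fit()] result.
#' @param points `m x 2` matrix of query points.
#' @return `m x 2` matrix of warped points; evaluating at the source
#'   landmarks returns the target landmarks.
#' @export
tps_evaluate <- function(warp, points) {
  stopifnot(inherits(warp, "tps_warp"))
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("query points must have two columns")
  aff <- cbind(1, points) %*% warp$affine
  k <- nrow(warp$source)
  # distances from each query point to each source landmark
  d <- sqrt(outer(points[, 1], warp$source[, 1], "-")^2 +
            outer(points[, 2], warp$source[, 2], "-")^2)
  aff + tps_kernel(d) %*% warp$weights
}

#' Deformation grid at a position along a principal component
#'
#' Reconstructs the shape at a chosen score along one PC of the tangent-space
#' PCA (`mean + score * mag * eigenvector`), fits a thin-plate spline from
#' the mean shape to it, and warps a rectangular reference grid bounding the
#' mean shape (expanded by 10%). These are the grids used to interpret
#' morphology along morphospace axes.
#'
#' @param mean_shape `p x 2` mean configuration (from [gpa()]).
#' @param pca A [pca_covariance()] result on the tangent coordinates.
#' @param axis PC index.
#' @param score Position along the axis; must lie within the observed score
#'   range times 1.25.
#' @param n_grid Grid resolution (cells per side; default 24).
#' @param mag Magnification of the reconstructed deformation (default 1).
#' @return Object of class `deformation_grid`: `grid` (warped grid points),
#'   `reference_grid`, `nx`, `ny`, `shape` (the reconstructed configuration),
#'   `mean_shape`, `axis`, `score`.
#' @export
deformation_grid <- function(mean_shape, pca, axis, score, n_grid = 24L, mag = 1) {
  stopifnot(inherits(pca, "pca_result"))
  if (axis < 1L || axis > ncol(pca$scores)) stop("`axis` out of range")
  rng <- max(abs(pca$scores[, axis]))
  if (abs(score) > 1.25 * rng + 1e-12) {
    stop(sprintf("|score| exceeds 1.25 x observed range (%.4g) on PC%d", rng, axis))
  }
  target_flat <- pca$center + score * mag * pca$eigenvectors[, axis]
  shape <- matrix(target_flat, ncol = 2L, byrow = TRUE)
  warp <- tps_fit(mean_shape, shape)

  xr <- range(mean_shape[, 1]); yr <- range(mean_shape[, 2])
  xr <- xr + c(-1, 1) * 0.1 * diff(xr)
  yr <- yr + c(-1, 1) * 0.1 * diff(yr)
  gx <- seq(xr[1], xr[2], length.out = n_grid + 1L)
  gy <- seq(yr[1], yr[2], length.out = n_grid + 1L)
  ref <- as.matrix(expand.grid(x = gx, y = gy))
  structure(
    list(grid = tps_evaluate(warp, ref), reference_grid = ref,
         nx = n_grid + 1L, ny = n_grid + 1L, shape = shape,
         mean_shape = mean_shape, axis = axis, score = score),
    class = "deformation_grid"
  )
}
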