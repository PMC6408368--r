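#' Principal component analysis from the covariance matrix
#'
#' Eigendecomposition of the sample covariance matrix (n - 1 denominator) of
#' the input rows — tangent-space shape coordinates or log10 measurements.
#' Eigenvector signs are fixed so each column's largest-magnitude entry is
#' positive, making results deterministic. Eigenvalues are clipped at zero
#' (rank-deficient shape data produce trailing numerically-negative values).
#'
#' @param x Numeric matrix, specimens in rows (>= 2), no missing values.
#' @param ids Optional specimen ids (defaults to rownames).
#' @return Object of class `pca_result`: `scores` (`n x p`,
#'   `(x - center) %*% eigenvectors`), `eigenvectors` (orthonormal columns),
#'   `eigenvalues` (descending, >= 0), `variance_fraction` (sums to 1),
#'   `center`, `ids`.
#' @export
pca_covariance <- function(x, ids = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  if (anyNA(x)) stop("missing values not allowed")
  if (is.null(ids)) ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  center <- colMeans(x)
  C <- stats::cov(x)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  if (sum(vals) <= 0) stop("rank-0 data: no variance to decompose")
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- sweep(x, 2L, center) %*% vecs
  colnames(scores) <- colnames(vecs) <- paste0("PC", seq_len(ncol(vecs)))
  rownames(scores) <- ids
  structure(
    list(scores = scores, eigenvectors = vecs, eigenvalues = vals,
         variance_fraction = vals / sum(vals), center = center, ids = ids),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("<pca_result> %d specimens x %d variables\n",
              nrow(x$scores), ncol(x$scores)))
  cat("variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$variance_fraction[seq_len(k)]),
            collapse = ", "),
      if (length(x$eigenvalues) > k) "...\n" else "\n")
  invisible(x)
}

#' Log10-transform a linear measurement table
#'
#' Builds the `n x 8` matrix of base-10 logs in the fixed column order
#' ML, MW, MD, HNF, WNF, LLTC, LMTC, WTS, the input to the covariance PCA of
#' the linear dataset. Under pure size variation the log transform makes PC1
#' an isometric size axis (near-equal loadings), which is why PC1 is excluded
#' from classification in linear mode.
#'
#' @param records Data.frame with `specimen_id` and the eight measurement
#'   columns, all strictly positive (as from [read_measurements()]).
#' @return Numeric matrix with specimen ids as rownames.
#' @export
log10_measurements <- function(records) {
  missing <- setdiff(c("specimen_id", MEASUREMENT_VARS), names(records))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  for (v in MEASUREMENT_VARS) {
    bad <- !is.finite(records[[v]]) | records[[v]] <= 0
    if (any(bad)) {
      stop(sprintf("non-positive %s for specimen(s): %s",
                   v, paste(records$specimen_id[bad], collapse = ", ")))
    }
  }
  m <- log10(as.matrix(records[, MEASUREMENT_VARS]))
  rownames(m) <- records$specimen_id
  m
}

#' Select a contiguous PC prefix for classification
#'
#' Landmark-mode models use PCs `1..length`; linear-mode models use PCs
#' `2..(length + 1)` because PC1 of log-measurement data is the size axis and
#' is not considered.
#'
#' @param pca A [pca_result] object.
#' @param mode `"landmark"` or `"linear"`.
#' @param length Prefix length (0 gives an empty selection, i.e. an
#'   intercept-only model).
#' @return Integer vector of component indices.
#' @export
select_pcs <- function(pca, mode = c("landmark", "linear"), length) {
  mode <- match.arg(mode)
  stopifnot(inherits(pca, "pca_result"))
  if (length < 0L) stop("`length` must be non-negative")
  start <- if (mode == "landmark") 1L else 2L
  idx <- seq_len(length) + start - 1L
  if (length > 0L && max(idx) > ncol(pca$scores)) {
    stop(sprintf("requested PCs up to %d but only %d available",
                 max(idx), ncol(pca$scores)))
  }
  idx
}
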