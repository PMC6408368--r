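#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid — the size measure removed by Procrustes superimposition.
#'
#' @param config Numeric matrix (>= 2 rows, 2 columns).
#' @return Positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2L) stop("need at least 2 points")
  centred <- sweep(config, 2L, colMeans(config))
  cs <- sqrt(sum(centred^2))
  if (cs < .Machine$double.eps) stop("degenerate configuration: all points coincident")
  cs
}

center_config <- function(config) sweep(config, 2L, colMeans(config))

rotate2d <- function(config, theta) {
  # counter-clockwise rotation of row-vector points by theta
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2L, 2L)
  config %*% R
}

#' Optimal rotation of one centred configuration onto another
#'
#' Closed-form least-squares rotation (no reflection, no scaling):
#' `theta = atan2(sum(x*y' - y*x'), sum(x*x' + y*y'))`, minimizing the summed
#' squared distance between the rotated source and the target.
#'
#' @param source,target Centred matrices with equal landmark counts.
#' @return List with `theta` (radians), `rss` (residual sum of squares), and
#'   `rotated` (the rotated source).
#' @export
optimal_rotation_2d <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!identical(dim(source), dim(target))) {
    stop("source and target must have the same landmark count")
  }
  num <- sum(source[, 1] * target[, 2] - source[, 2] * target[, 1])
  den <- sum(source[, 1] * target[, 1] + source[, 2] * target[, 2])
  theta <- atan2(num, den)
  rotated <- rotate2d(source, theta)
  list(theta = theta, rss = sum((rotated - target)^2), rotated = rotated)
}

# stack list of shapes / matrices into p x 2 x n array
shapes_to_array <- function(shapes) {
  if (is.array(shapes) && length(dim(shapes)) == 3L) return(shapes)
  mats <- lapply(shapes, function(s) {
    if (inherits(s, "specimen_shape")) s$points else as.matrix(s)
  })
  p <- unique(vapply(mats, nrow, integer(1)))
  if (length(p) != 1L) stop("configurations have unequal landmark counts")
  arr <- array(NA_real_, c(p, 2L, length(mats)))
  for (i in seq_along(mats)) arr[, , i] <- mats[[i]]
  ids <- if (inherits(shapes[[1]], "specimen_shape")) {
    vapply(shapes, function(s) s$specimen_id, character(1))
  } else if (!is.null(names(shapes))) names(shapes) else as.character(seq_along(mats))
  dimnames(arr) <- list(NULL, c("x", "y"), ids)
  arr
}

#' Generalized Procrustes analysis with optional sliding semilandmarks
#'
#' Removes translation, scale and rotation from a set of 2D configurations by
#' iterating: align every configuration to the current mean; if a slider
#' table is supplied, let each semilandmark slide along the chord between its
#' neighbours to minimize the chosen criterion against the mean (then
#' re-normalize and re-rotate); recompute the mean and normalize it to unit
#' centroid size. Iteration stops when the mean shape changes by less than
#' `tol` (root summed squared difference) or at `max_iter` (flagged, not
#' fatal). Reflections are never estimated: side standardization is an
#' explicit upstream step ([mirror_reflect()]).
#'
#' With `criterion = "bending_energy"` each configuration's sliding
#' displacements solve the thin-plate-spline normal equations against the
#' mean (minimum-bending-energy sliding); `"procrustes_distance"` projects
#' each semilandmark orthogonally toward the mean along its tangent. A
#' singular bending-energy system falls back to the Procrustes-distance
#' criterion with a warning.
#'
#' @param shapes List of [specimen_shape()] objects / matrices, or a
#'   `p x 2 x n` array.
#' @param sliders Optional [slider_table()].
#' @param max_iter,tol Convergence controls on the mean shape.
#' @param criterion Sliding criterion, `"bending_energy"` (default) or
#'   `"procrustes_distance"`.
#' @param slide_iter Number of leading GPA iterations during which sliding is
#'   applied (default 5, the practice of standard geometric-morphometrics
#'   toolchains); afterwards plain GPA runs to convergence. Sliding on every
#'   iteration is not contractive — semilandmarks can drift indefinitely
#'   along their tangents as the mean follows them — so a cap is required
#'   for a well-defined result.
#' @return An object of class `aligned_dataset`: `coords` (`p x 2 x n`, each
#'   configuration centred with unit centroid size), `centroid_sizes` (the
#'   original sizes), `mean_shape` (centred, unit centroid size),
#'   `n_iterations`, `objective_trace` (summed squared Procrustes deviation
#'   from the mean after each iteration), `converged`, `ids`.
#' @export
gpa <- function(shapes, sliders = NULL, max_iter = 100L, tol = 1e-8,
                criterion = c("bending_energy", "procrustes_distance"),
                slide_iter = 5L) {
  criterion <- match.arg(criterion)
  arr <- shapes_to_array(shapes)
  n <- dim(arr)[3L]; p <- dim(arr)[1L]
  if (n < 2L) stop("need at least 2 configurations")
  ids <- dimnames(arr)[[3L]]

  cs <- numeric(n)
  for (i in seq_len(n)) {
    cs[i] <- centroid_size(arr[, , i])
    arr[, , i] <- center_config(arr[, , i]) / cs[i]
  }

  mean_shape <- arr[, , 1L]
  mean_shape <- mean_shape / sqrt(sum(mean_shape^2))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      arr[, , i] <- optimal_rotation_2d(arr[, , i], mean_shape)$rotated
    }
    if (!is.null(sliders) && nrow(sliders) > 0L && iter <= slide_iter) {
      arr <- slide_semilandmarks(arr, mean_shape, sliders, criterion)
      for (i in seq_len(n)) {
        cfg <- center_config(arr[, , i])
        cfg <- cfg / sqrt(sum(cfg^2))
        arr[, , i] <- optimal_rotation_2d(cfg, mean_shape)$rotated
      }
    }
    new_mean <- apply(arr, c(1L, 2L), mean)
    new_mean <- center_config(new_mean)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    # align the new mean to the old so the trace measures shape change only
    new_mean <- optimal_rotation_2d(new_mean, mean_shape)$rotated
    trace <- c(trace, sum(sweep(arr, c(1L, 2L), new_mean)^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("GPA did not converge in %d iterations (last mean change above tol)", max_iter))
  }
  # final alignment to the converged mean
  for (i in seq_len(n)) {
    arr[, , i] <- optimal_rotation_2d(arr[, , i], mean_shape)$rotated
  }
  structure(
    list(coords = arr, centroid_sizes = stats::setNames(cs, ids),
         mean_shape = mean_shape, n_iterations = iter,
         objective_trace = trace, converged = converged, ids = ids,
         sliders = sliders, criterion = if (is.null(sliders)) NA_character_ else criterion),
    class = "aligned_dataset"
  )
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf(
    "<aligned_dataset> %d specimens x %d landmarks; %d GPA iteration(s), %s\n",
    dim(x$coords)[3L], dim(x$coords)[1L], x$n_iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Bending-energy matrix of a reference configuration
#'
#' Upper-left `k x k` block of the inverse thin-plate-spline system matrix of
#' the reference: the quadratic form `t(v) %*% B %*% v` gives the bending
#' energy of a map sending the reference to any target whose coordinate
#' vector is `v` (per coordinate, summed over x and y). It is the same matrix
#' that [tps_fit()] uses, annihilates affine functions of the reference, and
#' drives minimum-bending-energy sliding.
#'
#' @param reference Numeric `k x 2` matrix, `k >= 3`, not all collinear.
#' @return `k x k` symmetric positive semi-definite matrix.
#' @export
bending_energy_matrix <- function(reference) {
  reference <- as.matrix(reference)
  k <- nrow(reference)
  if (k < 3L) stop("need at least 3 reference landmarks")
  L <- tps_system_matrix(reference)
  Linv <- solve(L)
  B <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  (B + t(B)) / 2
}

#' Slide semilandmarks along their tangents against a reference
#'
#' Each semilandmark is displaced only along the unit chord between its
#' "before" and "after" neighbours in its own configuration. Displacements
#' minimize either the thin-plate-spline bending energy of the map from the
#' reference to the slid configuration (solved jointly for all sliders), or
#' the summed squared distance to the reference (independent orthogonal
#' projections). Fixed landmarks never move, and the criterion value cannot
#' increase (exact quadratic minimization).
#'
#' @param configs `p x 2 x n` array (or list) of configurations already
#'   aligned to `reference`.
#' @param reference `p x 2` reference (typically the current GPA mean).
#' @param sliders A [slider_table()].
#' @param criterion `"bending_energy"` or `"procrustes_distance"`.
#' @return The updated array, same dimensions.
#' @export
slide_semilandmarks <- function(configs, reference, sliders,
                                criterion = c("bending_energy", "procrustes_distance")) {
  criterion <- match.arg(criterion)
  arr <- shapes_to_array(configs)
  p <- dim(arr)[1L]; n <- dim(arr)[3L]
  if (nrow(sliders) == 0L) return(arr)
  if (max(sliders) > p) stop("slider indices exceed landmark count")
  sl <- sliders[, "slider"]; bf <- sliders[, "before"]; af <- sliders[, "after"]
  m <- length(sl)

  B <- NULL
  if (criterion == "bending_energy") {
    B <- tryCatch(bending_energy_matrix(reference), error = function(e) NULL)
    if (is.null(B)) {
      warning("singular bending-energy system; falling back to procrustes_distance sliding")
      criterion <- "procrustes_distance"
    }
  }

  for (i in seq_len(n)) {
    cfg <- arr[, , i]
    tang <- cfg[af, , drop = FALSE] - cfg[bf, , drop = FALSE]
    tlen <- sqrt(rowSums(tang^2))
    ok <- tlen > .Machine$double.eps
    tang[ok, ] <- tang[ok, , drop = FALSE] / tlen[ok]
    tang[!ok, ] <- 0

    if (criterion == "procrustes_distance") {
      lambda <- rowSums((reference[sl, , drop = FALSE] - cfg[sl, , drop = FALSE]) * tang)
    } else {
      # U maps slider displacements into coordinate space, one column per slider
      Ux <- matrix(0, p, m); Uy <- matrix(0, p, m)
      Ux[cbind(sl, seq_len(m))] <- tang[, 1]
      Uy[cbind(sl, seq_len(m))] <- tang[, 2]
      A <- crossprod(Ux, B %*% Ux) + crossprod(Uy, B %*% Uy)
      b <- -(crossprod(Ux, B %*% cfg[, 1]) + crossprod(Uy, B %*% cfg[, 2]))
      # smooth tangential reparameterizations cost almost no bending energy,
      # so A is near-singular along them; a tolerance pseudo-inverse keeps
      # those soft modes from amplifying digitizing noise
      ea <- eigen((A + t(A)) / 2, symmetric = TRUE)
      keep <- ea$values > max(ea$values, 0) * 1e-8
      if (!any(keep)) {
        lambda <- rowSums((reference[sl, , drop = FALSE] - cfg[sl, , drop = FALSE]) * tang)
      } else {
        V <- ea$vectors[, keep, drop = FALSE]
        lambda <- drop(V %*% ((crossprod(V, b)) / ea$values[keep]))
      }
    }
    # a slider may not overrun its neighbours: scale the whole step so each
    # displacement stays under half the distance to the nearer neighbour
    # (scaling a quadratic-minimizing step by alpha in (0,1] still decreases
    # the criterion)
    cap <- 0.5 * pmin(sqrt(rowSums((cfg[sl, , drop = FALSE] - cfg[bf, , drop = FALSE])^2)),
                      sqrt(rowSums((cfg[af, , drop = FALSE] - cfg[sl, , drop = FALSE])^2)))
    big <- abs(lambda) > cap
    alpha <- if (any(big)) min(cap[big] / abs(lambda[big])) else 1
    cfg[sl, ] <- cfg[sl, , drop = FALSE] + (alpha * lambda) * tang
    arr[, , i] <- cfg
  }
  arr
}

#' Project aligned configurations into the tangent space at the mean
#'
#' Orthogonal projection of each (unit-centroid-size, flattened)
#' configuration onto the plane tangent to the pre-shape sphere at the mean
#' shape, stabilizing the subsequent PCA. Rows are flattened as
#' `(x1, y1, x2, y2, ...)` and named by specimen id; each projected row minus
#' the mean is orthogonal to the mean vector.
#'
#' @param aligned An [gpa()] result.
#' @return `n x 2p` numeric matrix of tangent-space shape coordinates.
#' @export
tangent_projection <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_dataset"))
  arr <- aligned$coords
  n <- dim(arr)[3L]
  m <- as.numeric(t(aligned$mean_shape))      # (x1,y1,x2,y2,...)
  m_hat <- m / sqrt(sum(m^2))
  out <- matrix(NA_real_, n, length(m))
  for (i in seq_len(n)) {
    z <- as.numeric(t(arr[, , i]))
    out[i, ] <- m_hat + (z - sum(z * m_hat) * m_hat)
  }
  rownames(out) <- aligned$ids
  out
}

#' Procrustes distance between two configurations
#'
#' Square root of the minimal summed squared difference after centring,
#' scaling to unit centroid size, and optimal rotation.
#'
#' @param a,b Configurations with equal landmark counts.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- center_config(as.matrix(a)); a <- a / sqrt(sum(a^2))
  b <- center_config(as.matrix(b)); b <- b / sqrt(sum(b^2))
  sqrt(optimal_rotation_2d(a, b)$rss)
}
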