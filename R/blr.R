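#' Binomial logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with intercept, coded so that class 1 is
#' terrestrial/bipedal saltating and class 0 arboreal/scansorial throughout
#' the package. Convergence requires the largest absolute coefficient change
#' to fall below `tol` within `max_iter` Newton (IRLS) steps. Quasi-complete
#' or complete separation — the typical failure mode when too many PCs are
#' offered to a small sample — is flagged when any fitted probability ends
#' within 1e-8 of 0 or 1 or any slope magnitude exceeds 15 at termination.
#' The slope threshold is applied on internally standardized predictors
#' (columns scaled to unit SD before fitting), since raw tangent-space PC
#' scores have arbitrarily small scale and would make any fixed coefficient
#' cutoff meaningless; reported coefficients are on the original scale. Deviance is -2 x Bernoulli log-likelihood; the null model is
#' intercept-only; AIC = residual deviance + 2 x (number of coefficients).
#'
#' @param x Design matrix (predictors only, no intercept column), or `NULL` /
#'   zero-column matrix for an intercept-only fit.
#' @param y 0/1 response with both classes present; `n >= p + 1`.
#' @param max_iter,tol IRLS controls.
#' @return Object of class `blr_fit`: `coefficients` (intercept first),
#'   `fitted`, `converged`, `separation_detected`, `null_deviance`,
#'   `residual_deviance`, `aic`, `n_observations`, `iterations`.
#' @export
fit_blr <- function(x, y, max_iter = 100L, tol = 1e-8) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("`y` must be coded 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present in `y`")
  if (is.null(x)) x <- matrix(numeric(0), length(y), 0L)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("`x` and `y` sizes differ")
  n <- length(y)
  sds <- if (ncol(x)) apply(x, 2L, stats::sd) else numeric(0)
  sds[!is.finite(sds) | sds <= 0] <- 1
  xs <- if (ncol(x)) sweep(x, 2L, sds, "/") else x
  X <- cbind(`(Intercept)` = 1, xs)
  pcoef <- ncol(X)
  if (n < pcoef) stop("more coefficients than observations")

  beta <- numeric(pcoef)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XtWX <- crossprod(X, X * w)
    step <- tryCatch(solve(XtWX, crossprod(X, y - p)),
                     error = function(e) NULL)
    if (is.null(step)) break  # singular information: leave unconverged
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  p <- stats::plogis(drop(X %*% beta))
  slopes <- beta[-1L]
  separation <- any(p < 1e-8 | p > 1 - 1e-8) ||
    (length(slopes) > 0 && max(abs(slopes)) > 15)

  loglik <- function(prob) sum(y * log(pmax(prob, 1e-300)) +
                               (1 - y) * log(pmax(1 - prob, 1e-300)))
  dev <- -2 * loglik(p)
  p0 <- mean(y)
  null_dev <- -2 * loglik(rep(p0, n))
  # back-transform to the original predictor scale
  if (length(slopes)) beta[-1L] <- beta[-1L] / sds
  names(beta) <- colnames(X)
  structure(
    list(coefficients = beta, fitted = p, converged = converged,
         separation_detected = separation, null_deviance = null_dev,
         residual_deviance = dev, aic = dev + 2 * pcoef,
         n_observations = n, iterations = iter),
    class = "blr_fit"
  )
}

#' @export
print.blr_fit <- function(x, ...) {
  cat(sprintf(
    "<blr_fit> %d obs, %d coefficient(s); deviance %.3f (null %.3f), AIC %.3f%s%s\n",
    x$n_observations, length(x$coefficients), x$residual_deviance,
    x$null_deviance, x$aic,
    if (!x$converged) " [not converged]" else "",
    if (x$separation_detected) " [separation]" else ""
  ))
  invisible(x)
}

#' Iterative PC-prefix logistic model search with AIC selection
#'
#' The classification procedure at the heart of the pipeline: starting from
#' one component, fit a logistic model of ecology on a growing contiguous PC
#' prefix (landmark mode: PCs 1..m; linear mode: PCs 2..(m+1), skipping the
#' size axis), stopping the first time the data fail to produce a reliable
#' fit — IRLS non-convergence or separation. The preferred model is the
#' reliable attempt with the lowest AIC; if no attempt is reliable the search
#' reports failure (the behaviour seen for some views of real data) rather
#' than forcing a model. The preferred fit then predicts, for every
#' unassigned specimen (fossils and extant taxa of unknown habit), the
#' probability of terrestrial/bipedal-saltating ecology.
#'
#' Training rows are the extant specimens with an assigned ecology bin; the
#' prefix length is capped at `min(n_train - 2, max_prefix, available PCs)`
#' to keep fits away from saturation.
#'
#' @param pca A [pca_result] whose score rows are named by specimen id.
#' @param metadata Metadata data.frame (see [read_metadata()]) covering at
#'   least the scored specimens.
#' @param mode `"landmark"` or `"linear"`.
#' @param max_prefix Upper cap on prefix length (default 10).
#' @param max_iter,tol Passed to [fit_blr()].
#' @return Object of class `blr_search`: `attempts` (list of [fit_blr()]
#'   results with `$pc_indices`, ordered by prefix length), `preferred`
#'   (or `NULL`), `failure_reason`, `predictions` (data.frame `specimen_id`,
#'   `probability`), `training_ids`, `mode`.
#' @export
pc_search <- function(pca, metadata, mode = c("landmark", "linear"),
                      max_prefix = 10L, max_iter = 100L, tol = 1e-8) {
  mode <- match.arg(mode)
  stopifnot(inherits(pca, "pca_result"))
  md <- metadata[match(pca$ids, metadata$specimen_id), , drop = FALSE]
  if (anyNA(md$specimen_id)) {
    stop("metadata missing for specimen(s): ",
         paste(setdiff(pca$ids, metadata$specimen_id), collapse = ", "))
  }
  train <- !md$is_fossil & md$ecology_bin != "unassigned"
  y <- as.numeric(md$ecology_bin[train] == "terrestrial_saltating")
  if (sum(y == 0) < 2L || sum(y == 1) < 2L) {
    stop("need at least 2 training specimens per ecology bin")
  }
  scores <- pca$scores
  avail <- ncol(scores) - (mode == "linear")
  cap <- min(sum(train) - 2L, max_prefix, avail)
  if (cap < 1L) stop("too few training specimens or components for any model")

  attempts <- list()
  for (m in seq_len(cap)) {
    idx <- select_pcs(pca, mode, m)
    fit <- fit_blr(scores[train, idx, drop = FALSE], y,
                   max_iter = max_iter, tol = tol)
    fit$pc_indices <- idx
    attempts[[m]] <- fit
    if (!fit$converged || fit$separation_detected) break
  }
  reliable <- vapply(attempts, function(f) f$converged && !f$separation_detected,
                     logical(1))
  preferred <- NULL
  failure_reason <- NULL
  if (any(reliable)) {
    aics <- vapply(attempts, function(f) f$aic, numeric(1))
    aics[!reliable] <- Inf
    preferred <- attempts[[which.min(aics)]]
  } else {
    failure_reason <- "no convergent model"
  }

  predictions <- data.frame(specimen_id = character(), probability = numeric(),
                            stringsAsFactors = FALSE)
  unassigned <- which(!train)
  if (!is.null(preferred) && length(unassigned)) {
    predictions <- predict_unassigned(
      preferred, scores[unassigned, , drop = FALSE],
      ids = pca$ids[unassigned]
    )
  }
  structure(
    list(attempts = attempts, preferred = preferred,
         failure_reason = failure_reason, predictions = predictions,
         training_ids = pca$ids[train], mode = mode),
    class = "blr_search"
  )
}

#' @export
print.blr_search <- function(x, ...) {
  cat(sprintf("<blr_search> mode=%s, %d attempt(s)\n", x$mode, length(x$attempts)))
  if (is.null(x$preferred)) {
    cat("preferred model: none (", x$failure_reason, ")\n", sep = "")
  } else {
    cat(sprintf("preferred model: PCs %s, AIC %.3f, deviance %.3f (null %.3f)\n",
                paste(range(x$preferred$pc_indices), collapse = "-"),
                x$preferred$aic, x$preferred$residual_deviance,
                x$preferred$null_deviance))
    if (nrow(x$predictions)) {
      cat("predictions (1 = terrestrial/bipedal saltating):\n")
      print(x$predictions, row.names = FALSE, digits = 3)
    }
  }
  invisible(x)
}

#' Predict ecology probabilities for unassigned specimens
#'
#' Evaluates the logistic model on the fit's PC subset:
#' `p = 1 / (1 + exp(-(b0 + scores %*% b)))`, oriented so values approaching
#' 1 indicate terrestrial/bipedal-saltating and values approaching 0
#' arboreal/scansorial ecology.
#'
#' @param fit A [fit_blr()] result carrying `pc_indices` (as produced inside
#'   [pc_search()]).
#' @param scores Score matrix for the unassigned specimens containing every
#'   PC the fit uses.
#' @param ids Optional specimen ids (defaults to rownames).
#' @return Data.frame with `specimen_id` and `probability`.
#' @export
predict_unassigned <- function(fit, scores, ids = NULL) {
  stopifnot(inherits(fit, "blr_fit"))
  if (is.null(fit$pc_indices)) stop("fit carries no PC subset")
  scores <- as.matrix(scores)
  if (max(fit$pc_indices, 0L) > ncol(scores)) {
    stop("scores lack PC(s) required by the fit")
  }
  if (is.null(ids)) ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(scores)))
  eta <- drop(cbind(1, scores[, fit$pc_indices, drop = FALSE]) %*% fit$coefficients)
  data.frame(specimen_id = ids, probability = stats::plogis(eta),
             stringsAsFactors = FALSE, row.names = NULL)
}
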