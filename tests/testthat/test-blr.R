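test_that("intercept-only balanced fit has the closed-form deviance", {
  y <- rep(c(0, 1), each = 5)
  f <- fit_blr(NULL, y)
  expect_true(f$converged)
  expect_equal(unname(f$fitted), rep(0.5, 10), tolerance = 1e-9)
  expect_equal(f$residual_deviance, 2 * 10 * log(2), tolerance = 1e-9)
  expect_equal(f$null_deviance, f$residual_deviance, tolerance = 1e-9)
  expect_equal(f$aic, f$residual_deviance + 2, tolerance = 1e-9)
})

test_that("AIC always equals residual deviance plus twice the coefficient count", {
  set.seed(60)
  for (k in 1:3) {
    x <- matrix(rnorm(30 * k), 30, k)
    y <- rbinom(30, 1, plogis(x[, 1]))
    if (length(unique(y)) < 2) next
    f <- fit_blr(x, y)
    expect_equal(f$aic, f$residual_deviance + 2 * (k + 1), tolerance = 1e-12)
  }
})

test_that("IRLS reproduces glm estimates on well-behaved data", {
  set.seed(61)
  x <- matrix(rnorm(40 * 2), 40, 2)
  y <- rbinom(40, 1, plogis(0.5 + x[, 1] - 0.8 * x[, 2]))
  f <- fit_blr(x, y, tol = 1e-10)
  g <- stats::glm(y ~ x, family = stats::binomial)
  expect_true(f$converged)
  expect_false(f$separation_detected)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$residual_deviance, stats::deviance(g), tolerance = 1e-8)
  expect_equal(f$null_deviance, g$null.deviance, tolerance = 1e-8)
  expect_equal(f$aic, stats::AIC(g), tolerance = 1e-6)
})

test_that("the 8-observation MLE matches a likelihood grid search to 1e-3", {
  x <- c(-1.4, -0.9, -0.6, -0.2, 0.1, 0.5, 1.1, 1.3)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  f <- fit_blr(matrix(x), y, tol = 1e-12)
  expect_true(f$converged)
  # grid-search oracle works on the same standardized predictor scale
  oracle <- logistic_grid_oracle(x / stats::sd(x), y)
  expect_lt(abs(unname(f$coefficients[1]) - oracle[1]), 1e-3)
  expect_lt(abs(unname(f$coefficients[2]) * stats::sd(x) - oracle[2]), 1e-3)
})

test_that("label swap negates coefficients and reflects probabilities", {
  set.seed(62)
  x <- matrix(rnorm(30), 30, 1)
  y <- rbinom(30, 1, plogis(1.2 * x[, 1]))
  f1 <- fit_blr(x, y, tol = 1e-12)
  f2 <- fit_blr(x, 1 - y, tol = 1e-12)
  expect_equal(unname(f1$coefficients), -unname(f2$coefficients), tolerance = 1e-9)
  expect_equal(unname(f1$fitted), 1 - unname(f2$fitted), tolerance = 1e-9)
  expect_equal(f1$residual_deviance, f2$residual_deviance, tolerance = 1e-9)
})

test_that("degenerate inputs and separation are diagnosed", {
  expect_error(fit_blr(matrix(1:4), rep(1, 4)), "both classes")
  expect_error(fit_blr(matrix(rnorm(4), 2, 2), c(0, 1)), "more coefficients")
  # complete separation on one predictor
  x <- matrix(c(-3, -2, -1.5, -1, 1, 1.5, 2, 3))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  f <- fit_blr(x, y)
  expect_true(f$separation_detected)
})

test_that("residual deviance is non-increasing over nested PC prefixes", {
  set.seed(63)
  n <- 40
  scores <- matrix(rnorm(n * 6), n, 6)
  y <- rbinom(n, 1, plogis(0.8 * scores[, 1] + 0.4 * scores[, 3]))
  devs <- vapply(1:6, function(m) {
    fit_blr(scores[, 1:m, drop = FALSE], y)$residual_deviance
  }, numeric(1))
  expect_true(all(diff(devs) <= 1e-8))
})

search_fixture <- function(seed = 64L, beta1 = 0.9, n = 30L) {
  set.seed(seed)
  scores <- matrix(rnorm(n * 5, sd = rep(c(2, 1.4, 1, 0.7, 0.5), each = n)), n, 5)
  colnames(scores) <- paste0("PC", 1:5)
  y <- rbinom(n, 1, plogis(beta1 * scores[, 1] / 2))
  ids <- sprintf("s%02d", 1:n)
  rownames(scores) <- ids
  md <- data.frame(
    specimen_id = c(ids, "f1", "f2"),
    taxon = "t",
    ecology_bin = c(ifelse(y == 1, "terrestrial_saltating", "arboreal_scansorial"),
                    "unassigned", "unassigned"),
    is_fossil = c(rep(FALSE, n), TRUE, TRUE)
  )
  full <- rbind(scores, f1 = rnorm(5), f2 = rnorm(5))
  pca <- structure(list(
    scores = full, eigenvectors = diag(5), eigenvalues = c(4, 2, 1, 0.5, 0.25),
    variance_fraction = c(4, 2, 1, 0.5, 0.25) / 7.75,
    center = rep(0, 5), ids = rownames(full)
  ), class = "pca_result")
  list(pca = pca, metadata = md, y = y)
}

test_that("pc_search prefers the minimum-AIC reliable prefix", {
  fx <- search_fixture()
  s <- pc_search(fx$pca, fx$metadata, mode = "landmark")
  expect_false(is.null(s$preferred))
  expect_true(1L %in% s$preferred$pc_indices)
  # exhaustive refit oracle over the attempted prefixes
  reliable_aics <- vapply(s$attempts, function(f) {
    if (f$converged && !f$separation_detected) f$aic else Inf
  }, numeric(1))
  expect_equal(s$preferred$aic, min(reliable_aics))
  # every attempt is a contiguous prefix starting at PC1
  for (m in seq_along(s$attempts)) {
    expect_equal(s$attempts[[m]]$pc_indices, 1:m)
  }
  expect_equal(nrow(s$predictions), 2L)
  expect_true(all(s$predictions$probability >= 0 & s$predictions$probability <= 1))
})

test_that("pc_search stops at separation and can fail entirely", {
  fx <- search_fixture()
  # make PC1 perfectly separating
  sep_scores <- fx$pca$scores
  train <- seq_along(fx$y)
  sep_scores[train, 1] <- ifelse(fx$y == 1, 3, -3) + rnorm(length(fx$y), 0, 0.1)
  fx$pca$scores <- sep_scores
  s <- pc_search(fx$pca, fx$metadata, mode = "landmark")
  expect_length(s$attempts, 1L)       # stops at the first unreliable prefix
  expect_null(s$preferred)
  expect_equal(s$failure_reason, "no convergent model")
  expect_equal(nrow(s$predictions), 0L)
})

test_that("linear mode starts at PC2 and skips the size axis", {
  fx <- search_fixture(seed = 65L)
  # move the class signal to PC2; PC1 becomes pure (size-like) nuisance
  sc <- fx$pca$scores
  sc[, 2] <- sc[, 1]
  set.seed(66); sc[, 1] <- rnorm(nrow(sc), sd = 4)
  fx$pca$scores <- sc
  s <- pc_search(fx$pca, fx$metadata, mode = "linear")
  expect_false(is.null(s$preferred))
  expect_false(1L %in% s$preferred$pc_indices)
  expect_equal(s$preferred$pc_indices[1], 2L)
})

test_that("pc_search requires two training specimens per bin", {
  fx <- search_fixture()
  md <- fx$metadata
  md$ecology_bin[md$ecology_bin == "arboreal_scansorial"][-1] <- "unassigned"
  expect_error(pc_search(fx$pca, md, mode = "landmark"), "2 training specimens")
})

test_that("predictions evaluate the logistic formula exactly", {
  fx <- search_fixture()
  s <- pc_search(fx$pca, fx$metadata, mode = "landmark")
  pf <- s$preferred
  newsc <- fx$pca$scores[c("f1", "f2"), , drop = FALSE]
  got <- predict_unassigned(pf, newsc)
  eta <- cbind(1, newsc[, pf$pc_indices, drop = FALSE]) %*% pf$coefficients
  expect_equal(got$probability, unname(drop(1 / (1 + exp(-eta)))),
               tolerance = 1e-12)
  # zero scores on all used PCs -> logistic(intercept)
  zero <- matrix(0, 1, 5)
  expect_equal(predict_unassigned(pf, zero)$probability,
               unname(plogis(pf$coefficients[1])), tolerance = 1e-12)
  expect_error(predict_unassigned(pf, newsc[, 1, drop = FALSE][, 0, drop = FALSE]),
               "lack PC")
})
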