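test_that("VIF matches the closed form and flags exact collinearity", {
  n <- 200
  # columns orthogonal to each other and to the intercept
  set.seed(1)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n))))[, -1]
  expect_equal(unname(vif(Q)), rep(1, 4), tolerance = 1e-8)

  # duplicated column -> infinite VIF on the duplicates
  X <- cbind(Q, dup = Q[, 1])
  v <- vif(X)
  expect_true(is.infinite(v[1]) && is.infinite(v[5]))

  # exact pairwise correlation 0.9, other columns orthogonal to both
  z1 <- Q[, 1]
  z2 <- 0.9 * z1 + sqrt(1 - 0.81) * Q[, 2]
  X2 <- cbind(z1, z2, Q[, 3], Q[, 4])
  v2 <- vif(X2)
  expect_equal(unname(v2[1:2]), rep(1 / (1 - 0.81), 2), tolerance = 1e-6)

  # cross-check against an established implementation on random data
  skip_if_not_installed("car")
  set.seed(2)
  Xr <- matrix(rnorm(n * 5), n) %*% matrix(rnorm(25), 5)
  colnames(Xr) <- paste0("v", 1:5)
  df <- data.frame(y = rnorm(n), Xr)
  ref <- car::vif(lm(y ~ ., data = df))
  expect_equal(unname(vif(Xr)), unname(ref), tolerance = 1e-6)
})

test_that("varimax components recover planted variable blocks", {
  set.seed(11)
  n <- 600
  f <- matrix(rnorm(n * 5), n)
  blocks <- list(1:3, 4:5, 6:7, 8:9, 10:11)
  X <- matrix(0, n, 11)
  for (k in 1:5) for (j in blocks[[k]]) X[, j] <- f[, k] + rnorm(n, 0, 0.3)
  colnames(X) <- c("th_dissim", "th_cost", "x3", "ai_dissim", "ai_cost",
                   "topo_cost", "topo_len", "geodesic_km", "x9",
                   "relatedness", "x11")
  cs <- varimax_components(X, n_components = 5)
  # each rotated component concentrates on one block
  for (k in 1:5) {
    own <- apply(abs(cs$loadings[blocks[[k]], , drop = FALSE]), 1, max)
    expect_true(all(own >= 0.7))
  }
  # scores nearly uncorrelated
  cm <- cor(as.matrix(cs$scores))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.1)
  # deterministic rerun
  expect_identical(cs$loadings, varimax_components(X, 5)$loadings)
})

test_that("varimax rotation preserves the retained subspace variance", {
  set.seed(3)
  X <- matrix(rnorm(300 * 6), 300)
  cs <- varimax_components(X, n_components = 3, min_rows = 10)
  pc <- prcomp(X, scale. = TRUE)
  expect_equal(sum(cs$loadings^2), sum(pc$sdev[1:3]^2), tolerance = 1e-8)
  expect_error(varimax_components(X[1:20, ], 3), "complete rows")
})

test_that("BY adjustment reproduces hand-computed step-up values", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), rep(0.055, 3),
               tolerance = 1e-12)
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  set.seed(4)
  p <- runif(30)
  expect_true(all(adjust_fdr(p) >= p))
})

test_that("rank AUC matches exhaustive pair counting and pROC", {
  expect_equal(auc_rank(c(1, 0, 0), c(0.9, 0.8, 0.3)), 1)
  expect_equal(auc_rank(c(1, 0, 1), c(0.9, 0.8, 0.3)), 0.5)
  expect_equal(auc_rank(c(0, 1), c(0.5, 0.5)), 0.5)  # tie -> 1/2

  set.seed(5)
  y <- rbinom(10000, 1, 0.4)
  expect_equal(auc_rank(y, rnorm(10000)), 0.5, tolerance = 0.02)

  skip_if_not_installed("pROC")
  y2 <- rbinom(300, 1, 0.5); s2 <- rnorm(300) + y2
  ref <- as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE)))
  expect_equal(auc_rank(y2, s2), ref, tolerance = 1e-10)
})

test_that("model filters implement the three exclusion rules", {
  expect_false(model_filters(0.95, n = 500, converged = TRUE)$include)
  expect_equal(model_filters(0.95, 500, TRUE)$reason, "imbalanced")
  expect_false(model_filters(0.5, n = 49, converged = TRUE)$include)
  expect_equal(model_filters(0.5, 49, TRUE)$reason, "too_few")
  expect_false(model_filters(0.5, 500, FALSE)$include)
  expect_true(model_filters(0.5, n = 500, converged = TRUE)$include)
})

test_that("the mixed logit reduces to plain logistic regression when sigma = 0", {
  set.seed(21)
  d <- simulate_pair_model(900, 45, beta = c(-0.6, 0.4), sigma = 0)
  fit <- fit_mixed_logit(d, predictors = c("x1", "x2"))
  ref <- glm(share ~ x1 + x2, data = d, family = binomial())
  expect_equal(fit$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-2)
  expect_lt(fit$sigma2, 0.05)
})

test_that("the mixed logit recovers an injected coefficient and its sign", {
  set.seed(22)
  est <- vapply(1:5, function(i) {
    d <- simulate_pair_model(1200, 60, beta = -0.8, sigma = 0.7)
    fit_mixed_logit(d, predictors = "x1")$coefficients$estimate[2]
  }, numeric(1))
  expect_lt(max(est), 0)
  expect_lt(abs(mean(est) + 0.8), 0.25)
})

test_that("the shared random-intercept variance is estimated from crossed ids", {
  set.seed(23)
  d <- simulate_pair_model(2000, 60, beta = 0.5, sigma = 1)
  fit <- fit_mixed_logit(d, predictors = "x1")
  expect_gt(fit$sigma2, 0.3)
  expect_lt(fit$sigma2, 2.5)
  expect_true(fit$converged)
  expect_equal(fit$n, 2000)
})

test_that("Moran correlograms separate white noise from planted gradients", {
  set.seed(31)
  n <- 70
  coords <- tibble::tibble(lat = runif(n, -30, 30), lon = runif(n, 0, 40))
  cg_null <- morans_correlogram(rnorm(n), coords, n_bins = 5, n_perm = 99)
  expect_true(all(abs(cg_null$I[!cg_null$degenerate]) < 0.35))
  expect_true(all(cg_null$upper_km > cg_null$lower_km))

  cg_grad <- morans_correlogram(coords$lat / 10 + rnorm(n, 0, 0.1), coords,
                                n_bins = 5, n_perm = 199)
  expect_gt(cg_grad$I[1], 0.3)
  expect_lt(cg_grad$p_perm[1], 0.05)
})

test_that("degenerate residual variance is flagged in the correlogram", {
  n <- 30
  coords <- tibble::tibble(lat = runif(n, 0, 5), lon = runif(n, 0, 5))
  cg <- morans_correlogram(rep(1, n), coords, n_bins = 1, n_perm = 19)
  expect_true(all(cg$degenerate | is.na(cg$I)))
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(33)
  n <- 50
  coords <- tibble::tibble(lat = runif(n, -20, 20), lon = runif(n, 0, 30))
  pvals <- vapply(1:60, function(i) {
    morans_correlogram(rnorm(n), coords, n_bins = 2, n_perm = 49)$p_perm[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the per-trait driver fits, filters and adjusts across traits", {
  cfg <- tiny_config(n_societies = 40, mu_vertical = 1,
                     n_trait_categories = 6,
                     alpha_horizontal = qlogis(0.3))
  w <- suppressMessages(simulate_world(cfg, n_traits = 3))
  pairs <- nearest_pairs(w$societies, k = 10)
  b <- suppressMessages(pair_barriers(pairs, w$societies, w$env,
                                      w$elevation, w$graph))
  tt <- suppressMessages(recode_traits(w$traits))
  res <- suppressMessages(fit_sharing(pairs, b, w$societies, tt, w$tree))
  g <- glance(res)
  expect_equal(nrow(g), dplyr::n_distinct(tt$trait_id))
  td <- tidy(res)
  if (nrow(td) > 0) {
    expect_true(all(td$p_adjusted >= td$p_value - 1e-12))
    expect_true(all(c("label", "estimate", "std_error") %in% names(td)))
    expect_setequal(unique(td$term), paste0("RC", 1:5))
  }
  # deterministic rerun: identical results table
  res2 <- suppressMessages(fit_sharing(pairs, b, w$societies, tt, w$tree))
  expect_equal(tidy(res2), td, tolerance = 1e-8)
})
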