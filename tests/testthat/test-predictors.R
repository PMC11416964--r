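ridge_primal <- function(Z, y, lambda) {
  # independent oracle: primal closed form (Z'Z + lambda I)^-1 Z' (y - mu)
  mu <- mean(y)
  Zc <- sweep(Z, 2, colMeans(Z))
  drop(solve(crossprod(Zc) + lambda * diag(ncol(Z)), crossprod(Zc, y - mu)))
}

test_that("dual and primal ridge solutions coincide (Woodbury identity)", {
  set.seed(42)
  Z <- random_dosages(20, 50, seed = 42)
  y <- rnorm(20)
  m <- fit_rrblup(Z, y, lambda = 2)
  expect_equal(unname(m$marker_effects), unname(ridge_primal(Z, y, 2)),
               tolerance = 1e-8)
  # random instances up to 50 x 200
  for (r in 1:20) {
    n <- sample(20:50, 1); p <- sample(10:200, 1)
    Z <- random_dosages(n, p, seed = 500 + r)
    y <- rnorm(n)
    lam <- 10^runif(1, -2, 3)
    m <- fit_rrblup(Z, y, lambda = lam)
    expect_lt(max(abs(m$marker_effects - ridge_primal(Z, y, lam))), 1e-8)
  }
})

test_that("ridge with vanishing penalty matches OLS when n > m", {
  set.seed(7)
  Z <- random_dosages(30, 10, seed = 7)
  beta <- rnorm(10)
  y <- drop(Z %*% beta) + rnorm(30, sd = 0.3)
  m <- fit_rrblup(Z, y, lambda = 1e-8)
  ols <- lm(y ~ Z)
  expect_equal(unname(predict_gebv(m, Z)), unname(fitted(ols)),
               tolerance = 1e-4)
})

test_that("infinite shrinkage collapses every prediction to the intercept", {
  Z <- random_dosages(25, 40, seed = 9)
  y <- rnorm(25, mean = 5)
  m <- fit_rrblup(Z, y, lambda = 1e12)
  expect_lt(max(abs(predict_gebv(m, Z) - m$mu_hat)), 1e-3 * sd(y))
  expect_lt(sqrt(sum(m$marker_effects^2)), 1e-6)
})

test_that("shrinkage is monotone in lambda", {
  Z <- random_dosages(30, 60, seed = 11)
  y <- rnorm(30)
  lambdas <- c(0.1, 1, 10, 100, 1000)
  norms <- vapply(lambdas, function(l) {
    sqrt(sum(fit_rrblup(Z, y, lambda = l)$marker_effects^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("marker-effect and kinship-form GBLUP predictions coincide", {
  set.seed(13)
  Z <- random_dosages(30, 80, seed = 13)
  y <- rnorm(30)
  lam <- 3.7
  train <- 1:25; cand <- 26:30
  m <- fit_rrblup(Z[train, ], y[train], lambda = lam)
  got <- predict_gebv(m, Z[cand, , drop = FALSE])
  # independent kinship-form oracle on centered dosages
  mu <- mean(y[train])
  Zc_tr <- sweep(Z[train, ], 2, colMeans(Z[train, ]))
  Zc_cd <- sweep(Z[cand, , drop = FALSE], 2, colMeans(Z[train, ]))
  Knn <- tcrossprod(Zc_tr)
  Kcn <- tcrossprod(Zc_cd, Zc_tr)
  oracle <- mu + drop(Kcn %*% solve(Knn + lam * diag(25), y[train] - mu))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-8)
})

test_that("a genotype at the training marker means predicts the intercept exactly", {
  Z <- random_dosages(25, 30, seed = 15)
  y <- rnorm(25)
  m <- fit_rrblup(Z, y, lambda = 5)
  z0 <- matrix(colMeans(Z), 1, dimnames = list("center", colnames(Z)))
  expect_equal(unname(predict_gebv(m, z0)), m$mu_hat)
})

test_that("HEBLP|A exposes the printed lambda formula and shares the solver", {
  st <- sim_training_problem(n_lines = 45, n_markers = 300, n_qtl = 60,
                             n_hybrids = 250, h2 = 0.6, seed = 33,
                             groups = c(A = 15, B = 15, C = 15))
  y <- setNames(st$phenotypes$trait, st$phenotypes$hybrid_id)
  mh <- suppressWarnings(fit_heblp_a(st$hybrids, y))
  # lambda_he is exactly (1 - sigma_u2) / sigma_u2 for the clamped slope
  expect_equal(mh$lambda_he, (1 - mh$sigma_u2_he) / mh$sigma_u2_he)
  # given the same lambda, rrBLUP reproduces the identical effects
  mr <- fit_rrblup(st$hybrids, y, lambda = mh$lambda)
  expect_lt(max(abs(mr$marker_effects - mh$marker_effects)), 1e-10)
})

test_that("rrBLUP and HEBLP|A accuracies are close on an additive trait", {
  st <- sim_training_problem(n_lines = 60, n_markers = 500, n_qtl = 100,
                             n_hybrids = 500, h2 = 0.8, seed = 55)
  y <- setNames(st$phenotypes$trait, st$phenotypes$hybrid_id)
  tr <- st$phenotypes$hybrid_id[1:400]
  cd <- st$phenotypes$hybrid_id[401:500]
  acc <- function(model) accuracy(y[cd], predict_gebv(model, st$hybrids[cd, ]))
  a_rr <- acc(fit_rrblup(st$hybrids[tr, ], y[tr]))
  a_he <- acc(fit_heblp_a(st$hybrids[tr, ], y[tr]))
  expect_lt(abs(a_rr - a_he), 0.05)
  expect_gt(a_rr, 0.5)
})

test_that("the cross-validated lambda grid gives sane shrinkage", {
  st <- sim_training_problem(n_lines = 40, n_markers = 200, n_qtl = 50,
                             n_hybrids = 150, h2 = 0.7, seed = 77,
                             groups = c(A = 20, B = 20))
  y <- setNames(st$phenotypes$trait, st$phenotypes$hybrid_id)
  m <- fit_rrblup(st$hybrids, y, lambda_strategy = "cv_grid", seed = 3)
  expect_equal(m$lambda_strategy, "cv_grid")
  expect_gt(m$lambda, 0)
  # predictions correlate with the REML-lambda fit
  m2 <- fit_rrblup(st$hybrids, y, lambda_strategy = "reml")
  expect_gt(cor(predict_gebv(m, st$hybrids), predict_gebv(m2, st$hybrids)),
            0.9)
})

test_that("ensemble learners honour the degenerate-target and determinism contracts", {
  Z <- random_dosages(30, 40, seed = 19)
  y_const <- rep(3.5, 30)
  m_rf <- suppressWarnings(fit_ensemble("rf", Z, y_const, seed = 4))
  expect_equal(unname(predict_gebv(m_rf, Z)), rep(3.5, 30), tolerance = 1e-8)
  y <- rnorm(30)
  p1 <- predict_gebv(fit_ensemble("rf", Z, y, seed = 8), Z)
  p2 <- predict_gebv(fit_ensemble("rf", Z, y, seed = 8), Z)
  expect_identical(p1, p2)
  g1 <- predict_gebv(fit_ensemble("gbm", Z, y, seed = 8), Z)
  g2 <- predict_gebv(fit_ensemble("gbm", Z, y, seed = 8), Z)
  expect_identical(g1, g2)
})

test_that("prediction demands the training marker layout", {
  Z <- random_dosages(25, 30, seed = 23)
  y <- rnorm(25)
  m <- fit_rrblup(Z, y, lambda = 1)
  swapped <- Z[, c(2, 1, 3:30)]
  expect_error(predict_gebv(m, swapped), "marker mismatch")
  zna <- Z; zna[1, 1] <- NA
  expect_error(predict_gebv(m, zna), "missing")
})

test_that("parametric models survive a JSON round-trip", {
  Z <- random_dosages(22, 25, seed = 29)
  y <- rnorm(22)
  m <- fit_rrblup(Z, y, lambda = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_gp_model(m, path)
  back <- read_gp_model(path)
  expect_equal(predict_gebv(back, Z), predict_gebv(m, Z), tolerance = 1e-12)
  expect_error(write_gp_model(fit_ensemble("rf", Z, y), path), "parametric")
})
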