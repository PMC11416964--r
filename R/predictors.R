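# Genomic prediction methods.
#
# Parametric methods (rrBLUP, HEBLP|A) solve the same ridge system and
# differ only in how the shrinkage parameter lambda is chosen; ensemble
# baselines (random forest, gradient-boosted trees) are delegated to
# established implementations behind the same fit/predict contract.

new_gp_model <- function(method, mu_hat, marker_ids, train_marker_means,
                         marker_effects = NULL, lambda = NULL, ...) {
  structure(
    c(list(method = method, mu_hat = mu_hat, marker_ids = marker_ids,
           train_marker_means = train_marker_means,
           marker_effects = marker_effects, lambda = lambda),
      list(...)),
    class = "gp_model"
  )
}

#' @export
print.gp_model <- function(x, ...) {
  cat("Genomic prediction model [", x$method, "]\n", sep = "")
  cat("  markers:", length(x$marker_ids), " intercept:", signif(x$mu_hat, 5), "\n")
  if (!is.null(x$lambda)) cat("  lambda:", signif(x$lambda, 5),
                              if (!is.null(x$lambda_strategy)) paste0("(", x$lambda_strategy, ")"), "\n")
  invisible(x)
}

#' @export
tidy.gp_model <- function(x, ...) {
  if (is.null(x$marker_effects)) {
    abort("ensemble models expose no marker effects; use glance()")
  }
  tibble::tibble(marker_id = x$marker_ids, effect = unname(x$marker_effects))
}

#' @export
glance.gp_model <- function(x, ...) {
  tibble::tibble(
    method = x$method, mu_hat = x$mu_hat,
    lambda = x$lambda %||% NA_real_,
    lambda_strategy = x$lambda_strategy %||% NA_character_,
    n_train = x$n_train %||% NA_integer_,
    n_markers = length(x$marker_ids)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_train_input <- function(Z, y, min_n = 20) {
  if (anyNA(Z)) abort("training genotypes contain missing values; impute first")
  if (nrow(Z) != length(y)) abort("genotype rows and phenotype length differ")
  if (nrow(Z) < min_n) abort(paste0("need at least ", min_n, " training individuals"))
  if (anyNA(y)) abort("training phenotypes contain NA")
  if (sd(y) == 0) abort("training phenotype has zero variance")
  invisible(TRUE)
}

ridge_solve <- function(Zc, y_dev, lambda) {
  # n x n dual system: u = Zc' (Zc Zc' + lambda I)^-1 y_dev
  K <- tcrossprod(Zc)
  diag(K) <- diag(K) + lambda
  alpha <- tryCatch(
    solve(K, y_dev),
    error = function(e) {
      diag(K) <- diag(K) + 1e-8 * mean(diag(K))
      solve(K, y_dev)
    }
  )
  drop(crossprod(Zc, alpha))
}

#' Fit ridge-regression BLUP (rrBLUP)
#'
#' Model: `y = mu + Z u + e` with marker effects `u ~ N(0, I sigma_u^2)`.
#' The intercept is the training phenotype mean, marker columns are
#' centered by their training means, and the BLUP solution
#' `u = Z'(Z Z' + lambda I)^-1 (y - mu)` is computed through the n x n
#' system. The ridge parameter `lambda = sigma_e^2 / sigma_u^2` is chosen
#' by REML on the training kinship (default), by a 10-fold cross-validated
#' grid search, or fixed by the caller.
#'
#' @param Z training genotype matrix (hybrids x markers), no missing.
#' @param y training phenotypes.
#' @param lambda_strategy `"reml"` or `"cv_grid"`; ignored when `lambda`
#'   is given.
#' @param lambda optional fixed positive ridge parameter (solver scale).
#' @param n_folds folds for the CV grid.
#' @param seed seed controlling the CV fold assignment.
#' @return a `gp_model`.
#' @export
fit_rrblup <- function(Z, y, lambda_strategy = c("reml", "cv_grid"),
                       lambda = NULL, n_folds = 10, seed = 1) {
  lambda_strategy <- match.arg(lambda_strategy)
  check_train_input(Z, y)
  mu <- mean(y)
  centers <- colMeans(Z)
  Zc <- sweep(Z, 2, centers)

  if (is.null(lambda)) {
    if (lambda_strategy == "reml") {
      lambda <- lambda_from_reml(Zc, y)
    } else {
      lambda <- lambda_from_cv(Zc, y - mu, n_folds = n_folds, seed = seed)
    }
  } else {
    if (lambda <= 0) abort("lambda must be positive")
    lambda_strategy <- "fixed"
  }
  u <- ridge_solve(Zc, y - mu, lambda)
  new_gp_model("rrblup", mu, colnames(Z), centers,
               marker_effects = setNames(u, colnames(Z)),
               lambda = lambda, lambda_strategy = lambda_strategy,
               n_train = nrow(Z), seed = seed)
}

lambda_from_reml <- function(Zc, y) {
  K <- tcrossprod(Zc)
  cbar <- mean(diag(K))
  if (cbar <= 0) abort("training genotypes have no variation")
  rel <- K / cbar
  attr(rel, "kind") <- "grm"
  rownames(rel) <- colnames(rel) <- paste0("i", seq_len(nrow(rel)))
  est <- reml_heritability(rel, unname(y))
  h2 <- min(max(est$h2, 0.01), 0.99)
  # V = sigma_g2 * K / cbar + sigma_e2 I  =>  lambda_K = cbar (1 - h2) / h2
  cbar * (1 - h2) / h2
}

lambda_from_cv <- function(Zc, y_dev, n_folds = 10, seed = 1) {
  m <- ncol(Zc)
  grid <- m * 10^seq(-3, 3, length.out = 25)
  n <- nrow(Zc)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  mse <- vapply(grid, function(lam) {
    errs <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      ztr <- Zc[tr, , drop = FALSE]
      u <- ridge_solve(ztr, y_dev[tr] - mean(y_dev[tr]), lam)
      pred <- mean(y_dev[tr]) + drop(Zc[!tr, , drop = FALSE] %*% u)
      mean((y_dev[!tr] - pred)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  # ties broken toward stronger shrinkage
  grid[max(which(mse <= min(mse) + 1e-12))]
}

#' Fit HEBLP|A
#'
#' Same BLUP solution as [fit_rrblup()], but the shrinkage comes from
#' IBS-based Haseman-Elston regression: the IBS similarity is rescaled to
#' the relationship scale ([ibs_to_relationship()]), the HE slope on the
#' standardized phenotype scale estimates `sigma_u^2` (the heritability),
#' and `lambda = (1 - sigma_u^2) / sigma_u^2`. That variance ratio is mapped
#' onto the centered-dosage solver by the mean diagonal of the training
#' kinship, consistently with the REML route. The slope is clamped to
#' `[0.01, 0.99]` before forming the ratio.
#'
#' @param Z training genotype matrix, no missing.
#' @param y training phenotypes.
#' @param ibs optional precomputed IBS matrix aligned with the rows of `Z`
#'   (it may be computed from the unimputed dosages); computed from `Z`
#'   when absent.
#' @return a `gp_model` with `$lambda_he`, the standardized-scale
#'   `(1 - sigma_u^2) / sigma_u^2`, and `$he_clamped`.
#' @export
fit_heblp_a <- function(Z, y, ibs = NULL) {
  check_train_input(Z, y)
  if (is.null(ibs)) ibs <- compute_ibs(Z)
  if (nrow(ibs) != nrow(Z)) abort("IBS matrix does not align with training rows")
  est <- he_regression(ibs_to_relationship(ibs, Z), unname(y))
  s_u2 <- min(max(est$sigma_g2, 0.01), 0.99)
  at_boundary <- est$clamped || s_u2 != est$sigma_g2
  if (at_boundary) warn("HE variance estimate clamped to [0.01, 0.99] before forming lambda")
  lambda_he <- (1 - s_u2) / s_u2

  mu <- mean(y)
  centers <- colMeans(Z)
  Zc <- sweep(Z, 2, centers)
  cbar <- mean(diag(tcrossprod(Zc)))
  lambda <- cbar * lambda_he
  u <- ridge_solve(Zc, y - mu, lambda)
  new_gp_model("heblp_a", mu, colnames(Z), centers,
               marker_effects = setNames(u, colnames(Z)),
               lambda = lambda, lambda_strategy = "he",
               lambda_he = lambda_he, he_clamped = at_boundary,
               sigma_u2_he = s_u2, n_train = nrow(Z))
}

#' Fit an ensemble baseline (random forest or gradient-boosted trees)
#'
#' Delegates to `randomForest::randomForest()` or `xgboost::xgboost()`
#' with their default hyperparameters, markers as plain features. Fits are
#' deterministic given the seed.
#'
#' @param method `"rf"` or `"gbm"`.
#' @param Z training genotype matrix, no missing.
#' @param y training phenotypes (constant y is allowed here).
#' @param seed integer seed.
#' @param ... passed to the delegated learner.
#' @return a `gp_model` holding the delegated fit.
#' @export
fit_ensemble <- function(method = c("rf", "gbm"), Z, y, seed = 1, ...) {
  method <- match.arg(method)
  if (anyNA(Z)) abort("training genotypes contain missing values; impute first")
  if (nrow(Z) != length(y)) abort("genotype rows and phenotype length differ")
  if (anyNA(y)) abort("training phenotypes contain NA")
  set.seed(seed)
  fit <- if (method == "rf") {
    randomForest::randomForest(x = Z, y = y, ...)
  } else {
    xgboost::xgboost(x = Z, y = y, nthreads = 1, verbosity = 0, seed = seed,
                     ...)
  }
  new_gp_model(method, mean(y), colnames(Z), colMeans(Z),
               delegated_model = fit, n_train = nrow(Z), seed = seed)
}

#' Predict genomic estimated breeding values
#'
#' Parametric models: `GEBV = mu + (z - train_marker_means) . u`, so a
#' genotype equal to the training marker means predicts exactly the
#' intercept. Ensemble models delegate to the fitted learner.
#'
#' @param model a `gp_model`.
#' @param genotypes matrix of genotypes to predict (rows = individuals),
#'   markers matching the model's `marker_ids` in order, no missing.
#' @return numeric vector of GEBVs in trait units, named by row.
#' @export
predict_gebv <- function(model, genotypes) {
  if (is.null(colnames(genotypes)) ||
      !identical(colnames(genotypes), model$marker_ids)) {
    msg <- "marker mismatch with the trained model"
    if (!is.null(colnames(genotypes)) &&
        length(colnames(genotypes)) == length(model$marker_ids)) {
      bad <- which(colnames(genotypes) != model$marker_ids)[1]
      msg <- paste0(msg, " (first at column ", bad, ": '",
                    colnames(genotypes)[bad], "' vs '", model$marker_ids[bad], "')")
    }
    abort(msg)
  }
  if (anyNA(genotypes)) abort("genotypes to predict contain missing values")
  if (!is.null(model$marker_effects)) {
    dev <- sweep(genotypes, 2, model$train_marker_means)
    out <- model$mu_hat + drop(dev %*% model$marker_effects)
  } else {
    out <- predict(model$delegated_model, genotypes)
  }
  setNames(as.numeric(out), rownames(genotypes))
}

#' @export
predict.gp_model <- function(object, newdata, ...) predict_gebv(object, newdata)

#' Serialize a parametric model to JSON
#'
#' Ensemble models hold an opaque delegated fit and are not JSON
#' serializable; save those with `saveRDS()`.
#'
#' @param model parametric `gp_model`.
#' @param path output path.
#' @export
write_gp_model <- function(model, path) {
  if (is.null(model$marker_effects)) {
    abort("only parametric models serialize to JSON; use saveRDS() for ensembles")
  }
  jsonlite::write_json(
    list(method = model$method, mu_hat = model$mu_hat, lambda = model$lambda,
         lambda_strategy = model$lambda_strategy,
         marker_ids = model$marker_ids,
         train_marker_means = unname(model$train_marker_means),
         marker_effects = unname(model$marker_effects)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_gp_model
#' @export
read_gp_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_gp_model(x$method, x$mu_hat, x$marker_ids,
               setNames(x$train_marker_means, x$marker_ids),
               marker_effects = setNames(x$marker_effects, x$marker_ids),
               lambda = x$lambda, lambda_strategy = x$lambda_strategy)
}
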