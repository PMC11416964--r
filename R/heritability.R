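# SNP heritability: Haseman-Elston regression and single-component REML.
#
# Both estimators target h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2) under the
# additive model y = mu + g + e with g ~ N(0, sigma_g^2 * A) for a
# relatedness matrix A. A is normalized to unit mean diagonal before
# estimation, so sigma_g^2 is the mean per-individual genetic variance and
# h2 a genuine variance fraction: VanRaden GRMs have mean diagonal near
# 1 + F, which is ~2 on a fully inbred panel and ~1 on hybrids.

normalize_rel <- function(rel) {
  md <- mean(diag(rel))
  if (md <= 0) abort("relatedness matrix has non-positive mean diagonal")
  rel / md
}

new_heritability <- function(sigma_g2, sigma_e2, method, n, m, clamped) {
  tot <- sigma_g2 + sigma_e2
  structure(
    list(
      sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
      h2 = if (tot > 0) sigma_g2 / tot else NA_real_,
      method = method, n = n, m = m, clamped = clamped
    ),
    class = "heritability_est"
  )
}

#' @export
print.heritability_est <- function(x, ...) {
  cat(sprintf("SNP heritability (%s): h2 = %.4f  (sigma_g2 = %.4g, sigma_e2 = %.4g, n = %d%s)\n",
              toupper(x$method), x$h2, x$sigma_g2, x$sigma_e2, x$n,
              if (x$clamped) ", clamped" else ""))
  invisible(x)
}

#' @export
tidy.heritability_est <- function(x, ...) {
  tibble::tibble(
    method = x$method, h2 = x$h2, sigma_g2 = x$sigma_g2,
    sigma_e2 = x$sigma_e2, n = x$n, clamped = x$clamped
  )
}

#' Haseman-Elston regression heritability
#'
#' Moment estimator: with the phenotype standardized to zero mean and unit
#' variance, the products `y_i * y_j` over all pairs `i < j` are regressed
#' by ordinary least squares on the corresponding relatedness entries. The
#' slope estimates the genetic variance on the standardized scale, which is
#' the heritability itself; the residual variance is its complement. Raw
#' estimates outside `[0, 1]` are truncated and flagged. The relatedness
#' matrix is normalized to unit mean diagonal first (see the file-level
#' note); a matrix whose diagonal is already 1 passes through unchanged.
#'
#' @param rel relatedness matrix (IBS or GRM), ids as dimnames.
#' @param y named or aligned numeric phenotype vector.
#' @return a `heritability_est`; `$raw_slope` keeps the unclamped slope.
#' @export
he_regression <- function(rel, y) {
  y <- align_phenotype(rel, y)
  n <- length(y)
  if (n < 10) abort("need at least 10 phenotyped individuals")
  if (sd(y) == 0) abort("phenotype has zero variance")
  ys <- (y - mean(y)) / sd(y)
  rel <- normalize_rel(rel)
  ut <- upper.tri(rel)
  x <- rel[ut]
  prod <- tcrossprod(ys)[ut]
  if (sd(x) == 0) abort("relatedness has zero variance across pairs")
  slope <- cov(x, prod) / var(x)
  clamped <- slope < 0 || slope > 1
  s_g <- min(max(slope, 0), 1)
  est <- new_heritability(s_g, 1 - s_g, "he", n, NA_integer_, clamped)
  est$raw_slope <- slope
  est
}

#' Single-component REML heritability
#'
#' Restricted maximum likelihood for `y = 1*mu + g + e`,
#' `g ~ N(0, sigma_g^2 G)`, via the eigendecomposition of the GRM and a
#' bounded one-dimensional search over `h2 in [1e-6, 1 - 1e-6]`; the total
#' variance is profiled out analytically. Variance components are reported
#' on the observed phenotype scale.
#'
#' @param rel genomic relationship matrix (`kind = "grm"`).
#' @param y phenotype vector aligned with `rel`.
#' @return a `heritability_est` with `$loglik` (profiled restricted
#'   log-likelihood at the optimum) and `$restricted_loglik`, a function of
#'   h2 for diagnostics.
#' @export
reml_heritability <- function(rel, y) {
  kind <- attr(rel, "kind")
  if (!is.null(kind) && kind != "grm") abort("reml_heritability expects a GRM")
  y <- align_phenotype(rel, y)
  n <- length(y)
  if (n < 10) abort("need at least 10 phenotyped individuals")
  if (sd(y) == 0) abort("phenotype has zero variance")

  rel <- normalize_rel(rel)
  eg <- eigen((rel + t(rel)) / 2, symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-6 * max(abs(d))) abort("relatedness matrix is not PSD")
  d <- pmax(d, 0)
  yt <- crossprod(eg$vectors, y)
  xt <- crossprod(eg$vectors, rep(1, n))

  restricted_loglik <- function(h2) {
    lam <- h2 * d + (1 - h2)        # V / sigma_p^2 eigenvalues
    xvx <- sum(xt^2 / lam)
    xvy <- sum(xt * yt / lam)
    yvy <- sum(yt^2 / lam)
    ypy <- yvy - xvy^2 / xvx        # y' P y * sigma_p^2
    sp2 <- ypy / (n - 1)
    -0.5 * (sum(log(lam)) + log(xvx) + (n - 1) * (1 + log(sp2)))
  }
  opt <- optimize(restricted_loglik, c(1e-6, 1 - 1e-6), maximum = TRUE,
                  tol = 1e-6)
  h2 <- opt$maximum
  lam <- h2 * d + (1 - h2)
  xvx <- sum(xt^2 / lam)
  xvy <- sum(xt * yt / lam)
  yvy <- sum(yt^2 / lam)
  sp2 <- (yvy - xvy^2 / xvx) / (n - 1)

  est <- new_heritability(h2 * sp2, (1 - h2) * sp2, "reml", n, NA_integer_,
                          clamped = FALSE)
  est$loglik <- opt$objective
  est$restricted_loglik <- restricted_loglik
  est
}

align_phenotype <- function(rel, y) {
  if (!is.null(names(y)) && !is.null(rownames(rel))) {
    missing_ids <- setdiff(rownames(rel), names(y))
    if (length(missing_ids)) {
      abort(paste0("phenotype missing for: ", paste(head(missing_ids, 5), collapse = ", ")))
    }
    y <- y[rownames(rel)]
  } else if (length(y) != nrow(rel)) {
    abort("phenotype length does not match relatedness dimension")
  }
  if (anyNA(y)) abort("phenotype vector contains NA; subset first")
  as.numeric(y)
}

#' Estimate SNP heritability for each trait of a phenotype table
#'
#' Convenience wrapper: builds the hybrid relatedness once and runs the
#' chosen estimator per trait, dropping records with a missing value for
#' that trait.
#'
#' @param hybrids imputed hybrid genotype matrix (rows = hybrid ids).
#' @param phenotypes phenotype tibble (`hybrid_id`, traits ...).
#' @param traits trait column names; defaults to every numeric column.
#' @param method `"he"`, `"reml"` or both.
#' @return tibble with one row per trait x method.
#' @export
estimate_heritability <- function(hybrids, phenotypes,
                                  traits = NULL, method = c("he", "reml")) {
  method <- match.arg(method, several.ok = TRUE)
  if (is.null(traits)) {
    traits <- setdiff(names(phenotypes)[vapply(phenotypes, is.numeric, TRUE)],
                      c("hybrid_id", "parent1", "parent2"))
  }
  rel_cache <- list()
  get_rel <- function(kind, ids) {
    key <- paste(kind, length(ids), paste0(range(ids), collapse = ""))
    if (is.null(rel_cache[[key]])) {
      sub <- hybrids[ids, , drop = FALSE]
      rel_cache[[key]] <<- if (kind == "he") {
        ibs_to_relationship(compute_ibs(sub), sub)
      } else {
        compute_grm(impute_missing(sub))
      }
    }
    rel_cache[[key]]
  }
  purrr::map_dfr(traits, function(tr) {
    keep <- !is.na(phenotypes[[tr]])
    ids <- phenotypes$hybrid_id[keep]
    y <- setNames(phenotypes[[tr]][keep], ids)
    purrr::map_dfr(method, function(me) {
      rel <- get_rel(me, ids)
      est <- if (me == "he") he_regression(rel, y) else reml_heritability(rel, y)
      dplyr::bind_cols(tibble::tibble(trait = tr), tidy(est))
    })
  })
}
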