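# Prediction-accuracy protocol: repeated random train/candidate splits,
# Pearson-correlation accuracy, paired across methods within a replicate.

#' Random train/candidate splits
#'
#' Each replicate samples `n_train` ids uniformly without replacement; the
#' remaining ids form the candidate set. Replicate r uses seed
#' `seed + r`, so plans are reproducible and extendable.
#'
#' @param ids phenotyped individual ids.
#' @param n_train training-set size (< `length(ids)`).
#' @param n_replicates number of replicates.
#' @param seed base integer seed.
#' @return tibble with columns `replicate`, `train_ids` (list),
#'   `candidate_ids` (list), `seed`.
#' @export
make_splits <- function(ids, n_train, n_replicates = 10, seed = 1) {
  if (anyDuplicated(ids)) abort("duplicate ids")
  if (n_train >= length(ids)) abort("n_train must be smaller than the number of ids")
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    set.seed(seed + r)
    tr <- sort(sample(ids, n_train))
    tibble::tibble(replicate = r,
                   train_ids = list(tr),
                   candidate_ids = list(setdiff(ids, tr)),
                   seed = seed + r)
  })
}

#' Prediction accuracy
#'
#' The Pearson correlation between observed phenotypes and predicted
#' genotypic values.
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
accuracy <- function(observed, predicted) {
  if (length(observed) != length(predicted)) abort("length mismatch")
  if (length(observed) < 3) abort("need at least 3 pairs")
  if (sd(observed) == 0 || sd(predicted) == 0) abort("zero variance in accuracy input")
  cor(observed, predicted)
}

fit_method <- function(method, Z, y, seed) {
  switch(method,
    rrblup = fit_rrblup(Z, y, seed = seed),
    heblp_a = fit_heblp_a(Z, y),
    rf = fit_ensemble("rf", Z, y, seed = seed),
    gbm = fit_ensemble("gbm", Z, y, seed = seed),
    abort(paste0("unknown method: ", method))
  )
}

#' Evaluate genomic prediction methods under repeated splits
#'
#' For every trait, method and replicate: fit on the training hybrids,
#' predict the candidates, and score the Pearson accuracy. All methods
#' share the identical split within a replicate (paired design). Records
#' with a missing value for a trait are dropped for that trait only, so
#' candidate-set sizes vary with trait missingness. A failed fit or a
#' degenerate accuracy is recorded as `NA` with a warning and excluded
#' from aggregation.
#'
#' @param hybrids imputed hybrid genotype matrix (rows = hybrid ids).
#' @param phenotypes phenotype tibble.
#' @param traits trait columns to evaluate; default all numeric columns.
#' @param methods subset of `c("rrblup", "heblp_a", "rf", "gbm")`.
#' @param n_train training-set size.
#' @param n_replicates replicates.
#' @param seed base seed.
#' @return a `gp_accuracy` tibble `(trait, method, replicate, r, n_train,
#'   n_candidate)`; summarise with [summarize_accuracy()] or `glance()`.
#' @export
evaluate_methods <- function(hybrids, phenotypes, traits = NULL,
                             methods = c("rrblup", "heblp_a", "rf", "gbm"),
                             n_train, n_replicates = 10, seed = 1) {
  if (is.null(traits)) {
    traits <- setdiff(names(phenotypes)[vapply(phenotypes, is.numeric, TRUE)],
                      c("hybrid_id", "parent1", "parent2"))
  }
  res <- purrr::map_dfr(traits, function(tr) {
    keep <- !is.na(phenotypes[[tr]])
    ids <- phenotypes$hybrid_id[keep]
    y <- setNames(phenotypes[[tr]][keep], ids)
    splits <- make_splits(ids, n_train, n_replicates, seed)
    purrr::map_dfr(seq_len(nrow(splits)), function(i) {
      tr_ids <- splits$train_ids[[i]]
      cand_ids <- splits$candidate_ids[[i]]
      Ztr <- hybrids[tr_ids, , drop = FALSE]
      Zcand <- hybrids[cand_ids, , drop = FALSE]
      purrr::map_dfr(methods, function(me) {
        r <- tryCatch({
          model <- fit_method(me, Ztr, y[tr_ids], seed = splits$seed[i])
          accuracy(y[cand_ids], predict_gebv(model, Zcand))
        }, error = function(e) {
          warn(paste0(me, " failed on ", tr, " replicate ", i, ": ",
                      conditionMessage(e)))
          NA_real_
        })
        tibble::tibble(trait = tr, method = me, replicate = splits$replicate[i],
                       r = r, n_train = length(tr_ids),
                       n_candidate = length(cand_ids))
      })
    })
  })
  class(res) <- c("gp_accuracy", class(res))
  res
}

#' Summarise an accuracy report
#'
#' Mean accuracy and its standard error (`sd / sqrt(n_replicates)`) per
#' trait and method; a single replicate reports `se_r = 0` with
#' `se_defined = FALSE`.
#'
#' @param report a `gp_accuracy` tibble.
#' @return tibble `(trait, method, mean_r, se_r, n_replicates, se_defined)`.
#' @export
summarize_accuracy <- function(report) {
  report |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::group_by(.data$trait, .data$method) |>
    dplyr::summarise(
      mean_r = mean(.data$r),
      se_r = if (dplyr::n() > 1) sd(.data$r) / sqrt(dplyr::n()) else 0,
      n_replicates = dplyr::n(),
      se_defined = dplyr::n() > 1,
      .groups = "drop"
    )
}

#' @export
glance.gp_accuracy <- function(x, ...) summarize_accuracy(x)

#' Correlation between heritability and prediction accuracy
#'
#' Pearson correlation between per-trait SNP heritability and per-trait
#' accuracy averaged over methods, with a two-sided p-value from the
#' t-transform.
#'
#' @param report a `gp_accuracy` tibble.
#' @param h2 named numeric vector (or tibble with `trait`, `h2`) of
#'   per-trait heritability estimates.
#' @return tibble `(R, p_value, n_traits)`.
#' @export
correlate_h2_accuracy <- function(report, h2) {
  if (is.data.frame(h2)) h2 <- setNames(h2$h2, h2$trait)
  acc <- report |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(mean_r = mean(.data$r), .groups = "drop")
  if (nrow(acc) < 3) abort("need at least 3 traits")
  missing_tr <- setdiff(acc$trait, names(h2))
  if (length(missing_tr)) abort(paste0("no heritability for: ", paste(missing_tr, collapse = ", ")))
  x <- h2[acc$trait]
  y <- acc$mean_r
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance across traits")
  r <- cor(x, y)
  n <- length(x)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  tibble::tibble(R = r, p_value = 2 * pt(-abs(tstat), df = n - 2), n_traits = n)
}
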