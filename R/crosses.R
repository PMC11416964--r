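# Exhaustive half-diallel prediction, genetic gain, general combining
# ability and heterotic-pattern summaries.

#' Enumerate a complete half-diallel
#'
#' All `N (N - 1) / 2` unordered parent pairs, no self-crosses, canonical
#' order (lexicographically smaller parent first), enumerated
#' deterministically in lexicographic sequence.
#'
#' @param line_ids distinct parent line ids.
#' @return tibble `(parent1, parent2)`.
#' @export
enumerate_crosses <- function(line_ids) {
  if (anyDuplicated(line_ids)) abort("duplicate line ids")
  if (length(line_ids) < 2) abort("need at least two lines")
  ids <- sort(line_ids)
  n <- length(ids)
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n), use.names = FALSE)
  tibble::tibble(parent1 = ids[i], parent2 = ids[j])
}

#' Predict GEBVs for every cross of a half-diallel
#'
#' Builds in-silico hybrid genotypes in batches (never materialising the
#' full set of crosses at once) and predicts each cross's GEBV with the
#' trained model. GEBVs are identical whatever the batch size.
#'
#' @param model a `gp_model`.
#' @param parents imputed genotype matrix of the parent lines, markers
#'   covering the model's markers.
#' @param crosses optional tibble of parent pairs; defaults to the full
#'   half-diallel of `parents`.
#' @param batch_size crosses per batch.
#' @return a `cross_table` tibble `(parent1, parent2, gebv)` with the model
#'   method as attribute.
#' @export
predict_all_crosses <- function(model, parents, crosses = NULL,
                                batch_size = 2000) {
  if (anyNA(parents)) abort("parent genotypes contain missing values; impute first")
  if (!all(model$marker_ids %in% colnames(parents))) {
    abort("parent matrix lacks some model markers")
  }
  parents <- parents[, model$marker_ids, drop = FALSE]
  if (is.null(crosses)) crosses <- enumerate_crosses(rownames(parents))
  n <- nrow(crosses)
  gebv <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    h <- make_hybrid_genotypes(parents, crosses[idx, ])
    gebv[idx] <- predict_gebv(model, h)
  }
  out <- dplyr::bind_cols(canonical_pairs(crosses$parent1, crosses$parent2),
                          tibble::tibble(gebv = gebv))
  class(out) <- c("cross_table", class(out))
  attr(out, "method") <- model$method
  out
}

#' Top fraction of a cross table
#'
#' Sorts by GEBV descending and keeps `floor(fraction * n)` crosses; ties
#' at the boundary are broken by canonical pair order so the selection is
#' deterministic.
#'
#' @param table a `cross_table`.
#' @param fraction in (0, 1].
#' @return the selected subset, sorted.
#' @export
top_fraction <- function(table, fraction) {
  if (nrow(table) == 0) abort("empty cross table")
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  k <- floor(fraction * nrow(table))
  out <- table |>
    dplyr::arrange(dplyr::desc(.data$gebv), .data$parent1, .data$parent2) |>
    head(k)
  class(out) <- unique(c("cross_table", class(out)))
  out
}

#' Genetic gain from truncation selection on predicted crosses
#'
#' Mean GEBV of the top fraction minus the mean GEBV of all crosses;
#' non-negative by construction and non-increasing in the fraction.
#'
#' @inheritParams top_fraction
#' @return a single number in trait units.
#' @export
genetic_gain <- function(table, fraction) {
  mean(top_fraction(table, fraction)$gebv) - mean(table$gebv)
}

#' General combining ability from a complete half-diallel
#'
#' A line's GCA is its mean predicted GEBV over the `N - 1` crosses that
#' involve it (the operational breeding definition, not the classical
#' least-squares diallel decomposition). Requires the complete
#' half-diallel so every line is averaged over the same number of crosses.
#'
#' @param table a complete `cross_table`.
#' @return tibble `(line_id, gca, n_crosses)` sorted by GCA descending.
#' @export
gca <- function(table) {
  lines <- sort(unique(c(table$parent1, table$parent2)))
  n <- length(lines)
  if (nrow(table) != n * (n - 1) / 2) {
    full <- enumerate_crosses(lines)
    have <- canonical_pair_id(table$parent1, table$parent2)
    miss <- setdiff(canonical_pair_id(full$parent1, full$parent2), have)
    abort(paste0("incomplete half-diallel; e.g. missing cross ", miss[1]))
  }
  long <- dplyr::bind_rows(
    tibble::tibble(line_id = table$parent1, gebv = table$gebv),
    tibble::tibble(line_id = table$parent2, gebv = table$gebv)
  )
  long |>
    dplyr::group_by(.data$line_id) |>
    dplyr::summarise(gca = mean(.data$gebv), n_crosses = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$gca))
}

#' Heterotic-pattern summary over germplasm groups
#'
#' Classifies every cross by the unordered pair of its parents' germplasm
#' groups (`k` groups give `k (k + 1) / 2` categories), reporting count,
#' mean and sd of GEBV per category, plus, for each requested top
#' fraction, each category's share of the top set and the share of top
#' crosses with at least one parent in each single group.
#'
#' @param table a `cross_table`.
#' @param groups named vector (line id -> group) or tibble
#'   `(line_id, group)`.
#' @param top_fractions fractions to profile, default `c(0.05, 0.10)`.
#' @return a `heterotic_summary` list: `categories`, `top_shares`,
#'   `group_presence`, `overall_mean`.
#' @export
heterotic_summary <- function(table, groups, top_fractions = c(0.05, 0.10)) {
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$line_id)
  lines <- unique(c(table$parent1, table$parent2))
  unlabeled <- setdiff(lines, names(groups))
  if (length(unlabeled)) {
    abort(paste0("unlabeled parent(s): ", paste(head(unlabeled, 5), collapse = ", ")))
  }
  tab <- table |>
    dplyr::mutate(category = canonical_pair_id(unname(groups[.data$parent1]),
                                               unname(groups[.data$parent2])))
  categories <- tab |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(), mean_gebv = mean(.data$gebv),
                     sd_gebv = sd(.data$gebv), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_gebv))

  group_levels <- sort(unique(unname(groups[lines])))
  top_shares <- purrr::map_dfr(top_fractions, function(f) {
    top <- top_fraction(tab, f)
    top |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(fraction = f, share = .data$n / nrow(top)) |>
      dplyr::select("fraction", "category", "n", "share")
  })
  group_presence <- purrr::map_dfr(top_fractions, function(f) {
    top <- top_fraction(tab, f)
    purrr::map_dfr(group_levels, function(gr) {
      hit <- groups[top$parent1] == gr | groups[top$parent2] == gr
      tibble::tibble(fraction = f, group = gr,
                     share_with_parent = mean(hit))
    })
  })
  structure(
    list(categories = categories, top_shares = top_shares,
         group_presence = group_presence, overall_mean = mean(tab$gebv),
         n_crosses = nrow(tab), k_groups = length(group_levels)),
    class = "heterotic_summary"
  )
}

#' @export
print.heterotic_summary <- function(x, ...) {
  cat("Heterotic patterns:", nrow(x$categories), "categories over",
      x$k_groups, "groups;", x$n_crosses, "crosses, overall mean GEBV",
      signif(x$overall_mean, 5), "\n")
  print(x$categories)
  invisible(x)
}

#' @export
tidy.heterotic_summary <- function(x, ...) x$categories

#' Write a heterotic summary as JSON
#'
#' @param summary a `heterotic_summary`.
#' @param path output path.
#' @export
write_heterotic_summary <- function(summary, path) {
  jsonlite::write_json(
    list(categories = summary$categories, top_shares = summary$top_shares,
         group_presence = summary$group_presence,
         overall_mean = summary$overall_mean, n_crosses = summary$n_crosses),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
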