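# Marker retention filters and imputation.

#' Filter markers for hybrid genomic prediction
#'
#' Retains a marker only if it passes, in order:
#' (a) at least two distinct non-missing genotype classes at the locus,
#' (b) fraction of missing calls at most `max_missing`,
#' (c) minor-allele frequency among non-missing calls at least
#' `min_rare_allele`.
#' A dropped marker is attributed to the first criterion it fails, so the
#' per-criterion drop counts and the kept count always sum to the input
#' count. Marker order is preserved.
#'
#' @param g genotype matrix (lines x markers).
#' @param max_missing maximum tolerated missing fraction per marker.
#' @param min_rare_allele minimum minor-allele frequency per marker.
#' @return a list with `genotypes` (the filtered matrix) and `report`, a
#'   `filter_report` object; `tidy()` on the report gives the per-criterion
#'   drop table.
#' @export
filter_hybrid_markers <- function(g, max_missing = 0.3, min_rare_allele = 0.1) {
  validate_genotypes(g, fractional = TRUE)
  if (ncol(g) == 0) abort("empty genotype matrix")
  n <- nrow(g)

  n_classes <- apply(g, 2, function(x) length(unique(x[!is.na(x)])))
  miss_frac <- colMeans(is.na(g))
  p_alt <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  maf[is.nan(maf)] <- 0

  fail_a <- n_classes < 2
  fail_b <- !fail_a & miss_frac > max_missing
  fail_c <- !fail_a & !fail_b & maf < min_rare_allele
  keep <- !(fail_a | fail_b | fail_c)

  kept <- g[, keep, drop = FALSE]
  info <- attr(g, "marker_info")
  if (!is.null(info)) attr(kept, "marker_info") <- info[keep, , drop = FALSE]

  report <- structure(
    list(
      n_input_markers = ncol(g),
      n_kept = sum(keep),
      drops = c(monomorphic = sum(fail_a),
                missingness = sum(fail_b),
                rare_allele = sum(fail_c)),
      max_missing = max_missing,
      min_rare_allele = min_rare_allele,
      kept_marker_ids = colnames(kept)
    ),
    class = "filter_report"
  )
  if (report$n_kept == 0) warn("all markers dropped by the retention filters")
  list(genotypes = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Marker retention filter\n")
  cat("  input markers:", x$n_input_markers, "\n")
  cat("  kept:         ", x$n_kept, "\n")
  cat("  dropped: <2 genotype classes", x$drops[["monomorphic"]],
      "| missing >", x$max_missing, ":", x$drops[["missingness"]],
      "| MAF <", x$min_rare_allele, ":", x$drops[["rare_allele"]], "\n")
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) {
  tibble::tibble(
    criterion = c("kept", names(x$drops)),
    n = c(x$n_kept, unname(x$drops))
  )
}

#' Write a filter report as JSON
#'
#' @param report a `filter_report`.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    list(
      n_input_markers = report$n_input_markers,
      n_kept = report$n_kept,
      drops = as.list(report$drops),
      kept_marker_ids = report$kept_marker_ids
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Impute missing dosages by the marker mean
#'
#' Each missing entry is replaced by the mean of the non-missing calls at
#' that marker; observed entries are untouched, so per-marker means are
#' preserved exactly. Refuses markers with no observed call (filter first).
#'
#' @param g genotype or hybrid-genotype matrix.
#' @return matrix of the same shape with no missing entries.
#' @export
impute_missing <- function(g) {
  if (!anyNA(g)) return(g)
  mu <- colMeans(g, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu))) {
    abort("some markers have no observed call; run filter_hybrid_markers() first")
  }
  idx <- which(is.na(g))
  g[idx] <- mu[((idx - 1) %/% nrow(g)) + 1]
  g
}

#' Construct in-silico hybrid genotypes from inbred parents
#'
#' The dosage of a hybrid at a marker is the mean of its two parents'
#' dosages, which for fully inbred parents is exactly the F1 genotype on
#' the additive 0-2 scale (0 x 2 -> 1). The entry is missing when either
#' parent is missing. Hybrids are identified canonically with the
#' lexicographically smaller parent first, so `(A, B)` and `(B, A)` yield
#' the same row.
#'
#' @param parents genotype matrix of the inbred lines.
#' @param crosses two-column data frame (or tibble) of parent pairs.
#' @return hybrid genotype matrix (hybrids x markers) with a `parents`
#'   attribute tibble `(hybrid_id, parent1, parent2)`.
#' @export
make_hybrid_genotypes <- function(parents, crosses) {
  validate_genotypes(parents, fractional = TRUE)
  crosses <- as.data.frame(crosses)[, 1:2]
  names(crosses) <- c("parent1", "parent2")
  unknown <- setdiff(unique(c(crosses$parent1, crosses$parent2)), rownames(parents))
  if (length(unknown)) {
    abort(paste0("unknown parent line(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  if (any(crosses$parent1 == crosses$parent2)) {
    abort("self-crosses are excluded from the diallel")
  }
  pairs <- canonical_pairs(crosses$parent1, crosses$parent2)
  h <- (parents[pairs$parent1, , drop = FALSE] +
          parents[pairs$parent2, , drop = FALSE]) / 2
  ids <- paste(pairs$parent1, pairs$parent2, sep = " x ")
  rownames(h) <- ids
  attr(h, "parents") <- tibble::tibble(
    hybrid_id = ids, parent1 = pairs$parent1, parent2 = pairs$parent2
  )
  h
}
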