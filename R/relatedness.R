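# Genomic relationship (GRM) and identity-by-state (IBS) matrices.

#' Genomic relationship matrix (VanRaden scaling)
#'
#' Columns of the dosage matrix are centered by twice the observed
#' alt-allele frequency and scaled by `sqrt(2 p (1 - p))`; the GRM is
#' `G = W W' / m`. Under this scaling the expected diagonal is 1 for a
#' population in Hardy-Weinberg proportions. Input must be imputed
#' (no missing) and every marker polymorphic.
#'
#' @param g genotype matrix, no missing entries.
#' @return symmetric n x n matrix with attribute `kind = "grm"`.
#' @export
compute_grm <- function(g) {
  if (anyNA(g)) abort("compute_grm needs a complete matrix; impute_missing() first")
  if (nrow(g) < 2) abort("need at least two lines")
  p <- colMeans(g) / 2
  if (any(p <= 0 | p >= 1)) {
    abort("monomorphic marker(s) present; run filter_hybrid_markers() first")
  }
  w <- sweep(g, 2, 2 * p)
  w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  grm <- tcrossprod(w) / ncol(g)
  grm <- (grm + t(grm)) / 2
  dimnames(grm) <- list(rownames(g), rownames(g))
  attr(grm, "kind") <- "grm"
  grm
}

#' Identity-by-state similarity matrix
#'
#' `IBS_ij = 1 - mean(|d_i - d_j| / 2)` over the markers where both lines
#' are observed; the diagonal is 1. Missing calls are allowed: each pair
#' uses its pairwise-complete markers. Integer dosage matrices use an
#' indicator-product fast path; fractional dosages fall back to a chunked
#' generic path.
#'
#' @param g genotype matrix, missing allowed.
#' @return symmetric n x n matrix in `[0, 1]` with attribute `kind = "ibs"`.
#' @export
compute_ibs <- function(g) {
  if (nrow(g) < 2) abort("need at least two lines")
  v <- g[!is.na(g)]
  integerish <- all(v %in% c(0, 1, 2))
  obs <- !is.na(g)
  shared <- tcrossprod(obs * 1)
  if (any(shared == 0)) abort("some line pair shares no non-missing marker")
  if (integerish) {
    a0 <- (!is.na(g) & g == 0) * 1
    a1 <- (!is.na(g) & g == 1) * 1
    a2 <- (!is.na(g) & g == 2) * 1
    # sum over shared markers of |d_i - d_j|: distance 2 for 0-2 pairs, 1
    # for 0-1 and 1-2 pairs
    s <- 2 * (tcrossprod(a0, a2) + tcrossprod(a2, a0)) +
      tcrossprod(a0, a1) + tcrossprod(a1, a0) +
      tcrossprod(a1, a2) + tcrossprod(a2, a1)
  } else {
    n <- nrow(g)
    g0 <- g
    g0[is.na(g0)] <- 0
    s <- matrix(0, n, n)
    for (i in seq_len(n)) {
      d <- abs(sweep(g0, 2, g0[i, ], "-"))
      d[!obs] <- 0
      d <- sweep(d, 2, obs[i, ], "*")
      s[i, ] <- rowSums(d)
    }
  }
  ibs <- 1 - (s / shared) / 2
  ibs <- (ibs + t(ibs)) / 2
  diag(ibs) <- 1
  dimnames(ibs) <- list(rownames(g), rownames(g))
  attr(ibs, "kind") <- "ibs"
  ibs
}

#' Rescale an IBS similarity matrix to the relationship (correlation) scale
#'
#' Raw IBS is an absolute similarity: two unrelated lines still share
#' alleles by chance, so its entries live on a compressed scale and a
#' Haseman-Elston slope on raw IBS over-estimates the genetic variance.
#' Under independence the expected IBS between two lines is
#' `1 - b`, where the baseline dissimilarity `b` is the mean over markers
#' of `E|x - x'| / 2` for two independent draws from the marker's dosage
#' distribution, and the genetic correlation is linear in IBS:
#' `r = (IBS - (1 - b)) / b`. This map sends the no-missingness diagonal
#' to 1 and the expected unrelated pair to 0, putting the HE slope on the
#' heritability scale.
#'
#' @param ibs IBS matrix from [compute_ibs()].
#' @param g the genotype matrix the IBS was computed from (used to
#'   estimate the baseline dissimilarity).
#' @return matrix with attribute `kind = "ibs_rel"` and `baseline`.
#' @export
ibs_to_relationship <- function(ibs, g) {
  b <- baseline_dissimilarity(g)
  if (b <= 0) abort("no marker variation: baseline dissimilarity is zero")
  rel <- (ibs - (1 - b)) / b
  attr(rel, "kind") <- "ibs_rel"
  attr(rel, "baseline") <- b
  rel
}

baseline_dissimilarity <- function(g) {
  per_marker <- apply(g, 2, function(x) {
    x <- sort(x[!is.na(x)])
    n <- length(x)
    if (n < 2) return(NA_real_)
    # E|x - x'| for two independent draws from the empirical distribution
    2 * sum((2 * seq_len(n) - n - 1) * x) / n^2
  })
  mean(per_marker, na.rm = TRUE) / 2
}

#' Write / read a relatedness matrix as square TSV
#'
#' @param rel symmetric matrix with ids as dimnames.
#' @param path file path.
#' @export
write_relatedness <- function(rel, path) {
  df <- data.frame(id = rownames(rel), rel, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relatedness
#' @param kind relationship kind to tag the matrix with on read.
#' @export
read_relatedness <- function(path, kind = c("grm", "ibs")) {
  kind <- match.arg(kind)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    row.names = 1)
  m <- as.matrix(tab)
  attr(m, "kind") <- kind
  m
}
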