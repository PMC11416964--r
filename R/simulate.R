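# Synthetic breeding population with full ground truth.
#
# The simulator emulates a maize-style hybrid breeding design: a few
# hundred fully inbred founder lines structured into germplasm groups,
# tens of thousands of biallelic SNPs (scaled down as configured), an
# additive QTL architecture, hybrid phenotypes generated at a target
# heritability, and optional additive shifts attached to germplasm-group
# pairings to plant a heterotic pattern.

#' Simulation configuration
#'
#' @param n_lines_per_group named integer vector: founder lines per
#'   germplasm group.
#' @param n_markers number of biallelic SNPs.
#' @param divergence_f Balding-Nichols differentiation parameter F in
#'   (0, 1); larger F means more divergent groups.
#' @param n_qtl number of causal markers (<= `n_markers`).
#' @param h2_target narrow-sense heritability of the simulated trait, in
#'   (0, 1].
#' @param group_shift named numeric vector of additive shifts per unordered
#'   group pair, names like `"A x B"` (see [canonical_pair_id()]); empty
#'   for no heterotic structure.
#' @param missing_rate fraction of genotype calls masked as missing.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_lines_per_group = c(temperate = 50, temp_tropic = 50, tropic = 50),
                       n_markers = 2000, divergence_f = 0.2, n_qtl = 200,
                       h2_target = 0.7, group_shift = numeric(0),
                       missing_rate = 0, seed = 1) {
  if (is.null(names(n_lines_per_group)) || any(names(n_lines_per_group) == "")) {
    abort("n_lines_per_group must be a named vector of group sizes")
  }
  if (any(n_lines_per_group < 1)) abort("every group needs at least one line")
  if (n_markers < 1) abort("n_markers must be positive")
  if (n_qtl < 1 || n_qtl > n_markers) abort("need 1 <= n_qtl <= n_markers")
  if (h2_target <= 0 || h2_target > 1) abort("h2_target must be in (0, 1]")
  if (divergence_f <= 0 || divergence_f >= 1) abort("divergence_f must be in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1)")
  structure(
    list(n_lines_per_group = n_lines_per_group, n_markers = n_markers,
         divergence_f = divergence_f, n_qtl = n_qtl, h2_target = h2_target,
         group_shift = group_shift, missing_rate = missing_rate, seed = seed),
    class = "sim_config"
  )
}

#' Simulate inbred founder lines with germplasm-group structure
#'
#' Allele frequencies follow the Balding-Nichols construction: each
#' marker's ancestral frequency is uniform on `[0.1, 0.9]`, and each
#' group's frequency is Beta-distributed with mean `p` and variance
#' `F p (1 - p)`. Lines are fully homozygous (dosage 0 or 2) before
#' missingness is applied.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (matrix, lines x markers) and `truth`, a
#'   tibble-backed list recording `group_of_line`.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- names(config$n_lines_per_group)
  n <- sum(config$n_lines_per_group)
  m <- config$n_markers
  f <- config$divergence_f

  p_anc <- runif(m, 0.1, 0.9)
  shape <- (1 - f) / f
  g <- matrix(NA_real_, n, m)
  group_of_line <- rep(groups, config$n_lines_per_group)
  row <- 0
  for (gr in groups) {
    ng <- config$n_lines_per_group[[gr]]
    p_g <- rbeta(m, p_anc * shape, (1 - p_anc) * shape)
    # inbred lines: one allele draw per line per marker, dosage 0 or 2
    g[row + seq_len(ng), ] <- 2 * matrix(
      rbinom(ng * m, 1, rep(p_g, each = ng)), ng, m)
    row <- row + ng
  }
  line_ids <- sprintf("L%03d", seq_len(n))
  dimnames(g) <- list(line_ids, sprintf("M%05d", seq_len(m)))
  if (config$missing_rate > 0) {
    mask <- runif(length(g)) < config$missing_rate
    g[mask] <- NA_real_
  }
  truth <- list(group_of_line = setNames(group_of_line, line_ids))
  list(genotypes = g, truth = truth)
}

#' Simulate an additive QTL architecture
#'
#' QTL positions are sampled without replacement; effects are i.i.d.
#' standard normal, then rescaled so the sample variance of the true
#' genetic values across the founder lines is exactly 1 (missing dosages
#' are imputed by the marker mean for the genetic value). A panel with no
#' genetic variation is flagged `degenerate` and left unscaled.
#'
#' @param genotypes founder genotype matrix.
#' @param n_qtl number of causal markers.
#' @param seed integer seed.
#' @return list: `qtl_indices`, `qtl_effects` (named by marker),
#'   `true_genetic_values` (founder lines), `degenerate`.
#' @export
simulate_qtl_effects <- function(genotypes, n_qtl, seed = 1) {
  m <- ncol(genotypes)
  if (n_qtl < 1) abort("n_qtl must be at least 1")
  if (n_qtl > m) abort("n_qtl exceeds the number of markers")
  set.seed(seed)
  idx <- sort(sample.int(m, n_qtl))
  eff <- rnorm(n_qtl)
  gimp <- impute_missing(genotypes[, idx, drop = FALSE])
  gv <- drop(gimp %*% eff)
  v <- var(gv)
  degenerate <- !is.finite(v) || v <= 0
  if (!degenerate) {
    eff <- eff / sqrt(v)
    gv <- gv / sqrt(v)
  }
  list(qtl_indices = idx,
       qtl_effects = setNames(eff, colnames(genotypes)[idx]),
       true_genetic_values = setNames(gv, rownames(genotypes)),
       degenerate = degenerate)
}

#' Genetic values of arbitrary genotypes under a simulated architecture
#'
#' @param genotypes matrix (lines or hybrids x markers) covering the QTL
#'   columns; missing entries imputed by marker mean.
#' @param truth result of [simulate_qtl_effects()].
#' @return named numeric vector.
#' @export
true_genetic_values <- function(genotypes, truth) {
  gimp <- impute_missing(genotypes[, names(truth$qtl_effects), drop = FALSE])
  setNames(drop(gimp %*% truth$qtl_effects), rownames(genotypes))
}

#' Simulate hybrid phenotypes at a target heritability
#'
#' Phenotype = hybrid genetic value + group-pair shift + Gaussian noise
#' with variance `sigma_g^2 (1 - h2) / h2`, where `sigma_g^2` is the
#' variance of the hybrid genetic values; `h2_target = 1` gives exact
#' genetic values. Shifts are looked up by the canonical group-pair id of
#' the two parents' germplasm groups.
#'
#' @param hybrids hybrid genotype matrix from [make_hybrid_genotypes()].
#' @param truth QTL architecture from [simulate_qtl_effects()].
#' @param h2_target heritability in (0, 1].
#' @param group_of_line named vector mapping line id to group (required
#'   when `group_shift` is nonempty).
#' @param group_shift named shifts per group pair (see [sim_config()]).
#' @param seed integer seed.
#' @param trait_name name of the trait column.
#' @return phenotype tibble `(hybrid_id, parent1, parent2, <trait>)` with
#'   attribute `genetic_values`.
#' @export
simulate_hybrid_phenotypes <- function(hybrids, truth, h2_target,
                                       group_of_line = NULL,
                                       group_shift = numeric(0),
                                       seed = 1, trait_name = "trait") {
  if (nrow(hybrids) == 0) abort("no hybrids to phenotype")
  if (h2_target <= 0 || h2_target > 1) {
    abort("h2_target must be in (0, 1]: noise scaling is undefined at 0")
  }
  parents <- attr(hybrids, "parents")
  if (is.null(parents)) abort("hybrid matrix lacks the parents attribute")
  gv <- true_genetic_values(hybrids, truth)
  shift <- rep(0, nrow(hybrids))
  if (length(group_shift)) {
    if (is.null(group_of_line)) abort("group_of_line needed when group_shift is set")
    unlabeled <- setdiff(unique(c(parents$parent1, parents$parent2)),
                         names(group_of_line))
    if (length(unlabeled)) {
      abort(paste0("no group label for parent(s): ",
                   paste(head(unlabeled, 5), collapse = ", ")))
    }
    gp <- canonical_pair_id(group_of_line[parents$parent1],
                           group_of_line[parents$parent2])
    # pairs without an entry get no shift
    shift <- unname(group_shift[gp])
    shift[is.na(shift)] <- 0
  }
  s_g2 <- var(gv)
  set.seed(seed)
  noise <- if (h2_target == 1) 0 else rnorm(length(gv), 0, sqrt(s_g2 * (1 - h2_target) / h2_target))
  out <- tibble::tibble(
    hybrid_id = parents$hybrid_id,
    parent1 = parents$parent1,
    parent2 = parents$parent2,
    !!trait_name := unname(gv + shift + noise)
  )
  attr(out, "genetic_values") <- gv
  out
}

#' Simulate a complete breeding study
#'
#' One call reproducing the whole study design: founders with group
#' structure, a QTL architecture per trait, a random sample of phenotyped
#' crosses, and phenotypes at per-trait heritabilities. Distinct
#' sub-seeds are derived from `config$seed` for each stage.
#'
#' @param config a [sim_config()].
#' @param n_hybrids number of phenotyped crosses sampled from the
#'   half-diallel.
#' @param traits named numeric vector of per-trait target heritabilities;
#'   defaults to a single trait at `config$h2_target`.
#' @return list: `founders`, `truth` (incl. per-trait architectures),
#'   `hybrids` (genotypes of phenotyped crosses), `phenotypes`.
#' @export
simulate_study <- function(config, n_hybrids = 1000,
                           traits = c(trait = config$h2_target)) {
  fd <- simulate_founders(config)
  all_pairs <- enumerate_crosses(rownames(fd$genotypes))
  if (n_hybrids > nrow(all_pairs)) abort("n_hybrids exceeds the half-diallel size")
  set.seed(config$seed + 1L)
  sampled <- all_pairs[sort(sample.int(nrow(all_pairs), n_hybrids)), ]
  parents_imp <- impute_missing(fd$genotypes)
  hyb <- make_hybrid_genotypes(parents_imp, sampled)

  pheno <- NULL
  arch <- list()
  for (i in seq_along(traits)) {
    tr <- names(traits)[i]
    truth <- simulate_qtl_effects(fd$genotypes, config$n_qtl,
                                  seed = config$seed + 100L + i)
    arch[[tr]] <- truth
    ph <- simulate_hybrid_phenotypes(
      hyb, truth, traits[[i]],
      group_of_line = fd$truth$group_of_line,
      group_shift = config$group_shift,
      seed = config$seed + 200L + i, trait_name = tr)
    pheno <- if (is.null(pheno)) ph else dplyr::left_join(
      pheno, ph[, c("hybrid_id", tr)], by = "hybrid_id")
  }
  list(
    founders = fd$genotypes,
    truth = c(fd$truth, list(architecture = arch, h2_target = traits)),
    hybrids = hyb,
    phenotypes = pheno
  )
}
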