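test_that("founder simulation is seed-deterministic and fully homozygous", {
  cfg <- sim_config(n_lines_per_group = c(A = 50, B = 50, C = 50),
                    n_markers = 2000, divergence_f = 0.2, seed = 1)
  a <- simulate_founders(cfg)
  b <- simulate_founders(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_true(all(a$genotypes %in% c(0, 2)))
  expect_equal(unname(table(a$truth$group_of_line)), c(50L, 50L, 50L),
               ignore_attr = TRUE)
})

test_that("group differentiation tracks the Balding-Nichols F parameter", {
  ibs_gap <- function(f, seed) {
    cfg <- sim_config(n_lines_per_group = c(A = 25, B = 25), n_markers = 5000,
                      divergence_f = f, seed = seed)
    fd <- simulate_founders(cfg)
    ibs <- compute_ibs(fd$genotypes)
    grp <- fd$truth$group_of_line[rownames(ibs)]
    same <- outer(grp, grp, "==") & upper.tri(ibs)
    diff <- (!outer(grp, grp, "==")) & upper.tri(ibs)
    mean(ibs[same]) - mean(ibs[diff])
  }
  # divergence_f -> 0: within- and between-group similarity coincide
  expect_lt(abs(ibs_gap(1e-4, 2)), 0.01)
  # F = 0.2: clear margin, checked over 10 Monte-Carlo replicates
  gaps <- vapply(1:10, function(r) ibs_gap(0.2, 100 + r), numeric(1))
  expect_gt(min(gaps), 0.02)
})

test_that("QTL effects are scaled to unit genetic variance across lines", {
  g <- random_inbreds(200, 100, seed = 7)
  tru <- simulate_qtl_effects(g, n_qtl = 20, seed = 3)
  expect_length(tru$qtl_effects, 20)
  expect_equal(var(tru$true_genetic_values), 1, tolerance = 1e-9)
  # determinism
  tru2 <- simulate_qtl_effects(g, n_qtl = 20, seed = 3)
  expect_identical(tru$qtl_indices, tru2$qtl_indices)
  expect_identical(tru$qtl_effects, tru2$qtl_effects)
})

test_that("a panel with no variation is reported as degenerate", {
  g <- matrix(2, 10, 5, dimnames = list(paste0("L", 1:10), paste0("M", 1:5)))
  tru <- simulate_qtl_effects(g, n_qtl = 5, seed = 1)
  expect_true(tru$degenerate)
  expect_equal(var(tru$true_genetic_values), 0)
  expect_error(simulate_qtl_effects(g, n_qtl = 0), "at least 1")
})

test_that("h2 = 1 phenotypes equal the true genetic values exactly", {
  st <- sim_training_problem(n_lines = 30, n_hybrids = 100, h2 = 1, seed = 5,
                             groups = c(A = 15, B = 15))
  expect_equal(unname(st$phenotypes$trait),
               unname(attr(st$phenotypes, "genetic_values")))
})

test_that("realized heritability matches the target at n = 2000", {
  cfg <- sim_config(n_lines_per_group = c(A = 40, B = 40, C = 40),
                    n_markers = 600, n_qtl = 120, seed = 13)
  fd <- simulate_founders(cfg)
  tru <- simulate_qtl_effects(fd$genotypes, 120, seed = 14)
  crosses <- enumerate_crosses(rownames(fd$genotypes))
  set.seed(15)
  hyb <- make_hybrid_genotypes(fd$genotypes,
                               crosses[sample.int(nrow(crosses), 2000), ])
  r2 <- vapply(1:20, function(r) {
    ph <- simulate_hybrid_phenotypes(hyb, tru, h2_target = 0.5, seed = r)
    cor(ph$trait, attr(ph, "genetic_values"))^2
  }, numeric(1))
  expect_gte(mean(r2), 0.44)
  expect_lte(mean(r2), 0.56)
})

test_that("a planted group-pair shift moves exactly that category's mean", {
  # averaged over architectures: a single QTL draw leaves the categories
  # with small genetic mean differences of their own
  gaps <- vapply(1:5, function(r) {
    cfg <- sim_config(n_lines_per_group = c(A = 40, B = 40, C = 40),
                      n_markers = 600, n_qtl = 120, seed = 23 + 10 * r)
    fd <- simulate_founders(cfg)
    tru <- simulate_qtl_effects(fd$genotypes, 120, seed = 24 + 10 * r)
    crosses <- enumerate_crosses(rownames(fd$genotypes))
    set.seed(25 + 10 * r)
    hyb <- make_hybrid_genotypes(fd$genotypes,
                                 crosses[sample.int(nrow(crosses), 2000), ])
    ph <- simulate_hybrid_phenotypes(hyb, tru, h2_target = 0.9,
                                     group_of_line = fd$truth$group_of_line,
                                     group_shift = c("A x A" = 10),
                                     seed = 26 + 10 * r)
    grp <- fd$truth$group_of_line
    cat_aa <- grp[ph$parent1] == "A" & grp[ph$parent2] == "A"
    mean(ph$trait[cat_aa]) - mean(ph$trait[!cat_aa])
  }, numeric(1))
  expect_equal(mean(gaps), 10, tolerance = 0.5 / 10)
})

test_that("phenotype simulation rejects undefined noise scalings", {
  st <- sim_training_problem(n_lines = 30, n_hybrids = 50, seed = 2,
                             groups = c(A = 15, B = 15))
  arch <- st$truth$architecture$trait
  expect_error(simulate_hybrid_phenotypes(st$hybrids, arch, h2_target = 0),
               "h2_target")
  expect_error(simulate_hybrid_phenotypes(st$hybrids[0, ], arch, 0.5),
               "no hybrids")
})

test_that("simulate_study ties its pieces together reproducibly", {
  cfg <- sim_config(n_lines_per_group = c(A = 20, B = 20), n_markers = 300,
                    n_qtl = 50, h2_target = 0.6, missing_rate = 0.05, seed = 31)
  s1 <- simulate_study(cfg, n_hybrids = 150)
  s2 <- simulate_study(cfg, n_hybrids = 150)
  expect_identical(s1$founders, s2$founders)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_equal(nrow(s1$phenotypes), 150)
  expect_true(anyNA(s1$founders))
  expect_false(anyNA(s1$hybrids))  # hybrids built from imputed parents
})
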