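random_cross_table <- function(n_lines = 12, seed = 1) {
  ids <- sprintf("L%03d", seq_len(n_lines))
  tab <- enumerate_crosses(ids)
  set.seed(seed)
  tab$gebv <- rnorm(nrow(tab), 100, 15)
  class(tab) <- c("cross_table", class(tab))
  tab
}

test_that("the half-diallel has N(N-1)/2 canonical lexicographic pairs", {
  p360 <- enumerate_crosses(sprintf("L%03d", 1:360))
  expect_equal(nrow(p360), 64620)
  expect_equal(nrow(enumerate_crosses(c("a", "b"))), 1)
  p5 <- enumerate_crosses(c("e", "c", "a", "d", "b"))
  expect_equal(nrow(p5), 10)
  expect_true(all(p5$parent1 < p5$parent2))
  expect_identical(p5, p5[order(p5$parent1, p5$parent2), ])
  expect_error(enumerate_crosses(c("a", "a", "b")), "duplicate")
})

test_that("exhaustive prediction is invariant to batching", {
  st <- sim_training_problem(n_lines = 24, n_markers = 200, n_qtl = 40,
                             n_hybrids = 150, h2 = 0.8, seed = 71,
                             groups = c(A = 12, B = 12))
  y <- setNames(st$phenotypes$trait, st$phenotypes$hybrid_id)
  model <- fit_rrblup(st$hybrids, y)
  a <- predict_all_crosses(model, st$founders_kept, batch_size = 7)
  b <- predict_all_crosses(model, st$founders_kept, batch_size = 1000)
  expect_equal(nrow(a), 24 * 23 / 2)
  expect_equal(a$gebv, b$gebv, tolerance = 1e-12)
  expect_identical(a[, c("parent1", "parent2")], b[, c("parent1", "parent2")])
})

test_that("additive GEBV of a cross is the parental-average prediction", {
  st <- sim_training_problem(n_lines = 20, n_markers = 150, n_qtl = 30,
                             n_hybrids = 120, h2 = 0.9, seed = 73,
                             groups = c(A = 10, B = 10))
  y <- setNames(st$phenotypes$trait, st$phenotypes$hybrid_id)
  model <- fit_rrblup(st$hybrids, y)
  parents <- st$founders_kept[1:5, ]
  tab <- predict_all_crosses(model, parents)
  # oracle: mu + u . ((zA + zB)/2 - centers), directly
  u <- model$marker_effects
  for (k in seq_len(nrow(tab))) {
    zmid <- (parents[tab$parent1[k], ] + parents[tab$parent2[k], ]) / 2
    expect_equal(tab$gebv[k],
                 model$mu_hat + sum((zmid - model$train_marker_means) * u),
                 tolerance = 1e-10)
  }
})

test_that("top-fraction selection sizes follow floor(fraction x total)", {
  tab <- random_cross_table(360, seed = 2)   # 64620 crosses
  expect_equal(nrow(top_fraction(tab, 0.05)), 3231)
  expect_equal(nrow(top_fraction(tab, 0.10)), 6462)
  full <- top_fraction(tab, 1)
  expect_equal(nrow(full), nrow(tab))
  expect_true(all(diff(full$gebv) <= 0))
  expect_error(top_fraction(tab, 0), "fraction")
})

test_that("tied GEBVs at the selection boundary break deterministically", {
  tab <- random_cross_table(8, seed = 3)
  tab$gebv <- rep(1, nrow(tab))
  top <- top_fraction(tab, 0.25)
  expect_equal(nrow(top), 7)
  expect_identical(top[, c("parent1", "parent2")],
                   tab[order(tab$parent1, tab$parent2)[1:7],
                       c("parent1", "parent2")])
})

test_that("genetic gain matches hand computation and is monotone", {
  tab <- random_cross_table(5, seed = 4)
  tab$gebv <- 1:10
  expect_equal(genetic_gain(tab, 0.2), mean(c(10, 9)) - mean(1:10))
  expect_equal(genetic_gain(tab, 1), 0)
  const <- tab; const$gebv <- rep(7, 10)
  expect_equal(genetic_gain(const, 0.3), 0)
  rt <- random_cross_table(20, seed = 5)
  gains <- vapply(c(0.05, 0.1, 0.25, 0.5, 1), function(f) genetic_gain(rt, f),
                  numeric(1))
  expect_true(all(gains >= 0))
  expect_true(all(diff(gains) <= 1e-12))
})

test_that("GCA averages each line over its N-1 crosses and keeps the mean identity", {
  tab <- random_cross_table(15, seed = 6)
  g <- gca(tab)
  expect_equal(nrow(g), 15)
  expect_equal(unique(g$n_crosses), 14)
  # mean of per-line GCAs equals the overall cross mean, exactly
  expect_equal(mean(g$gca), mean(tab$gebv), tolerance = 1e-12)
  const <- tab; const$gebv <- 5
  expect_true(all(gca(const)$gca == 5))
  expect_error(gca(tab[-3, ]), "incomplete")
})

test_that("heterotic categories count k(k+1)/2 and conserve totals", {
  tab <- random_cross_table(12, seed = 7)
  groups <- tibble::tibble(line_id = sprintf("L%03d", 1:12),
                           group = rep(c("temp", "tt", "trop"), each = 4))
  het <- heterotic_summary(tab, groups)
  expect_equal(nrow(het$categories), 6)
  expect_equal(sum(het$categories$n), nrow(tab))
  for (f in unique(het$top_shares$fraction)) {
    sh <- het$top_shares[het$top_shares$fraction == f, ]
    expect_equal(sum(sh$share), 1)
    expect_equal(sum(sh$n), floor(f * nrow(tab)))
  }
  one <- heterotic_summary(tab, tibble::tibble(line_id = sprintf("L%03d", 1:12),
                                               group = "only"))
  expect_equal(nrow(one$categories), 1)
  expect_equal(one$categories$n, nrow(tab))
  expect_error(heterotic_summary(tab, groups[1:5, ]), "unlabeled")
})

test_that("a planted group-level boost is recovered against ground truth", {
  # A carries a GCA boost: +delta for A x A, +delta/2 for A x other.
  # The predicted category gap (A x A vs crosses without an A parent) is
  # compared with the true gap, which includes the architecture's own
  # genetic baseline between categories.
  delta <- 0.7
  errs <- vapply(1:3, function(r) {
    cfg <- sim_config(n_lines_per_group = c(A = 25, B = 25, C = 25),
                      n_markers = 800, n_qtl = 150, h2_target = 0.8,
                      seed = 900 + r,
                      group_shift = c("A x A" = delta, "A x B" = delta / 2,
                                      "A x C" = delta / 2))
    st <- simulate_study(cfg, n_hybrids = 600)
    keep <- filter_hybrid_markers(st$founders, min_rare_allele = 0)$genotypes
    hy <- st$hybrids[, colnames(keep)]
    y <- setNames(st$phenotypes$trait, st$phenotypes$hybrid_id)
    model <- suppressWarnings(fit_heblp_a(hy, y))
    tab <- predict_all_crosses(model, impute_missing(keep))
    grp <- st$truth$group_of_line
    cat_id <- canonical_pair_id(grp[tab$parent1], grp[tab$parent2])
    aa <- cat_id == "A x A"
    rest <- cat_id %in% c("B x B", "B x C", "C x C")
    est_gap <- mean(tab$gebv[aa]) - mean(tab$gebv[rest])
    gv <- true_genetic_values(
      make_hybrid_genotypes(impute_missing(st$founders), tab[, 1:2]),
      st$truth$architecture$trait)
    true_gap <- (mean(gv[aa]) + delta) - mean(gv[rest])
    abs(est_gap - true_gap)
  }, numeric(1))
  expect_lt(max(errs), 0.25 * delta)
})
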