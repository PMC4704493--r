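test_that("hypergeometric tail matches exhaustive enumeration", {
  # the canonical worked example: N=10, K=5, n=4, k=3
  uni <- sprintf("g%02d", 1:10)
  res <- hypergeom_overlap(uni[1:5], c(uni[1:3], uni[6]), uni)
  expect_equal(res$overlap, 3L)
  expect_equal(res$p_value, 55 / 210)
  expect_equal(res$p_value, enumerate_hyper_tail(10, 5, 4, 3))

  # k = 0 spans the whole support
  expect_equal(hypergeom_overlap(uni[1:5], uni[6:9], uni)$p_value, 1)
  # forced total overlap
  expect_equal(hypergeom_overlap(uni, uni, uni)$p_value, 1)

  # enumeration oracle across all feasible configurations with N <= 12
  for (N in 1:12) {
    u <- sprintf("e%02d", seq_len(N))
    for (K in 0:N) {
      for (n in 0:N) {
        k_min <- max(0, K + n - N)
        for (k in k_min:min(K, n)) {
          set_a <- u[seq_len(K)]
          set_b <- c(u[seq_len(k)],
                     u[K + seq_len(n - k)])
          r <- hypergeom_overlap(set_a, set_b, u)
          expect_equal(r$overlap, k)
          expect_equal(r$p_value,
                       min(1, enumerate_hyper_tail(N, K, n, k)),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("hypergeometric pmf and tail behave as a distribution", {
  for (cfg in list(c(20, 7, 5), c(15, 10, 9), c(30, 4, 12))) {
    N <- cfg[1]; K <- cfg[2]; n <- cfg[3]
    support <- max(0, K + n - N):min(K, n)
    expect_equal(sum(dhyper(support, K, N - K, n)), 1, tolerance = 1e-9)
    u <- sprintf("x%03d", seq_len(N))
    ps <- vapply(support, function(k) {
      hypergeom_overlap(u[seq_len(K)],
                        c(u[seq_len(k)], u[K + seq_len(n - k)]),
                        u)$p_value
    }, numeric(1))
    expect_true(all(diff(ps) <= 1e-12))   # non-increasing in k
  }
  expect_error(hypergeom_overlap(c("a", "zzz"), "a", c("a", "b")),
               class = "mimicscreen_membership_error")
})

test_that("target enrichment detects planted signal and not its absence", {
  # planted ~3-fold enrichment in a universe of 1000
  n_sig <- 0L
  for (s in 1:20) {
    set.seed(s)
    universe <- sprintf("g%04d", 1:1000)
    predicted <- sample(universe, 150)
    # responsive genes: 3x over-representation of predicted targets
    p_resp <- ifelse(universe %in% predicted, 0.3, 0.1)
    responsive <- universe[runif(1000) < p_resp]
    r <- target_enrichment(responsive, predicted, universe)
    if (r$p_value < 0.05) n_sig <- n_sig + 1L
  }
  expect_gte(n_sig, 19L)   # >= 95% of replicates

  # total overlap by construction
  u <- sprintf("g%02d", 1:20)
  tot <- target_enrichment(u, u, u)
  expect_equal(tot$overlap, 20L)
  expect_equal(tot$p_value, 1)
  # anti-enrichment: disjoint sets where overlap was expected
  anti <- target_enrichment(u[1:10], u[11:20], u)
  expect_gt(anti$p_value, 0.99)
})

test_that("context-score curve counts two-fold knockdown per bin", {
  pred <- data.frame(gene_id = sprintf("t%02d", 1:8),
                     context_score = c(-0.05, -0.15, -0.25, -0.25, -0.35,
                                       -0.45, -0.5, -0.02),
                     is_expressed = c(rep(TRUE, 7), FALSE))
  lr <- setNames(c(-1.2, -0.5, -1.0, -2.0, 0.2, -1.1, -3.0, -9),
                 pred$gene_id)
  curve <- context_score_curve(pred, lr)
  expect_equal(curve$n_targets, c(1L, 1L, 2L, 1L, 2L))
  # bin (-0.3, -0.2]: both t03 (-1.0, exactly 2-fold) and t04 down
  expect_equal(curve$probability_down[3], 1)
  expect_equal(curve$n_down[1], 1L)     # unexpressed t08 never counted
  # all targets down -> every populated bin at probability 1
  lr_all <- setNames(rep(-2, 8), pred$gene_id)
  c_all <- context_score_curve(pred, lr_all)
  expect_true(all(c_all$probability_down[c_all$n_targets > 0] == 1))
  # empty bin flagged undefined
  pred2 <- pred[pred$context_score > -0.4, ]
  expect_warning(
    c2 <- context_score_curve(pred2, lr,
                              bin_edges = c(0, -0.4, -Inf)),
    class = "mimicscreen_undefined_warning")
  expect_true(is.na(c2$probability_down[2]))
  expect_error(context_score_curve(pred, lr, fold_threshold = 1),
               class = "mimicscreen_config_error")
  expect_error(context_score_curve(pred, lr, bin_edges = c(0, -0.2, -0.1)),
               class = "mimicscreen_config_error")
})

test_that("simulated 41%-down score bin is recovered within binomial error", {
  sim <- simulate_expression_response(n_genes = 3000, seed = 77)
  curve <- context_score_curve(sim$predictions, sim$log2_ratios,
                               bin_edges = c(-0.2, -Inf))
  n <- curve$n_targets[1]
  expect_gte(n, 400)
  se <- sqrt(0.41 * 0.59 / n)
  expect_lt(abs(curve$probability_down[1] - 0.41), 3 * se)
})

test_that("phenocopy nomination requires both pools, positive r, and activity", {
  lines <- paste0("L", 1:6)
  mimic <- c(0.2, 0.9, 0.3, 0.8, 0.1, 0.6)
  perfect <- rbind(mimic, mimic)
  anti <- rbind(1 - mimic, 1 - mimic)
  one_pool <- rbind(mimic, rev(mimic))
  panel <- phenocopy_panel(
    lines, mimic,
    list(gA = perfect, gB = anti, gC = one_pool),
    index_line = "L1",
    screen_viability = c(gA = 0.3, gB = 0.3, gC = 0.3))
  res <- phenocopy_screen(panel)
  expect_equal(res$r_pool1[res$gene_id == "gA"], 1)
  expect_true(res$nominated[res$gene_id == "gA"])
  # strong but negative correlation is rejected (sign requirement)
  expect_lt(res$r_pool1[res$gene_id == "gB"], 0)
  expect_gt(res$r2_pool1[res$gene_id == "gB"], 0.35)
  expect_false(res$nominated[res$gene_id == "gB"])
  # one passing pool is not enough
  expect_false(res$nominated[res$gene_id == "gC"])

  # stage-1 failure blocks nomination even at r = 1
  panel2 <- phenocopy_panel(lines, mimic, list(gA = perfect), "L1",
                            screen_viability = c(gA = 0.9))
  expect_false(phenocopy_screen(panel2)$nominated)

  # constant profile: excluded with a logged reason
  panel3 <- phenocopy_panel(
    lines, mimic, list(gA = perfect, gD = rbind(rep(1, 6), mimic)), "L1",
    screen_viability = c(gA = 0.3, gD = 0.3))
  res3 <- phenocopy_screen(panel3)
  expect_match(attr(res3, "excluded"), "gD")
  expect_false(res3$nominated[res3$gene_id == "gD"])
})

test_that("phenocopy results are invariant to line order and affine rescaling", {
  sim <- simulate_phenocopy_panel(seed = 31)
  res <- phenocopy_screen(sim$panel)
  # permute cell lines consistently
  set.seed(17)
  perm <- sample(seq_along(sim$panel$cell_lines))
  p2 <- phenocopy_panel(
    sim$panel$cell_lines[perm], sim$panel$mimic_profile[perm],
    lapply(sim$panel$gene_profiles, function(m) m[, perm, drop = FALSE]),
    sim$panel$index_line, sim$panel$screen_viability)
  res2 <- phenocopy_screen(p2)
  expect_equal(res2$nominated, res$nominated)
  expect_equal(res2$r_pool1, res$r_pool1)
  # positive affine rescaling of the mimic profile
  p3 <- sim$panel
  p3$mimic_profile <- 3 * p3$mimic_profile + 10
  expect_equal(phenocopy_screen(p3)$r_pool2, res$r_pool2)
})

test_that("nomination set is the intersection of the per-pool rules", {
  sim <- simulate_phenocopy_panel(n_genes = 20, planted_r = 0.7, seed = 9)
  res <- phenocopy_screen(sim$panel)
  pool1_ok <- res$passes_viability_filter & !is.na(res$r_pool1) &
    res$r_pool1 > 0 & res$r2_pool1 > 0.35
  pool2_ok <- res$passes_viability_filter & !is.na(res$r_pool2) &
    res$r_pool2 > 0 & res$r2_pool2 > 0.35
  expect_equal(res$nominated, pool1_ok & pool2_ok)
})
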