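test_that("MK tables apply the >6 marginal filter", {
  t1 <- build_mk_table("g", p_r = 2, p_s = 10, d_r = 10, d_s = 5)
  expect_true(t1$included)   # margins (12, 15, 12, 15) all > 6
  t2 <- build_mk_table("g", p_r = 1, p_s = 2, d_r = 10, d_s = 10)
  expect_false(t2$included)  # P_R + P_S = 3
  t3 <- build_mk_table("g", 0, 0, 0, 0)
  expect_false(t3$included)
})

test_that("MK Fisher p equals hypergeometric enumeration and is symmetric", {
  t1 <- build_mk_table("g", p_r = 2, p_s = 10, d_r = 10, d_s = 5)
  expect_equal(mk_fisher_test(t1), fisher_oracle(10, 5, 2, 10),
               tolerance = 1e-12)
  # proportional table carries no association
  tp <- build_mk_table("g", p_r = 8, p_s = 4, d_r = 4, d_s = 2)
  expect_equal(mk_fisher_test(tp), 1.0)
  # simultaneous row/column swap leaves p unchanged
  set.seed(3)
  for (i in 1:25) {
    x <- rpois(4, 6)
    a <- build_mk_table("g", x[1], x[2], x[3], x[4])
    b <- build_mk_table("g", x[2], x[1], x[4], x[3])
    expect_equal(mk_fisher_test(a), mk_fisher_test(b), tolerance = 1e-12)
    expect_equal(mk_fisher_test(a), fisher_oracle(x[3], x[4], x[1], x[2]),
                 tolerance = 1e-9)
  }
})

test_that("DoS follows its closed form and bounds", {
  t1 <- build_mk_table("g", p_r = 2, p_s = 10, d_r = 10, d_s = 5)
  expect_equal(dos_statistic(t1), 10 / 15 - 2 / 12)  # 0.5
  expect_equal(dos_statistic(build_mk_table("g", 4, 2, 8, 4)), 0)
  expect_equal(dos_statistic(build_mk_table("g", 0, 5, 3, 0)), 1)
  expect_error(dos_statistic(build_mk_table("g", 1, 1, 0, 0)), "undefined")
  set.seed(5)
  for (i in 1:50) {
    x <- rpois(4, 4) + c(1, 1, 1, 1)
    t <- build_mk_table("g", x[1], x[2], x[3], x[4])
    d <- dos_statistic(t)
    expect_gte(d, -1)
    expect_lte(d, 1)
    # same sign as alpha_point whenever both defined and P_S, D_S > 0
    a <- alpha_point(t)
    expect_gte(d * a, -1e-12)
  }
})

test_that("per-gene alpha point estimate follows its closed form", {
  t1 <- build_mk_table("g", p_r = 2, p_s = 10, d_r = 10, d_s = 5)
  expect_equal(alpha_point(t1), 0.9)
  expect_equal(alpha_point(build_mk_table("g", 4, 2, 8, 4)), 0)
  expect_error(alpha_point(build_mk_table("g", 1, 8, 0, 8)), "undefined")
})

test_that("family ML alpha collapses to the pooled point estimate", {
  tabs <- replicate(6, build_mk_table("g", 2, 10, 10, 5), simplify = FALSE)
  est <- alpha_family_ml(tabs)
  expect_lt(abs(est$alpha - 0.9), 1e-3)
  expect_true(est$ci[1] <= est$alpha && est$alpha <= est$ci[2])
  expect_lte(est$alpha, 1)
  expect_error(alpha_family_ml(tabs[1]), "2 included genes")
})

test_that("family ML alpha recovers simulated truth with valid intervals", {
  cfg <- scenario_config(n_background = 0, div_f = 0.2,
                         families = list(F1 = list(n_genes = 120,
                                                   gene_bp = 999,
                                                   large = FALSE,
                                                   alpha_true = 0.4)))
  ann <- generate_genome(cfg, seed = 31)
  d <- generate_divergence(cfg, ann, seed = 32)
  tabs <- lapply(seq_len(nrow(d$counts)), function(k)
    with(d$counts[k, ], build_mk_table(gene, P_R, P_S, D_R, D_S)))
  est <- alpha_family_ml(tabs, d$site_lengths[d$counts$gene])
  expect_lt(abs(est$alpha - 0.4), 0.15)
  expect_true(est$ci[1] <= est$alpha && est$alpha <= est$ci[2])
  expect_lt(est$f, 0.4)
  expect_gt(est$f, 0.1)
})

test_that("omega_a scales alpha by relative synonymous divergence", {
  tabs <- list(build_mk_table("a", 2, 10, 10, 5),
               build_mk_table("b", 3, 9, 8, 7))
  sl <- list(compute_site_lengths(degeneracy = rep(c(1, 1, 4), 100)),
             compute_site_lengths(degeneracy = rep(c(1, 1, 4), 80)))
  est <- alpha_family_ml(tabs, sl)
  est0 <- est
  est0$alpha <- 0
  expect_equal(omega_a(est0, tabs, sl)$omega_a, 0)
  est5 <- est
  est5$alpha <- 0.5
  got <- omega_a(est5, tabs, sl)$omega_a
  DR <- 18; DS <- 12
  Ln <- 200 + 160; Ls <- 100 + 80
  expect_equal(got, 0.5 * (DR / Ln) / (DS / Ls), tolerance = 1e-12)
})

test_that("subgroup contrasts recover ordering and skip empty classes", {
  cfg <- function(a) scenario_config(n_background = 0, div_f = 0.2,
    families = list(F1 = list(n_genes = 60, gene_bp = 999, large = FALSE,
                              alpha_true = a)))
  ann <- generate_genome(cfg(0.4), seed = 41)
  hits <- 0
  for (i in 1:10) {
    dA <- generate_divergence(cfg(0.4), ann, seed = 500 + i)
    dB <- generate_divergence(cfg(0.0), ann, seed = 700 + i)
    tabs <- c(
      lapply(seq_len(nrow(dA$counts)), function(k)
        with(dA$counts[k, ], build_mk_table(gene, P_R, P_S, D_R, D_S))),
      lapply(seq_len(nrow(dB$counts)), function(k)
        with(dB$counts[k, ], build_mk_table(gene, P_R, P_S, D_R, D_S))))
    tags <- rep(c("hot", "cold"), each = nrow(dA$counts))
    ests <- subgroup_contrast(tabs, tags)
    if (ests$hot$alpha > ests$cold$alpha) hits <- hits + 1
  }
  expect_gte(hits, 9)
  expect_warning(
    subgroup_contrast(list(build_mk_table("g", 2, 10, 10, 5)), "solo"),
    "solo")
})

test_that("Bonferroni-significant genes are a subset of nominal ones", {
  set.seed(61)
  tabs <- lapply(1:40, function(i) {
    x <- rpois(4, 8) + 2
    build_mk_table(paste0("g", i), x[1], x[2], x[3], x[4])
  })
  rep <- mk_report(tabs)
  expect_true(all(which(rep$sig_bonf) %in% which(rep$sig)))
})
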