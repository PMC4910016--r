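test_that("Weir-Cockerham estimator hits its analytic anchors", {
  expect_equal(wc_fst_site(c(10, 10), c(1, 0))$theta, 1)
  expect_equal(wc_fst_site(c(7, 3), c(0, 1))$theta, 1)
  expect_equal(wc_fst_site(c(2, 19), c(1, 0))$theta, 1)
  r <- wc_fst_site(c(10, 10), c(0.4, 0.4))
  expect_lte(r$a, 0)
  expect_lte(r$theta, 0)
  expect_false(wc_fst_site(c(10, 8), c(0, 0))$defined)
  expect_false(wc_fst_site(c(10, 8), c(1, 1))$defined)
})

test_that("estimator matches the brute-force ANOVA oracle", {
  set.seed(7)
  for (i in 1:400) {
    npop <- sample(2:5, 1)
    n <- sample(2:25, npop, replace = TRUE)
    counts <- vapply(n, function(k) sample(0:k, 1), 1L)
    p <- counts / n
    got <- wc_fst_site(n, p)$theta
    want <- wc_oracle(n, p)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
  # vectorised two-population path agrees with the scalar estimator
  n1 <- sample(2:30, 200, replace = TRUE)
  n2 <- sample(2:30, 200, replace = TRUE)
  p1 <- round(runif(200) * n1) / n1
  p2 <- round(runif(200) * n2) / n2
  v <- famsel:::wc_fst_vec(n1, n2, p1, p2)
  s <- vapply(1:200, function(i) wc_fst_site(c(n1[i], n2[i]),
                                             c(p1[i], p2[i]))$theta,
              numeric(1))
  expect_equal(v, s, tolerance = 1e-12)
})

test_that("multi-locus Fst decreases with migration rate", {
  mean_theta <- function(M) {
    m <- demography_model(c("a", "b"), c(8, 8),
                          migration = matrix(c(0, M, M, 0), 2, 2))
    reps <- simulate_replicates(m, 300, theta = 3, seed = 300 + round(M * 10))
    th <- unlist(lapply(reps, function(r) {
      H <- r$haplotypes
      if (ncol(H) == 0) return(numeric(0))
      famsel:::wc_fst_vec(8, 8, colMeans(H[1:8, , drop = FALSE]),
                          colMeans(H[9:16, , drop = FALSE]))
    }))
    mean(th, na.rm = TRUE)
  }
  v <- c(mean_theta(0.5), mean_theta(2), mean_theta(8))
  expect_true(all(diff(v) < 0))
})

test_that("gene mean Fst averages defined records over SNPs and pairs", {
  fst <- data.frame(site = c(1, 1, 2, 2, 3),
                    theta = c(0.2, 0.4, NA, 0.6, 0.9),
                    pair = c("A-B", "A-C", "A-B", "A-C", "A-B"))
  expect_equal(gene_mean_fst(fst, c(1, 2)), mean(c(0.2, 0.4, 0.6)))
  expect_equal(gene_mean_fst(fst, 3), 0.9)
  expect_true(is.na(gene_mean_fst(fst, integer(0))))
})

test_that("empirical tail threshold uses the ceiling-rank convention", {
  x <- seq_len(1000) / 1000
  thr <- empirical_tail_threshold(x, 0.01)
  expect_equal(thr, 0.990)
  expect_equal(sum(x >= thr), 11)
  expect_equal(empirical_tail_threshold(x, 0), 1.0)
  # ties: all equal values are all outliers
  y <- rep(0.5, 200)
  thr2 <- empirical_tail_threshold(y, 0.01)
  expect_equal(sum(y >= thr2), 200)
  expect_error(empirical_tail_threshold(runif(50), 0.01), ">= 100")
})

test_that("outlier sets are nested across tail probabilities", {
  set.seed(12)
  fst <- data.frame(site = 1:2000, chrom = "2L", pos = 1:2000,
                    pair = "A-B", theta = runif(2000), defined = TRUE,
                    class = "replacement", chrom_class = "autosome")
  o1 <- fst_tail_outliers(fst, q = 0.01)
  o5 <- fst_tail_outliers(fst, q = 0.05)
  expect_true(all(o1$site[o1$outlier] %in% o5$site[o5$outlier]))
})

test_that("family enrichment ranks, warns on empty families, conserves mass", {
  set.seed(13)
  n <- 3000
  fam <- sample(c("F1", "F2", "F3"), n, replace = TRUE)
  theta <- runif(n)
  theta[fam == "F1"] <- theta[fam == "F1"]^0.25  # inflate F1
  fst <- data.frame(site = 1:n, chrom = "2L", pos = 1:n, pair = "A-B",
                    theta = theta, defined = TRUE, class = "replacement",
                    chrom_class = "autosome")
  out <- fst_tail_outliers(fst, q = 0.05)
  enr <- family_tail_enrichment(out, fam)
  expect_equal(enr$family[1], "F1")
  expect_equal(enr$rank, 1:3)
  # weighted fractions reproduce the global tail mass
  expect_equal(sum(enr$outliers), sum(out$outlier))
  expect_equal(sum(enr$fraction * enr$total) / sum(enr$total),
               mean(out$outlier))
  # family with all SNPs above threshold
  fam2 <- fam
  fst2 <- fst
  top <- order(theta, decreasing = TRUE)[1:20]
  fam2[top] <- "Fx"
  out2 <- fst_tail_outliers(fst2, q = 0.05)
  enr2 <- family_tail_enrichment(out2, fam2)
  expect_equal(enr2$fraction[enr2$family == "Fx"], 1.0)
  expect_equal(enr2$family[1], "Fx")
  # zero-SNP family is excluded with a warning
  fam3 <- fam
  fam3[1] <- NA
  expect_warning(family_tail_enrichment(out[out$site != 1, ],
                                        replace(fam, fam == "F3", "F1")),
                 regexp = NA)
  sub <- out[fam %in% c("F1", "F2"), ]
  expect_warning(family_tail_enrichment(sub, fam), "F3")
})

test_that("simulated thresholds are seed-stable and near zero without structure", {
  m <- demography_model(c("a", "b"), c(20, 20),
                        migration = matrix(c(0, 200, 200, 0), 2, 2))
  r1 <- simulated_fst_thresholds(m, n_reps = 60, theta = 5, seed = 5)
  r2 <- simulated_fst_thresholds(m, n_reps = 60, theta = 5, seed = 5)
  expect_identical(r1, r2)
  # near-panmixia: mean theta is near zero and the 99% threshold stays
  # moderate (the tail reflects private low-frequency variants, not
  # structure)
  expect_lt(r1$q0.01, 0.5)
  reps <- simulate_replicates(m, 60, theta = 5, seed = 5)
  th <- unlist(lapply(reps, function(r) {
    H <- r$haplotypes
    if (ncol(H) == 0) return(numeric(0))
    famsel:::wc_fst_vec(20, 20, colMeans(H[1:20, , drop = FALSE]),
                        colMeans(H[21:40, , drop = FALSE]))
  }))
  expect_lt(abs(mean(th, na.rm = TRUE)), 0.02)
  r3 <- simulated_fst_thresholds(m, n_reps = 40, theta = 5, seed = 6,
                                 empirical = c("a-b" = 0.9))
  expect_true(r3$exceeds_sim)
})

test_that("standing variation counts segregating derived candidates", {
  expect_equal(standing_variation_fraction(c(1, 1, 1)), 0)   # fixed derived
  expect_equal(standing_variation_fraction(1 / 13), 1)       # 1 of 13 lines
  expect_equal(standing_variation_fraction(c(rep(0.3, 9), 0)), 0.9)
})

test_that("divergent-selection candidates need outliers in different pairs", {
  out <- data.frame(site = c(1, 2, 3, 4, 5),
                    pair = c("B-Z", "B-Z", "B-Z", "I-Z", "B-Z"),
                    outlier = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  genes <- c("g1", "g1", "g2", "g2", "g3")
  cand <- divergent_selection_candidates(out, genes)
  expect_false("g1" %in% cand)  # two SNPs, same pair
  expect_true("g2" %in% cand)   # SNPs outlier in different pairs
  expect_false("g3" %in% cand)  # single SNP
})
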