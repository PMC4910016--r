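test_that("pairwise coalescence time matches theory (ms scaling)", {
  m <- demography_model("p", 2)
  set.seed(1)
  tm <- replicate(3000, tmrca(simulate_genealogy(m)))
  # E[T2] = 0.5 in units of 4N generations, sd(T2) = 0.5
  expect_lt(abs(mean(tm) - 0.5), 3 * sd(tm) / sqrt(length(tm)))
})

test_that("recombination controls the number of marginal trees", {
  m <- demography_model("p", 8)
  expect_equal(n_marginal_trees(simulate_genealogy(m, rho = 0, seed = 2)), 1)
  expect_gt(n_marginal_trees(simulate_genealogy(m, rho = 20, seed = 2)), 1)
})

test_that("un-coalescible models are rejected with the isolated populations", {
  m <- demography_model(c("a", "b"), c(3, 3))
  expect_error(simulate_genealogy(m), "isolated")
})

test_that("fixed-S conditioning is exact and degenerate cases are valid", {
  m <- demography_model("p", 6)
  arg <- simulate_genealogy(m, seed = 5)
  r0 <- drop_mutations_fixed_s(arg, 0, seed = 1)
  expect_equal(ncol(r0$haplotypes), 0)
  reps <- simulate_replicates(m, 60, S = 25, seed = 9)
  expect_true(all(vapply(reps, function(r) ncol(r$haplotypes), 1L) == 25))
  # n = 2: every site separates the two samples
  m2 <- demography_model("p", 2)
  r2 <- drop_mutations_fixed_s(simulate_genealogy(m2, seed = 3), 10, seed = 4)
  expect_true(all(colSums(r2$haplotypes) == 1))
})

test_that("theta-mode mutation counts and diversity match Watterson", {
  m <- demography_model("p", 10)
  th0 <- drop_mutations_theta(simulate_genealogy(m, seed = 1), 0, seed = 1)
  expect_equal(ncol(th0$haplotypes), 0)
  st <- summarize_replicates(simulate_replicates(m, 3000, theta = 5,
                                                 seed = 10))
  a9 <- sum(1 / (1:9))
  expect_lt(abs(mean(st$S) - 5 * a9), 3 * sd(st$S) / sqrt(nrow(st)))
  expect_lt(abs(mean(st$pi) - 5), 3 * sd(st$pi) / sqrt(nrow(st)))
  h <- st$fay_wu_h[!is.na(st$fay_wu_h)]
  expect_lt(abs(mean(h)), 3 * sd(h) / sqrt(length(h)))
})

test_that("replicate summaries follow site-frequency conventions", {
  # all-singleton replicate has positive H
  hap <- matrix(0, 6, 4)
  hap[cbind(1:4, 1:4)] <- 1
  rec <- unfolded_sfs(hap)
  expect_gt(fay_wu_h(rec), 0)
  # S = 0 replicate: statistics undefined / zero by convention
  r <- list(haplotypes = matrix(0L, 6, 0), positions = numeric(0))
  class(r) <- "sim_replicate"
  st <- summarize_replicates(r)
  expect_equal(st$S, 0)
  expect_equal(st$pi, 0)
  expect_true(is.na(st$fay_wu_h))
})

test_that("null quantile tables are deterministic and span the replicates", {
  m <- demography_model("p", 8)
  q1 <- null_quantiles(m, list(rho = 0, S = 12), 80, "fay_wu_h",
                       probs = c(0, 1), seed = 3)
  q2 <- null_quantiles(m, list(rho = 0, S = 12), 80, "fay_wu_h",
                       probs = c(0, 1), seed = 3)
  expect_identical(q1, q2)
  expect_lt(q1[[1]], q1[[2]])
})

test_that("demographic presets simulate, including the X-linked scaling", {
  for (p in c("constant", "bottleneck", "bottleneck_growth")) {
    mod <- demography_preset(p)
    rep1 <- simulate_replicates(mod, 2, S = 10, seed = 1)[[1]]
    expect_equal(ncol(rep1$haplotypes), 10)
    expect_equal(nrow(rep1$haplotypes), 84)
  }
  # 3/4 scaling shrinks coalescence times proportionally
  ma <- demography_model("p", 2)
  mx <- demography_model("p", 2, chrom_scale = 3 / 4)
  set.seed(8)
  ta <- replicate(2500, tmrca(simulate_genealogy(ma)))
  tx <- replicate(2500, tmrca(simulate_genealogy(mx)))
  expect_lt(abs(mean(tx) / mean(ta) - 0.75), 0.08)
})

test_that("island-model statistics match an independent simulator (msprime)", {
  # two demes, symmetric scaled migration M = 4*N0*m = 1, theta = 5
  M <- 1
  theta <- 5
  n_rep <- 800
  m <- demography_model(c("a", "b"), c(4, 4),
                        migration = matrix(c(0, M, M, 0), 2, 2))
  st <- summarize_replicates(simulate_replicates(m, n_rep, theta = theta,
                                                 seed = 17))
  py <- sprintf('
import msprime
dem = msprime.Demography()
dem.add_population(name="a", initial_size=1.0)
dem.add_population(name="b", initial_size=1.0)
dem.set_migration_rate("a", "b", %f)
dem.set_migration_rate("b", "a", %f)
for i in range(%d):
    ts = msprime.sim_ancestry(samples={"a": 2, "b": 2}, demography=dem,
                              ploidy=2, sequence_length=1,
                              random_seed=1000 + i)
    mts = msprime.sim_mutations(ts, rate=%f, random_seed=2000 + i,
                                discrete_genome=False)
    print(mts.num_sites)
', M / 4, M / 4, n_rep, theta / 4)
  pf <- withr::local_tempfile(fileext = ".py")
  writeLines(py, pf)
  out <- suppressWarnings(system2("python", pf, stdout = TRUE))
  s_msprime <- as.integer(out)
  expect_equal(length(s_msprime), n_rep)
  ks <- suppressWarnings(ks.test(st$S, s_msprime))
  expect_gt(ks$p.value, 0.01)
})
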