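test_that("dataset generation is fully deterministic under a fixed seed", {
  cfg <- test_config()
  d1 <- generate_dataset(cfg, seed = 5)
  d2 <- generate_dataset(cfg, seed = 5)
  expect_identical(d1$snps$genotypes$calls, d2$snps$genotypes$calls)
  expect_identical(d1$snps$genotypes$sites, d2$snps$genotypes$sites)
  expect_identical(d1$cnv$cnvs, d2$cnv$cnvs)
  expect_identical(d1$responses$responses, d2$responses$responses)
  # byte-identical files on disk
  t1 <- withr::local_tempdir()
  t2 <- withr::local_tempdir()
  write_dataset(d1, t1)
  write_dataset(d2, t2)
  for (f in list.files(t1)) {
    expect_identical(readLines(file.path(t1, f)),
                     readLines(file.path(t2, f)))
  }
  d3 <- generate_dataset(cfg, seed = 6)
  expect_false(identical(d1$snps$genotypes$calls, d3$snps$genotypes$calls))
})

test_that("scenario validation enforces the large-family floor", {
  expect_error(scenario_config(families = list(
    Or = list(n_genes = 19, gene_bp = 900, large = TRUE, alpha_true = 0))),
    ">= 20 genes")
  ann <- generate_genome(test_config(), seed = 2)
  for (fam in c("Or", "Obp"))
    expect_gte(sum(ann$genes$family == fam), 20)
})

test_that("generated tables round-trip through the standard formats", {
  cfg <- test_config(n_background = 10)
  ds <- generate_dataset(cfg, seed = 11)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  gt <- read_snp_vcf(file.path(dir, "snps.vcf"),
                     ds$snps$genotypes$line_pops)
  expect_equal(gt$calls, ds$snps$genotypes$calls)
  ann2 <- read_gene_bed(file.path(dir, "genes.bed"),
                        file.path(dir, "families.tsv"), strict = FALSE)
  expect_setequal(ann2$genes$gene, ds$annotation$genes$gene)
  expect_equal(sort(ann2$large_families),
               sort(ds$annotation$large_families))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_true("fst_inflation" %in% names(truth))
})

test_that("a no-signal genome yields flat family enrichment", {
  cfg <- test_config(het_rate = 0, missing_rate = 0)
  ds <- generate_dataset(cfg, seed = 23)
  hap <- haploidize_and_impute(ds$snps$genotypes, seed = 1)
  # homozygous, complete data: haploidization is a pass-through
  expect_identical(hap$calls, ds$snps$genotypes$calls)
  fst <- fst_all_pairs(hap)
  fst$class <- ds$snps$effects$class[fst$site]
  fst$chrom_class <- ifelse(fst$chrom == "X", "X", "autosome")
  out <- fst_tail_outliers(fst, q = 0.05, effect_class = "replacement")
  enr <- suppressWarnings(
    family_tail_enrichment(out, ds$snps$effects$family))
  # outlier counts proportional to family totals (chi-square, no signal)
  cs <- suppressWarnings(
    chisq.test(enr$outliers, p = enr$total / sum(enr$total)))
  expect_gt(cs$p.value, 0.01)
})

test_that("planted differentiation drives the family to the top rank", {
  cfg <- test_config(fst_inflation = list(family = "Obp", intensity = 0.6))
  ann <- generate_genome(cfg, seed = 31)
  snps <- generate_population_snps(cfg, ann, seed = 32)
  hap <- haploidize_and_impute(snps$genotypes, seed = 1)
  fst <- fst_all_pairs(hap)
  fst$class <- snps$effects$class[fst$site]
  fst$chrom_class <- ifelse(fst$chrom == "X", "X", "autosome")
  out <- fst_tail_outliers(fst, q = 0.01)
  enr <- suppressWarnings(family_tail_enrichment(out, snps$effects$family))
  expect_equal(enr$family[1], "Obp")
})

test_that("ancestral posteriors miss the threshold at the configured rate", {
  cfg <- test_config(frac_unpolarized = 0.3)
  ds <- generate_dataset(cfg, seed = 41)
  pol <- polarize_alleles(ds$snps$anc_posterior)
  frac <- mean(pol == "unpolarized")
  se <- sqrt(0.3 * 0.7 / length(pol))
  expect_lt(abs(frac - 0.3), 4 * se)
})

test_that("divergence generation respects truth and degenerate limits", {
  cfg <- test_config()
  ann <- generate_genome(cfg, seed = 3)
  d0 <- generate_divergence(cfg, ann, seed = 4, theta_s = 0, t_s = 0)
  tabs <- lapply(seq_len(nrow(d0$counts)), function(k)
    with(d0$counts[k, ], build_mk_table(gene, P_R, P_S, D_R, D_S)))
  expect_true(all(!vapply(tabs, function(t) t$included, logical(1))))
  d1 <- generate_divergence(cfg, ann, seed = 4)
  expect_equal(d1$truth$alpha_true[["Or"]], 0.4)
  expect_true(all(d1$counts[, c("P_S", "P_R", "D_S", "D_R")] >= 0))
})

test_that("planted CNV structures and nulls are recovered exactly", {
  cfg <- test_config()
  ann <- generate_genome(cfg, seed = 51)
  cnv <- generate_cnv_indel_set(cfg, ann, seed = 52)
  cls <- classify_cnv_gene_events(cnv$cnvs, ann)
  truth <- cnv$truth
  got_dup <- sort(cls$genes[cls$class == "complete_duplication"])
  expect_equal(got_dup, sort(truth$complete_duplication))
  got_chim <- sort(vapply(which(cls$class == "chimera"),
                          function(i) cls$genes[i], ""))
  want_chim <- sort(vapply(truth$chimera,
                           function(x) paste(x$genes, collapse = ","), ""))
  expect_equal(got_chim, want_chim)
  got_fus <- cls[cls$class == "fusion", ]
  expect_equal(sort(got_fus$genes),
               sort(vapply(truth$fusion,
                           function(x) paste(x$genes, collapse = ","), "")))
  expect_true(all(got_fus$same_strand))
  # high-frequency nulls: exact set equality (no false calls)
  fams <- setNames(ann$genes$family, ann$genes$gene)
  fams <- fams[fams != "background"]
  s <- null_allele_summary(cnv$disruptions, fams)
  flagged <- sort(rownames(s$per_gene)[rowSums(s$per_gene) > 0])
  want <- sort(unique(vapply(truth$hf_null, `[[`, "", "gene")))
  expect_equal(flagged, want)
})

test_that("tuning-breadth coupling shapes the response matrix", {
  cfg <- test_config(kl_coupling = -0.9,
                     fst_inflation = list(family = "Or", intensity = 0.6,
                                          graded = TRUE))
  ann <- generate_genome(cfg, seed = 61)
  rg <- ann$genes$gene[ann$genes$family == "Or"]
  d_g <- setNames(seq(0.05, 0.6, length.out = length(rg)), rg)
  r <- generate_response_matrix(cfg, rg, d_g = d_g, seed = 62)
  kl <- lifetime_kurtosis_matrix(r$responses)
  # strongly differentiated receptors are broadly tuned: low kurtosis
  expect_lt(cor(d_g, kl), 0)
  # zero coupling needs no differentiation input
  r0 <- generate_response_matrix(test_config(), rg, seed = 63)
  expect_equal(dim(r0$responses), c(length(rg), 50))
})
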