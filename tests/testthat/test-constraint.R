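test_that("replacement/silent diversity ratios follow the per-site scaling", {
  sl <- compute_site_lengths(degeneracy = rep(c(1, 1, 4), 100))  # ns 200, s 100
  expect_equal(pr_ps_ratio(2, 1, sl), 1.0)     # equal per-site diversities
  expect_equal(pr_ps_ratio(0, 1, sl), 0)
  expect_equal(pr_ps_ratio(1.5, 2.25, sl), (1.5 / 200) / (2.25 / 100))
  expect_true(is.na(pr_ps_ratio(1, 0, sl)))
})

test_that("constraint comparison detects a shifted family", {
  set.seed(19)
  expect_error(family_constraint_compare(runif(10), rep("A", 10)),
               ">= 2 families")
  hit <- 0
  for (i in 1:10) {
    r <- c(rbeta(50, 2, 6), rbeta(50, 2, 6) + 0.2)
    fam <- rep(c("bg", "shift"), each = 50)
    res <- family_constraint_compare(r, fam)
    if (res$kw_p < 0.05) hit <- hit + 1
  }
  expect_gte(hit, 9)
  # null calibration: identical distributions rarely reject
  rej <- 0
  for (i in 1:40) {
    r <- rbeta(60, 2, 6)
    if (family_constraint_compare(r, rep(c("a", "b", "c"), 20))$kw_p < 0.05)
      rej <- rej + 1
  }
  expect_lte(rej / 40, 0.15)
})

cnv_fixture <- function() {
  genes <- data.frame(gene = c("gA", "gB", "gC", "gD"),
                      chrom = "2L", strand = c("+", "+", "-", "-"),
                      family = "F", subgroup = "none")
  exons <- data.frame(gene = genes$gene, chrom = "2L",
                      start = c(1000, 3000, 5000, 7000),
                      end = c(1900, 3900, 5900, 7900))
  ann <- gene_annotation(genes, exons)
  lines <- setNames(rep(c("P1", "P2"), each = 4),
                    paste0("L", 1:8))
  ev <- data.frame(event_id = c("e1", "e2", "e3", "e4", "e5", "e6"),
                   type = c("duplication", "duplication", "deletion",
                            "deletion", "deletion", "insertion"),
                   chrom = "2L",
                   start = c(950, 1500, 5500, 1200, 2100, 2200),
                   end = c(1950, 3500, 7500, 1400, 2500, 2300))
  pres <- matrix(0L, 6, 8, dimnames = list(NULL, names(lines)))
  pres[, 1] <- 1L
  ev <- cbind(ev, pres)
  list(ann = ann, cnvs = cnv_table(ev, lines), lines = lines)
}

test_that("CNV gene-event rules classify the canonical cases", {
  fx <- cnv_fixture()
  cls <- classify_cnv_gene_events(fx$cnvs, fx$ann)
  expect_equal(cls$class[cls$event_id == "e1"], "complete_duplication")
  expect_equal(cls$genes[cls$event_id == "e1"], "gA")
  expect_equal(cls$class[cls$event_id == "e2"], "chimera")  # half gA, half gB
  expect_equal(cls$genes[cls$event_id == "e2"], "gA,gB")
  expect_equal(cls$class[cls$event_id == "e3"], "fusion")   # gC + gD tandem
  expect_true(cls$same_strand[cls$event_id == "e3"])
  expect_equal(cls$class[cls$event_id == "e4"], "gene_deletion")
  expect_equal(cls$class[cls$event_id == "e5"], "intergenic")
  expect_equal(cls$class[cls$event_id == "e6"], "intergenic")
})

test_that("classification is order-independent and exhaustive", {
  fx <- cnv_fixture()
  cls <- classify_cnv_gene_events(fx$cnvs, fx$ann)
  perm <- c(4, 2, 6, 1, 3, 5)
  cls2 <- classify_cnv_gene_events(fx$cnvs[perm, ], fx$ann)
  m1 <- cls[order(cls$event_id), c("event_id", "class", "genes")]
  m2 <- cls2[order(cls2$event_id), c("event_id", "class", "genes")]
  rownames(m1) <- rownames(m2) <- NULL
  expect_identical(m1, m2)
  expect_equal(nrow(cls), nrow(fx$cnvs))         # one class per event
})

test_that("CNV size bounds are enforced", {
  lines <- setNames(rep("P1", 2), c("L1", "L2"))
  ev <- data.frame(event_id = "bad", type = "deletion", chrom = "2L",
                   start = 100, end = 124, L1 = 1L, L2 = 0L)
  expect_error(cnv_table(ev, lines), "out of bounds")
})

test_that("null-allele flags apply the single-class >= 10% rule", {
  fams <- setNames(rep("F", 3), c("g1", "g2", "g3"))
  disr <- data.frame(
    gene = c("g1", "g2", "g3", "g3"),
    class = c("nonsense", "nonsense", "frameshift_indel", "nonsense"),
    freq_B = 0,
    freq_Z = c(2 / 13, 1 / 19, 0.05, 0.05))
  s <- null_allele_summary(disr, fams)
  expect_true(s$per_gene["g1", "Z"])     # 15.4% in Zimbabwe
  expect_false(s$per_gene["g2", "Z"])    # 5.3%
  expect_false(s$per_gene["g3", "Z"])    # two classes at 5%: never summed
  expect_equal(s$family_fraction["F", "Z"], 1 / 3)
  # monotone in threshold: lowering it never unflags
  s2 <- null_allele_summary(disr, fams, threshold = 0.04)
  expect_true(all(s$per_gene <= s2$per_gene))
  # span counts are consistent
  sp <- s$population_span
  expect_lte(sp$all, sp$any)
  expect_lte(sp$any, sp$size)
  expect_equal(sp$none + sp$any, sp$size)
})

test_that("deletion:duplication ratios reduce and handle zero denominators", {
  cl <- data.frame(family = "F",
                   class = c(rep("gene_deletion", 10),
                             rep("complete_duplication", 2)),
                   max_freq = c(rep(0.2, 10), 0.2, 0.2))
  r <- del_dup_ratio(cl, "F")
  expect_equal(r$overall$label, "5:1")
  expect_equal(r$overall$ratio, 5)
  cl2 <- data.frame(family = "F", class = rep("gene_deletion", 19),
                    max_freq = 0.01)
  r2 <- del_dup_ratio(cl2, "F")
  expect_equal(r2$overall$label, "19:0")
  expect_equal(r2$overall$ratio, Inf)
  expect_equal(r2$above_floor$label, "0:0")
  r3 <- del_dup_ratio(cl2, "empty_family")
  expect_equal(r3$overall$label, "0:0")
  expect_true(is.na(r3$overall$ratio))
})
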