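test_that("site effects follow the codon table", {
  expect_equal(classify_site_effect("GGA", 3, "A", "G"), "synonymous")
  expect_equal(classify_site_effect("TGG", 3, "G", "A"), "nonsense")
  expect_equal(classify_site_effect("AAA", 2, "A", "G"), "replacement")
  expect_error(classify_site_effect("GGA", 1, "A", "G"), "does not match")
})

test_that("effect classification agrees with exhaustive codon enumeration", {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  for (codon in names(code)) {
    for (p in 1:3) {
      ref <- substr(codon, p, p)
      for (alt in setdiff(bases, ref)) {
        mut <- codon
        substr(mut, p, p) <- alt
        expected <- if (code[[mut]] == code[[codon]]) "synonymous"
        else if (code[[mut]] == "*") "nonsense" else "replacement"
        expect_equal(classify_site_effect(codon, p, ref, alt), expected)
      }
    }
  }
})

test_that("site lengths follow the degeneracy weighting formulas", {
  # ten GGA codons: third position 4-fold, first two positions 1-fold
  sl <- compute_site_lengths(degeneracy = codon_degeneracy(rep("GGA", 10)))
  expect_equal(sl$L1, 20)
  expect_equal(sl$L4, 10)
  expect_equal(sl$length_ns, 20)
  expect_equal(sl$length_s, 10)
  # all one-fold gene has zero silent length
  sl2 <- compute_site_lengths(degeneracy = codon_degeneracy(rep("TGG", 4)))
  expect_equal(sl2$length_s, 0)
  expect_equal(sl2$length_ns, 12)
  # two-fold positions contribute 2/3 and 1/3
  base <- compute_site_lengths(degeneracy = rep(1, 9))
  with2 <- compute_site_lengths(degeneracy = c(rep(1, 6), rep(2, 3)))
  expect_equal(with2$length_ns - base$length_ns + 3, 2)
  expect_equal(with2$length_s - base$length_s, 1)
})

test_that("length accounting is exact for random genes", {
  set.seed(21)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  for (rep in 1:20) {
    codons <- sample(sense, sample(5:60, 1), replace = TRUE)
    deg <- codon_degeneracy(codons)
    # independent per-codon oracle
    deg_oracle <- unlist(lapply(codons, function(cd) {
      vapply(1:3, function(p) {
        sum(vapply(c("A", "C", "G", "T"), function(b) {
          x <- cd
          substr(x, p, p) <- b
          Biostrings::GENETIC_CODE[[x]] == Biostrings::GENETIC_CODE[[cd]]
        }, logical(1)))
      }, integer(1))
    }))
    expect_equal(deg, deg_oracle)
    sl <- compute_site_lengths(degeneracy = deg)
    expect_equal(sl$L1 + sl$L2 + sl$L3 + sl$L4, 3 * length(codons))
    expect_equal(sl$length_ns + sl$length_s, 3 * length(codons),
                 tolerance = 1e-9)
  }
})

test_that("polarization threshold is inclusive at 0.85", {
  expect_equal(polarize_alleles(0.95), "alt")
  expect_equal(polarize_alleles(0.80), "unpolarized")
  expect_equal(polarize_alleles(0.85), "alt")
  expect_equal(polarize_alleles(0.10), "ref")
  expect_equal(polarize_alleles(0.15), "ref")
  expect_error(polarize_alleles(1.2), "outside")
})

test_that("haploidization passes through clean data and respects support", {
  gt <- toy_gt(matrix(c(0, 1, 1, 0), 2, 2), c(L1 = "P", L2 = "P"))
  expect_equal(haploidize_and_impute(gt, seed = 1)$calls, gt$calls)
  # heterozygote resolves within {0,1} under any seed
  gth <- toy_gt(matrix(c(0.5, 1), 1, 2), c(L1 = "P", L2 = "P"))
  for (s in 1:5)
    expect_true(haploidize_and_impute(gth, seed = s)$calls[1, 1] %in% c(0, 1))
  # missing call with population frequency 1 imputes alt
  gtm <- toy_gt(matrix(c(NA, 1, 1), 1, 3),
                c(L1 = "P", L2 = "P", L3 = "P"))
  expect_equal(unname(haploidize_and_impute(gtm, seed = 3)$calls[1, 1]), 1)
  # all-missing site in a population is a named error
  gtx <- toy_gt(matrix(c(NA, NA, 1, 0), 1, 4),
                c(L1 = "A", L2 = "A", L3 = "B", L4 = "B"))
  expect_error(haploidize_and_impute(gtx, seed = 1), "population A")
})

test_that("haploidization is seed-reproducible and imputation is unbiased", {
  set.seed(4)
  n <- 400
  calls <- matrix(rbinom(n * 30, 1, 0.3), 30, n)
  calls[sample(length(calls), 4000)] <- NA
  gt <- toy_gt(calls, setNames(rep("P", n), paste0("L", 1:n)))
  h1 <- haploidize_and_impute(gt, seed = 99)
  h2 <- haploidize_and_impute(gt, seed = 99)
  expect_identical(h1$calls, h2$calls)
  # marginal frequency of imputed calls matches the population frequency
  miss <- is.na(calls)
  pop_f <- rowMeans(calls, na.rm = TRUE)
  imp <- h1$calls[miss]
  expected <- rep(pop_f, ncol(calls))[as.vector(miss)]
  n_imp <- length(imp)
  se <- sqrt(sum(expected * (1 - expected))) / n_imp
  expect_lt(abs(mean(imp) - mean(expected)), 3 * se + 1e-12)
})

test_that("only exonic frameshifting indels are disruptive", {
  genes <- data.frame(gene = "g1", chrom = "2L", strand = "+",
                      family = "F", subgroup = "none")
  exons <- data.frame(gene = "g1", chrom = "2L", start = 100, end = 400)
  ann <- gene_annotation(genes, exons)
  indels <- data.frame(chrom = "2L", pos = c(150, 200, 500),
                       ref = c("ACGTA", "ACGTACG", "TAC"),
                       alt = c("A", "A", "T"))
  res <- detect_disruptive_indels(indels, ann)
  expect_equal(res$class[res$pos == 150], "frameshift_indel")  # 4 bp
  expect_equal(res$class[res$pos == 200], "other")             # 6 bp in-frame
  expect_equal(res$class[res$pos == 500], "other")             # intergenic
  expect_true(is.na(res$gene[res$pos == 500]))
})
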