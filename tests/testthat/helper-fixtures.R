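# Shared fixtures and independent oracles, built in code at test time.

# small genotype table: `calls` given sites x lines
toy_gt <- function(calls, pops, chrom = "2L", pos = NULL) {
  calls <- as.matrix(calls)
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  if (is.null(names(pops))) names(pops) <- colnames(calls)
  if (is.null(pos)) pos <- seq_len(nrow(calls)) * 10L
  genotype_table(data.frame(chrom = chrom, pos = pos,
                            ref = "A", alt = "G"),
                 calls, pops)
}

# independent Weir-Cockerham oracle: rebuilds the ANOVA from expanded 0/1
# allele vectors rather than from (n, p) moment formulas
wc_oracle <- function(n, p) {
  counts <- round(n * p)
  x <- unlist(lapply(seq_along(n), function(i)
    c(rep(1, counts[i]), rep(0, n[i] - counts[i]))))
  g <- factor(rep(seq_along(n), n))
  N <- length(x)
  r <- nlevels(g)
  xb <- mean(x)
  if (xb == 0 || xb == 1) return(NA_real_)
  means <- tapply(x, g, mean)
  ssb <- sum(tapply(x, g, length) * (means[levels(g)] - xb)^2)
  ssw <- sum((x - means[g])^2)
  msp <- ssb / (r - 1)
  msg <- ssw / (N - r)
  nc <- (N - sum(table(g)^2) / N) / (r - 1)
  a <- (msp - msg) / nc
  if (a + msg == 0) return(NA_real_)
  a / (a + msg)
}

# independent two-sided Fisher oracle: exhaustive hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  c1 <- a + c
  lo <- max(0, c1 - m2)
  hi <- min(m1, c1)
  probs <- dhyper(lo:hi, m1, m2, c1)
  p_obs <- dhyper(a, m1, m2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent Fay & Wu H oracle from the collapsed weight form
h_collapsed <- function(xi, n) {
  i <- seq_len(n - 1)
  sum(i * (n - 2 * i) * xi) / choose(n, 2)
}

# small five-population panel config scaled down for unit tests
test_config <- function(n_background = 40, ...) {
  scenario_config(
    families = list(
      Or = list(n_genes = 20, gene_bp = 900, large = TRUE, alpha_true = 0.4),
      Obp = list(n_genes = 20, gene_bp = 600, large = TRUE, alpha_true = 0)),
    n_background = n_background, background_bp = 900, ...)
}

# brute-force interval membership for intersect_variants_genes
brute_intersect <- function(gt, ann) {
  out <- setNames(vector("list", nrow(ann$genes)), ann$genes$gene)
  for (g in names(out)) out[[g]] <- integer(0)
  for (i in seq_len(nrow(gt$sites))) {
    for (e in seq_len(nrow(ann$exons))) {
      if (gt$sites$chrom[i] == ann$exons$chrom[e] &&
          gt$sites$pos[i] >= ann$exons$start[e] &&
          gt$sites$pos[i] < ann$exons$end[e]) {
        g <- ann$exons$gene[e]
        out[[g]] <- sort(unique(c(out[[g]], i)))
      }
    }
  }
  out
}
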