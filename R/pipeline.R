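## End-to-end pipeline over a synthetic (or externally loaded) dataset:
## annotate -> mk -> fst -> sfs -> constraint -> kurtosis -> report.

# summed nucleotide diversity over sites: unbiased per-site heterozygosity
# 2 p (1-p) n/(n-1) of haploid calls
pi_sum <- function(calls) {
  if (nrow(calls) == 0) return(0)
  n <- rowSums(!is.na(calls))
  p <- rowMeans(calls, na.rm = TRUE)
  ok <- n >= 2
  sum((2 * p * (1 - p) * n / (n - 1))[ok])
}

#' Run the full two-timescale selection analysis on a dataset
#'
#' Stages: effect annotation and polarization; MK tables, DoS, family alpha
#' and omega_a; per-SNP Weir-Cockerham Fst over all population pairs with
#' empirical-tail family enrichment, standing-variation fraction and
#' divergent-selection candidates; per-population Fay and Wu's H per gene
#' with family bootstrap; constraint ratios, CNV gene-event classes and
#' null-allele summaries; receptor tuning-breadth correlation.
#'
#' @param dataset a `famsel_dataset` from [generate_dataset()].
#' @param seed integer seed for the stochastic stages (haploidization,
#'   bootstrap).
#' @param fst_q empirical tail probability (default 0.01).
#' @param bootstrap_B bootstrap resamples for family H (default 2000).
#' @return list of class `famsel_report`; see the methods vignette.
#' @export
run_pipeline <- function(dataset, seed = 1, fst_q = 0.01,
                         bootstrap_B = 2000) {
  stopifnot(inherits(dataset, "famsel_dataset"))
  seeds <- derive_seeds(seed, 4)
  ann <- dataset$annotation
  gt <- dataset$snps$genotypes
  effects <- dataset$snps$effects
  log_counter("pipeline", sites = nrow(gt$sites), genes = nrow(ann$genes))

  # --- annotate: polarization ------------------------------------------
  derived <- polarize_alleles(dataset$snps$anc_posterior)
  effects$derived <- derived

  # --- haploidize once for the frequency-based stages ------------------
  hap <- haploidize_and_impute(gt, seed = seeds[[1]])

  # --- mk: Zimbabwe polymorphism + generated divergence ----------------
  zcols <- hap$line_pops == "Z"
  zcalls <- hap$calls[, zcols, drop = FALSE]
  zseg <- rowSums(zcalls) > 0 & rowSums(zcalls) < sum(zcols)
  poly <- effects[zseg & effects$class %in% c("synonymous", "replacement"), ,
                  drop = FALSE]
  div <- dataset$divergence$counts
  tables <- build_mk_tables(poly[, c("gene", "class")],
                            data.frame(gene = div$gene, d_r = div$D_R,
                                       d_s = div$D_S))
  mk_tab <- mk_report(tables)
  mk_tab$family <- ann$genes$family[match(mk_tab$gene, ann$genes$gene)]
  fams <- setdiff(unique(ann$genes$family), character(0))
  sl <- dataset$divergence$site_lengths
  alpha <- list()
  for (fm in fams) {
    idx <- which(vapply(tables, function(t)
      identical(ann$genes$family[match(t$gene, ann$genes$gene)], fm),
      logical(1)))
    est <- tryCatch({
      e <- alpha_family_ml(tables[idx], sl[div$gene[idx]])
      omega_a(e, tables[idx], sl[div$gene[idx]])
    }, error = function(e) NULL)
    if (!is.null(est)) alpha[[fm]] <- est
  }

  # --- fst -------------------------------------------------------------
  fst <- fst_all_pairs(hap)
  fst$class <- effects$class[fst$site]
  fst$chrom_class <- ifelse(fst$chrom == "X", "X", "autosome")
  outl <- fst_tail_outliers(fst, q = fst_q, effect_class = "replacement")
  site_fam <- effects$family[order(effects$site)]
  enrich <- tryCatch(family_tail_enrichment(outl, site_fam),
                     error = function(e) NULL)
  # standing variation: derived-allele frequency of outlier SNPs in Z
  cand_sites <- unique(outl$site[outl$outlier])
  cand_sites <- cand_sites[effects$derived[cand_sites] != "unpolarized"]
  sv <- if (length(cand_sites)) {
    fz <- rowMeans(hap$calls[cand_sites, zcols, drop = FALSE])
    fz <- ifelse(effects$derived[cand_sites] == "alt", fz, 1 - fz)
    standing_variation_fraction(fz)
  } else NA_real_
  div_cand <- divergent_selection_candidates(outl, effects$gene)

  # --- sfs: per-gene per-population H on polarized sites ---------------
  pol <- effects$derived != "unpolarized"
  pops <- sort(unique(hap$line_pops))
  h_rows <- list()
  for (k in seq_len(nrow(ann$genes))) {
    g <- ann$genes$gene[k]
    sidx <- effects$site[effects$gene == g & pol]
    if (length(sidx) == 0) next
    for (p in pops) {
      m <- t(hap$calls[sidx, hap$line_pops == p, drop = FALSE])
      # orient to derived coding
      swap <- effects$derived[sidx] == "ref"
      if (any(swap)) m[, swap] <- 1 - m[, swap]
      rec <- unfolded_sfs(m, gene = g, population = p)
      h_rows[[length(h_rows) + 1]] <-
        data.frame(gene = g, family = ann$genes$family[k], population = p,
                   S = sum(rec$xi), H = rec$H)
    }
  }
  h_tab <- do.call(rbind, h_rows)
  h_boot <- list()
  for (fm in fams) {
    hv <- h_tab$H[h_tab$family == fm]
    h_boot[[fm]] <- tryCatch(
      family_h_bootstrap(hv, B = bootstrap_B, seed = seeds[[2]]),
      error = function(e) NULL)
  }

  # --- constraint ------------------------------------------------------
  ratios <- vapply(seq_len(nrow(ann$genes)), function(k) {
    g <- ann$genes$gene[k]
    er <- effects$site[effects$gene == g & effects$class == "replacement"]
    es <- effects$site[effects$gene == g & effects$class == "synonymous"]
    lens <- sl[[g]]
    if (is.null(lens)) return(NA_real_)
    pr_ps_ratio(pi_sum(hap$calls[er, , drop = FALSE]),
                pi_sum(hap$calls[es, , drop = FALSE]), lens)
  }, numeric(1))
  constraint_test <- tryCatch(
    family_constraint_compare(ratios, ann$genes$family),
    error = function(e) NULL)
  cnv_classes <- classify_cnv_gene_events(dataset$cnv$cnvs, ann)
  fam_of <- setNames(ann$genes$family, ann$genes$gene)
  cnv_classes$family <- fam_of[vapply(strsplit(cnv_classes$genes, ","),
                                      function(g) g[1] %||% NA_character_,
                                      "")]
  freq_cols <- grep("^freq_", names(dataset$cnv$cnvs), value = TRUE)
  cnv_classes$max_freq <- apply(
    dataset$cnv$cnvs[match(cnv_classes$event_id,
                           dataset$cnv$cnvs$event_id),
                     freq_cols, drop = FALSE], 1, max)
  fam_members <- setNames(ann$genes$family, ann$genes$gene)
  fam_members <- fam_members[fam_members != "background"]
  nulls <- null_allele_summary(dataset$cnv$disruptions, fam_members)
  deldup <- lapply(setdiff(fams, "background"), function(fm)
    del_dup_ratio(cnv_classes, fm))
  names(deldup) <- setdiff(fams, "background")

  # --- kurtosis --------------------------------------------------------
  kl <- lifetime_kurtosis_matrix(dataset$responses$responses)
  rgenes <- names(kl)
  mean_fst <- vapply(rgenes, function(g)
    gene_mean_fst(fst, effects$site[effects$gene == g]), numeric(1))
  klcor <- tryCatch(kl_fst_correlation(kl, mean_fst),
                    error = function(e) NULL)

  structure(list(mk = mk_tab, alpha = alpha, fst = fst,
                 fst_outliers = outl, enrichment = enrich,
                 standing_variation = sv,
                 divergent_candidates = div_cand,
                 h_table = h_tab, h_bootstrap = h_boot,
                 constraint_ratios = ratios,
                 constraint_test = constraint_test,
                 cnv_classes = cnv_classes, null_alleles = nulls,
                 del_dup = deldup, kl = kl, kl_fst = klcor),
            class = "famsel_report")
}

#' @export
print.famsel_report <- function(x, ...) {
  cat("famsel pipeline report\n")
  cat("  MK: ", sum(x$mk$included), "of", nrow(x$mk), "genes tested;",
      sum(x$mk$sig_bonf, na.rm = TRUE), "Bonferroni-significant\n")
  for (fm in names(x$alpha)) {
    a <- x$alpha[[fm]]
    cat(sprintf("  alpha[%s] = %.3f (CI %.3f:%.3f), omega_a = %.3f\n",
                fm, a$alpha, a$ci[1], a$ci[2], a$omega_a))
  }
  if (!is.null(x$enrichment)) {
    top <- x$enrichment[1, ]
    cat(sprintf("  Fst tail: top family %s (fraction %.3f)\n",
                top$family, top$fraction))
  }
  cat(sprintf("  standing variation fraction: %.3f\n",
              x$standing_variation))
  for (fm in names(x$h_bootstrap)) {
    b <- x$h_bootstrap[[fm]]
    if (!is.null(b))
      cat(sprintf("  H[%s] = %.3f (CI %.3f:%.3f)%s\n", fm, b$mean_h,
                  b$ci[1], b$ci[2], if (b$significant) " *" else ""))
  }
  if (!is.null(x$kl_fst))
    cat(sprintf("  K_L ~ Fst: r = %.3f (p = %.3g, n = %d)\n",
                x$kl_fst$r, x$kl_fst$p, x$kl_fst$n))
  invisible(x)
}
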