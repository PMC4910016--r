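## Weir-Cockerham Fst (haploid variance-components form), empirical tails,
## family enrichment, simulation thresholds, standing-variation and
## divergent-selection candidate calls.

#' Weir-Cockerham Fst at one site (haploid allele counts)
#'
#' Variance-components estimator for unequal sample sizes on haploid
#' (line-level) allele calls: a is the between-population component,
#' b the within-population component, theta = a / (a + b). Negative
#' estimates are reported as computed; sites monomorphic across all
#' populations are flagged undefined.
#'
#' @param n integer vector of per-population sample sizes (>= 2 each, at
#'   least two populations).
#' @param p per-population alternate/derived allele frequencies.
#' @return list of class `fst_record`: `a`, `b`, `theta`, `defined`.
#' @export
#' @examples
#' wc_fst_site(c(10, 10), c(1, 0))$theta  # reciprocally fixed: 1
wc_fst_site <- function(n, p) {
  stopifnot(length(n) == length(p), length(n) >= 2, all(n >= 2),
            all(p >= 0 & p <= 1))
  r <- length(n)
  N <- sum(n)
  pbar <- sum(n * p) / N
  if (pbar == 0 || pbar == 1) {
    return(structure(list(a = 0, b = 0, theta = NA_real_, defined = FALSE),
                     class = "fst_record"))
  }
  msp <- sum(n * (p - pbar)^2) / (r - 1)
  msg <- sum(n * p * (1 - p)) / (N - r)
  nc <- (N - sum(n^2) / N) / (r - 1)
  a <- (msp - msg) / nc
  b <- msg
  theta <- if (a + b == 0) NA_real_ else a / (a + b)
  structure(list(a = a, b = b, theta = theta, defined = !is.na(theta)),
            class = "fst_record")
}

#' Per-SNP Fst over all population pairs of a genotype table
#'
#' Haploidizes/imputes per gene slice upstream; here calls are expected to
#' be haploid already (0/1); heterozygous calls contribute half an alternate
#' allele and missing calls are dropped from the per-population counts.
#'
#' @param gt a [genotype_table].
#' @param pairs optional 2-column character matrix of population pairs
#'   (default: all pairs).
#' @param min_n minimum per-population non-missing calls (default 2).
#' @return data frame: `site` (row index), `chrom`, `pos`, `pair`, `theta`,
#'   `defined`.
#' @export
fst_all_pairs <- function(gt, pairs = NULL, min_n = 2) {
  pops <- sort(unique(gt$line_pops))
  if (is.null(pairs)) pairs <- t(combn(pops, 2))
  freqs <- pop_allele_freqs(gt)
  sizes <- pop_sample_sizes(gt)
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    p1 <- pairs[k, 1]; p2 <- pairs[k, 2]
    n1 <- sizes[, p1]; n2 <- sizes[, p2]
    f1 <- freqs[, p1]; f2 <- freqs[, p2]
    theta <- rep(NA_real_, nrow(gt$sites))
    ok <- n1 >= min_n & n2 >= min_n & is.finite(f1) & is.finite(f2)
    theta[ok] <- wc_fst_vec(n1[ok], n2[ok], f1[ok], f2[ok])
    out[[k]] <- data.frame(site = seq_len(nrow(gt$sites)),
                           chrom = gt$sites$chrom, pos = gt$sites$pos,
                           pair = paste(p1, p2, sep = "-"), theta = theta)
  }
  res <- do.call(rbind, out)
  res$defined <- !is.na(res$theta)
  res
}

# vectorised two-population form of wc_fst_site (same estimator)
wc_fst_vec <- function(n1, n2, p1, p2) {
  N <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / N
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (N - 2)
  nc <- N - (n1^2 + n2^2) / N
  a <- (msp - msg) / nc
  theta <- a / (a + msg)
  theta[pbar == 0 | pbar == 1 | (a + msg) == 0] <- NA_real_
  theta
}

#' Mean Fst of a gene over its SNPs and all population pairs
#'
#' Arithmetic mean of per-SNP theta over the gene's SNPs and the population
#' pairs; undefined (monomorphic) records are skipped.
#'
#' @param fst data frame from [fst_all_pairs()].
#' @param site_idx integer site indices belonging to the gene.
#' @return mean theta (NA if no defined record).
#' @export
gene_mean_fst <- function(fst, site_idx) {
  v <- fst$theta[fst$site %in% site_idx]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Empirical upper-tail threshold of an Fst distribution
#'
#' The threshold is the value at ascending rank ceiling((1 - q) * N); values
#' greater than or equal to it are outliers (ties at the threshold count as
#' outliers).
#'
#' @param theta numeric vector of defined theta values (>= 100 of them).
#' @param q upper-tail probability (e.g. 0.01).
#' @return the threshold value.
#' @export
empirical_tail_threshold <- function(theta, q) {
  theta <- theta[!is.na(theta)]
  if (length(theta) < 100)
    stop("empirical tail needs >= 100 defined values, got ", length(theta))
  s <- sort(theta)
  s[max(1L, ceiling((1 - q) * length(s)))]
}

#' Call per-pair empirical-tail outlier SNPs
#'
#' Thresholds are computed per population pair and chromosome class
#' (autosomes and X separately) on the genome-wide distribution of the
#' chosen effect class.
#'
#' @param fst data frame from [fst_all_pairs()] with an added `class`
#'   column (`"replacement"`, `"synonymous"`, ...) and `chrom_class`.
#' @param q tail probability.
#' @param effect_class restrict the distribution and calls to this class
#'   (NULL = all SNPs).
#' @return the input rows augmented with a logical `outlier` column and an
#'   attached `thresholds` attribute (data frame pair x chrom_class).
#' @export
fst_tail_outliers <- function(fst, q = 0.01, effect_class = "replacement") {
  d <- fst[fst$defined, , drop = FALSE]
  if (!is.null(effect_class)) d <- d[d$class %in% effect_class, , drop = FALSE]
  key <- interaction(d$pair, d$chrom_class, drop = TRUE)
  thr <- tapply(d$theta, key, empirical_tail_threshold, q = q)
  d$outlier <- d$theta >= thr[as.character(key)]
  attr(d, "thresholds") <- data.frame(stratum = names(thr),
                                      threshold = as.numeric(thr), q = q)
  d
}

#' Family enrichment in the Fst upper tail
#'
#' For each family, the number of its (replacement) SNPs falling in the
#' upper tail scaled by its total number of such SNPs, with families ranked
#' by that fraction. A SNP is counted once per (site, pair) record.
#'
#' @param outliers data frame from [fst_tail_outliers()].
#' @param site_families character vector mapping site index to family id
#'   (names or positions = site indices).
#' @return data frame per family: `family`, `outliers`, `total`, `fraction`,
#'   `rank` (1 = most enriched); families with no SNPs are dropped with a
#'   warning.
#' @export
family_tail_enrichment <- function(outliers, site_families) {
  fam <- site_families[outliers$site]
  keep <- !is.na(fam)
  d <- outliers[keep, , drop = FALSE]
  fam <- fam[keep]
  all_fams <- unique(site_families[!is.na(site_families)])
  missing <- setdiff(all_fams, unique(fam))
  if (length(missing))
    warning("families with no qualifying SNPs excluded: ",
            paste(missing, collapse = ", "))
  tot <- tapply(rep(1, length(fam)), fam, sum)
  out <- tapply(d$outlier, fam, sum)
  res <- data.frame(family = names(tot), outliers = as.integer(out),
                    total = as.integer(tot),
                    fraction = as.numeric(out / tot))
  res <- res[order(-res$fraction, res$family), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Neutral-simulation Fst tail thresholds
#'
#' Simulates neutral replicates under a demographic model, computes per-SNP
#' Fst for every population pair, and returns the upper-tail quantiles, plus
#' a comparison report when empirical thresholds are supplied.
#'
#' @param model a [demography_model].
#' @param n_reps number of replicate loci.
#' @param q tail probabilities (default 0.01 and 0.05).
#' @param theta scaled mutation rate per locus.
#' @param rho scaled recombination rate per locus.
#' @param empirical optional named vector of empirical thresholds keyed by
#'   pair label ("A-B").
#' @param seed optional integer seed.
#' @return data frame: `pair`, one column per `q`, and (when `empirical` is
#'   given) `empirical` and `exceeds_sim` columns.
#' @export
simulated_fst_thresholds <- function(model, n_reps = 200, q = c(0.01, 0.05),
                                     theta = 10, rho = 0, empirical = NULL,
                                     seed = NULL) {
  reps <- simulate_replicates(model, n_reps, rho = rho, theta = theta,
                              seed = seed)
  pops <- model$populations[model$sample_sizes > 0]
  labels <- rep(model$populations, model$sample_sizes)
  pairs <- t(combn(sort(pops), 2))
  acc <- setNames(vector("list", nrow(pairs)),
                  paste(pairs[, 1], pairs[, 2], sep = "-"))
  for (r in reps) {
    H <- r$haplotypes
    if (ncol(H) == 0) next
    for (k in seq_len(nrow(pairs))) {
      i1 <- labels == pairs[k, 1]
      i2 <- labels == pairs[k, 2]
      f1 <- colMeans(H[i1, , drop = FALSE])
      f2 <- colMeans(H[i2, , drop = FALSE])
      th <- vapply(seq_len(ncol(H)), function(s) {
        rec <- wc_fst_site(c(sum(i1), sum(i2)), c(f1[s], f2[s]))
        rec$theta
      }, numeric(1))
      acc[[k]] <- c(acc[[k]], th[!is.na(th)])
    }
  }
  res <- data.frame(pair = names(acc))
  for (qq in q)
    res[[paste0("q", qq)]] <- vapply(acc, function(v)
      quantile(v, 1 - qq, names = FALSE, type = 1), numeric(1))
  if (!is.null(empirical)) {
    res$empirical <- as.numeric(empirical[res$pair])
    res$exceeds_sim <- res$empirical > res[[paste0("q", q[1])]]
  }
  res
}

#' Fraction of selection candidates segregating in the ancestral population
#'
#' Among polarized candidate SNPs, the fraction whose derived allele is
#' present but not fixed (frequency strictly between 0 and 1) in the
#' ancestral-range population sample: the standing-variation fraction.
#'
#' @param derived_freq derived-allele frequencies of the candidates in the
#'   ancestral population.
#' @return fraction in \[0, 1\].
#' @export
standing_variation_fraction <- function(derived_freq) {
  stopifnot(all(derived_freq >= 0 & derived_freq <= 1, na.rm = TRUE))
  f <- derived_freq[!is.na(derived_freq)]
  if (length(f) == 0) return(NA_real_)
  mean(f > 0 & f < 1)
}

#' Genes under divergent selection across population pairs
#'
#' Candidates carry two or more distinct replacement outlier SNPs whose
#' outlier status arises in different population pairs.
#'
#' @param outliers data frame from [fst_tail_outliers()] (replacement
#'   class), with `site`, `pair`, `outlier`.
#' @param site_genes character vector mapping site index to gene id.
#' @return character vector of candidate gene ids.
#' @export
divergent_selection_candidates <- function(outliers, site_genes) {
  d <- outliers[outliers$outlier, , drop = FALSE]
  d$gene <- site_genes[d$site]
  d <- d[!is.na(d$gene), , drop = FALSE]
  cand <- character(0)
  for (g in unique(d$gene)) {
    dg <- d[d$gene == g, , drop = FALSE]
    if (length(unique(dg$site)) < 2) next
    # at least two distinct SNPs whose outlier pairs differ
    site_pairs <- split(dg$pair, dg$site)
    found <- FALSE
    sites <- names(site_pairs)
    for (i in seq_along(sites)) {
      for (j in seq_len(i - 1L)) {
        if (length(setdiff(site_pairs[[i]], site_pairs[[j]])) > 0 ||
            length(setdiff(site_pairs[[j]], site_pairs[[i]])) > 0) {
          found <- TRUE
        }
      }
    }
    if (found) cand <- c(cand, g)
  }
  sort(cand)
}
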