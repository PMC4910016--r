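## Site-frequency-spectrum statistics: unfolded SFS, Fay & Wu's H,
## family bootstrap, and coalescent-simulation significance.

# spectrum helpers; xi is the unfolded SFS (counts of derived alleles at
# frequency i/n for i = 1..n-1)
theta_pi_from_sfs <- function(xi, n) {
  if (n < 2 || sum(xi) == 0) return(0)
  i <- seq_len(n - 1)
  sum(i * (n - i) * xi) / choose(n, 2)
}

theta_h_from_sfs <- function(xi, n) {
  if (n < 2 || sum(xi) == 0) return(0)
  i <- seq_len(n - 1)
  sum(i^2 * xi) / choose(n, 2)
}

fay_wu_h_from_sfs <- function(xi, n) {
  if (n < 3 || sum(xi) == 0) return(NA_real_)
  theta_pi_from_sfs(xi, n) - theta_h_from_sfs(xi, n)
}

tajima_d_from_sfs <- function(xi, n) {
  S <- sum(xi)
  if (n < 4 || S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi_from_sfs(xi, n) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Unfolded site-frequency spectrum from a haplotype matrix
#'
#' Tallies derived-allele counts of polarized segregating sites into the
#' unfolded spectrum xi_1..xi_(n-1). Sites fixed derived (count n) or absent
#' (count 0) are not segregating and are excluded.
#'
#' @param haplotypes 0/1 matrix (rows = haploid samples, columns = sites)
#'   with derived alleles coded 1; unpolarized sites must already be removed.
#' @param gene optional gene id stored on the record.
#' @param population optional population label stored on the record.
#' @return an `sfs_record`: `n`, spectrum `xi`, `theta_pi`, `theta_h`, `H`.
#' @export
#' @examples
#' h <- matrix(c(1, 0, 0, 0), nrow = 4)
#' unfolded_sfs(h)$xi
unfolded_sfs <- function(haplotypes, gene = NA_character_,
                         population = NA_character_) {
  stopifnot(is.matrix(haplotypes), all(haplotypes %in% c(0, 1)))
  n <- nrow(haplotypes)
  counts <- if (ncol(haplotypes) > 0) colSums(haplotypes) else integer(0)
  seg <- counts > 0 & counts < n
  xi <- tabulate(counts[seg], nbins = max(n - 1, 0))
  structure(list(gene = gene, population = population, n = n, xi = xi,
                 theta_pi = theta_pi_from_sfs(xi, n),
                 theta_h = theta_h_from_sfs(xi, n),
                 H = fay_wu_h_from_sfs(xi, n)),
            class = "sfs_record")
}

#' Fay and Wu's H
#'
#' H = theta_pi - theta_H with theta_pi = sum i (n-i) xi_i / C(n,2) and
#' theta_H = sum i^2 xi_i / C(n,2). Negative H flags an excess of
#' high-frequency derived alleles, the footprint of a recent selective
#' sweep. Defined for n >= 3 and at least one segregating site.
#'
#' @param rec an `sfs_record` from [unfolded_sfs()].
#' @return numeric H (NA when undefined).
#' @export
fay_wu_h <- function(rec) {
  stopifnot(inherits(rec, "sfs_record"))
  fay_wu_h_from_sfs(rec$xi, rec$n)
}

#' Family-level bootstrap of mean Fay and Wu's H
#'
#' Resamples genes with replacement and reports the mean H with a percentile
#' bootstrap confidence interval; a family is flagged significantly negative
#' when the interval's upper bound is below zero.
#'
#' @param h_values numeric vector of per-gene H values (NA dropped).
#' @param B number of bootstrap resamples.
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return list: `mean_h`, `ci` (length 2), `significant`, `n_genes`, `B`.
#' @export
family_h_bootstrap <- function(h_values, B = 10000, conf = 0.95, seed = NULL) {
  h <- h_values[!is.na(h_values)]
  if (length(h) < 2) stop("family bootstrap needs >= 2 genes with defined H")
  boot <- with_seed(seed, vapply(seq_len(B), function(b)
    mean(sample(h, length(h), replace = TRUE)), numeric(1)))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 1))
  list(mean_h = mean(h), ci = ci, significant = ci[2] < 0,
       n_genes = length(h), B = B)
}

#' Coalescent significance of an observed Fay and Wu's H
#'
#' Compares an observed H against neutral null distributions simulated under
#' a grid of demographic models and recombination rates, conditioning on the
#' gene's observed number of segregating sites. The p-value in each cell is
#' the fraction of neutral replicates with H at or below the observed value
#' (a lower-tail test for the sweep signature); a p of 0 is reported as
#' 1/n_reps, the resolution bound of the simulation.
#'
#' @param h_obs observed H.
#' @param S observed number of segregating sites used for conditioning.
#' @param n haploid sample size for the simulation.
#' @param models named list of [demography_model] objects (the grid rows).
#' @param rho_grid numeric vector of scaled recombination rates.
#' @param n_reps replicates per cell.
#' @param locus_length_bp physical length metadata (family median length).
#' @param seed optional integer seed.
#' @param null_h optional precomputed list of null H vectors keyed by
#'   `"model|rho"`, to share simulations across genes with equal S.
#' @return data frame with columns `model`, `rho`, `p`, `sig05`, `sig025`.
#' @export
h_significance_sim <- function(h_obs, S, n, models, rho_grid = c(1, 50, 250),
                               n_reps = 1000, locus_length_bp = 1500,
                               seed = NULL, null_h = NULL) {
  stopifnot(S >= 1, n >= 3)
  if (inherits(models, "demography_model")) models <- list(model = models)
  seeds <- derive_seeds(seed, length(models) * length(rho_grid))
  cells <- expand.grid(model = names(models), rho = rho_grid,
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(ci) {
    key <- paste0(cells$model[ci], "|", cells$rho[ci])
    h0 <- if (!is.null(null_h) && !is.null(null_h[[key]])) {
      null_h[[key]]
    } else {
      reps <- simulate_replicates(models[[cells$model[ci]]], n_reps,
                                  rho = cells$rho[ci], S = S,
                                  locus_length_bp = locus_length_bp,
                                  seed = seeds[[ci]])
      summarize_replicates(reps)$fay_wu_h
    }
    h0 <- h0[!is.na(h0)]
    p <- mean(h0 <= h_obs)
    if (p == 0) p <- 1 / length(h0)
    data.frame(model = cells$model[ci], rho = cells$rho[ci], p = p,
               sig05 = p < 0.05, sig025 = p < 0.025)
  })
  do.call(rbind, res)
}

#' Precompute null H distributions over a (model, rho) grid
#'
#' @inheritParams h_significance_sim
#' @return list of numeric H vectors keyed by `"model|rho"`.
#' @export
h_null_grid <- function(S, n, models, rho_grid = c(1, 50, 250),
                        n_reps = 1000, locus_length_bp = 1500, seed = NULL) {
  if (inherits(models, "demography_model")) models <- list(model = models)
  seeds <- derive_seeds(seed, length(models) * length(rho_grid))
  out <- list()
  ci <- 0
  for (m in names(models)) for (r in rho_grid) {
    ci <- ci + 1
    reps <- simulate_replicates(models[[m]], n_reps, rho = r, S = S,
                                locus_length_bp = locus_length_bp,
                                seed = seeds[[ci]])
    out[[paste0(m, "|", r)]] <- summarize_replicates(reps)$fay_wu_h
  }
  out
}

#' Call sweep candidates from a table of per-cell p-values
#'
#' A gene is a candidate when it is significant at the 5% tier under every
#' demographic model for at least the two higher recombination rates.
#'
#' @param ptab data frame from [h_significance_sim()].
#' @param tier significance tier (default 0.05).
#' @return logical: candidate or not.
#' @export
h_sweep_candidate <- function(ptab, tier = 0.05) {
  rhos <- sort(unique(ptab$rho), decreasing = TRUE)
  keep <- ptab$rho %in% rhos[seq_len(min(2, length(rhos)))]
  all(tapply(ptab$p[keep] < tier, ptab$model[keep], all))
}
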