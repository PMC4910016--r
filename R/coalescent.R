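#' Simulate an ancestral recombination graph under a demographic model
#'
#' Runs the structured coalescent with recombination (Hudson's algorithm)
#' for one locus spanning the unit interval. With `rho = 0` the result holds
#' a single marginal tree; otherwise marginal trees change at recombination
#' breakpoints.
#'
#' @param model a [demography_model].
#' @param locus_length_bp physical locus length, carried as metadata (the
#'   engine works on \[0,1) with `rho` already scaled as 4*N0*r*L).
#' @param rho scaled recombination rate of the whole locus.
#' @param seed optional integer seed.
#' @return an object of class `famsel_arg` with node times, edge table
#'   (left/right/parent/child on \[0,1)), sample population labels.
#' @export
#' @examples
#' arg <- simulate_genealogy(demography_model("p", 4), rho = 0, seed = 1)
#' n_marginal_trees(arg)
simulate_genealogy <- function(model, locus_length_bp = 1000, rho = 0,
                               seed = NULL) {
  stopifnot(inherits(model, "demography_model"), rho >= 0)
  if (sum(model$sample_sizes) < 2) stop("need at least 2 samples in total")
  iso <- check_coalescible(model)
  if (!is.null(iso)) {
    stop("model is not coalescible; isolated population groups: ",
         paste(vapply(iso, paste, "", collapse = "+"), collapse = " | "))
  }
  arg <- with_seed(seed, .arg_simulate(model$sample_sizes, model$sizes,
                                       model$growth, model$migration,
                                       model$events, rho))
  arg$sample_pops <- rep(model$populations, model$sample_sizes)
  arg$locus_length_bp <- locus_length_bp
  arg$rho <- rho
  class(arg) <- "famsel_arg"
  arg
}

#' Number of distinct marginal trees in a simulated genealogy
#' @param arg a `famsel_arg` from [simulate_genealogy()].
#' @return integer count of breakpoint-delimited intervals.
#' @export
n_marginal_trees <- function(arg) .arg_n_trees(unclass(arg))

#' Time to the most recent common ancestor at a genome position
#' @param arg a `famsel_arg`.
#' @param at position in \[0,1).
#' @return TMRCA in units of 4N0 generations.
#' @export
tmrca <- function(arg, at = 0.5) .arg_tmrca(unclass(arg), at)

new_sim_replicate <- function(drop, arg) {
  structure(list(haplotypes = drop$genotypes, positions = drop$positions,
                 sample_pops = arg$sample_pops,
                 n_trees = drop$n_trees), class = "sim_replicate")
}

#' Place exactly S mutations on a genealogy (fixed-S conditioning)
#'
#' Mutations are placed on branches with probability proportional to
#' span-weighted branch length (Hudson's method, as in `ms -s`), yielding an
#' infinite-sites 0/1 haplotype matrix with derived alleles coded 1.
#'
#' @param arg a `famsel_arg`.
#' @param S number of segregating sites to place (>= 0).
#' @param seed optional integer seed.
#' @return a `sim_replicate`: haplotype matrix (samples x S), positions,
#'   sample population labels.
#' @export
drop_mutations_fixed_s <- function(arg, S, seed = NULL) {
  stopifnot(inherits(arg, "famsel_arg"), S >= 0, S == round(S))
  drop <- with_seed(seed, .arg_drop_mutations(unclass(arg), as.numeric(S), TRUE))
  new_sim_replicate(drop, arg)
}

#' Place mutations on a genealogy at rate theta
#'
#' Poisson mutation dropping: the number of mutations is Poisson with mean
#' theta times the span-weighted total branch length (time in 4N0 units, so
#' theta = 4*N0*mu per locus).
#'
#' @param arg a `famsel_arg`.
#' @param theta scaled locus mutation rate (>= 0).
#' @param seed optional integer seed.
#' @return a `sim_replicate`.
#' @export
drop_mutations_theta <- function(arg, theta, seed = NULL) {
  stopifnot(inherits(arg, "famsel_arg"), theta >= 0)
  drop <- with_seed(seed, .arg_drop_mutations(unclass(arg), theta, FALSE))
  new_sim_replicate(drop, arg)
}

#' Simulate many replicates under one model
#'
#' @param model a [demography_model].
#' @param n_reps number of independent replicates.
#' @param rho scaled recombination rate.
#' @param S fixed number of segregating sites (fixed-S mode), or `NULL`.
#' @param theta scaled mutation rate (theta mode), or `NULL`. Exactly one of
#'   `S` and `theta` must be given.
#' @param locus_length_bp metadata only.
#' @param seed optional integer seed governing the whole batch.
#' @return list of `sim_replicate` objects.
#' @export
simulate_replicates <- function(model, n_reps, rho = 0, S = NULL,
                                theta = NULL, locus_length_bp = 1000,
                                seed = NULL) {
  stopifnot(n_reps >= 1, xor(is.null(S), is.null(theta)))
  with_seed(seed, lapply(seq_len(n_reps), function(i) {
    arg <- simulate_genealogy(model, locus_length_bp, rho)
    if (!is.null(S)) drop_mutations_fixed_s(arg, S)
    else drop_mutations_theta(arg, theta)
  }))
}

#' Summary statistics for simulated replicates
#'
#' Computes, per replicate, the number of segregating sites S, mean pairwise
#' diversity pi, Tajima's D and Fay and Wu's H from the derived-coded
#' haplotype matrix, through the same site-frequency-spectrum code used for
#' empirical data.
#'
#' @param reps list of `sim_replicate` objects (or a single one).
#' @return data frame with columns `S`, `pi`, `tajima_d`, `fay_wu_h`.
#' @export
summarize_replicates <- function(reps) {
  if (inherits(reps, "sim_replicate")) reps <- list(reps)
  out <- lapply(reps, function(r) {
    H <- r$haplotypes
    n <- nrow(H)
    counts <- if (ncol(H) > 0) colSums(H) else integer(0)
    seg <- counts > 0 & counts < n
    xi <- tabulate(counts[seg], nbins = n - 1)
    data.frame(S = sum(seg), pi = theta_pi_from_sfs(xi, n),
               tajima_d = tajima_d_from_sfs(xi, n),
               fay_wu_h = fay_wu_h_from_sfs(xi, n))
  })
  do.call(rbind, out)
}

#' Null quantiles of a summary statistic under a demographic model
#'
#' Runs `n_reps` neutral replicates and returns empirical quantiles of the
#' chosen statistic, the machinery behind simulation-based Fst thresholds
#' and Fay and Wu's H significance tiers.
#'
#' @param model a [demography_model].
#' @param locus_spec list with elements `rho`, and either `S` or `theta`,
#'   and optionally `length_bp`.
#' @param n_reps number of replicates (>= 1).
#' @param statistic one of `"S"`, `"pi"`, `"tajima_d"`, `"fay_wu_h"`, or a
#'   function mapping a `sim_replicate` to a scalar.
#' @param probs quantile probabilities.
#' @param seed optional integer seed.
#' @return named numeric vector of quantiles (type-1 empirical quantiles).
#' @export
null_quantiles <- function(model, locus_spec, n_reps, statistic = "fay_wu_h",
                           probs = c(0.01, 0.025, 0.05), seed = NULL) {
  stopifnot(n_reps >= 1)
  reps <- simulate_replicates(model, n_reps,
                              rho = locus_spec$rho %||% 0,
                              S = locus_spec$S, theta = locus_spec$theta,
                              locus_length_bp = locus_spec$length_bp %||% 1000,
                              seed = seed)
  vals <- if (is.function(statistic)) {
    vapply(reps, statistic, numeric(1))
  } else {
    summarize_replicates(reps)[[statistic]]
  }
  quantile(vals, probs = probs, na.rm = TRUE, type = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default locus lengths (bp) for the chemosensory families
#'
#' Median gene lengths used when simulating family-specific null
#' distributions: Or and Gr 1500 bp, Ir 2000 bp, Obp 600 bp.
#' @return named numeric vector.
#' @export
family_locus_lengths <- function() c(Or = 1500, Gr = 1500, Ir = 2000, Obp = 600)

#' Export replicates in ms-compatible text form
#'
#' Writes `//` blocks with `segsites:` and `positions:` lines so replicates
#' can be fed to external tools that consume ms output.
#'
#' @param reps list of `sim_replicate` objects.
#' @param path output file path.
#' @param cmdline first header line (free text).
#' @return `path`, invisibly.
#' @export
write_ms <- function(reps, path, cmdline = "famsel coalescent") {
  if (inherits(reps, "sim_replicate")) reps <- list(reps)
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(reps[[1]]$haplotypes)
  writeLines(c(paste(cmdline), paste(n, length(reps)), ""), con)
  for (r in reps) {
    writeLines("//", con)
    S <- ncol(r$haplotypes)
    writeLines(paste("segsites:", S), con)
    if (S > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.5f", r$positions), collapse = " ")), con)
      writeLines(apply(r$haplotypes, 1, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
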