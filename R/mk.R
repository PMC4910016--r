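## McDonald-Kreitman tables, DoS, family-level maximum-likelihood alpha and
## omega_a.

#' Assemble a McDonald-Kreitman table for one gene
#'
#' Polymorphism counts come from the focal (African/ancestral-range)
#' population only; divergence counts from the outgroup comparison (in
#' polarized mode only substitutions assigned to the focal branch). Genes
#' whose 2x2 marginal sums are not all greater than 6 are flagged excluded.
#'
#' @param gene gene id.
#' @param p_r,p_s replacement / silent polymorphism counts.
#' @param d_r,d_s replacement / silent substitution counts.
#' @param polarized logical flag recording the divergence mode.
#' @return list of class `mk_counts` with an `included` flag.
#' @export
#' @examples
#' build_mk_table("g1", p_r = 2, p_s = 10, d_r = 10, d_s = 5)
build_mk_table <- function(gene, p_r, p_s, d_r, d_s, polarized = FALSE) {
  counts <- c(p_r, p_s, d_r, d_s)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  margins <- c(p_r + p_s, d_r + d_s, p_r + d_r, p_s + d_s)
  structure(list(gene = gene, P_R = p_r, P_S = p_s, D_R = d_r, D_S = d_s,
                 polarized = polarized, included = all(margins > 6)),
            class = "mk_counts")
}

#' MK tables for many genes from per-gene variant effects and divergence
#'
#' @param effects data frame with columns `gene`, `class`
#'   (synonymous/replacement), restricted to the focal population's
#'   polymorphisms.
#' @param divergence data frame with columns `gene`, `d_r`, `d_s`.
#' @param polarized stored on each table.
#' @return list of `mk_counts`, one per gene in `divergence`.
#' @export
build_mk_tables <- function(effects, divergence, polarized = FALSE) {
  lapply(seq_len(nrow(divergence)), function(i) {
    g <- divergence$gene[i]
    e <- effects[effects$gene == g, , drop = FALSE]
    build_mk_table(g,
                   p_r = sum(e$class == "replacement"),
                   p_s = sum(e$class == "synonymous"),
                   d_r = divergence$d_r[i], d_s = divergence$d_s[i],
                   polarized = polarized)
  })
}

#' Fisher's exact test on an MK table
#'
#' Two-sided exact p-value of the 2x2 table (D_R, D_S | P_R, P_S), summing
#' over all tables with fixed margins whose hypergeometric probability does
#' not exceed the observed one.
#'
#' @param t an `mk_counts`.
#' @return two-sided p-value.
#' @export
mk_fisher_test <- function(t) {
  stopifnot(inherits(t, "mk_counts"))
  fisher.test(matrix(c(t$D_R, t$D_S, t$P_R, t$P_S), 2, 2))$p.value
}

#' Direction of selection (DoS) statistic
#'
#' DoS = D_R/(D_R+D_S) - P_R/(P_R+P_S); positive under adaptive divergence,
#' negative under segregating slightly deleterious replacement variation.
#' Requires both divergence and polymorphism to be non-empty.
#'
#' @param t an `mk_counts`.
#' @return DoS in \[-1, 1\].
#' @export
dos_statistic <- function(t) {
  stopifnot(inherits(t, "mk_counts"))
  if (t$D_R + t$D_S == 0 || t$P_R + t$P_S == 0)
    stop("DoS undefined: needs D_R+D_S > 0 and P_R+P_S > 0")
  t$D_R / (t$D_R + t$D_S) - t$P_R / (t$P_R + t$P_S)
}

#' Point estimate of the adaptive substitution fraction for one gene
#'
#' alpha = 1 - (D_S * P_R) / (D_R * P_S).
#'
#' @param t an `mk_counts` with D_R > 0 and P_S > 0.
#' @return alpha (at most 1; can be negative).
#' @export
alpha_point <- function(t) {
  stopifnot(inherits(t, "mk_counts"))
  if (t$D_R == 0 || t$P_S == 0)
    stop("alpha undefined: needs D_R > 0 and P_S > 0")
  1 - (t$D_S * t$P_R) / (t$D_R * t$P_S)
}

# profile log-likelihood of (alpha, f) for a set of MK tables under the
# Poisson factorization: P_S ~ Pois(th_i Ls), P_R ~ Pois(f th_i Ln),
# D_S ~ Pois(tt_i Ls), D_R ~ Pois(f tt_i Ln / (1 - alpha)); the per-gene
# nuisance rates th_i, tt_i are profiled out in closed form.
mk_profile_loglik <- function(alpha, log_f, PS, PR, DS, DR, Ls, Ln) {
  f <- exp(log_f)
  # theta_i profiled at (PS+PR)/(Ls + f Ln); t_i at (DS+DR)/(Ls + w)
  th <- (PS + PR) / (Ls + f * Ln)
  w <- f * Ln / (1 - alpha)
  td <- (DS + DR) / (Ls + w)
  # 0*log(0) terms dropped via the guards
  sum(ifelse(PS > 0, PS * log(th * Ls), 0) +
        ifelse(PR > 0, PR * log(f * th * Ln), 0) - (PS + PR)) +
    sum(ifelse(DS > 0, DS * log(td * Ls), 0) +
          ifelse(DR > 0, DR * log(td * w), 0) - (DS + DR))
}

#' Maximum-likelihood estimate of a shared alpha across a gene family
#'
#' Fits a Poisson count model in which each gene has free polymorphism and
#' divergence rates, the family shares an effectively-neutral replacement
#' fraction f, and adaptive substitutions inflate replacement divergence by
#' 1/(1-alpha). Per-gene rates are profiled out analytically; (alpha, f)
#' are maximised numerically. The confidence interval is the profile
#' likelihood region within 2 log-likelihood units of the maximum, and the
#' likelihood-ratio test contrasts the fit with alpha fixed at 0 (1 df).
#'
#' @param tables list of `mk_counts` (excluded tables are dropped).
#' @param site_lengths list of `site_lengths` parallel to `tables`, or NULL
#'   to use equal lengths (pure count model).
#' @param alpha_bounds search interval for alpha (upper bound < 1).
#' @param apply_filter drop tables whose `included` flag is FALSE.
#' @param compute_ci profile the 2-log-likelihood-unit confidence interval
#'   (default TRUE; disable in large calibration loops).
#' @return list of class `alpha_estimate`: `alpha`, `ci` (2 log-likelihood
#'   units), `f`, `omega_a` (NA until scaled), `lrt_p`, `n_genes`, `logL`.
#' @export
alpha_family_ml <- function(tables, site_lengths = NULL,
                            alpha_bounds = c(-10, 0.999),
                            apply_filter = TRUE, compute_ci = TRUE) {
  if (!is.null(site_lengths) && length(site_lengths) != length(tables))
    stop("site_lengths must parallel tables")
  if (apply_filter) {
    keep <- vapply(tables, function(t) t$included, logical(1))
    tables <- tables[keep]
    if (!is.null(site_lengths)) site_lengths <- site_lengths[keep]
  }
  if (length(tables) < 2)
    stop("family-level alpha needs at least 2 included genes")
  if (is.null(site_lengths)) {
    Ls <- rep(1, length(tables))
    Ln <- rep(1, length(tables))
  } else {
    Ls <- vapply(site_lengths, function(s) s$length_s, numeric(1))
    Ln <- vapply(site_lengths, function(s) s$length_ns, numeric(1))
  }
  PS <- vapply(tables, function(t) t$P_S, numeric(1))
  PR <- vapply(tables, function(t) t$P_R, numeric(1))
  DS <- vapply(tables, function(t) t$D_S, numeric(1))
  DR <- vapply(tables, function(t) t$D_R, numeric(1))
  prof <- function(alpha) {
    opt <- optimize(function(lf)
      -mk_profile_loglik(alpha, lf, PS, PR, DS, DR, Ls, Ln),
      interval = c(-12, 6))
    -opt$objective
  }
  fit <- optim(c(alpha = 0, log_f = log(0.2)),
               function(par) {
                 a <- par[1]
                 if (a <= alpha_bounds[1] || a >= alpha_bounds[2]) return(1e10)
                 -mk_profile_loglik(a, par[2], PS, PR, DS, DR, Ls, Ln)
               }, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  if (fit$convergence != 0)
    stop("alpha ML fit did not converge: optim code ", fit$convergence,
         "; ", fit$counts[1], " function evaluations, value ", fit$value)
  a_hat <- fit$par[1]
  ll_hat <- -fit$value
  ci <- c(NA_real_, NA_real_)
  if (compute_ci) {
    # profile-likelihood interval at 2 log-likelihood units
    g <- function(a) prof(a) - (ll_hat - 2)
    ci[1] <- if (g(alpha_bounds[1]) > 0) alpha_bounds[1]
    else uniroot(g, c(alpha_bounds[1], a_hat), tol = 1e-5)$root
    ci[2] <- if (g(alpha_bounds[2]) > 0) alpha_bounds[2]
    else uniroot(g, c(a_hat, alpha_bounds[2]), tol = 1e-5)$root
  }
  lrt <- 2 * (ll_hat - prof(0))
  structure(list(alpha = unname(a_hat), ci = ci,
                 f = unname(exp(fit$par[2])), omega_a = NA_real_,
                 lrt_p = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
                 n_genes = length(tables), logL = ll_hat),
            class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf("alpha = %.3f (CI %.3f : %.3f), LRT p = %.3g, %d genes\n",
              x$alpha, x$ci[1], x$ci[2], x$lrt_p, x$n_genes))
  invisible(x)
}

#' Scale alpha by the relative synonymous substitution rate (omega_a)
#'
#' omega_a = alpha * (sum D_R / sum length_ns) / (sum D_S / sum length_s),
#' using counts pooled over the estimate's genes.
#'
#' @param est an `alpha_estimate`.
#' @param tables the `mk_counts` list the estimate was fitted on.
#' @param site_lengths parallel list of `site_lengths`.
#' @param apply_filter drop excluded tables (as in the fit).
#' @return the `alpha_estimate` with `omega_a` filled in.
#' @export
omega_a <- function(est, tables, site_lengths, apply_filter = TRUE) {
  stopifnot(inherits(est, "alpha_estimate"),
            length(tables) == length(site_lengths))
  if (apply_filter) {
    keep <- vapply(tables, function(t) t$included, logical(1))
    tables <- tables[keep]
    site_lengths <- site_lengths[keep]
  }
  DR <- sum(vapply(tables, function(t) t$D_R, numeric(1)))
  DS <- sum(vapply(tables, function(t) t$D_S, numeric(1)))
  Ln <- sum(vapply(site_lengths, function(s) s$length_ns, numeric(1)))
  Lss <- sum(vapply(site_lengths, function(s) s$length_s, numeric(1)))
  if (DS <= 0) stop("omega_a undefined: pooled D_S must be positive")
  est$omega_a <- est$alpha * (DR / Ln) / (DS / Lss)
  est
}

#' Independent alpha estimates for tagged subgroups of genes
#'
#' Splits the tables by tag and runs [alpha_family_ml()] per subgroup;
#' empty or singleton tag classes are skipped with a warning.
#'
#' @param tables list of `mk_counts`.
#' @param tags character vector of subgroup tags parallel to `tables`.
#' @param site_lengths optional parallel list of `site_lengths`.
#' @return named list of `alpha_estimate` per subgroup.
#' @export
subgroup_contrast <- function(tables, tags, site_lengths = NULL) {
  stopifnot(length(tags) == length(tables))
  out <- list()
  for (tg in unique(tags)) {
    idx <- which(tags == tg)
    sl <- if (is.null(site_lengths)) NULL else site_lengths[idx]
    est <- tryCatch(alpha_family_ml(tables[idx], sl),
                    error = function(e) {
                      warning("subgroup ", tg, " skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(est)) out[[tg]] <- est
  }
  out
}

#' Per-gene MK report table
#'
#' @param tables list of `mk_counts`.
#' @param bonferroni apply Bonferroni correction across the tested
#'   (included) genes.
#' @return data frame: gene, counts, inclusion flag, DoS (NA when
#'   undefined), Fisher p, adjusted p, significance flags.
#' @export
mk_report <- function(tables, bonferroni = TRUE) {
  rows <- lapply(tables, function(t) {
    dos <- tryCatch(dos_statistic(t), error = function(e) NA_real_)
    p <- if (t$included) mk_fisher_test(t) else NA_real_
    data.frame(gene = t$gene, P_R = t$P_R, P_S = t$P_S, D_R = t$D_R,
               D_S = t$D_S, included = t$included, dos = dos, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- if (bonferroni) {
    pmin(out$p * sum(out$included), 1)
  } else out$p
  out$sig <- !is.na(out$p) & out$p < 0.05
  out$sig_bonf <- !is.na(out$p_bonf) & out$p_bonf < 0.05
  out
}
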