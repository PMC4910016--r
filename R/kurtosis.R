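## Receptor tuning breadth (lifetime kurtosis) and its relation to
## gene-level differentiation.

#' Lifetime kurtosis of a receptor response profile
#'
#' K_L = \[ (1/M) sum ((r_i - rbar)/sigma_r)^4 \] - 3, the excess fourth
#' standardized moment of the responses of one receptor across the M
#' odorants tested, using population (1/M) moments. High K_L means a
#' narrowly tuned receptor (few strong responses among many weak ones);
#' low K_L means broad tuning. Invariant to affine rescaling of the
#' response vector.
#'
#' @param responses numeric response vector (missing values dropped).
#' @param excess subtract 3 (default TRUE); the correlation analyses are
#'   invariant to this constant shift.
#' @param min_m minimum number of odorants (default 4).
#' @return K_L.
#' @export
#' @examples
#' lifetime_kurtosis(c(-1, -1, 1, 1))  # -2: maximally broad (bimodal)
lifetime_kurtosis <- function(responses, excess = TRUE, min_m = 4) {
  r <- responses[!is.na(responses)]
  M <- length(r)
  if (M < min_m) stop("lifetime kurtosis needs >= ", min_m, " responses")
  s <- sqrt(mean((r - mean(r))^2))
  if (s == 0) stop("constant response vector: sigma_r = 0")
  k <- mean(((r - mean(r)) / s)^4)
  if (excess) k - 3 else k
}

#' Kurtosis for every receptor of a response matrix
#'
#' @param responses matrix/data frame, rows = receptors, columns = odorants;
#'   NA entries are dropped per receptor.
#' @param min_m minimum odorants per receptor; receptors below it get NA.
#' @return named numeric vector of K_L.
#' @export
lifetime_kurtosis_matrix <- function(responses, min_m = 4) {
  m <- as.matrix(responses)
  out <- apply(m, 1, function(r) {
    tryCatch(lifetime_kurtosis(r, min_m = min_m), error = function(e) NA_real_)
  })
  setNames(as.numeric(out), rownames(m))
}

#' Correlation between tuning breadth and gene-level Fst
#'
#' Relates each receptor's K_L to the mean Fst of its gene (averaged over
#' SNPs and the 10 population pairs), reporting the product-moment
#' correlation with its test p-value and the linear regression slope
#' (Fst regressed on K_L). A rank (Spearman) option is available.
#'
#' @param kl named numeric vector of K_L per receptor.
#' @param mean_fst named numeric vector of mean Fst per receptor gene
#'   (matched by name; non-overlapping entries dropped).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list: `r`, `p`, `slope`, `slope_p`, `n`.
#' @export
kl_fst_correlation <- function(kl, mean_fst, method = c("pearson",
                                                        "spearman")) {
  method <- match.arg(method)
  common <- intersect(names(kl), names(mean_fst))
  x <- kl[common]
  y <- mean_fst[common]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop("correlation needs >= 3 receptors with both K_L and Fst, got ",
         length(x))
  ct <- cor.test(x, y, method = method, exact = FALSE)
  fit <- summary(lm(y ~ x))
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = fit$coefficients["x", "Estimate"],
       slope_p = fit$coefficients["x", "Pr(>|t|)"], n = length(x))
}
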