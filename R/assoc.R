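#' Haploid single-variant allelic association
#'
#' Each individual contributes one allele (mtDNA is effectively haploid, so
#' no diploid doubling). Per SNP: the 2x2 Pearson chi-square (1 df, no
#' continuity correction) of alternate/reference counts by case/control
#' status; the asymptotic p-value; and the odds ratio
#' \code{(cases_alt * controls_ref) / (cases_ref * controls_alt)}, with the
#' Haldane-Anscombe 0.5 correction applied to all cells when any cell is
#' zero. Monomorphic SNPs (one allele across all called individuals) get NA
#' statistic, p and OR, flagged \code{monomorphic}.
#'
#' @param g a \code{\link{genotype_table}} with phenotypes.
#' @param alpha discovery threshold for the \code{significant} flag
#'   (default 0.05).
#' @return data.frame with one row per SNP: id, position, the four counts,
#'   \code{chi2}, \code{p}, \code{or}, \code{direction}
#'   ("risk"/"protective"/"none"), and flags \code{haldane},
#'   \code{monomorphic} and \code{significant}.
#' @export
allelic_test <- function(g, alpha = 0.05) {
  ca <- is_case(g); co <- is_control(g)
  if (!any(ca) || !any(co)) abort("need both cases and controls")
  gca <- g$geno[ca, , drop = FALSE]
  gco <- g$geno[co, , drop = FALSE]
  a <- colSums(gca == 1L, na.rm = TRUE)  # cases alt
  b <- colSums(gca == 0L, na.rm = TRUE)  # cases ref
  c_ <- colSums(gco == 1L, na.rm = TRUE) # controls alt
  d <- colSums(gco == 0L, na.rm = TRUE)  # controls ref
  mono <- (a + c_ == 0L) | (b + d == 0L)
  chi2 <- chisq_2x2(a, b, c_, d)
  p <- chisq_p(chi2)
  zero_cell <- (a == 0L | b == 0L | c_ == 0L | d == 0L) & !mono
  or <- ifelse(zero_cell,
               (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5)),
               a * d / (b * c_))
  chi2[mono] <- NA_real_; p[mono] <- NA_real_; or[mono] <- NA_real_
  data.frame(
    id = g$snp_meta$id, pos = g$snp_meta$pos,
    cases_alt = a, cases_ref = b, controls_alt = c_, controls_ref = d,
    chi2 = chi2, p = p, or = or,
    direction = ifelse(is.na(or) | or == 1, "none",
                       ifelse(or > 1, "risk", "protective")),
    haldane = zero_cell, monomorphic = mono,
    significant = !is.na(p) & p < alpha,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Bonferroni-corrected per-test alpha
#'
#' @param n_tests number of tests in the family (>= 1).
#' @param family_alpha family-wise error rate (default 0.05).
#' @return \code{family_alpha / n_tests}.
#' @examples
#' bonferroni_alpha(13)   # 3.85e-3
#' bonferroni_alpha(126)  # 3.97e-4
#' @export
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  stopifnot(n_tests >= 1)
  family_alpha / n_tests
}

#' Tally risk vs protective directions among significant variants
#'
#' Among variants with p below \code{p_threshold} and a defined, non-unit
#' odds ratio, counts OR > 1 (risk) against OR < 1 (protective) and tests the
#' split against 50:50 with a two-sided exact binomial test.
#'
#' @param results output of \code{\link{allelic_test}} (or rows with columns
#'   \code{p} and \code{or}).
#' @param p_threshold significance threshold (default 0.05).
#' @return list with \code{n_risk}, \code{n_protective} and \code{binomial_p}
#'   (NA with a \code{defined = FALSE} flag when nothing is significant).
#' @export
risk_direction_tally <- function(results, p_threshold = 0.05) {
  sig <- !is.na(results$p) & results$p < p_threshold &
    !is.na(results$or) & results$or != 1
  n_risk <- sum(results$or[sig] > 1)
  n_prot <- sum(results$or[sig] < 1)
  if (n_risk + n_prot == 0)
    return(list(n_risk = 0L, n_protective = 0L, binomial_p = NA_real_,
                defined = FALSE))
  list(n_risk = as.integer(n_risk), n_protective = as.integer(n_prot),
       binomial_p = stats::binom.test(n_risk, n_risk + n_prot, 0.5)$p.value,
       defined = TRUE)
}

#' Case-control power for a haploid locus
#'
#' The disease model is multiplicative on the single allele: prevalence
#' \code{K = p K1 + (1 - p) K0} with penetrance ratio \code{K1 / K0 = R}.
#' Retrospective allele frequencies follow by Bayes:
#' \code{p_case = p K1 / K}, \code{p_control = p (1 - K1) / (1 - K)}.
#' The allelic 1-df chi-square has noncentrality
#' \code{(p_case - p_control)^2 / (pbar (1 - pbar) (1/n_cases + 1/n_controls))}
#' with \code{pbar} the sample-size-weighted mean frequency; power is the
#' upper tail of the noncentral chi-square above the central \code{1 - alpha}
#' quantile. With \code{R = 1} the power equals \code{alpha} exactly.
#'
#' @param prevalence disease prevalence K in (0, 1).
#' @param risk_allele_freq population risk-allele frequency p in (0, 0.5].
#' @param effect_size per-allele relative risk R (>= 1).
#' @param n_cases,n_controls cohort sizes.
#' @param alpha test size.
#' @return list with \code{power}, the noncentrality \code{lambda}, the
#'   penetrances \code{K0}, \code{K1} and the retrospective frequencies
#'   \code{p_case}, \code{p_control}.
#' @export
power_calc <- function(prevalence, risk_allele_freq, effect_size,
                       n_cases, n_controls, alpha = 0.05) {
  K <- prevalence; p <- risk_allele_freq; R <- effect_size
  stopifnot(K > 0, K < 1, p > 0, p <= 0.5, R >= 1, alpha > 0, alpha < 1,
            n_cases >= 1, n_controls >= 1)
  K0 <- K / (p * R + 1 - p)
  K1 <- R * K0
  if (K1 > 1)
    abort("implied penetrance K1 = %.3f > 1: prevalence/effect inconsistent", K1)
  p_case <- p * K1 / K
  p_control <- p * (1 - K1) / (1 - K)
  pbar <- (n_cases * p_case + n_controls * p_control) / (n_cases + n_controls)
  lambda <- (p_case - p_control)^2 /
    (pbar * (1 - pbar) * (1 / n_cases + 1 / n_controls))
  power <- stats::pchisq(stats::qchisq(1 - alpha, df = 1), df = 1,
                         ncp = lambda, lower.tail = FALSE)
  list(power = power, lambda = lambda, K0 = K0, K1 = K1,
       p_case = p_case, p_control = p_control)
}
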