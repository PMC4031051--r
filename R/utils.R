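#' Pearson chi-square for a 2x2 table (vectorised)
#'
#' Closed-form Pearson statistic \code{n (ad - bc)^2 / (r1 r2 c1 c2)} on the
#' table \code{rbind(c(a, b), c(c, d))}, with one degree of freedom and no
#' continuity correction. When any row or column margin is zero the statistic
#' is defined as 0 (the table carries no information about association).
#'
#' @param a,b,c,d non-negative counts; vectors are recycled to a common
#'   length so many tables can be scored in one call.
#' @return numeric vector of chi-square statistics (>= 0).
#' @examples
#' chisq_2x2(10, 40, 40, 10) # 36
#' @export
chisq_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n  <- a + b + c + d
  r1 <- a + b; r2 <- c + d
  c1 <- a + c; c2 <- b + d
  num <- (a * d - b * c)^2 * n
  den <- r1 * r2 * c1 * c2
  out <- numeric(length(num))
  ok  <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Upper-tail p-value for a 1-df chi-square statistic
#' @param chi2 numeric vector of statistics.
#' @return p-values in (0, 1].
#' @export
chisq_p <- function(chi2) {
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

# internal: stop with a formatted message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
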