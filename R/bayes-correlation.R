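# Bayes factors for Pearson correlations.
#
# H1 places a symmetric stretched-beta prior on the population correlation
# rho: (rho + 1)/2 ~ Beta(1/kappa, 1/kappa) on (-1, 1); kappa = 1 is the
# uniform default. The Bayes factor integrates the exact sampling density
# of the observed correlation coefficient r given rho over that prior.

# log of Gauss hypergeometric 2F1(a, b; c; x) by series; converges fast for
# our use (a = b = 1/2, c = n - 1/2 large, 0 <= x < 1)
log_hyp2f1 <- function(a, b, cc, x) {
  term <- 1; s <- 1; k <- 0
  repeat {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * x
    s <- s + term
    k <- k + 1
    if (abs(term) < 1e-17 * abs(s) || k > 200000) break
  }
  log(s)
}

# exact log sampling density of Pearson's r given rho (n >= 4)
log_dr_given_rho <- function(r, n, rho) {
  log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) +
    ((n - 4) / 2) * log1p(-r^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
    (n - 1.5) * log1p(-rho * r) +
    log_hyp2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2)
}

#' Log Bayes factor for a nonzero Pearson correlation
#'
#' @param r observed Pearson correlation, |r| < 1.
#' @param n sample size (>= 4).
#' @param kappa prior width of the stretched beta (default 1: uniform on
#'   (-1, 1)).
#' @return a list of class `wcst_cor_bf`: `r`, `n`, `kappa`, `log_bf10`
#'   (natural log).
#' @export
jeffreys_correlation_log_bf <- function(r, n, kappa = 1) {
  if (!is.finite(r) || abs(r) >= 1)
    stop("r must lie strictly inside (-1, 1)", call. = FALSE)
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  a <- 1 / kappa
  logf <- function(rho)
    dbeta((rho + 1) / 2, a, a, log = TRUE) - log(2) +
      vapply(rho, function(p) log_dr_given_rho(r, n, p), 0)
  lmax <- logf(r)
  m1 <- integrate(function(rho) {
    z <- logf(rho) - lmax
    ifelse(is.finite(z), exp(z), 0)
  }, -1, 1, rel.tol = 1e-10, abs.tol = 0, subdivisions = 400L)
  structure(list(r = r, n = as.integer(n), kappa = kappa,
                 log_bf10 = lmax + log(m1$value) - log_dr_given_rho(r, n, 0)),
            class = "wcst_cor_bf")
}

#' Pairwise Bayesian correlation matrix
#'
#' Pearson correlations with natural-log Bayes factors for every pair of
#' the supplied measure columns, using pairwise-complete observations
#' (undefined percentages enter as `NA` and are dropped per pair).
#'
#' @param measures cohort measures data.frame.
#' @param columns measure columns to correlate.
#' @param kappa prior width, as in [jeffreys_correlation_log_bf()].
#' @return a data.frame with one row per unordered pair: `var1`, `var2`,
#'   `n`, `pearson_r`, `log_bf10`.
#' @export
bayes_correlation_matrix <- function(measures,
                                     columns = c("categories_pct", "sle_pct",
                                                 "npe_pct", "rpe_pct",
                                                 "ie_pct"),
                                     kappa = 1) {
  miss <- setdiff(columns, names(measures))
  if (length(miss))
    stop("unknown measure columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  pairs <- utils::combn(columns, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    ok <- stats::complete.cases(measures[[v1]], measures[[v2]])
    x <- measures[[v1]][ok]; y <- measures[[v2]][ok]
    rr <- suppressWarnings(stats::cor(x, y))
    lbf <- if (length(x) >= 4 && is.finite(rr) && abs(rr) < 1)
      jeffreys_correlation_log_bf(rr, length(x), kappa)$log_bf10
    else NA_real_
    data.frame(var1 = v1, var2 = v2, n = length(x), pearson_r = rr,
               log_bf10 = lbf, stringsAsFactors = FALSE)
  }))
}
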