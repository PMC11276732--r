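# Independent, naive re-implementations used as oracles. These transcribe
# the scoring definitions trial by trial (no shared code with the vectorized
# scorer) and integrate Bayes-factor integrands on dense uniform grids with
# stats::dt / an integral-representation hypergeometric (no shared code with
# the package's log-space quadrature).

oracle_label_trials <- function(session) {
  tr <- session$trials
  n <- nrow(tr)
  tgt <- cbind(tr$target_color, tr$target_shape, tr$target_number)
  fb <- tr$feedback
  m <- tr$matched_dimension
  rsb <- tr$rule_switch_before
  info_of <- function(j) {
    if (j < 1) return(NA_character_)
    if (fb[j] == 0 && m[j] != "ODD") m[j] else NA_character_
  }
  out <- data.frame(label = character(n), pe_occasion = character(n),
                    sle_occasion = logical(n), ie_occasion = logical(n),
                    stringsAsFactors = FALSE)
  for (t in seq_len(n)) {
    d1 <- info_of(t - 1)
    d0 <- info_of(t - 2)
    pe_occ <- "NONE"
    if (!is.na(d1)) {
      di <- match(d1, c("COLOR", "SHAPE", "NUMBER"))
      pe_occ <- if (tgt[t, di] == tgt[t - 1, di]) "REPETITIVE"
                else "NON_REPETITIVE"
    }
    ie_occ <- !is.na(d0) && !is.na(d1) && d0 != d1
    sle_occ <- t > 1 && fb[t - 1] == 1 && !rsb[t]
    lab <-
      if (fb[t] == 1) "CORRECT"
      else if (m[t] == "ODD") "OE"
      else if (pe_occ != "NONE" && m[t] == d1) {
        if (pe_occ == "REPETITIVE") "PE_REP" else "PE_NONREP"
      }
      else if (ie_occ && m[t] == d0) "IE"
      else if (sle_occ) "SLE"
      else if (rsb[t] && t > 1 && m[t] == tr$rule[t - 1])
        "SWITCH_SIGNAL_ERROR"
      else "UNCLASSIFIED_ERROR"
    out$label[t] <- lab
    out$pe_occasion[t] <- pe_occ
    out$sle_occasion[t] <- sle_occ
    out$ie_occasion[t] <- ie_occ
  }
  out
}

# dense-grid Riemann/Simpson oracle for the JZS log BF, built on stats::dt
oracle_jzs_log_bf10 <- function(t, n, r = sqrt(2) / 2, nodes = 40001L) {
  df <- n - 1
  dhat <- t / sqrt(n)
  W <- 20 / sqrt(n) + 2 * abs(dhat) + 10 * r
  g <- seq(dhat - W, dhat + W, length.out = nodes)
  # far-tail dt values underflow with a "full precision" warning; their
  # contribution to the integral is negligible at this tolerance
  f <- dcauchy(g, 0, r) * suppressWarnings(dt(t, df, ncp = g * sqrt(n)))
  h <- g[2] - g[1]
  # Simpson weights on the uniform grid
  w <- rep(c(4, 2), length.out = nodes - 2L)
  m1 <- h / 3 * (f[1] + f[nodes] + sum(w * f[2:(nodes - 1L)]))
  log(m1) - dt(t, df, log = TRUE)
}

# dense-grid oracle for the delta posterior median / credible interval
oracle_delta_quantiles <- function(t, n, r = sqrt(2) / 2, p = c(0.025, 0.5,
                                   0.975), nodes = 200001L) {
  df <- n - 1
  dhat <- t / sqrt(n)
  W <- 12 / sqrt(n) + abs(dhat) + 2 * r
  g <- seq(dhat - W, dhat + W, length.out = nodes)
  f <- dcauchy(g, 0, r) * suppressWarnings(dt(t, df, ncp = g * sqrt(n)))
  cdf <- (cumsum(f) - f / 2) / sum(f)
  approx(cdf, g, p, ties = "ordered")$y
}

# hypergeometric 2F1 via Euler's integral representation (b = 1/2 case)
oracle_hyp2f1 <- function(a, b, cc, x) {
  stopifnot(cc > b, b > 0)
  v <- integrate(function(u) u^(b - 1) * (1 - u)^(cc - b - 1) *
                   (1 - x * u)^(-a), 0, 1, rel.tol = 1e-12)$value
  exp(lgamma(cc) - lgamma(b) - lgamma(cc - b)) * v
}

# dense-grid oracle for the correlation log BF (uniform prior, kappa = 1)
oracle_cor_log_bf10 <- function(r, n, nodes = 20001L) {
  # plain-arithmetic density of Pearson's r; valid for moderate |r| where
  # (1 - r^2)^((n-4)/2) stays inside double range
  dens <- function(rho) {
    (n - 2) * exp(lgamma(n - 1) - lgamma(n - 0.5)) *
      (1 - rho^2)^((n - 1) / 2) * (1 - r^2)^((n - 4) / 2) /
      (sqrt(2 * pi) * (1 - rho * r)^(n - 1.5)) *
      oracle_hyp2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2)
  }
  g <- seq(-1 + 1e-9, 1 - 1e-9, length.out = nodes)
  f <- vapply(g, dens, 0) * 0.5   # uniform prior on (-1, 1)
  h <- g[2] - g[1]
  w <- rep(c(4, 2), length.out = nodes - 2L)
  m1 <- h / 3 * (f[1] + f[nodes] + sum(w * f[2:(nodes - 1L)]))
  log(m1) - log(dens(0))
}
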