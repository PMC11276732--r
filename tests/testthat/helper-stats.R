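# exact (Clopper-Pearson) 95% binomial confidence interval
binom_ci <- function(k, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - a, k + 1, n - k)
  c(lo, hi)
}
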