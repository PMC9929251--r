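# Independent oracles, deliberately written as direct transcriptions of
# definitions rather than reusing any package internals.

# prefix-by-prefix set intersection, the definition of the concordance curve
concordance_oracle <- function(a, b) {
  k <- min(length(a), length(b))
  vapply(seq_len(k), function(i) {
    length(intersect(a[seq_len(i)], b[seq_len(i)]))
  }, integer(1))
}

aucc_oracle <- function(a, b, normalization = "paper") {
  cc <- concordance_oracle(a, b)
  k <- length(cc)
  denom <- if (normalization == "paper") k^2 / 2 else k * (k + 1) / 2
  sum(cc) / denom
}

# closed-form expected-mean-squares (ANOVA) estimator for the balanced
# additive two-way crossed random model y_ijk = mu + a_i + b_j + e_ijk
ems_two_way <- function(y, fa, fb) {
  fa <- factor(fa)
  fb <- factor(fb)
  a <- nlevels(fa)
  b <- nlevels(fb)
  r <- length(y) / (a * b)
  stopifnot(r == round(r))
  ybar <- mean(y)
  ssa <- b * r * sum((tapply(y, fa, mean) - ybar)^2)
  ssb <- a * r * sum((tapply(y, fb, mean) - ybar)^2)
  sse <- sum((y - ybar)^2) - ssa - ssb
  msa <- ssa / (a - 1)
  msb <- ssb / (b - 1)
  mse <- sse / (a * b * r - a - b + 1)
  c(
    donor = (msa - mse) / (b * r),
    stimulus = (msb - mse) / (a * r),
    residual = mse
  )
}
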