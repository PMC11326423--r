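# Independent brute-force oracles for the agreement statistics, shared by
# the unit and acceptance suites.

# ICC from the two-way ANOVA table fitted by stats::aov (independent of the
# closed-form mean-square implementation under test).
icc_oracle <- function(a, b, variant = "icc2_1") {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- 2
  if (variant == "icc2_1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

# Kappa by explicit double loop over the contingency table.
kappa_oracle <- function(a, b, weighting, categories) {
  k <- length(categories)
  num <- den <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- if (weighting == "quadratic") ((i - j) / (k - 1))^2 else as.numeric(i != j)
      o <- mean(a == categories[i] & b == categories[j])
      e <- mean(a == categories[i]) * mean(b == categories[j])
      num <- num + w * o
      den <- den + w * e
    }
  }
  1 - num / den
}

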