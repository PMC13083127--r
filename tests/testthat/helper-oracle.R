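# Independent brute-force evaluation of the disproportionality formulas,
# written scalar and straight from their printed definitions. This oracle
# deliberately shares no code with the package.

oracle_ror <- function(a, b, c, d) {
  if (a == 0 || b == 0 || c == 0 || d == 0) return(list(defined = FALSE))
  ror <- (a / c) / (b / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(defined = TRUE, ror = ror,
       low = exp(log(ror) - 1.96 * se),
       high = exp(log(ror) + 1.96 * se))
}

oracle_prr <- function(a, b, c, d) {
  if ((a + b) == 0 || c == 0 || (c + d) == 0) return(list(defined = FALSE))
  list(defined = TRUE, prr = (a / (a + b)) / (c / (c + d)))
}

oracle_chi2 <- function(a, b, c, d) {
  if ((a + b) == 0 || (a + c) == 0 || (c + d) == 0 || (b + d) == 0) {
    return(list(defined = FALSE))
  }
  n <- a + b + c + d
  list(defined = TRUE,
       chi2 = (a * d - b * c)^2 * n / ((a + b) * (a + c) * (c + d) * (b + d)))
}

oracle_ic <- function(a, b, c, d) {
  if (a == 0) return(list(defined = FALSE))
  n <- a + b + c + d
  list(defined = TRUE, ic = log2(a * n / ((a + b) * (a + c))))
}

# closed-form BCPNN posterior moments, re-derived scalar
oracle_bcpnn <- function(a, b, c, d, ai = 1, bj = 1, al = 2, be = 2, gij = 1) {
  n <- a + b + c + d
  g <- gij * (n + al) * (n + be) / ((a + b + ai) * (a + c + bj))
  e_ic <- log2((a + gij) * (n + al) * (n + be) /
                 ((n + g) * (a + b + ai) * (a + c + bj)))
  v_ic <- (1 / log(2))^2 * (
    (n - a + g - gij) / ((a + gij) * (1 + n + g)) +
    (n - a - b + al - ai) / ((a + b + ai) * (1 + n + al)) +
    (n - a - c + be - bj) / ((a + c + bj) * (1 + n + be)))
  list(e_ic = e_ic, v_ic = v_ic, ic025 = e_ic - 2 * sqrt(v_ic))
}
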