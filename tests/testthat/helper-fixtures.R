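# Shared fixtures and independent oracle implementations.

metals7 <- c("Cr", "Mn", "Fe", "Cu", "Zn", "Cd", "Pb")

# a small deterministic 5 x 3 table
tiny_table <- function() {
  concentration_table(
    matrix(c(1, 2, 3, 4, 5,
             10, 9, 8, 7, 6,
             0.5, 0.5, 1.5, 2.5, 5.0), 5, 3,
           dimnames = list(NULL, c("Cr", "Mn", "Cd"))))
}

random_table <- function(n = 60, m = 7, seed = 1) {
  set.seed(seed)
  concentration_table(matrix(rlnorm(n * m), n, m,
                             dimnames = list(NULL, metals7[seq_len(m)])))
}

write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# two-pass oracle for descriptive statistics (adjusted estimators), written
# independently of the package internals
oracle_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  dev <- x - mu
  s <- sqrt(sum(dev^2) / (n - 1))
  m2 <- sum(dev^2) / n
  m3 <- sum(dev^3) / n
  m4 <- sum(dev^4) / n
  g1 <- m3 / m2^(3 / 2)
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- m4 / m2^2 - 3
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  c(min = min(x), max = max(x), mean = mu, sd = s,
    cv_percent = 100 * s / mu, skewness = G1, kurtosis = G2)
}

# partial-correlation KMO oracle via residual regressions (independent of
# the package's inverse-matrix route)
oracle_kmo <- function(x) {
  R <- cor(x)
  m <- ncol(x)
  q <- matrix(NA_real_, m, m)
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      others <- setdiff(seq_len(m), c(i, j))
      ri <- resid(lm(x[, i] ~ x[, others]))
      rj <- resid(lm(x[, j] ~ x[, others]))
      q[i, j] <- q[j, i] <- cor(ri, rj)
    }
  }
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(q[off]^2))
}

# fake single-population risk result (printed-table driven acceptance
# checks construct these from published numbers)
make_risk_result <- function(hq, ilcr) {
  list(hazard = structure(list(
         per_metal = data.frame(metal = names(hq), hq = unname(hq)),
         HI = sum(hq), class = if (sum(hq) < 1) "safe" else "severe"),
         class = "risk_result"),
       cancer = structure(list(
         per_metal = data.frame(metal = names(ilcr), ilcr = unname(ilcr)),
         TCR = sum(ilcr), class = "acceptable"),
         class = "risk_result"))
}

# source_contributions built from known percentages (sources x metals)
make_contribs <- function(per_metal_percent) {
  structure(list(per_metal_percent = per_metal_percent,
                 unapportioned_percent =
                   100 - colSums(per_metal_percent),
                 raw_ugL = per_metal_percent,
                 intercept_ugL = setNames(rep(0, ncol(per_metal_percent)),
                                          colnames(per_metal_percent)),
                 negative_policy = "truncate",
                 metals = colnames(per_metal_percent)),
            class = "source_contributions")
}
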