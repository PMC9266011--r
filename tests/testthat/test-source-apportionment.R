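test_that("Pearson matrix matches direct formula and cor.test p-values", {
  set.seed(31)
  x <- cbind(A = rnorm(5), B = rnorm(5), C = rnorm(5))
  x <- x - min(x)                                # keep concentrations >= 0
  tab <- concentration_table(x)
  cs <- pearson_matrix(tab)
  # direct covariance-ratio oracle on one small pair
  a <- x[, 1]; b <- x[, 2]
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cs$r["A", "B"], r_hand, tolerance = 1e-12)
  ct <- cor.test(a, b)
  expect_equal(cs$p["A", "B"], ct$p.value, tolerance = 1e-12)
  expect_equal(diag(cs$r), c(A = 1, B = 1, C = 1))

  neg <- concentration_table(cbind(A = 1:5, B = 11 - (1:5)))
  expect_equal(pearson_matrix(neg)$r["A", "B"], -1)
})

test_that("constant columns give NA correlations, not errors", {
  tab <- concentration_table(cbind(A = c(1, 2, 3), B = c(5, 5, 5)))
  cs <- pearson_matrix(tab)
  expect_true(is.na(cs$r["A", "B"]))
  expect_equal(cs$r["A", "A"], 1)
})

test_that("KMO: analytic 2-variable value, brute-force oracle, singularity", {
  set.seed(7)
  x2 <- matrix(rlnorm(40), 20, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(kmo_statistic(cor(x2)), 0.5, tolerance = 1e-12)

  for (seed in c(2, 9)) {
    set.seed(seed)
    x <- matrix(rnorm(60 * 7), 60, 7)
    expect_equal(kmo_statistic(cor(x)), oracle_kmo(x), tolerance = 1e-10)
  }
  # near-singular block design still matches the oracle
  set.seed(5)
  z <- rnorm(60)
  xs <- cbind(z + rnorm(60, sd = 1e-3), z + rnorm(60, sd = 1e-3),
              matrix(rnorm(60 * 3), 60, 3))
  expect_equal(kmo_statistic(cor(xs)), oracle_kmo(xs), tolerance = 1e-8)

  sing <- matrix(1, 3, 3)
  expect_error(kmo_statistic(sing), "singular")
})

test_that("Bartlett sphericity follows the closed form", {
  R <- diag(7)
  out <- bartlett_sphericity(R, n_sites = 60)
  expect_equal(out$chi2, 0)
  expect_equal(out$p, 1)
  expect_equal(out$dof, 21)

  set.seed(12)
  x <- matrix(rnorm(60 * 2), 60, 2)
  x[, 2] <- x[, 1] * 0.9 + x[, 2] * 0.1
  R <- cor(x)
  got <- bartlett_sphericity(R, 60)
  expect_equal(got$chi2, -(60 - 1 - (2 * 2 + 5) / 6) * log(det(R)),
               tolerance = 1e-12)
  expect_error(bartlett_sphericity(R, n_sites = 2), "n_sites")
})

test_that("varimax rotation preserves communalities and matches stats::varimax", {
  tab <- generate_survey(reference_synthetic_spec(), seed = 21)$table
  model <- fit_pca_varimax(tab, retention = "fixed", n_components = 3)
  R <- cor(tab$values)
  eig <- eigen(R, symmetric = TRUE)
  A <- eig$vectors[, 1:3] %*% diag(sqrt(eig$values[1:3]))
  # communality and total-variance preservation under rotation
  expect_equal(rowSums(model$loadings^2), setNames(rowSums(A^2), tab$metals),
               tolerance = 1e-10)
  expect_equal(sum(model$explained_percent), sum(eig$values[1:3]) / 7 * 100,
               tolerance = 1e-10)
  expect_equal(model$cumulative_percent, cumsum(model$explained_percent),
               tolerance = 1e-12)

  # independent oracle: stats::varimax, aligned by column/sign
  vm <- stats::varimax(A, normalize = TRUE, eps = 1e-8)
  L2 <- unclass(vm$loadings)
  align <- function(L, ref) {
    perm <- apply(abs(cor(ref, L)), 1, which.max)
    out <- L[, perm, drop = FALSE]
    for (j in seq_len(ncol(out))) {
      if (sum(out[, j] * ref[, j]) < 0) out[, j] <- -out[, j]
    }
    out
  }
  expect_equal(unname(align(L2, model$loadings)), unname(model$loadings),
               tolerance = 1e-4)
})

test_that("retention rules and rank-deficient input behave as specified", {
  set.seed(3)
  z <- rlnorm(30)
  dup <- concentration_table(cbind(A = z, B = z, C = rlnorm(30), D = rlnorm(30)))
  ev <- eigen(cor(dup$values), symmetric = TRUE)$values
  expect_gte(ev[1], 2)

  tab <- generate_survey(reference_synthetic_spec(), seed = 21)$table
  expect_error(fit_pca_varimax(tab, retention = "fixed", n_components = 0),
               "component")
  m3 <- fit_pca_varimax(tab, retention = "fixed", n_components = 3)
  expect_equal(m3$n_components, 3)
})

test_that("low-noise three-source data yield block-structured loadings", {
  spec <- reference_synthetic_spec()
  spec$noise_cv <- 0.05
  spec$outlier_metal <- NULL
  sim <- generate_survey(spec, seed = 6)
  model <- fit_pca_varimax(sim$table, retention = "fixed", n_components = 3)
  dominant <- apply(abs(model$loadings), 1, which.max)
  # metals generated from the same source share a dominant component
  expect_equal(dominant[["Cu"]], dominant[["Pb"]])
  expect_equal(dominant[["Mn"]], dominant[["Cd"]])
  expect_equal(dominant[["Cr"]], dominant[["Fe"]])
  expect_equal(length(unique(dominant[c("Cu", "Mn", "Cr")])), 3)
})

test_that("APCS anchors the zero-concentration sample at exactly zero", {
  for (seed in c(1, 13, 40)) {
    tab <- generate_survey(reference_synthetic_spec(), seed = seed)$table
    model <- fit_pca_varimax(tab, retention = "fixed", n_components = 3)
    zero <- concentration_table(matrix(0, 2, 7, dimnames = list(NULL, metals7)))
    sc0 <- apcs(model, zero)
    expect_lt(max(abs(unclass(sc0))), 1e-12)
  }
})

test_that("APCS linear-score algebra: mean site and constant shifts", {
  tab <- generate_survey(reference_synthetic_spec(), seed = 9)$table
  model <- fit_pca_varimax(tab, retention = "fixed", n_components = 3)
  mean_site <- concentration_table(matrix(colMeans(tab$values), 1,
                                          dimnames = list(NULL, metals7)))
  got <- drop(unclass(apcs(model, mean_site)))
  want <- drop((model$center / model$scale) %*% model$score_coef)
  expect_equal(got, want, tolerance = 1e-10)

  shifted <- concentration_table(sweep(tab$values, 2, c(5, 0, 0, 0, 0, 0, 0), "+"))
  d <- unclass(apcs(model, shifted)) - unclass(apcs(model, tab))
  expect_lt(max(abs(sweep(d, 2, d[1, ]))), 1e-10)   # identical shift per site
})

test_that("MLR satisfies the fit identity and recovers exact linear structure", {
  tab <- generate_survey(reference_synthetic_spec(), seed = 17)$table
  model <- fit_pca_varimax(tab, retention = "fixed", n_components = 3)
  sc <- apcs(model, tab)
  # construct concentrations exactly from the APCS columns
  beta <- rbind(c(2, 0.5, 1), c(0, 3, 0.2))
  y <- 1.5 + unclass(sc) %*% t(beta)
  y <- y - min(y)                                  # nonneg for the container
  ytab <- concentration_table(`colnames<-`(y, c("Cu", "Mn")))
  reg <- fit_mlr(sc, ytab)
  expect_equal(unname(reg$coefficients[, "Cu"]), c(2, 0.5, 1), tolerance = 1e-8)
  expect_equal(unname(reg$r_squared), c(1, 1), tolerance = 1e-10)
  # fit identity at machine precision
  pred <- matrix(reg$intercept, nrow(y), 2, byrow = TRUE) +
    unclass(sc) %*% reg$coefficients
  expect_equal(unname(pred), unname(reg$fitted), tolerance = 1e-12)

  # a pure-noise response has low R^2 at n = 60
  r2 <- vapply(c(101, 102, 103), function(s) {
    set.seed(s)
    ntab <- concentration_table(cbind(Cu = runif(60)))
    fit_mlr(sc, ntab)$r_squared
  }, numeric(1))
  expect_true(all(r2 < 0.2))

  # predicted/measured mean ratio is 1 by OLS (intercept included)
  full <- fit_mlr(sc, tab)
  expect_equal(unname(full$pred_meas_ratio), rep(1, 7), tolerance = 1e-10)
  expect_error(fit_mlr(sc, concentration_table(tab$values[1:4, ])),
               "sites")
})

test_that("contribution percentages: degenerate identities and policies", {
  # one source, zero intercept, noiseless: 100% from that source
  spec <- synthetic_spec(n_sites = 30, metals = c("A", "B", "C"),
                         loadings = rbind(s1 = c(2, 1, 4)),
                         noise_cv = 0, outlier_metal = NULL)
  sim <- generate_survey(spec, seed = 2)
  # with a single latent source the scores are exactly recoverable by
  # regression on any one column; emulate APCS with the normalized column
  fake_apcs <- structure(cbind(F1 = sim$table$values[, "A"] / 2),
                         class = c("apcs_matrix", "matrix", "array"))
  reg <- fit_mlr(fake_apcs, sim$table)
  contribs <- metal_source_contributions(reg, fake_apcs)
  expect_equal(unname(contribs$per_metal_percent["F1", ]), rep(100, 3),
               tolerance = 1e-8)
  expect_equal(unname(contribs$unapportioned_percent), rep(0, 3),
               tolerance = 1e-8)

  # two sources contributing equal mean terms, zero intercept: 50/50
  set.seed(88)
  s1 <- rlnorm(100); s2 <- rlnorm(100)
  vals <- cbind(A = s1 * mean(s2) + s2 * mean(s1))  # equal mean terms
  ap <- structure(cbind(F1 = s1, F2 = s2),
                  class = c("apcs_matrix", "matrix", "array"))
  reg2 <- fit_mlr(ap, concentration_table(vals))
  c2 <- metal_source_contributions(reg2, ap)
  expect_equal(unname(c2$per_metal_percent[, "A"]), c(50, 50),
               tolerance = 1e-6)

  # absolute policy keeps magnitude of negative terms
  expect_s3_class(metal_source_contributions(reg2, ap, "absolute"),
                  "source_contributions")
})

test_that("overall aggregation averages per-metal source-only shares", {
  pm <- rbind(F1 = c(A = 80, B = 20), F2 = c(A = 20, B = 80))
  contribs <- make_contribs(pm)
  expect_equal(unname(overall_source_contributions(contribs)), c(50, 50))

  pm2 <- rbind(F1 = c(A = 100, B = 100), F2 = c(A = 0, B = 0))
  expect_equal(unname(overall_source_contributions(make_contribs(pm2))),
               c(100, 0))
  # concentration weighting tilts toward the high-load metal
  tab <- concentration_table(cbind(A = c(10, 10), B = c(1, 1)))
  got <- overall_source_contributions(make_contribs(pm), "concentration",
                                      table = tab)
  expect_gt(got[["F1"]], 70)
})
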