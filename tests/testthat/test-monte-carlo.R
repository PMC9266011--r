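test_that("lognormal fitting recovers parameters and degenerates safely", {
  set.seed(14)
  x <- rlnorm(5000, meanlog = 1.3, sdlog = 0.7)
  sp <- fit_lognormal(x)
  expect_equal(sp$pars$meanlog, 1.3, tolerance = 3 * 0.7 / sqrt(5000) / 1.3)
  expect_equal(sp$pars$sdlog, 0.7, tolerance = 0.05)
  expect_true(is.finite(attr(sp, "ks_stat")))

  const <- fit_lognormal(rep(2.5, 10))
  expect_equal(const$pars$sdlog, 0)

  sym <- fit_lognormal(c(exp(-1), exp(1)))
  expect_equal(sym$pars$meanlog, 0, tolerance = 1e-12)

  expect_error(fit_lognormal(c(1, 0)), "positive")
})

test_that("distribution specs validate and draw correctly", {
  expect_error(dist_spec("triangular", min = 2, mode = 1, max = 3), "triangular")
  expect_error(dist_spec("uniform", min = 3, max = 1), "min > max")
  expect_error(dist_spec("normal", mean = 0), "sd")

  set.seed(2)
  tri <- draw_dist(dist_spec("triangular", min = 1, mode = 2, max = 3), 20000)
  expect_true(all(tri >= 1 & tri <= 3))
  expect_equal(median(tri), 2, tolerance = 0.02)

  tn <- draw_dist(dist_spec("normal", mean = 0, sd = 1, lower = 0), 1000)
  expect_true(all(tn >= 0))

  expect_equal(draw_dist(dist_spec("point", value = 7), 3), c(7, 7, 7))
})

test_that("degenerate distributions reproduce the deterministic engine", {
  cw <- setNames(c(6.52, 175, 36.6, 1.57, 22.9, 0.05, 2.17), metals7)
  conc_specs <- lapply(cw, function(v) dist_spec("point", value = v))
  mc <- run_mc_risk(conc_specs, config = mc_config(n_trials = 5, seed = 1),
                    exposure_specs = list(adult_male = NULL,
                                          adult_female = NULL, child = NULL))
  det <- health_risk(cw)
  for (pop in names(det)) {
    s <- mc$populations[[pop]]$summary
    expect_equal(s["HI", "mean"], det[[pop]]$hazard$HI, tolerance = 1e-14)
    expect_equal(s["TCR", "mean"], det[[pop]]$cancer$TCR, tolerance = 1e-14)
    expect_equal(unname(unlist(s[paste0("HQ_", metals7), "mean"])),
                 det[[pop]]$hazard$per_metal$hq, tolerance = 1e-14)
    expect_equal(unname(unlist(s[paste0("ILCR_", c("Cr", "Cd", "Pb")), "mean"])),
                 det[[pop]]$cancer$per_metal$ilcr, tolerance = 1e-14)
    expect_equal(s["HI", "sd"], 0)
    expect_equal(s["HI", "mean"], s["HI", "median"], tolerance = 1e-14)
  }
})

test_that("same seed gives bit-identical summaries", {
  specs <- list(Cr = fit_lognormal(rlnorm(50, 1, 1)))
  a <- run_mc_risk(specs, mc_config(500, seed = 77))
  b <- run_mc_risk(specs, mc_config(500, seed = 77))
  expect_identical(a$populations$child$summary, b$populations$child$summary)
})

test_that("simulated mean HQ matches the closed-form lognormal moment", {
  # only Cw random: HQ is a scaled lognormal with known mean
  p <- default_exposure()$adult_male
  tox <- default_toxicity()
  ml <- log(6); sl <- 0.8
  specs <- list(Cr = dist_spec("lognormal", meanlog = ml, sdlog = sl))
  mc <- run_mc_risk(specs, mc_config(10000, seed = 3),
                    exposure = list(adult_male = p),
                    exposure_specs = list(adult_male = NULL))
  pc <- default_permeability()["Cr"]
  scale_hq <- (1e-3 * p$IR * p$EF * p$ED / (p$BW * p$AT_nc)) /
    tox$rfd_oral[tox$metal == "Cr"] +
    (1e-3 * p$SA * pc * p$ET * p$EF * p$ED * p$CF / (p$BW * p$AT_nc)) /
    (tox$rfd_oral[tox$metal == "Cr"] * tox$abs_gi[tox$metal == "Cr"])
  analytic_mean <- scale_hq * exp(ml + sl^2 / 2)
  analytic_sd <- scale_hq * exp(ml + sl^2 / 2) * sqrt(exp(sl^2) - 1)
  got <- mc$populations$adult_male$summary["HQ_Cr", ]
  expect_lt(abs(got$mean - analytic_mean), 3 * analytic_sd / sqrt(10000))
})

test_that("exceedance probabilities", {
  expect_equal(exceedance(c(2, 3, 4), 1), 1)
  expect_equal(exceedance(c(2, 3, 4), 10), 0)
  set.seed(5)
  u <- runif(10000, 0, 2)
  expect_equal(exceedance(u, 1), 0.5, tolerance = 0.02)
  # p_exceed column uses the same definition
  specs <- list(Cr = dist_spec("point", value = 1e9))   # absurdly high
  mc <- run_mc_risk(specs, mc_config(10, seed = 1),
                    exposure = default_exposure()["child"],
                    exposure_specs = list(child = NULL))
  expect_equal(mc$populations$child$summary["HQ_Cr", "p_exceed"], 1)
})

test_that("CI width shrinks like 1/sqrt(n_trials)", {
  specs <- list(Cr = dist_spec("lognormal", meanlog = 1, sdlog = 0.6))
  width <- function(n, seed) {
    s <- run_mc_risk(specs, mc_config(n, seed = seed),
                     exposure = default_exposure()["adult_male"],
                     exposure_specs = list(adult_male = NULL)
                     )$populations$adult_male$summary["HQ_Cr", ]
    s$ci_hi - s$ci_lo
  }
  ratios <- vapply(1:3, function(s) width(1000, s) / width(10000, s + 100),
                   numeric(1))
  expect_true(all(ratios > 2 & ratios < 4.6))     # ideal sqrt(10) = 3.16
})

test_that("scaling the concentration distribution scales mean HQ (linear branch)", {
  base <- dist_spec("lognormal", meanlog = 1, sdlog = 0.5)
  scaled <- dist_spec("lognormal", meanlog = 1 + log(3), sdlog = 0.5)
  m1 <- run_mc_risk(list(Cr = base), mc_config(2000, seed = 9),
                    exposure = default_exposure()["child"],
                    exposure_specs = list(child = NULL))
  m3 <- run_mc_risk(list(Cr = scaled), mc_config(2000, seed = 9),
                    exposure = default_exposure()["child"],
                    exposure_specs = list(child = NULL))
  expect_equal(m3$populations$child$summary["HQ_Cr", "mean"],
               3 * m1$populations$child$summary["HQ_Cr", "mean"],
               tolerance = 1e-12)
})
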