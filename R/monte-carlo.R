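#' Distribution specification
#'
#' A small tagged container for the input distributions of the Monte Carlo
#' risk engine. Families: `point` (degenerate at `value`), `lognormal`
#' (`meanlog`, `sdlog`), `normal` (`mean`, `sd`), `uniform` (`min`,
#' `max`), `triangular` (`min`, `mode`, `max`). Optional truncation bounds
#' apply after sampling via inverse-CDF restriction (normal/lognormal) or
#' clipping of impossible bounds.
#'
#' @param family distribution family.
#' @param ... family parameters (see above).
#' @param lower,upper optional truncation bounds.
#' @return object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("point", "lognormal", "normal", "uniform",
                                 "triangular"),
                      ..., lower = NULL, upper = NULL) {
  family <- match.arg(family)
  pars <- list(...)
  need <- switch(family,
                 point = "value", lognormal = c("meanlog", "sdlog"),
                 normal = c("mean", "sd"), uniform = c("min", "max"),
                 triangular = c("min", "mode", "max"))
  miss <- setdiff(need, names(pars))
  if (length(miss)) {
    stop(sprintf("dist_spec(%s): missing parameter '%s'", family, miss[1]))
  }
  if (family == "uniform" && pars$min > pars$max) stop("min > max")
  if (family == "triangular" &&
      !(pars$min <= pars$mode && pars$mode <= pars$max)) {
    stop("triangular requires min <= mode <= max")
  }
  if (!is.null(lower) && !is.null(upper) && lower > upper) {
    stop("truncation bounds out of order")
  }
  structure(list(family = family, pars = pars, lower = lower, upper = upper),
            class = "dist_spec")
}

# inverse CDF of the triangular distribution
qtri <- function(p, min, mode, max) {
  fc <- if (max > min) (mode - min) / (max - min) else 0
  ifelse(p < fc,
         min + sqrt(p * (max - min) * (mode - min)),
         max - sqrt((1 - p) * (max - min) * (max - mode)))
}

#' Draw from a distribution spec
#'
#' Sampling uses the current RNG stream (set the seed once per run).
#' Truncated normal/lognormal draws use inverse-CDF restriction so the
#' draw count per input is fixed and the run's draw order is stable.
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$pars
  x <- switch(spec$family,
    point = rep(p$value, n),
    lognormal = {
      if (is.null(spec$lower) && is.null(spec$upper)) {
        rlnorm(n, p$meanlog, p$sdlog)
      } else {
        lo <- plnorm(spec$lower %||% 0, p$meanlog, p$sdlog)
        hi <- plnorm(spec$upper %||% Inf, p$meanlog, p$sdlog)
        stats::qlnorm(lo + runif(n) * (hi - lo), p$meanlog, p$sdlog)
      }
    },
    normal = {
      if (is.null(spec$lower) && is.null(spec$upper)) {
        rnorm(n, p$mean, p$sd)
      } else {
        lo <- stats::pnorm(spec$lower %||% -Inf, p$mean, p$sd)
        hi <- stats::pnorm(spec$upper %||% Inf, p$mean, p$sd)
        qnorm(lo + runif(n) * (hi - lo), p$mean, p$sd)
      }
    },
    uniform = runif(n, p$min, p$max),
    triangular = qtri(runif(n), p$min, p$mode, p$max))
  x
}

#' Fit a lognormal distribution by maximum likelihood
#'
#' `meanlog` is the mean of the logs; `sdlog` the ML (1/n) standard
#' deviation of the logs. A one-sample Kolmogorov-Smirnov statistic
#' against the fitted distribution is reported as a goodness-of-fit
#' indicator (it is not an honest p-value since parameters are estimated).
#' Constant samples return `sdlog = 0` (a degenerate spec).
#'
#' @param values strictly positive sample.
#' @return a [dist_spec()] with attributes `ks_stat` and `ks_p`.
#' @export
fit_lognormal <- function(values) {
  if (any(values <= 0)) stop("lognormal fit requires strictly positive values")
  lx <- log(values)
  ml <- mean(lx)
  sl <- sqrt(mean((lx - ml)^2))
  spec <- dist_spec("lognormal", meanlog = ml, sdlog = sl)
  if (sl > 0) {
    ks <- suppressWarnings(ks.test(values, "plnorm", ml, sl))
    attr(spec, "ks_stat") <- unname(ks$statistic)
    attr(spec, "ks_p") <- ks$p.value
  } else {
    attr(spec, "ks_stat") <- NA_real_
    attr(spec, "ks_p") <- NA_real_
  }
  spec
}

#' Monte Carlo configuration
#'
#' @param n_trials number of random trials (default 10000).
#' @param seed RNG seed for the run's single shared stream.
#' @param conf_level confidence level (percent) for the CI of the mean
#'   (default 95).
#' @return object of class `mc_config`.
#' @export
mc_config <- function(n_trials = 10000, seed = 1L, conf_level = 95) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (conf_level <= 0 || conf_level >= 100) stop("conf_level in (0, 100)")
  structure(list(n_trials = as.integer(n_trials), seed = as.integer(seed),
                 conf_level = conf_level), class = "mc_config")
}

#' Default exposure-parameter distributions
#'
#' Turns one population's point parameters into the conventional random
#' inputs of a probabilistic drinking-water assessment: IR triangular
#' (0.5x, 1x, 1.5x the point value), EF triangular (180, 365, 365
#' days/year), ED normal (mean ED, sd 20%, truncated at 0.2x-2x), BW
#' normal (mean BW, sd 15%, truncated at half/double). SA, ET, CF stay
#' fixed. Replace any entry to match a study-specific appendix table.
#'
#' @param params one population's parameter list.
#' @return named list of [dist_spec()] / point values.
#' @export
mc_exposure_specs <- function(params) {
  list(IR = dist_spec("triangular", min = 0.5 * params$IR, mode = params$IR,
                      max = 1.5 * params$IR),
       EF = dist_spec("triangular", min = 180, mode = 365, max = 365),
       ED = dist_spec("normal", mean = params$ED, sd = 0.2 * params$ED,
                      lower = 0.2 * params$ED, upper = 2 * params$ED),
       BW = dist_spec("normal", mean = params$BW, sd = 0.15 * params$BW,
                      lower = 0.5 * params$BW, upper = 2 * params$BW))
}

# summary block for one vector of draws
mc_summarize <- function(x, conf_level, threshold) {
  n <- length(x)
  mu <- mean(x)
  s <- sd(x)
  z <- qnorm(1 - (1 - conf_level / 100) / 2)
  se <- s / sqrt(n)
  c(mean = mu, median = median(x), sd = s,
    ci_lo = mu - z * se, ci_hi = mu + z * se,
    p5 = unname(quantile(x, 0.05)), p95 = unname(quantile(x, 0.95)),
    p_exceed = mean(x > threshold))
}

#' Monte Carlo probabilistic risk simulation
#'
#' Runs `n_trials` independent draws of the dose-response chain for every
#' population: per-metal concentration draws from `conc_specs` (ug/L),
#' exposure draws from per-population specs, then HQ/HI and ILCR/TCR per
#' draw via the same formulas as the deterministic engine (drawn ED also
#' drives the non-carcinogenic averaging time `AT_nc = ED * 365`;
#' carcinogenic AT stays at the lifetime value). One shared RNG stream
#' seeded once; the draw order is: per metal Cw, then per population IR,
#' EF, ED, BW.
#'
#' @param conc_specs named list of [dist_spec()] per metal (e.g. from
#'   [fit_lognormal()] on each column).
#' @param config an [mc_config()].
#' @param exposure populations list, see [default_exposure()].
#' @param exposure_specs optional per-population named lists of
#'   [dist_spec()] overriding [mc_exposure_specs()]; `NULL` entries mean
#'   all-point (degenerate) exposure.
#' @param tox toxicity table.
#' @param pc per-metal permeability.
#' @param keep_draws keep the raw per-draw HI/TCR/HQ/ILCR matrices.
#' @return object of class `mc_risk_summary`: per population a summary
#'   data.frame (rows `HQ_<metal>`, `HI`, `ILCR_<metal>`, `TCR`; columns
#'   mean, median, sd, ci_lo, ci_hi, p5, p95, p_exceed with thresholds 1
#'   for HQ/HI, 1e-6 for ILCR, 1e-4 for TCR) and optionally `draws`.
#' @export
run_mc_risk <- function(conc_specs, config = mc_config(),
                        exposure = default_exposure(),
                        exposure_specs = lapply(exposure, mc_exposure_specs),
                        tox = default_toxicity(),
                        pc = default_permeability(),
                        keep_draws = TRUE) {
  stopifnot(inherits(config, "mc_config"))
  metals <- names(conc_specs)
  if (is.null(metals)) stop("conc_specs must be a named list (metals)")
  tx <- tox_lookup(tox, metals)
  pcv <- if (length(pc) == 1) rep(pc, length(metals)) else pc[metals]
  n <- config$n_trials
  set.seed(config$seed)
  cw <- sapply(metals, function(m) draw_dist(conc_specs[[m]], n))
  cw <- matrix(cw, n, length(metals), dimnames = list(NULL, metals))
  out <- list()
  for (popname in names(exposure)) {
    p0 <- exposure[[popname]]
    es <- exposure_specs[[popname]]
    dr <- function(name) {
      if (!is.null(es) && !is.null(es[[name]])) draw_dist(es[[name]], n)
      else rep(p0[[name]], n)
    }
    IR <- dr("IR"); EF <- dr("EF"); ED <- dr("ED"); BW <- dr("BW")
    at_nc <- ED * 365
    at_ca <- rep(p0$AT_ca, n)
    # doses: trials x metals; operation order mirrors add_oral()/add_dermal()
    # exactly so point-mass inputs reproduce the deterministic engine
    oral_nc <- (cw * 1e-3) * IR * EF * ED / (BW * at_nc)
    derm_nc <- sweep((cw * 1e-3) * p0$SA, 2, pcv, "*") * p0$ET * EF * ED *
      p0$CF / (BW * at_nc)
    hq <- sweep(oral_nc, 2, tx$rfd_oral, "/") +
      sweep(derm_nc, 2, tx$rfd_oral * tx$abs_gi, "/")
    hi <- rowSums(hq)
    carc <- which(tx$carcinogen)
    rows <- rbind(
      t(apply(hq, 2, mc_summarize, conf_level = config$conf_level,
              threshold = 1)),
      HI = mc_summarize(hi, config$conf_level, 1))
    ilcr <- NULL
    if (length(carc)) {
      cwc <- cw[, carc, drop = FALSE]
      oral_ca <- (cwc * 1e-3) * IR * EF * ED / (BW * at_ca)
      derm_ca <- sweep((cwc * 1e-3) * p0$SA, 2, pcv[carc], "*") * p0$ET * EF *
        ED * p0$CF / (BW * at_ca)
      ilcr <- pmin(ilcr_from_dose(oral_ca, rep(tx$csf[carc], each = n)) +
                     ilcr_from_dose(derm_ca, rep(tx$csf[carc] / tx$abs_gi[carc],
                                                 each = n)), 1)
      tcr <- rowSums(ilcr)
      rows <- rbind(
        rows,
        t(apply(ilcr, 2, mc_summarize, conf_level = config$conf_level,
                threshold = 1e-6)),
        TCR = mc_summarize(tcr, config$conf_level, 1e-4))
    }
    rownames(rows) <- c(paste0("HQ_", metals), "HI",
                        if (length(carc)) c(paste0("ILCR_", metals[carc]),
                                            "TCR"))
    popres <- list(summary = as.data.frame(rows))
    if (keep_draws) {
      popres$draws <- list(hq = hq, hi = hi)
      if (length(carc)) {
        colnames(ilcr) <- metals[carc]
        popres$draws$ilcr <- ilcr
        popres$draws$tcr <- tcr
      }
    }
    out[[popname]] <- popres
  }
  structure(list(populations = out, config = config, metals = metals),
            class = "mc_risk_summary")
}

#' Exceedance probability
#'
#' Fraction of draws strictly above a threshold.
#'
#' @param draws numeric vector of simulated values.
#' @param threshold cutoff.
#' @return probability in \[0, 1\].
#' @export
exceedance <- function(draws, threshold) {
  mean(draws > threshold)
}
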