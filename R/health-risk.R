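#' Default exposure parameters
#'
#' Drinking-water exposure parameters for the three populations used by the
#' deterministic and Monte Carlo risk engines. Values are conventional
#' USEPA/Chinese-HRA defaults (Appendix-style tables vary by study; every
#' value is overridable through the config or by editing the returned
#' list):
#' IR ingestion rate (L/day), EF exposure frequency (days/year), ED
#' exposure duration (years), BW body weight (kg), SA skin surface area
#' (cm^2), ET bathing/shower exposure time (h/day), CF volumetric
#' conversion (L/cm^3). Averaging time is ED * 365 days for
#' non-carcinogenic risk and 70 * 365 days (lifetime) for carcinogenic
#' risk.
#'
#' @return named list of populations, each a parameter list.
#' @export
default_exposure <- function() {
  list(
    adult_male = list(IR = 2.0, EF = 365, ED = 30, BW = 70,
                      SA = 18000, ET = 0.58, CF = 1e-3,
                      AT_nc = 30 * 365, AT_ca = 70 * 365),
    adult_female = list(IR = 1.8, EF = 365, ED = 30, BW = 60,
                        SA = 16000, ET = 0.58, CF = 1e-3,
                        AT_nc = 30 * 365, AT_ca = 70 * 365),
    child = list(IR = 1.0, EF = 365, ED = 6, BW = 15,
                 SA = 6600, ET = 1.0, CF = 1e-3,
                 AT_nc = 6 * 365, AT_ca = 70 * 365))
}

#' Default dermal permeability coefficients (cm/h)
#'
#' Per-metal Kp values from the usual dermal-assessment tabulations.
#'
#' @return named numeric vector.
#' @export
default_permeability <- function() {
  c(Cr = 2e-3, Mn = 1e-3, Fe = 1e-3, Cu = 1e-3, Zn = 6e-4,
    Cd = 1e-3, Pb = 1e-4)
}

#' Default toxicity table
#'
#' Oral reference doses RfD (mg/kg/day), gastrointestinal absorption
#' fractions ABS_gi (dermal RfD = oral RfD x ABS_gi; dermal CSF = oral
#' CSF / ABS_gi), cancer slope factors CSF ((mg/kg/day)^-1) for the
#' carcinogens Cr, Cd, Pb, and the carcinogen flag. HQ is computed for all
#' seven metals; ILCR only for the three carcinogens.
#'
#' @return data.frame with one row per metal.
#' @export
default_toxicity <- function() {
  data.frame(
    metal = HM_METALS,
    rfd_oral = c(Cr = 3e-3, Mn = 2.4e-2, Fe = 0.7, Cu = 4e-2, Zn = 0.3,
                 Cd = 5e-4, Pb = 1.4e-3),
    abs_gi = c(Cr = 0.025, Mn = 0.04, Fe = 1, Cu = 1, Zn = 1,
               Cd = 0.025, Pb = 1),
    csf = c(Cr = 0.5, Mn = NA, Fe = NA, Cu = NA, Zn = NA,
            Cd = 6.1, Pb = 8.5e-3),
    carcinogen = HM_METALS %in% c("Cr", "Cd", "Pb"),
    row.names = NULL)
}

check_params <- function(p) {
  need <- c("IR", "EF", "ED", "BW", "SA", "ET", "CF", "AT_nc", "AT_ca")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop(sprintf("exposure parameter '%s' missing", miss[1]))
  if (p$BW <= 0) stop("BW must be > 0")
  if (p$AT_nc <= 0 || p$AT_ca <= 0) stop("AT must be > 0")
  invisible(p)
}

#' Average daily dose by ingestion
#'
#' `ADD_oral = (Cw/1000) * IR * EF * ED / (BW * AT)` in mg/kg/day; the
#' factor 1/1000 converts the ug/L input concentration to mg/L.
#'
#' @param cw concentration in ug/L (vectorized).
#' @param params one population's parameter list (see [default_exposure()]).
#' @param at averaging time in days; defaults to the non-carcinogenic
#'   `params$AT_nc`, pass `params$AT_ca` for cancer doses.
#' @return dose in mg/kg/day.
#' @export
add_oral <- function(cw, params, at = params$AT_nc) {
  check_params(params)
  if (any(cw < 0)) stop("concentration must be >= 0")
  (cw * 1e-3) * params$IR * params$EF * params$ED / (params$BW * at)
}

#' Average daily dose by dermal contact
#'
#' `ADD_dermal = (Cw/1000) * SA * PC * ET * EF * ED * CF / (BW * AT)` in
#' mg/kg/day; SA (cm^2) x PC (cm/h) x ET (h/day) x CF (L/cm^3) gives the
#' effective dermal water intake in L/day.
#'
#' @inheritParams add_oral
#' @param pc dermal permeability coefficient, cm/h (scalar or per-metal).
#' @return dose in mg/kg/day.
#' @export
add_dermal <- function(cw, params, pc, at = params$AT_nc) {
  check_params(params)
  if (any(cw < 0)) stop("concentration must be >= 0")
  (cw * 1e-3) * params$SA * pc * params$ET * params$EF * params$ED *
    params$CF / (params$BW * at)
}

tox_lookup <- function(tox, metals) {
  idx <- match(metals, tox$metal)
  if (anyNA(idx)) {
    stop(sprintf("no toxicity entry for metal '%s'", metals[which(is.na(idx))[1]]))
  }
  tox[idx, , drop = FALSE]
}

#' Non-carcinogenic hazard for one population
#'
#' HQ per metal and route (`HQ = ADD / RfD`, dermal RfD = oral RfD x
#' ABS_gi) and the hazard index `HI = sum HQ` over all metals and both
#' routes. HI < 1 is considered safe; HI > 1 severe.
#'
#' @param cw named concentration vector, ug/L (typically the survey means).
#' @param params one population's exposure parameter list.
#' @param tox toxicity table as in [default_toxicity()].
#' @param pc per-metal dermal permeability, cm/h.
#' @return list of class `risk_result` (non-carcinogenic part): per-metal
#'   data.frame plus `HI` and `class`.
#' @export
hazard <- function(cw, params, tox = default_toxicity(),
                   pc = default_permeability()) {
  metals <- names(cw)
  tx <- tox_lookup(tox, metals)
  if (anyNA(tx$rfd_oral)) {
    stop(sprintf("missing oral RfD for metal '%s'",
                 metals[which(is.na(tx$rfd_oral))[1]]))
  }
  pcv <- if (length(pc) == 1) rep(pc, length(cw)) else pc[metals]
  ao <- add_oral(cw, params)
  ad <- add_dermal(cw, params, pcv)
  hq_o <- ao / tx$rfd_oral
  hq_d <- ad / (tx$rfd_oral * tx$abs_gi)
  hq <- hq_o + hq_d
  hi <- sum(hq)
  structure(list(
    per_metal = data.frame(metal = metals, add_oral = ao, add_dermal = ad,
                           hq_oral = hq_o, hq_dermal = hq_d, hq = hq,
                           row.names = NULL),
    HI = hi,
    class = if (hi < 1) "safe" else "severe"),
    class = "risk_result")
}

# scalar/vector ILCR with the linear/exponential branch switch at 0.01
ilcr_from_dose <- function(add, csf) {
  x <- add * csf
  ifelse(x <= 0.01, x, 1 - exp(-x))
}

#' Carcinogenic risk for one population
#'
#' ILCR per carcinogen (Cr, Cd, Pb): `ADD * CSF` on the linear branch
#' (product <= 0.01) and `1 - exp(-ADD * CSF)` beyond it, computed per
#' route (dermal CSF = oral CSF / ABS_gi) with the lifetime averaging time
#' `AT_ca`, summed over routes and clamped at 1. `TCR = sum ILCR`; bands:
#' negligible < 1e-6, acceptable 1e-6 to 1e-4, unacceptable > 1e-4.
#'
#' @inheritParams hazard
#' @return list of class `risk_result` (carcinogenic part): per-metal
#'   data.frame plus `TCR` and `class`.
#' @export
cancer_risk <- function(cw, params, tox = default_toxicity(),
                        pc = default_permeability()) {
  metals <- names(cw)
  tx <- tox_lookup(tox, metals)
  carc <- which(tx$carcinogen)
  if (!length(carc)) stop("no carcinogenic metals in input")
  if (anyNA(tx$csf[carc])) {
    stop(sprintf("missing CSF for metal '%s'",
                 metals[carc[which(is.na(tx$csf[carc]))[1]]]))
  }
  pcv <- if (length(pc) == 1) rep(pc, length(cw)) else pc[metals]
  mets <- metals[carc]
  ao <- add_oral(cw[carc], params, at = params$AT_ca)
  ad <- add_dermal(cw[carc], params, pcv[carc], at = params$AT_ca)
  r_o <- ilcr_from_dose(ao, tx$csf[carc])
  r_d <- ilcr_from_dose(ad, tx$csf[carc] / tx$abs_gi[carc])
  ilcr <- pmin(r_o + r_d, 1)
  tcr <- sum(ilcr)
  structure(list(
    per_metal = data.frame(metal = mets, add_oral = ao, add_dermal = ad,
                           ilcr_oral = r_o, ilcr_dermal = r_d, ilcr = ilcr,
                           row.names = NULL),
    TCR = tcr,
    class = classify_tcr(tcr)),
    class = "risk_result")
}

classify_tcr <- function(x) {
  ifelse(x < 1e-6, "negligible", ifelse(x <= 1e-4, "acceptable",
                                        "unacceptable"))
}

#' Deterministic risk assessment of a concentration table
#'
#' Runs [hazard()] and [cancer_risk()] for every population, either on the
#' per-metal mean concentrations (`mode = "mean"`, the usual reporting
#' convention) or site by site (`mode = "per_site"`).
#'
#' @param table a [concentration_table()] (or a named concentration
#'   vector, ug/L).
#' @param exposure populations list, see [default_exposure()].
#' @param tox toxicity table, see [default_toxicity()].
#' @param pc per-metal permeability, see [default_permeability()].
#' @param mode `"mean"` or `"per_site"`.
#' @return for `"mean"`: named list per population with `hazard` and
#'   `cancer` `risk_result`s. For `"per_site"`: per population a
#'   data.frame of site-level HI and TCR.
#' @export
health_risk <- function(table, exposure = default_exposure(),
                        tox = default_toxicity(),
                        pc = default_permeability(),
                        mode = c("mean", "per_site")) {
  mode <- match.arg(mode)
  if (inherits(table, "conc_table")) {
    vals <- table$values
  } else {
    vals <- matrix(table, 1, dimnames = list(NULL, names(table)))
  }
  if (mode == "mean") {
    cw <- colMeans(vals)
    lapply(exposure, function(p) {
      list(hazard = hazard(cw, p, tox, pc),
           cancer = cancer_risk(cw, p, tox, pc))
    })
  } else {
    lapply(exposure, function(p) {
      hi <- apply(vals, 1, function(cw) hazard(cw, p, tox, pc)$HI)
      tcr <- apply(vals, 1, function(cw) cancer_risk(cw, p, tox, pc)$TCR)
      data.frame(site = rownames(vals) %||% seq_len(nrow(vals)),
                 HI = hi, TCR = tcr, row.names = NULL)
    })
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
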