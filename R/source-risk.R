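#' Apportion health risk to pollution sources
#'
#' Couples the receptor model to the risk engine: source k's
#' non-carcinogenic risk for a population is `sum_m HQ_m * share_km / 100`
#' over the metals, and likewise for ILCR over the carcinogens; i.e. each
#' metal's (mean) risk is split in proportion to its source-contribution
#' percentages. The per-metal unapportioned share (intercept/negative-term
#' remainder) accumulates into an `unapportioned` row, so attributed risks
#' plus the remainder conserve the total HI (or TCR) exactly. Percent
#' shares are normalized over the sources only, matching the usual
#' reporting convention.
#'
#' @param risk mean-mode result of [health_risk()] (named list per
#'   population with `hazard` and `cancer`), or a single population's
#'   list.
#' @param contribs a [metal_source_contributions()] result.
#' @return object of class `source_risk_table`: long data.frame
#'   (`population`, `risk_type`, `source`, `absolute`, `percent`), plus
#'   `per_metal` breakdown matrices.
#' @export
apportion_risk <- function(risk, contribs) {
  stopifnot(inherits(contribs, "source_contributions"))
  if (!is.null(risk$hazard)) risk <- list(population = risk)
  shares <- contribs$per_metal_percent          # sources x metals
  unapp <- contribs$unapportioned_percent
  sources <- rownames(shares)
  rows <- list()
  per_metal <- list()
  for (popname in names(risk)) {
    for (rtype in c("non_carcinogenic", "carcinogenic")) {
      part <- if (rtype == "non_carcinogenic") {
        setNames(risk[[popname]]$hazard$per_metal$hq,
                 risk[[popname]]$hazard$per_metal$metal)
      } else {
        setNames(risk[[popname]]$cancer$per_metal$ilcr,
                 risk[[popname]]$cancer$per_metal$metal)
      }
      mets <- names(part)
      miss <- setdiff(mets, colnames(shares))
      if (length(miss)) {
        stop(sprintf("no source contribution for metal '%s'", miss[1]))
      }
      sh <- shares[, mets, drop = FALSE]
      attributed <- drop(sh %*% part) / 100       # per source
      rem <- sum(unapp[mets] * part) / 100
      tot_src <- sum(attributed)
      pct <- if (tot_src > 0) attributed / tot_src * 100 else
        rep(undefined_marker(), length(attributed))
      rows[[length(rows) + 1]] <- data.frame(
        population = popname, risk_type = rtype,
        source = c(sources, "unapportioned"),
        absolute = c(attributed, rem),
        percent = c(pct, NA_real_), row.names = NULL)
      per_metal[[paste(popname, rtype, sep = ".")]] <-
        sweep(sh, 2, part, "*") / 100
    }
  }
  structure(list(table = do.call(rbind, rows), per_metal = per_metal,
                 sources = sources),
            class = "source_risk_table")
}

#' Priority ranking of metals and sources
#'
#' Ranks metals by their percent contribution to HI and to TCR, and
#' sources by total attributed risk, for each population; the top entries
#' are the priority-control candidates.
#'
#' @param risk mean-mode result of [health_risk()].
#' @param source_table optional [apportion_risk()] result for the source
#'   ranking.
#' @return list per population with `metal_hi` and `metal_tcr` data.frames
#'   (sorted, with `percent`), and `sources` when available.
#' @export
priority_ranking <- function(risk, source_table = NULL) {
  if (!is.null(risk$hazard)) risk <- list(population = risk)
  out <- list()
  for (popname in names(risk)) {
    hz <- risk[[popname]]$hazard$per_metal
    hi <- sum(hz$hq)
    mh <- data.frame(metal = hz$metal, value = hz$hq,
                     percent = if (hi > 0) hz$hq / hi * 100 else NA_real_)
    mh <- mh[order(-mh$value), ]
    ca <- risk[[popname]]$cancer$per_metal
    tcr <- sum(ca$ilcr)
    mc <- data.frame(metal = ca$metal, value = ca$ilcr,
                     percent = if (tcr > 0) ca$ilcr / tcr * 100 else NA_real_)
    mc <- mc[order(-mc$value), ]
    entry <- list(metal_hi = `rownames<-`(mh, NULL),
                  metal_tcr = `rownames<-`(mc, NULL))
    if (!is.null(source_table)) {
      tab <- source_table$table
      tab <- tab[tab$population == popname & tab$source != "unapportioned", ]
      agg <- stats::aggregate(absolute ~ source, tab, sum)
      entry$sources <- agg[order(-agg$absolute), ]
    }
    out[[popname]] <- entry
  }
  out
}
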