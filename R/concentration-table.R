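#' Concentration tables
#'
#' A `conc_table` holds a sites x metals matrix of dissolved-metal
#' concentrations in ug/L, together with site identifiers and an optional
#' censoring mask for values reported below the analytical detection limit.
#' All downstream stages (indices, receptor model, risk engine) consume this
#' container; ug/L is the single internal unit and every formula that needs
#' mg/L converts explicitly.
#'
#' @param values numeric matrix or data.frame, sites in rows, metals in
#'   columns (column names are the metal symbols).
#' @param site_ids character vector of site identifiers; defaults to
#'   `S1..Sn`.
#' @param metals metal names; defaults to `colnames(values)`.
#' @param censored optional logical matrix (same shape as `values`) flagging
#'   entries that were below the detection limit.
#' @param detection_limits optional numeric matrix of detection limits for
#'   censored entries (NA elsewhere).
#' @param unit `"ug/L"` (default) or `"mg/L"`; mg/L input is converted to
#'   ug/L by multiplying by exactly 1000.
#' @return an object of class `conc_table`.
#' @export
concentration_table <- function(values, site_ids = NULL, metals = NULL,
                                censored = NULL, detection_limits = NULL,
                                unit = c("ug/L", "mg/L")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(metals)) metals <- colnames(values)
  if (is.null(metals)) stop("metal names are required (column names)")
  metals <- as.character(metals)
  if (anyDuplicated(metals)) stop("metal names must be unique")
  if (ncol(values) != length(metals)) stop("values/metals dimension mismatch")
  if (is.null(site_ids)) site_ids <- paste0("S", seq_len(nrow(values)))
  site_ids <- as.character(site_ids)
  if (length(site_ids) != nrow(values)) stop("site_ids length mismatch")
  if (unit == "mg/L") values <- values * 1000
  dimnames(values) <- list(site_ids, metals)

  bad <- which(values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative concentration at site '%s', metal '%s'",
                 site_ids[bad[1, 1]], metals[bad[1, 2]]))
  }
  all_na <- colSums(!is.na(values)) == 0
  if (any(all_na)) {
    stop(sprintf("metal column '%s' is entirely missing",
                 metals[which(all_na)[1]]))
  }
  if (is.null(censored)) {
    censored <- matrix(FALSE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  } else {
    censored <- as.matrix(censored)
    dimnames(censored) <- dimnames(values)
  }
  if (is.null(detection_limits)) {
    detection_limits <- matrix(NA_real_, nrow(values), ncol(values),
                               dimnames = dimnames(values))
  } else {
    detection_limits <- as.matrix(detection_limits)
    dimnames(detection_limits) <- dimnames(values)
  }
  structure(list(values = values, site_ids = site_ids, metals = metals,
                 censored = censored, detection_limits = detection_limits),
            class = "conc_table")
}

#' @export
print.conc_table <- function(x, ...) {
  cat(sprintf("<conc_table> %d sites x %d metals (ug/L)\n",
              nrow(x$values), ncol(x$values)))
  cat("metals:", paste(x$metals, collapse = ", "), "\n")
  if (any(x$censored)) {
    cat(sprintf("censored entries: %d\n", sum(x$censored)))
  }
  print(utils::head(x$values, 4))
  if (nrow(x$values) > 4) cat("...\n")
  invisible(x)
}

#' @export
dim.conc_table <- function(x) dim(x$values)

# format a double so that read-back reproduces the identical bit pattern
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
}

#' Read a concentration table from CSV
#'
#' Expects an RFC-4180 CSV with a header row naming the metals and an
#' optional leading site-identifier column (`site`, `site_id` or `id`).
#' Cells of the form `<x` (e.g. `"<0.01"`) are treated as below the
#' detection limit `x` and substituted according to `censored_policy`:
#' half the limit (default), zero, or the full limit. A leading comment
#' line starting with `#` (the schema tag emitted by
#' [write_concentration_table()]) is ignored.
#'
#' @param path CSV file path.
#' @param unit input unit, `"ug/L"` (default) or `"mg/L"`.
#' @param censored_policy substitution rule for `<DL` cells: `"half"`,
#'   `"zero"` or `"full"`.
#' @return a [concentration_table()].
#' @export
read_concentration_table <- function(path, unit = c("ug/L", "mg/L"),
                                     censored_policy = c("half", "zero", "full")) {
  unit <- match.arg(unit)
  censored_policy <- match.arg(censored_policy)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 comment.char = "#", strip.white = TRUE)
  if (!nrow(df)) stop("empty concentration table")
  cols <- names(df)
  site_ids <- NULL
  if (tolower(cols[1]) %in% c("site", "site_id", "id")) {
    site_ids <- df[[1]]
    df <- df[, -1, drop = FALSE]
    cols <- names(df)
  }
  n <- nrow(df); m <- ncol(df)
  values <- matrix(NA_real_, n, m)
  censored <- matrix(FALSE, n, m)
  dl <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      cell <- df[i, j]
      if (is.na(cell) || cell == "" || toupper(cell) == "NA") next
      if (startsWith(cell, "<")) {
        lim <- suppressWarnings(as.numeric(substring(cell, 2)))
        if (is.na(lim)) {
          stop(sprintf("unparseable cell '%s' at row %d, column '%s'",
                       cell, i, cols[j]))
        }
        censored[i, j] <- TRUE
        dl[i, j] <- lim
        values[i, j] <- switch(censored_policy,
                               half = lim / 2, zero = 0, full = lim)
      } else {
        v <- suppressWarnings(as.numeric(cell))
        if (is.na(v)) {
          stop(sprintf("unparseable cell '%s' at row %d, column '%s'",
                       cell, i, cols[j]))
        }
        if (v < 0) {
          stop(sprintf("negative value %s at row %d, column '%s'",
                       cell, i, cols[j]))
        }
        values[i, j] <- v
      }
    }
  }
  concentration_table(values, site_ids = site_ids, metals = cols,
                      censored = censored, detection_limits = dl,
                      unit = unit)
}

#' Write a concentration table to CSV
#'
#' Emits a schema comment line, then an RFC-4180 table with a `site_id`
#' column. Censored entries are written back as `<DL` tokens so a
#' read/write cycle under the same substitution policy is lossless;
#' uncensored numeric values are formatted so the read-back double is
#' bit-identical.
#'
#' @param table a [concentration_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(table, path) {
  stopifnot(inherits(table, "conc_table"))
  v <- table$values
  out <- matrix("", nrow(v), ncol(v))
  for (j in seq_len(ncol(v))) out[, j] <- fmt_num(v[, j])
  cen <- which(table$censored, arr.ind = TRUE)
  if (nrow(cen)) {
    out[cen] <- paste0("<", fmt_num(table$detection_limits[cen]))
  }
  df <- data.frame(site_id = table$site_ids, out, check.names = FALSE)
  names(df) <- c("site_id", table$metals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# schema: gwhm-conc-1", con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# adjusted Fisher-Pearson (sample-size-corrected) skewness
skewness_stat <- function(x, estimator = c("adjusted", "moment")) {
  estimator <- match.arg(estimator)
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0 || n < 3) return(undefined_marker())
  g1 <- mean((x - m)^3) / m2^1.5
  if (estimator == "moment") return(g1)
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# excess kurtosis; "adjusted" is the usual sample-corrected G2 (normal -> 0)
kurtosis_stat <- function(x, estimator = c("adjusted", "moment")) {
  estimator <- match.arg(estimator)
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0 || n < 4) return(undefined_marker())
  g2 <- mean((x - m)^4) / m2^2 - 3
  if (estimator == "moment") return(g2)
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Descriptive statistics per metal
#'
#' Returns min, max, mean, sd, coefficient of variation (percent), skewness
#' and excess kurtosis for every metal column, in the table's metal order.
#' Skewness/kurtosis use the adjusted Fisher-Pearson (sample-size-corrected)
#' estimators by default; the excess convention makes a normal sample score
#' zero kurtosis. Constant columns report cv 0 and NA skewness/kurtosis.
#'
#' @param table a [concentration_table()].
#' @param estimator `"adjusted"` (default) or `"moment"` skewness/kurtosis.
#' @return a data.frame of class `descriptive_stats`, one row per metal.
#' @export
descriptive_stats <- function(table, estimator = c("adjusted", "moment")) {
  stopifnot(inherits(table, "conc_table"))
  estimator <- match.arg(estimator)
  if (nrow(table$values) < 2) stop("need at least 2 sites per metal")
  stats_one <- function(x) {
    x <- x[!is.na(x)]
    mu <- mean(x); s <- sd(x)
    cv <- if (mu > 0) 100 * s / mu else if (s == 0) 0 else undefined_marker()
    c(min = min(x), max = max(x), mean = mu, sd = s, cv_percent = cv,
      skewness = skewness_stat(x, estimator),
      kurtosis = kurtosis_stat(x, estimator))
  }
  res <- t(apply(table$values, 2, stats_one))
  out <- data.frame(metal = table$metals, res, row.names = NULL)
  class(out) <- c("descriptive_stats", "data.frame")
  out
}

#' Maximum/mean ratio per metal
#'
#' The max/mean ratio flags metals whose load is concentrated at a few
#' hotspot sites (a ratio near 1 means a spatially flat field). Undefined
#' (NA) when the mean is zero.
#'
#' @param stats a `descriptive_stats` data.frame (or anything with `metal`,
#'   `max` and `mean` columns).
#' @return named numeric vector of max/mean ratios.
#' @export
max_mean_ratios <- function(stats) {
  stopifnot(all(c("metal", "max", "mean") %in% names(stats)))
  r <- ifelse(stats$mean > 0, stats$max / stats$mean, undefined_marker())
  setNames(r, stats$metal)
}
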