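#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson r between metal columns with two-sided p-values from
#' the t distribution (`t = r * sqrt(n - 2) / sqrt(1 - r^2)`). Constant
#' columns yield NA in their row/column rather than an error.
#'
#' @param table a [concentration_table()].
#' @return object of class `correlation_summary` with elements `r`
#'   (metal x metal), `p` and `n`.
#' @export
pearson_matrix <- function(table) {
  stopifnot(inherits(table, "conc_table"))
  x <- table$values
  n <- nrow(x)
  if (n < 3) stop("need at least 3 sites")
  sds <- apply(x, 2, sd)
  r <- suppressWarnings(cor(x))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  structure(list(r = r, p = p, n = n), class = "correlation_summary")
}

corr_input <- function(corr) {
  if (inherits(corr, "correlation_summary")) corr$r else as.matrix(corr)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' KMO = sum of squared off-diagonal correlations divided by that sum plus
#' the sum of squared off-diagonal partial correlations (anti-image
#' correlations from the inverse correlation matrix). Values near 1 favour
#' a factor model; below 0.5 is usually considered marginal.
#'
#' @param corr a `correlation_summary` or a correlation matrix.
#' @return scalar in \[0, 1\].
#' @export
kmo_statistic <- function(corr) {
  R <- corr_input(corr)
  Ri <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; KMO undefined")
  })
  d <- 1 / sqrt(diag(Ri))
  Q <- -Ri * outer(d, d)       # partial correlations, diagonal = -1
  off <- row(R) != col(R)
  r2 <- sum(R[off]^2)
  q2 <- sum(Q[off]^2)
  r2 / (r2 + q2)
}

#' Bartlett's test of sphericity
#'
#' Tests H0: the correlation matrix is the identity.
#' `chi2 = -(n - 1 - (2m + 5)/6) * log det(R)` with `m(m-1)/2` degrees of
#' freedom.
#'
#' @param corr a `correlation_summary` or correlation matrix.
#' @param n_sites number of samples behind the correlation matrix (taken
#'   from the summary when available).
#' @return list with `chi2`, `dof`, `p`.
#' @export
bartlett_sphericity <- function(corr, n_sites = NULL) {
  R <- corr_input(corr)
  if (is.null(n_sites) && inherits(corr, "correlation_summary")) {
    n_sites <- corr$n
  }
  m <- ncol(R)
  if (is.null(n_sites) || n_sites <= m) stop("need n_sites > number of metals")
  dt <- determinant(R, logarithm = TRUE)
  if (dt$sign <= 0) stop("correlation matrix is not positive definite")
  chi2 <- -(n_sites - 1 - (2 * m + 5) / 6) * as.numeric(dt$modulus)
  dof <- m * (m - 1) / 2
  list(chi2 = chi2, dof = dof,
       p = pchisq(chi2, df = dof, lower.tail = FALSE))
}

# Kaiser-normalized pairwise varimax rotation.
# Returns the rotated loadings and rotation matrix; convergence by relative
# change of the varimax criterion, max_sweeps full sweeps.
varimax_pairwise <- function(A, normalize = TRUE, eps = 1e-6,
                             max_sweeps = 100) {
  p <- nrow(A); k <- ncol(A)
  if (k < 2) return(list(loadings = A, rotmat = diag(k)))
  h <- if (normalize) sqrt(rowSums(A^2)) else rep(1, p)
  h[h == 0] <- 1
  L <- A / h
  rot <- diag(k)
  crit <- function(L) sum(apply(L^2, 2, function(z) mean(z^2) - mean(z)^2))
  old <- crit(L)
  for (sweep_i in seq_len(max_sweeps)) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        x <- L[, i]; y <- L[, j]
        u <- x^2 - y^2; v <- 2 * x * y
        A1 <- sum(u); B1 <- sum(v)
        C1 <- sum(u^2 - v^2); D1 <- sum(2 * u * v)
        num <- D1 - 2 * A1 * B1 / p
        den <- C1 - (A1^2 - B1^2) / p
        phi <- atan2(num, den) / 4
        if (abs(phi) < 1e-12) next
        cs <- cos(phi); sn <- sin(phi)
        L[, i] <- cs * x + sn * y
        L[, j] <- -sn * x + cs * y
        ri <- rot[, i]; rj <- rot[, j]
        rot[, i] <- cs * ri + sn * rj
        rot[, j] <- -sn * ri + cs * rj
      }
    }
    new <- crit(L)
    if (new - old <= eps * max(old, .Machine$double.eps)) break
    old <- new
  }
  L <- L * h
  list(loadings = L, rotmat = rot)
}

#' Varimax-rotated PCA of a concentration table
#'
#' Standardizes each metal to z-scores, eigendecomposes the correlation
#' matrix, retains components (eigenvalue > 1 by default, or a fixed
#' count), and varimax-rotates the retained loadings (Kaiser row
#' normalization, pairwise rotations, relative tolerance 1e-6, up to 100
#' sweeps). Columns are sign-fixed (largest |loading| positive) and ordered
#' by post-rotation explained variance. Score coefficients use the
#' regression (least-squares) method `W = R^-1 L`.
#'
#' @param table a [concentration_table()].
#' @param retention `"kaiser"` (eigenvalue > 1) or `"fixed"`.
#' @param n_components retained count when `retention = "fixed"`.
#' @return object of class `pca_model`: rotated `loadings` (metals x
#'   components), `eigenvalues` (all), `explained_percent` and
#'   `cumulative_percent` (post-rotation), `score_coef`, `center`, `scale`.
#' @export
fit_pca_varimax <- function(table, retention = c("kaiser", "fixed"),
                            n_components = NULL) {
  stopifnot(inherits(table, "conc_table"))
  retention <- match.arg(retention)
  x <- table$values
  m <- ncol(x)
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  if (any(scale_ == 0)) stop("constant metal column; cannot standardize")
  R <- cor(x)
  eig <- eigen(R, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  p <- if (retention == "kaiser") sum(ev > 1) else as.integer(n_components)
  if (is.na(p) || p < 1) stop("retention rule yields < 1 component")
  if (p < 2) stop("need >= 2 retained components for varimax rotation")
  A <- eig$vectors[, seq_len(p), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(p)]), p)
  vr <- varimax_pairwise(A)
  L <- vr$loadings
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(p)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  ss <- ss[ord]
  dimnames(L) <- list(table$metals, paste0("F", seq_len(p)))
  W <- solve(R, L)                      # regression score coefficients
  dimnames(W) <- dimnames(L)
  structure(list(loadings = L, eigenvalues = eig$values,
                 explained_percent = ss / m * 100,
                 cumulative_percent = cumsum(ss / m * 100),
                 score_coef = W, center = center, scale = scale_,
                 metals = table$metals, n_components = p),
            class = "pca_model")
}

#' Absolute principal component scores
#'
#' Factor scores of each site minus the score of an artificial
#' zero-concentration sample (z-scored at `-mean/sd`), anchoring the score
#' origin at zero concentration so scores act as nonnegative-oriented
#' source activities in the downstream regression. The zero sample itself
#' scores exactly 0 in every component.
#'
#' @param model a [fit_pca_varimax()] model.
#' @param table the [concentration_table()] to score (same metal set).
#' @return site x component APCS matrix (class `apcs_matrix`).
#' @export
apcs <- function(model, table) {
  stopifnot(inherits(model, "pca_model"), inherits(table, "conc_table"))
  if (!identical(model$metals, table$metals)) {
    stop("metal set of table does not match the fitted model")
  }
  z <- sweep(sweep(table$values, 2, model$center), 2, model$scale, "/")
  scores <- z %*% model$score_coef
  z0 <- -model$center / model$scale
  score0 <- drop(z0 %*% model$score_coef)
  out <- sweep(scores, 2, score0)
  rownames(out) <- table$site_ids
  class(out) <- c("apcs_matrix", class(out))
  out
}

#' Per-metal regression on APCS columns
#'
#' Ordinary least squares of each metal's raw concentration (ug/L) on the
#' APCS columns: `C_n = xi0 + sum_k xi_k * APCS_k`. Reports coefficients,
#' R^2 and the predicted/measured mean ratio per metal.
#'
#' @param apcs an [apcs()] matrix.
#' @param table the same [concentration_table()].
#' @return object of class `source_regression` with `intercept`,
#'   `coefficients` (components x metals), `r_squared`,
#'   `pred_meas_ratio`, `fitted` (sites x metals).
#' @export
fit_mlr <- function(apcs, table) {
  stopifnot(inherits(table, "conc_table"))
  X <- unclass(apcs)
  n <- nrow(X); k <- ncol(X)
  if (n != nrow(table$values)) stop("APCS and table cover different sites")
  if (n < k + 2) stop("need sites >= components + 2")
  if (qr(cbind(1, X))$rank < k + 1) stop("collinear APCS columns")
  m <- length(table$metals)
  intercept <- setNames(numeric(m), table$metals)
  coefs <- matrix(0, k, m, dimnames = list(colnames(X), table$metals))
  r2 <- setNames(numeric(m), table$metals)
  ratio <- setNames(numeric(m), table$metals)
  fit <- matrix(0, n, m, dimnames = list(table$site_ids, table$metals))
  for (j in seq_len(m)) {
    y <- table$values[, j]
    mod <- lm(y ~ X)
    cf <- coef(mod)
    intercept[j] <- cf[1]
    coefs[, j] <- cf[-1]
    fit[, j] <- fitted(mod)
    ss_res <- sum((y - fit[, j])^2)
    ss_tot <- sum((y - mean(y))^2)
    r2[j] <- if (ss_tot > 0) 1 - ss_res / ss_tot else undefined_marker()
    ratio[j] <- if (mean(y) > 0) mean(fit[, j]) / mean(y) else undefined_marker()
  }
  structure(list(intercept = intercept, coefficients = coefs,
                 r_squared = r2, pred_meas_ratio = ratio, fitted = fit,
                 metals = table$metals),
            class = "source_regression")
}

#' Per-metal source contributions
#'
#' Source k's raw (signed) mean contribution to metal n is
#' `xi_kn * mean(APCS_k)`. Negative mean terms -- a known artifact of the
#' APCS/MLR construction -- are truncated to zero by default (`"truncate"`)
#' or replaced by their absolute value (`"absolute"`) before percentaging.
#' The denominator is the sum of the nonnegative source terms plus the
#' intercept when positive; the intercept share is reported as
#' unapportioned, so per-metal shares over sources plus the unapportioned
#' share sum to 100.
#'
#' @param reg a [fit_mlr()] regression.
#' @param apcs the matching [apcs()] matrix.
#' @param negative_policy `"truncate"` (default) or `"absolute"`.
#' @return object of class `source_contributions`: `per_metal_percent`
#'   (sources x metals), `unapportioned_percent`, `raw_ugL` (signed mean
#'   terms), `intercept_ugL`.
#' @export
metal_source_contributions <- function(reg, apcs,
                                       negative_policy = c("truncate", "absolute")) {
  stopifnot(inherits(reg, "source_regression"))
  negative_policy <- match.arg(negative_policy)
  mean_apcs <- colMeans(unclass(apcs))
  raw <- reg$coefficients * mean_apcs          # sources x metals, ug/L
  adj <- if (negative_policy == "truncate") pmax(raw, 0) else abs(raw)
  inter <- pmax(reg$intercept, 0)
  denom <- colSums(adj) + inter
  if (all(denom == 0)) stop("all-zero mean contributions; shares undefined")
  per_metal <- sweep(adj, 2, denom, "/") * 100
  per_metal[, denom == 0] <- undefined_marker()
  unapp <- 100 - colSums(per_metal)
  structure(list(per_metal_percent = per_metal,
                 unapportioned_percent = unapp,
                 raw_ugL = raw, intercept_ugL = reg$intercept,
                 negative_policy = negative_policy,
                 metals = reg$metals),
            class = "source_contributions")
}

#' Overall source contributions
#'
#' Aggregates per-metal shares into one percentage per source. By default
#' each metal counts equally: its source shares are renormalized over
#' sources (dropping the unapportioned part), averaged over metals, and
#' renormalized to 100. `weighting = "concentration"` weights metals by
#' their mean concentration instead (so high-load metals dominate).
#'
#' @param contribs a [metal_source_contributions()] result.
#' @param weighting `"equal"` (default) or `"concentration"`.
#' @param table required for `"concentration"` weighting.
#' @return named numeric vector of per-source percentages summing to 100.
#' @export
overall_source_contributions <- function(contribs,
                                         weighting = c("equal", "concentration"),
                                         table = NULL) {
  stopifnot(inherits(contribs, "source_contributions"))
  weighting <- match.arg(weighting)
  pm <- contribs$per_metal_percent
  src_sum <- colSums(pm)
  keep <- !is.na(src_sum) & src_sum > 0
  if (!any(keep)) stop("no metal has a defined source decomposition")
  src_only <- sweep(pm[, keep, drop = FALSE], 2, src_sum[keep], "/") * 100
  w <- if (weighting == "equal") {
    rep(1, sum(keep))
  } else {
    if (is.null(table)) stop("concentration weighting needs the table")
    colMeans(table$values)[contribs$metals][keep]
  }
  overall <- drop(src_only %*% (w / sum(w)))
  overall / sum(overall) * 100
}

#' Run the full receptor model
#'
#' Convenience wrapper chaining [pearson_matrix()], adequacy diagnostics,
#' [fit_pca_varimax()], [apcs()], [fit_mlr()],
#' [metal_source_contributions()] and [overall_source_contributions()].
#'
#' @inheritParams fit_pca_varimax
#' @inheritParams metal_source_contributions
#' @inheritParams overall_source_contributions
#' @return list with all intermediate objects (`correlation`, `kmo`,
#'   `bartlett`, `pca`, `apcs`, `regression`, `contributions`, `overall`).
#' @export
apportion <- function(table, retention = c("kaiser", "fixed"),
                      n_components = NULL,
                      negative_policy = c("truncate", "absolute"),
                      weighting = c("equal", "concentration")) {
  retention <- match.arg(retention)
  corr <- pearson_matrix(table)
  model <- fit_pca_varimax(table, retention, n_components)
  sc <- apcs(model, table)
  reg <- fit_mlr(sc, table)
  contribs <- metal_source_contributions(reg, sc, negative_policy)
  overall <- overall_source_contributions(contribs, weighting, table = table)
  list(correlation = corr,
       kmo = kmo_statistic(corr),
       bartlett = bartlett_sphericity(corr),
       pca = model, apcs = sc, regression = reg,
       contributions = contribs, overall = overall)
}
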