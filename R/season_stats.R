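#' Relative seasonal change of a diversity value
#'
#' `-1 * (1 - dry/wet)`: negative values indicate a decrease and
#' positive values an increase from the wet to the dry season; the value
#' is -1 when the dry-season assemblage scores 0 and 0 when the two
#' seasons are equal.
#'
#' @param wet wet-season value(s); must be strictly positive.
#' @param dry dry-season value(s), nonnegative.
#' @return Numeric vector of relative changes in \[-1, Inf).
#' @export
relative_change <- function(wet, dry) {
  if (any(wet <= 0)) stop("wet-season value must be > 0")
  if (any(dry < 0)) stop("dry-season value must be >= 0")
  -1 * (1 - dry / wet)
}

#' Paired comparison of observed versus null (or wet versus dry) values
#'
#' With `paired = TRUE` (default) this is the classical paired design:
#' a one-sample t test of the per-site differences `x - y` against zero,
#' with n - 1 degrees of freedom.  `paired = FALSE` gives the unpaired
#' two-sided Welch t test.  All tests are two-sided.
#'
#' @param x,y numeric vectors of equal length (per-site values; `y` is
#'   typically the per-site null mean).
#' @param paired paired design (default) or unpaired Welch.
#' @return Object of class `paired_test`: n, mean difference, t,
#'   df, two-sided p.
#' @export
paired_test <- function(x, y, paired = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs")
  if (paired) {
    d <- x - y
    if (sd(d) == 0)
      stop("zero variance of paired differences; t statistic undefined")
    ht <- t.test(d)
  } else {
    ht <- t.test(x, y, var.equal = FALSE)
  }
  structure(list(n = n, mean_diff = mean(x) - mean(y),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = ht$p.value,
                 paired = paired),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(if (x$paired) "Paired" else "Welch two-sample",
      " t test: t = ", signif(x$statistic, 4), ", df = ",
      signif(x$df, 4), ", p = ", signif(x$p.value, 4),
      " (mean difference ", signif(x$mean_diff, 4), ", n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' Standardised effect sizes of observed values against a null
#' distribution
#'
#' SES = (observed - null mean) / null SD, with the observed value's
#' quantile rank within the null distribution as a nonparametric
#' companion.
#'
#' @param observed per-site observed values.
#' @param null_matrix replicate-by-site (or site-list) null values:
#'   either a matrix with one column per site or a list of numeric
#'   vectors.
#' @return Data frame with ses and rank quantile per site.
#' @export
ses_values <- function(observed, null_matrix) {
  cols <- if (is.list(null_matrix)) null_matrix
          else asplit(null_matrix, 2)
  stopifnot(length(observed) == length(cols))
  out <- mapply(function(obs, nul) {
    nul <- nul[!is.na(nul)]
    s <- sd(nul)
    c(ses = if (length(nul) < 2 || s == 0) NA_real_ else (obs - mean(nul)) / s,
      rank_q = mean(nul < obs) + 0.5 * mean(nul == obs))
  }, observed, cols)
  data.frame(ses = out["ses", ], rank_q = out["rank_q", ])
}

#' Functional/phylogenetic redundancy regression with AIC stepwise
#' simplification
#'
#' Fits `response ~ SR + SR^2` by ordinary least squares, attempts
#' stepwise deletion of the polynomial term, and selects the model with
#' the lower small-sample corrected AIC (AICc; Gaussian log-likelihood
#' convention, error variance counted as a parameter).  The correction
#' matters here: with the dozen-site designs this analysis targets,
#' n/k is far below 40 and plain AIC retains a spurious quadratic term
#' in roughly one fit in six, so the correction term `2k(k+1)/(n-k-1)`
#' is applied to both candidate models, and the quadratic term is kept
#' only when it improves AICc by more than the conventional two-unit
#' evidence threshold; uncorrected AIC values are reported alongside.
#' Redundancy — a saturating, concave diversity-richness relationship —
#' is flagged when the quadratic term is retained with a negative
#' coefficient.
#'
#' @param sr per-site species richness (integer-valued).
#' @param response per-site diversity values (FD or PD; observed or null
#'   mean).
#' @return Object of class `redundancy_fit`: coefficients of the
#'   selected model, AICc (and uncorrected AIC) of both models,
#'   selected-model label, R2, the
#'   redundancy flag, and leverage/residual diagnostics.
#' @export
redundancy_regression <- function(sr, response) {
  ok <- complete.cases(sr, response)
  sr <- sr[ok]; response <- response[ok]
  if (length(sr) < 4) stop("need at least 4 sites")
  if (length(unique(sr)) < 2) stop("SR is constant; regression undefined")
  if (length(unique(sr)) < 3)
    stop("need at least 3 distinct SR values for the quadratic fit")
  fit_full <- lm(response ~ sr + I(sr^2))
  fit_lin <- lm(response ~ sr)
  n <- length(sr)
  aicc <- function(fit) {
    k <- attr(stats::logLik(fit), "df")
    if (n - k - 1 <= 0) return(Inf)
    AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
  }
  aic_full <- aicc(fit_full); aic_lin <- aicc(fit_lin)
  # two-unit evidence threshold: models within 2 AICc units carry
  # comparable support, so the quadratic term must improve AICc by more
  # than 2 to be retained; otherwise parsimony keeps the linear model
  drop_quad <- aic_lin <= aic_full + 2
  sel <- if (drop_quad) fit_lin else fit_full
  cf <- coef(sel)
  structure(list(
    selected = if (drop_quad) "linear" else "quadratic",
    linear_coef = unname(cf["sr"]),
    quadratic_coef = if (drop_quad) NA_real_ else unname(cf["I(sr^2)"]),
    intercept = unname(cf["(Intercept)"]),
    aic_full = aic_full, aic_linear = aic_lin,
    aic_full_uncorrected = AIC(fit_full),
    aic_linear_uncorrected = AIC(fit_lin),
    r_squared = summary(sel)$r.squared,
    redundancy = !drop_quad && unname(cf["I(sr^2)"]) < 0,
    n = length(sr),
    diagnostics = list(max_leverage = max(hatvalues(sel)),
                       max_abs_std_resid = max(abs(rstandard(sel)))),
    model = sel),
    class = "redundancy_fit")
}

#' @export
print.redundancy_fit <- function(x, ...) {
  cat("Redundancy regression (n = ", x$n, "): ", x$selected,
      " model selected (AIC ", signif(x$aic_linear, 5), " linear vs ",
      signif(x$aic_full, 5), " quadratic); R2 = ", signif(x$r_squared, 3),
      "\n", sep = "")
  if (x$selected == "quadratic")
    cat("  quadratic coefficient ", signif(x$quadratic_coef, 4),
        if (x$redundancy) "  -> redundancy (saturating) pattern" else "",
        "\n", sep = "")
  invisible(x)
}

#' Moran's I spatial autocorrelation of a site-level variable
#'
#' Standard Moran's I with inverse Euclidean distance weights (zero
#' diagonal), expectation -1/(n-1), variance and two-sided p under the
#' randomisation assumption.
#'
#' @param values per-site values, in the order of `coords$site`.
#' @param coords a [site_coords()] data frame.
#' @param row_standardise divide each row of the weight matrix by its
#'   sum before testing.
#' @return Object of class `moran_report`.
#' @export
morans_i <- function(values, coords, row_standardise = FALSE) {
  n <- nrow(coords)
  if (n < 3) stop("need at least 3 sites")
  if (length(values) != n) stop("one value per site required")
  if (sd(values) == 0) stop("constant values; Moran's I undefined")
  dm <- as.matrix(stats::dist(coords[, c("x", "y")]))
  if (any(dm[upper.tri(dm)] == 0))
    stop("coincident sites give infinite inverse-distance weights")
  w <- 1 / dm
  diag(w) <- 0
  if (row_standardise) w <- w / rowSums(w)
  res <- ape::Moran.I(values, w, alternative = "two.sided")
  structure(list(observed = res$observed, expected = res$expected,
                 sd = res$sd, p.value = res$p.value, n = n,
                 row_standardised = row_standardise),
            class = "moran_report")
}

#' @export
print.moran_report <- function(x, ...) {
  cat("Moran's I = ", signif(x$observed, 4), " (expected ",
      signif(x$expected, 4), ", sd ", signif(x$sd, 4), "), p = ",
      signif(x$p.value, 4), "\n", sep = "")
  invisible(x)
}
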