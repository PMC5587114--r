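# Validation statistics: intraclass correlation, Bland-Altman limits of
# agreement, fixed and random-intercept regressions, negative binomial
# counts, paired t, the implant-site scoring rubric, and light/dark
# summaries.

#' Average-measures intraclass correlation, ICC(1,k)
#'
#' One-way random-effects, average-of-k-measurements ICC:
#' \code{(BMS - WMS) / BMS}, where BMS and WMS are the between- and
#' within-subject mean squares of the one-way ANOVA decomposition of the
#' n x k matrix.  A two-way absolute-agreement average-measures variant,
#' ICC(A,k) in the McGraw-Wong naming, is available via
#' \code{type = "ICCAk"} since the "average absolute agreement" label mixes
#' the two naming systems.
#'
#' @param m Numeric n x k matrix: n subjects (rows) by k raters/methods,
#'   no missing cells.
#' @param type \code{"ICC1k"} (default) or \code{"ICCAk"}.
#' @return List with \code{icc}, \code{bms}, \code{wms}, \code{n}, \code{k}
#'   (plus \code{jms}, \code{ems} for the two-way variant).  \code{icc} is
#'   \code{NA} with a note when the total variance is zero.
#' @export
icc_1k <- function(m, type = c("ICC1k", "ICCAk")) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (anyNA(m)) stop("ICC requires a complete matrix", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("ICC needs n >= 2 subjects and k >= 2 columns",
                           call. = FALSE)
  grand <- mean(m)
  rowm <- rowMeans(m)
  bms <- k * sum((rowm - grand)^2) / (n - 1)
  wms <- sum((m - rowm)^2) / (n * (k - 1))
  if (type == "ICC1k") {
    icc <- if (bms <= 0) NA_real_ else (bms - wms) / bms
    res <- list(icc = icc, bms = bms, wms = wms, n = n, k = k, type = type)
  } else {
    colm <- colMeans(m)
    jms <- n * sum((colm - grand)^2) / (k - 1)
    ems <- sum((sweep(sweep(m, 1, rowm), 2, colm) + grand)^2) /
      ((n - 1) * (k - 1))
    denom <- bms + (jms - ems) / n
    icc <- if (denom <= 0) NA_real_ else (bms - ems) / denom
    res <- list(icc = icc, bms = bms, wms = wms, jms = jms, ems = ems,
                n = n, k = k, type = type)
  }
  if (is.na(res$icc)) res$note <- "undefined: zero between-subject variance"
  res
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference x - y), SD of the differences (n - 1 denominator)
#' and 95 percent limits of agreement at bias +/- 1.96 SD.
#'
#' @param x,y Equal-length paired measurements, n >= 2.
#' @return List with \code{bias}, \code{sd_diff}, \code{loa_low},
#'   \code{loa_high}, \code{n}.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       n = length(d))
}

regression_fit <- function(coef_table, sigma2, label, tau2 = NA_real_,
                           model = NULL) {
  structure(list(coefficients = coef_table, sigma2 = sigma2, tau2 = tau2,
                 label = label, model = model),
            class = "regression_fit")
}

coef_table_lm <- function(fit) {
  s <- summary(fit)$coefficients
  data.table::data.table(term = rownames(s), estimate = s[, 1], se = s[, 2],
                         p = s[, 4])
}

#' Ordinary least squares fit
#'
#' Classical least-squares fit of a fixed-effects model such as
#' \code{readrate ~ shielded + height + tag_id + baseplate}.  Categorical
#' terms are treatment-coded with the first level (alphabetically) as
#' reference.  A rank-deficient design is an error naming the aliased terms.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @return A \code{regression_fit}: coefficient table (estimate, SE,
#'   two-sided p), residual variance \code{sigma2}, label \code{"eq_ols"}.
#' @export
fit_ols <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  mm <- stats::model.matrix(formula, mf)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(formula, data)
  regression_fit(coef_table_lm(fit), sigma2 = summary(fit)$sigma^2,
                 label = "eq_ols", model = fit)
}

#' Random-intercept mixed model (REML)
#'
#' REML fit of fixed effects plus a single random intercept, as in
#' \code{temperature ~ day + cage + week + baseplate + phase + (1 | rat)}.
#' With fewer than two grouping levels the fit falls back to OLS with a
#' warning flag in the label.
#'
#' @param formula An \pkg{lme4}-style formula with exactly one
#'   \code{(1 | group)} term.
#' @param data Data frame.
#' @return A \code{regression_fit} with residual variance \code{sigma2},
#'   random-intercept variance \code{tau2} and label \code{"eq_mixed"} (or
#'   \code{"eq_mixed_ols_fallback"}).  Fixed-effect p values are two-sided
#'   Wald tests.
#' @export
fit_random_intercept <- function(formula, data) {
  bars <- lme4::findbars(formula)
  if (length(bars) != 1L)
    stop("formula must contain exactly one (1 | group) term", call. = FALSE)
  gvar <- deparse(bars[[1]][[3]])
  ng <- length(unique(data[[gvar]]))
  if (ng < 2L) {
    warning("only one grouping level; falling back to OLS", call. = FALSE)
    fixed <- lme4::nobars(formula)
    fit <- stats::lm(fixed, data)
    return(regression_fit(coef_table_lm(fit), sigma2 = summary(fit)$sigma^2,
                          tau2 = 0, label = "eq_mixed_ols_fallback",
                          model = fit))
  }
  fit <- lme4::lmer(formula, data, REML = TRUE)
  s <- summary(fit)$coefficients
  ct <- data.table::data.table(term = rownames(s), estimate = s[, 1],
                               se = s[, 2],
                               p = 2 * stats::pnorm(-abs(s[, 1] / s[, 2])))
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == gvar][1]
  sigma2 <- vc$vcov[vc$grp == "Residual"][1]
  regression_fit(ct, sigma2 = sigma2, tau2 = tau2, label = "eq_mixed",
                 model = fit)
}

#' Negative binomial count regression
#'
#' Log-link negative binomial maximum-likelihood fit for over-dispersed
#' transition counts (the bounded, zero-heavy alternative to the linear
#' mixed model).
#'
#' @param formula Model formula; the response must be non-negative integers.
#' @param data Data frame.
#' @return A \code{regression_fit} with label \code{"negbin"};
#'   \code{sigma2} holds the estimated dispersion parameter theta.
#' @export
fit_negbin <- function(formula, data) {
  y <- stats::model.response(stats::model.frame(formula, data))
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("response must be non-negative integer counts", call. = FALSE)
  fit <- tryCatch(MASS::glm.nb(formula, data), error = function(e) NULL)
  theta <- if (is.null(fit)) Inf else fit$theta
  if (is.null(fit)) {
    # dispersion unidentifiable (e.g. under-dispersed or constant counts):
    # the negative binomial degenerates to its Poisson limit
    fit <- stats::glm(formula, data, family = stats::poisson())
  }
  s <- summary(fit)$coefficients
  ct <- data.table::data.table(term = rownames(s), estimate = s[, 1],
                               se = s[, 2], p = s[, 4])
  regression_fit(ct, sigma2 = theta, label = "negbin", model = fit)
}

#' Two-sided paired t-test
#'
#' @param x1,x2 Equal-length paired vectors, n >= 2.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
paired_t <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("paired vectors must have equal length",
                                     call. = FALSE)
  if (length(x1) < 2) stop("need n >= 2 pairs", call. = FALSE)
  if (stats::sd(x1 - x2) == 0)
    stop("zero-variance differences: t statistic undefined", call. = FALSE)
  ht <- stats::t.test(x1, x2, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# Half-open scoring bands [lower, upper): findInterval maps a metric to its
# band, boundaries belonging to the band they open.
band_score <- function(x, breaks) as.integer(findInterval(x, breaks) + 1L)

#' Implant-site scoring rubric
#'
#' Maps validation metrics onto the 1-5 selection-rubric bands: read
#' frequency (Hz; 5 at >= 0.75, down to 1 below 0.3), tracking ICC (5 at >=
#' 0.9, 1 below 0), side-view R squared (same upper bands, 2 at [0.3, 0.5),
#' 1 below 0.3), and implantation issues (number of rats out of six with
#' intraperitoneal injection, migration or extrusion; 5 = none).  Bands are
#' half-open \code{[lower, upper)}.
#'
#' @param read_freq_hz Mean per-tag read frequency, Hz.
#' @param icc_tracking ICC against manual birds-eye tracking.
#' @param r2_sideview R squared against side-view motion.
#' @param implant_issues Count of affected rats (default 0).
#' @return \code{data.table} with \code{criterion}, \code{metric},
#'   \code{score}; metrics passed as \code{NULL} are omitted.
#' @export
rubric_scores <- function(read_freq_hz = NULL, icc_tracking = NULL,
                          r2_sideview = NULL, implant_issues = NULL) {
  rows <- list()
  add <- function(criterion, metric, score)
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      criterion = criterion, metric = metric, score = score)
  if (!is.null(read_freq_hz))
    add("read_frequency", read_freq_hz,
        band_score(read_freq_hz, c(0.3, 0.4, 0.6, 0.75)))
  if (!is.null(icc_tracking))
    add("tracking_icc", icc_tracking,
        band_score(icc_tracking, c(0, 0.5, 0.7, 0.9)))
  if (!is.null(r2_sideview))
    add("sideview_r2", r2_sideview,
        band_score(r2_sideview, c(0.3, 0.5, 0.7, 0.9)))
  if (!is.null(implant_issues))
    add("implantation_issues", implant_issues,
        pmax(1L, 5L - as.integer(implant_issues)))
  out <- data.table::rbindlist(rows)
  if (nrow(out) && any(out$score < 1 | out$score > 5))
    stop("metric outside the rubric's valid range", call. = FALSE)
  out
}

#' Light/dark phase summary of binned series
#'
#' Per-animal and whole-cage phase means, dark:light ratio, and dark - light
#' difference, for activity or temperature bins.
#'
#' @param bins Output of \code{\link{count_transitions}} or
#'   \code{\link{bin_temperature}}.
#' @param value_col Column to summarise (e.g. \code{"n_transitions"},
#'   \code{"distance_cm"}, \code{"mean_temp"}).
#' @return List with \code{per_animal} (\code{data.table}: animal_id,
#'   light_mean, dark_mean, ratio, difference) and \code{cage} (the same for
#'   the pooled cage).  The ratio is \code{NA} when the light-phase mean is
#'   zero.
#' @export
light_dark_summary <- function(bins, value_col = "n_transitions") {
  v <- bins[[value_col]]
  summarise <- function(sel) {
    lm_ <- mean(v[sel & bins$phase == "light"], na.rm = TRUE)
    dm_ <- mean(v[sel & bins$phase == "dark"], na.rm = TRUE)
    list(light_mean = lm_, dark_mean = dm_,
         ratio = if (!is.na(lm_) && lm_ != 0) dm_ / lm_ else NA_real_,
         difference = dm_ - lm_)
  }
  ids <- sort(unique(bins$animal_id))
  per <- data.table::rbindlist(lapply(ids, function(id) {
    s <- summarise(bins$animal_id == id)
    data.table::data.table(animal_id = id, light_mean = s$light_mean,
                           dark_mean = s$dark_mean, ratio = s$ratio,
                           difference = s$difference)
  }))
  cage <- summarise(rep(TRUE, nrow(bins)))
  list(per_animal = per, cage = cage)
}
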