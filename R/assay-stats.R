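#' Fit a saturating-exponential calibration curve
#'
#' Least-squares fit of the immunoassay calibration model
#' \deqn{S(c) = S_\infty - (S_\infty - S_0)\, e^{-kc},}
#' the standard saturating form for sandwich-assay signal versus antigen
#' concentration: `s0` is the blank asymptote, `s_inf` the saturation
#' plateau, and `k` the rate constant per concentration unit.  Starting
#' values come from the data (blank mean for `s0`, top-level mean for
#' `s_inf`, log-linearized residual slope for `k`); the nonlinear fit uses
#' Levenberg-Marquardt via [minpack.lm::nlsLM()].
#'
#' @param table data.frame with columns `concentration` and `signal`
#'   (replicates as repeated rows); at least 4 distinct concentrations
#'   including a blank (c = 0).
#' @param unit concentration unit label carried into reports (e.g. "nM").
#' @return list of class `calibration_fit` with `s0`, `s_inf`, `k`,
#'   `r_squared`, `n`, `unit`, and the `model` object.
#' @seealso [calibration_signal()], [invert_calibration()], [lod()]
#' @export
fit_calibration <- function(table, unit = "nM") {
  if (!all(c("concentration", "signal") %in% names(table)))
    stop("table needs 'concentration' and 'signal' columns")
  tab <- table[is.finite(table$concentration) & is.finite(table$signal), ]
  concs <- sort(unique(tab$concentration))
  if (length(concs) < 4L) stop("need at least 4 distinct concentrations")
  if (min(concs) != 0) stop("calibration requires blank (c = 0) wells")
  means <- tapply(tab$signal, tab$concentration, mean)
  s0_0 <- means[[as.character(0)]]
  top <- means[[length(means)]]
  if (top <= s0_0)
    stop("fit failure: top-level signal does not exceed the blank")
  s_inf_0 <- top + 0.05 * (top - s0_0)
  # log-linearized slope for k: log(s_inf - S) = log(s_inf - s0) - k c
  cpos <- as.numeric(names(means))
  resid <- s_inf_0 - as.numeric(means)
  ok <- resid > 0
  k0 <- -unname(coef(stats::lm(log(resid[ok]) ~ cpos[ok]))[2L])
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / max(cpos[cpos > 0])
  fit <- minpack.lm::nlsLM(
    signal ~ s_inf - (s_inf - s0) * exp(-k * concentration),
    data = tab,
    start = list(s0 = s0_0, s_inf = s_inf_0, k = k0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  est <- coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((tab$signal - mean(tab$signal))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  if (est[["s_inf"]] <= est[["s0"]])
    stop("fit failure: fitted s_inf does not exceed s0")
  structure(list(s0 = est[["s0"]], s_inf = est[["s_inf"]], k = est[["k"]],
                 r_squared = r2, n = nrow(tab), unit = unit, model = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> S(c) = %.4g - (%.4g - %.4g) exp(-%.4g c)  [c in %s]\n",
    x$s_inf, x$s_inf, x$s0, x$k, x$unit))
  cat(sprintf("R^2 = %.6f on n = %d points\n", x$r_squared, x$n))
  invisible(x)
}

#' Predicted calibration signal at given concentrations
#'
#' @param fit a [fit_calibration()] result (or a list with `s0`, `s_inf`,
#'   `k`).
#' @param concentration numeric vector.
#' @return expected signals.
#' @export
calibration_signal <- function(fit, concentration) {
  fit$s_inf - (fit$s_inf - fit$s0) * exp(-fit$k * concentration)
}

#' Invert a calibration fit: concentration at a given signal
#'
#' Closed-form inverse of the saturating exponential,
#' \deqn{c = -\frac{1}{k}\,\ln\frac{S_\infty - S}{S_\infty - S_0}.}
#'
#' @inheritParams calibration_signal
#' @param signal signals strictly below `s_inf`.
#' @return concentrations.
#' @export
invert_calibration <- function(fit, signal) {
  if (any(signal >= fit$s_inf))
    stop("signal at or beyond the saturation asymptote cannot be inverted")
  -log((fit$s_inf - signal) / (fit$s_inf - fit$s0)) / fit$k
}

#' Blank-based limit of detection
#'
#' The decision signal is the blank mean plus three blank standard
#' deviations (signal-to-noise ratio of 3); the LOD is the concentration
#' whose expected calibration signal equals that decision signal, obtained
#' through the closed-form inverse of the fit.  Negative inversions (blank
#' mean below the fitted blank asymptote) are clamped to 0.
#'
#' @param blanks replicate blank signals (>= 3 values).
#' @param fit a [fit_calibration()] result.
#' @return list of class `lod_result` with `blank_mean`, `blank_sd`,
#'   `decision_signal`, `lod`, and `unit`.
#' @export
lod <- function(blanks, fit) {
  x <- as.numeric(blanks)
  if (length(x) < 3L) stop("need at least 3 blank replicates")
  m <- mean(x); s <- sd(x)
  decision <- m + 3 * s
  if (decision >= fit$s_inf)
    stop("LOD beyond dynamic range: blank + 3 s.d. reaches saturation")
  value <- max(0, invert_calibration(fit, decision))
  structure(list(blank_mean = m, blank_sd = s, decision_signal = decision,
                 lod = value, unit = fit$unit),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> LOD = %.4g %s (blank %.4g +/- %.4g)\n",
              x$lod, x$unit, x$blank_mean, x$blank_sd))
  invisible(x)
}

#' Intra- and inter-assay coefficients of variation
#'
#' Lot-to-lot reproducibility report at each concentration level
#' (typically low/medium/high): the intra-assay %CV is the within-run
#' 100 x s.d./mean, averaged over runs; the inter-assay %CV is the %CV of
#' the run means.  Sample (n-1) standard deviations throughout.
#'
#' @param table data.frame with columns `level`, `run`, `signal`; at least
#'   2 replicates per (level, run) and 2 runs per level.
#' @return data.frame of class `cv_report`: one row per level with
#'   `intra_cv` and `inter_cv` (percent).
#' @export
cv_report <- function(table) {
  if (!all(c("level", "run", "signal") %in% names(table)))
    stop("table needs 'level', 'run', 'signal' columns")
  levels_ <- unique(table$level)
  out <- data.frame(level = levels_, intra_cv = NA_real_,
                    inter_cv = NA_real_)
  for (i in seq_along(levels_)) {
    sub <- table[table$level == levels_[i], ]
    runs <- split(sub$signal, sub$run)
    if (length(runs) < 2L)
      stop(sprintf("level '%s': need at least 2 runs", levels_[i]))
    if (any(vapply(runs, length, 1L) < 2L))
      stop(sprintf("level '%s': need >= 2 replicates per run", levels_[i]))
    mu <- vapply(runs, mean, 1)
    if (any(mu == 0) || mean(mu) == 0)
      stop(sprintf("level '%s': zero mean signal", levels_[i]))
    out$intra_cv[i] <- mean(100 * vapply(runs, sd, 1) / mu)
    out$inter_cv[i] <- 100 * sd(mu) / mean(mu)
  }
  class(out) <- c("cv_report", class(out))
  out
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Sweeps the decision threshold over the observed scores (rule: score >=
#' threshold is called positive), traces the ROC curve from (0, 0) to
#' (1, 1), and integrates the AUC by the trapezoid rule — numerically
#' identical to the Mann-Whitney pairwise-concordance statistic with ties
#' counted 1/2.  The optimal cutoff maximizes the Youden index
#' J = sensitivity + specificity - 1; ties go to the lowest threshold.
#'
#' @param scores numeric classifier scores (higher = more disease-like).
#' @param labels vector distinguishing the two classes.
#' @param positive the label value of the positive (diseased) class;
#'   defaults to `"positive"` when present, else the last sorted level.
#' @return list of class `roc_result` with `curve` (data.frame: threshold,
#'   fpr, tpr), `auc`, `cutoff`, `sensitivity`, `specificity`, `n_pos`,
#'   `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  lab <- as.character(labels)
  if (is.null(positive))
    positive <- if ("positive" %in% lab) "positive" else sort(unique(lab))[
      length(unique(lab))]
  is_pos <- lab == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[is_pos] >= t), 1)
  fpr <- vapply(th, function(t) mean(scores[!is_pos] >= t), 1)
  curve <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  auc <- trapz(curve$fpr, curve$tpr)
  j <- curve$tpr - curve$fpr
  best <- which(j == max(j))
  # lowest threshold among the maximizers
  best <- best[which.min(curve$threshold[best])]
  structure(list(curve = curve, auc = auc,
                 cutoff = curve$threshold[best],
                 sensitivity = curve$tpr[best],
                 specificity = 1 - curve$fpr[best],
                 youden = max(j), n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (%d pos / %d neg); cutoff %.4g: sens %.3f, spec %.3f\n",
    x$auc, x$n_pos, x$n_neg, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' Mann-Whitney concordance AUC
#'
#' Pairwise-concordance estimate of the AUC (ties counted 1/2), used as the
#' independent cross-check of the trapezoid integral in [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
concordance_auc <- function(scores, labels, positive = NULL) {
  lab <- as.character(labels)
  if (is.null(positive))
    positive <- if ("positive" %in% lab) "positive" else sort(unique(lab))[
      length(unique(lab))]
  xp <- scores[lab == positive]
  xn <- scores[lab != positive]
  if (!length(xp) || !length(xn)) stop("both classes must be present")
  cmp <- outer(xp, xn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

#' Method agreement: Pearson correlation and Bland-Altman limits
#'
#' Compares paired measurements of the same quantity by two methods:
#' Pearson r, plus the Bland-Altman bias (mean difference x - y) and 95%
#' limits of agreement, bias +/- 1.96 x sample s.d. of the differences.
#'
#' @param x,y paired numeric vectors (n >= 2, since the limits need a
#'   sample s.d. of the differences).
#' @return list of class `agreement_report` with `r`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`.  When either series has zero variance the
#'   correlation is undefined: `r` is `NA` with a warning, while the
#'   Bland-Altman quantities are still reported.
#' @export
agreement <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  r <- if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in a series: Pearson r undefined")
    NA_real_
  } else cor(x, y)
  structure(list(r = r, bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(x)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> r = %.3f; bias %.4g, 95%% LOA [%.4g, %.4g] (n = %d)\n",
    x$r, x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}
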