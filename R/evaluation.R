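#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; 1 means perfect overlap, 0 complete mismatch.
#' Two empty masks are defined to agree perfectly (DSC 1) with a warning
#' attribute; one empty mask gives 0.
#'
#' @param a,b Binary 3-D arrays (or [label_grid()]s; foreground = any
#'   kidney class) on identical lattices.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (inherits(a, "label_grid")) a <- a$data > 0
  if (inherits(b, "label_grid")) b <- b$data > 0
  if (!all(dim(a) == dim(b)))
    stop("masks must share a lattice", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na == 0L && nb == 0L) {
    out <- 1
    attr(out, "both_empty") <- TRUE
    return(out)
  }
  2 * sum(a & b) / (na + nb)
}

#' Percentage volume error
#'
#' `|vol_man - vol_pred| / vol_man * 100`, the standard relative volumetric
#' error against the manual reference.
#'
#' @param vol_man Manual (reference) volume, mL; must be > 0.
#' @param vol_pred Predicted volume, mL.
#' @return Error in percent (non-negative).
#' @export
percent_volume_error <- function(vol_man, vol_pred) {
  if (any(vol_man <= 0))
    stop("manual reference volume must be positive", call. = FALSE)
  abs(vol_man - vol_pred) / vol_man * 100
}

#' Absolute axis error
#'
#' `|x_man - x_pred|` for an axis measurement (length, width or thickness).
#'
#' @param x_man,x_pred Axis values, mm.
#' @return Absolute error, mm.
#' @export
absolute_error <- function(x_man, x_pred) abs(x_man - x_pred)

icc_band <- function(icc) {
  if (icc < 0.50) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.90) "good"
  else "excellent"
}

#' Intraclass correlation, single-rater consistency (two-way mixed)
#'
#' ICC(3,1) from the two-way ANOVA decomposition:
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)`, with the
#' exact F-based 95% confidence interval and the p-value of
#' `F = MS_subjects / MS_error` on `(n - 1, (n - 1)(k - 1))` degrees of
#' freedom.  Consistency (not absolute agreement): invariant under adding a
#' per-rater constant.  Bands follow the 0.50 / 0.75 / 0.90 cut points
#' (poor / moderate / good / excellent).
#'
#' @param ratings Numeric matrix or data.frame, subjects x raters, no
#'   missing cells; >= 5 subjects and >= 2 raters.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `icc_result`: list with `icc`, `ci95`,
#'   `p_value`, `n_subjects`, `n_raters`, `band`, `F`, `df1`, `df2`.
#' @export
icc_consistency <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (anyNA(x))
    stop("ratings table contains missing cells", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 5L || k < 2L)
    stop("need >= 5 subjects and >= 2 raters, got ", n, " x ", k,
         call. = FALSE)
  grand <- mean(x)
  ssb <- k * sum((rowMeans(x) - grand)^2)       # between subjects
  ssc <- n * sum((colMeans(x) - grand)^2)       # between raters
  sst <- sum((x - grand)^2)
  sse <- sst - ssb - ssc
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  msb <- ssb / df1
  mse <- max(sse / df2, 0)
  if (msb <= .Machine$double.eps * abs(grand + 1))
    stop("zero variance across subjects: ICC undefined", call. = FALSE)
  if (mse <= 1e-12 * msb) mse <- 0  # exact-agreement limit despite rounding
  if (mse == 0) {
    icc <- 1
    f0 <- Inf
    ci <- c(1, 1)
    p <- 0
  } else {
    icc <- (msb - mse) / (msb + (k - 1) * mse)
    f0 <- msb / mse
    alpha <- 1 - conf_level
    fl <- f0 / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f0 * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    p <- stats::pf(f0, df1, df2, lower.tail = FALSE)
  }
  structure(list(icc = icc, ci95 = ci, p_value = p, n_subjects = n,
                 n_raters = k, band = icc_band(icc), F = f0,
                 df1 = df1, df2 = df2),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(paste0("ICC(3,1) = %.3f (95%% CI %.3f-%.3f), p = %.3g, ",
                     "n = %d subjects x %d raters [%s]\n"),
              x$icc, x$ci95[1], x$ci95[2], x$p_value, x$n_subjects,
              x$n_raters, x$band))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Differences are taken as `predicted - manual`; bias is their mean and
#' the 95% limits of agreement are `bias +/- 1.96 * sd` (sample sd, n - 1
#' denominator).
#'
#' @param manual,predicted Paired measurement vectors (same length,
#'   n >= 2), or `manual` may be a 2-column matrix of (manual, predicted).
#' @return An object of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, `differences`, `means`.
#' @export
bland_altman <- function(manual, predicted = NULL) {
  if (is.null(predicted)) {
    m <- as.matrix(manual)
    stopifnot(ncol(m) == 2L)
    manual <- m[, 1]; predicted <- m[, 2]
  }
  if (length(manual) != length(predicted) || length(manual) < 2L)
    stop("need >= 2 matched pairs", call. = FALSE)
  d <- predicted - manual
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n = length(d), differences = d,
                 means = (manual + predicted) / 2),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Cohort-level agreement report
#'
#' Aggregates per-kidney automated-versus-manual comparisons into the
#' standard report: DSC mean +/- sd with a normal-theory 95% CI, mean
#' percentage volume error, mean absolute error per axis, ICC (single-rater
#' consistency) per parameter, and Bland-Altman for volume.  Cohort means
#' are unweighted means of per-kidney values.
#'
#' @param manual,predicted data.frames of per-kidney measurements with
#'   columns `case`, `side`, `volume_ml`, `length_mm`, `width_mm`,
#'   `thickness_mm` (e.g. from [measure_kidneys()] plus a case id).
#' @param dsc Optional data.frame with columns `case`, `side`, `dsc` giving
#'   the per-kidney spatial overlap of the two segmentations.
#' @return An object of class `cohort_report`: list with `summary`
#'   (data.frame of metric, mean, sd, ci_low, ci_high, n), `icc` (list of
#'   [icc_consistency()] results per parameter), `bland_altman_volume`, and
#'   `per_kidney` (the merged table with per-row errors).
#' @export
evaluate_cohort <- function(manual, predicted, dsc = NULL) {
  req <- c("case", "side", "volume_ml", "length_mm", "width_mm",
           "thickness_mm")
  for (nmd in list(manual, predicted))
    if (!all(req %in% names(nmd)))
      stop("measurement tables need columns: ", paste(req, collapse = ", "),
           call. = FALSE)
  key_m <- paste(manual$case, manual$side)
  key_p <- paste(predicted$case, predicted$side)
  missing_p <- setdiff(key_m, key_p)
  missing_m <- setdiff(key_p, key_m)
  if (length(missing_p) || length(missing_m))
    stop("unmatched cases between manual and predicted tables: ",
         paste(c(missing_p, missing_m), collapse = "; "), call. = FALSE)
  merged <- merge(manual, predicted, by = c("case", "side"),
                  suffixes = c("_man", "_pred"), sort = TRUE)
  if (!is.null(dsc)) {
    merged <- merge(merged, dsc[, c("case", "side", "dsc")],
                    by = c("case", "side"), sort = TRUE)
  }
  merged$mpve <- percent_volume_error(merged$volume_ml_man,
                                      merged$volume_ml_pred)
  for (axn in c("length_mm", "width_mm", "thickness_mm"))
    merged[[paste0("mae_", sub("_mm", "", axn))]] <-
      absolute_error(merged[[paste0(axn, "_man")]],
                     merged[[paste0(axn, "_pred")]])

  norm_ci <- function(v) {
    m <- mean(v); s <- stats::sd(v)
    half <- stats::qnorm(0.975) * s / sqrt(length(v))
    c(mean = m, sd = s, lo = m - half, hi = m + half)
  }
  rows <- list()
  add_row <- function(metric, v) {
    st <- norm_ci(v)
    rows[[length(rows) + 1]] <<- data.frame(
      metric = metric, mean = st[["mean"]], sd = st[["sd"]],
      ci_low = st[["lo"]], ci_high = st[["hi"]], n = length(v),
      stringsAsFactors = FALSE)
  }
  if (!is.null(dsc)) add_row("dsc", merged$dsc)
  add_row("mpve_pct", merged$mpve)
  add_row("mae_length_mm", merged$mae_length)
  add_row("mae_width_mm", merged$mae_width)
  add_row("mae_thickness_mm", merged$mae_thickness)

  icc <- lapply(stats::setNames(nm = c("volume_ml", "length_mm", "width_mm",
                                       "thickness_mm")), function(par)
    icc_consistency(cbind(manual = merged[[paste0(par, "_man")]],
                          predicted = merged[[paste0(par, "_pred")]])))
  ba <- bland_altman(merged$volume_ml_man, merged$volume_ml_pred)

  structure(list(summary = do.call(rbind, rows), icc = icc,
                 bland_altman_volume = ba, per_kidney = merged),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort agreement report (", nrow(x$per_kidney), " kidneys)\n",
      sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s %6.2f +/- %.2f  (95%% CI %.2f-%.2f)\n",
                s$metric[i], s$mean[i], s$sd[i], s$ci_low[i], s$ci_high[i]))
  for (par in names(x$icc)) {
    ic <- x$icc[[par]]
    cat(sprintf("  ICC %-12s %.3f (%.3f-%.3f), p = %.2g [%s]\n", par,
                ic$icc, ic$ci95[1], ic$ci95[2], ic$p_value, ic$band))
  }
  print(x$bland_altman_volume)
  invisible(x)
}
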