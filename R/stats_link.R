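#' Two-stage weekly-to-monthly aggregation
#'
#' Monthly values are formed by first averaging the weekly measurements of a
#' given month per electrode, and then averaging across electrodes per
#' mouse. Typed-missing values (`NA`) are excluded from the means; the
#' electrode-month intermediate is retained for channel-level matching.
#'
#' @param table tidy data.frame with columns `subject_id`, `genotype`,
#'   `age_week`, `age_month`, `channel`, `metric`, `band_label`, `value`
#'   (extra columns are ignored).
#' @return list with `electrode_month` (subject x channel x month) and
#'   `mouse_month` (subject x month) data.frames.
#' @export
weekly_to_monthly <- function(table) {
  mean_na <- function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }
  el <- stats::aggregate(
    value ~ subject_id + genotype + age_month + channel + metric + band_label,
    data = table, FUN = mean_na, na.action = stats::na.pass)
  mo <- stats::aggregate(
    value ~ subject_id + genotype + age_month + metric + band_label,
    data = el, FUN = mean_na, na.action = stats::na.pass)
  list(electrode_month = el, mouse_month = mo)
}

#' Repeated measures correlation
#'
#' ANCOVA estimate of the common within-subject association between two
#' repeatedly measured variables: `y` is regressed on subject indicators
#' plus a common slope on `x`; the coefficient is
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_residual))` with
#' `dof = N - n_subjects - 1`. Confidence interval via the Fisher z
#' transform with a dof-adjusted standard error (`1/sqrt(dof - 1)`).
#' Subjects with fewer than 2 pairs or zero x-variance contribute no slope
#' information and are dropped (recorded in the `dropped_subjects`
#' attribute).
#'
#' @param pairs data.frame with columns `subject`, `x`, `y`.
#' @param conf confidence level (default 0.95).
#' @return object of class `rmcorr_result`: list with `r_rm`, `ci95`, `p`,
#'   `dof`, `n_pairs`, `n_subjects`, `slope`.
#' @export
rmcorr <- function(pairs, conf = 0.95) {
  pairs <- pairs[is.finite(pairs$x) & is.finite(pairs$y), , drop = FALSE]
  keep <- vapply(split(pairs$x, pairs$subject), function(v) {
    length(v) >= 2 && stats::var(v) > 0
  }, TRUE)
  dropped <- names(keep)[!keep]
  pairs <- pairs[pairs$subject %in% names(keep)[keep], , drop = FALSE]
  n_sub <- length(unique(pairs$subject))
  if (n_sub < 2L) stop("rmcorr: need >= 2 subjects with >= 2 pairs and x-variance")
  subj <- factor(pairs$subject)
  f1 <- stats::lm(y ~ subj + x, data = data.frame(y = pairs$y, subj = subj,
                                                  x = pairs$x))
  f0 <- stats::lm(y ~ subj, data = data.frame(y = pairs$y, subj = subj))
  rss1 <- sum(stats::residuals(f1)^2)
  rss0 <- sum(stats::residuals(f0)^2)
  ss_x <- rss0 - rss1
  slope <- unname(stats::coef(f1)["x"])
  n <- nrow(pairs)
  dof <- n - n_sub - 1L
  r <- sign(slope) * sqrt(max(0, ss_x) / (ss_x + rss1))
  tstat <- r * sqrt(dof / max(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), dof)
  z <- atanh(min(1 - 1e-12, max(-1 + 1e-12, r)))
  se <- 1 / sqrt(max(1, dof - 1))
  q <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(c(z - q * se, z + q * se))
  structure(list(r_rm = r, ci95 = ci, p = p, dof = dof, n_pairs = n,
                 n_subjects = n_sub, slope = slope,
                 dropped_subjects = dropped),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("<rmcorr> r_rm = %.3f [%.3f, %.3f], p = %.3g (dof = %d, %d pairs, %d subjects)\n",
              x$r_rm, x$ci95[1], x$ci95[2], x$p, x$dof, x$n_pairs,
              x$n_subjects))
  invisible(x)
}

#' Match monthly channel-level fE/I with monthly PAC
#'
#' Inner join on (subject, channel, month): one (fE/I, MI) pair per key;
#' repeated measures within a subject are months x channels. Missing values
#' on either side drop the pair.
#'
#' @param fei_monthly data.frame with `subject_id`, `channel`, `age_month`,
#'   `value` (electrode-month fE/I for one band).
#' @param pac_monthly data.frame with `subject_id`, `channel`, `age_month`,
#'   `value` (monthly MI summary).
#' @return data.frame with `subject`, `x` (fE/I), `y` (MI).
#' @export
match_fei_pac <- function(fei_monthly, pac_monthly) {
  j <- merge(fei_monthly[, c("subject_id", "channel", "age_month", "value")],
             pac_monthly[, c("subject_id", "channel", "age_month", "value")],
             by = c("subject_id", "channel", "age_month"),
             suffixes = c("_fei", "_mi"))
  j <- j[is.finite(j$value_fei) & is.finite(j$value_mi), ]
  if (!nrow(j)) stop("match_fei_pac: empty join")
  data.frame(subject = j$subject_id, x = j$value_fei, y = j$value_mi)
}

#' Match weekly mouse-level fE/I with weekly spike rates
#'
#' fE/I is averaged across channels per (subject, week), joined with the
#' weekly spike rate; weeks with zero spiking frequency are excluded.
#'
#' @param fei_weekly data.frame with `subject_id`, `age_week`, `channel`,
#'   `value`.
#' @param rates_weekly data.frame with `subject_id`, `age_week`, `rate`.
#' @return data.frame with `subject`, `x` (fE/I), `y` (rate).
#' @export
match_fei_spikes <- function(fei_weekly, rates_weekly) {
  fw <- stats::aggregate(value ~ subject_id + age_week,
                         data = fei_weekly[is.finite(fei_weekly$value), ],
                         FUN = mean)
  j <- merge(fw, rates_weekly, by = c("subject_id", "age_week"))
  j <- j[is.finite(j$rate) & j$rate > 0, ]
  if (!nrow(j)) stop("match_fei_spikes: empty join")
  data.frame(subject = j$subject_id, x = j$value, y = j$rate)
}

#' Match monthly PAC with monthly mean spike rates
#'
#' PAC summaries and weekly spike rates are grouped by (subject, month) and
#' averaged to one pair per subject-month; months with zero spiking
#' frequency are excluded.
#'
#' @param pac_monthly data.frame with `subject_id`, `age_month`, `channel`,
#'   `value`.
#' @param rates_weekly data.frame with `subject_id`, `age_week`,
#'   `age_month`, `rate`.
#' @return data.frame with `subject`, `x` (MI), `y` (rate).
#' @export
match_pac_spikes <- function(pac_monthly, rates_weekly) {
  pm <- stats::aggregate(value ~ subject_id + age_month,
                         data = pac_monthly[is.finite(pac_monthly$value), ],
                         FUN = mean)
  rm_ <- stats::aggregate(rate ~ subject_id + age_month,
                          data = rates_weekly, FUN = mean)
  j <- merge(pm, rm_, by = c("subject_id", "age_month"))
  j <- j[is.finite(j$rate) & j$rate > 0, ]
  if (!nrow(j)) stop("match_pac_spikes: empty join")
  data.frame(subject = j$subject_id, x = j$value, y = j$rate)
}

#' Monthly genotype contrasts with variance-gated t-tests and FDR
#'
#' Per month, mouse-level values are compared between two genotypes:
#' Levene's test (classic form: one-way ANOVA on absolute deviations from
#' the group mean) decides between the unpaired Student's t-test (equal
#' variance) and Welch's t-test (unequal variance); raw p-values are then
#' Benjamini-Hochberg corrected across the months at the given q.
#'
#' @param mouse_month data.frame with `subject_id`, `genotype`, `age_month`,
#'   `value` (one row per mouse-month; see [weekly_to_monthly()]).
#' @param q FDR level (default 0.05).
#' @param levene_alpha variance-gate alpha (default 0.05).
#' @param control optional control-genotype label (defaults to the first
#'   level encountered).
#' @return data.frame with one row per testable month: `age_month`,
#'   `mean_control`, `mean_affected`, `delta`, `test`, `levene_p`, `p_raw`,
#'   `p_fdr`, `significant`.
#' @export
genotype_compare <- function(mouse_month, q = 0.05, levene_alpha = 0.05,
                             control = NULL) {
  gts <- unique(mouse_month$genotype)
  if (length(gts) != 2L) stop("genotype_compare: need exactly 2 genotypes")
  if (is.null(control)) control <- gts[1]
  affected <- setdiff(gts, control)
  rows <- list()
  for (mo in sort(unique(mouse_month$age_month))) {
    d <- mouse_month[mouse_month$age_month == mo & is.finite(mouse_month$value), ]
    a <- d$value[d$genotype == control]
    b <- d$value[d$genotype == affected]
    if (length(a) < 2L || length(b) < 2L) next   # untestable month, skipped
    z <- c(abs(a - mean(a)), abs(b - mean(b)))
    grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
    # degenerate case: deviations (near-)constant within groups makes the
    # F-test unreliable; decide directly from the group deviation means
    fit <- stats::lm(z ~ grp)
    if (sum(stats::residuals(fit)^2) < 1e-12 * max(1, sum(z^2))) {
      lev_p <- if (abs(diff(tapply(z, grp, mean))) >
                     1e-8 * max(1, mean(z))) 0 else 1
    } else {
      lev_p <- stats::anova(fit)[["Pr(>F)"]][1]
    }
    welch <- is.finite(lev_p) && lev_p < levene_alpha
    tt <- stats::t.test(b, a, var.equal = !welch)
    rows[[length(rows) + 1L]] <- data.frame(
      age_month = mo, mean_control = mean(a), mean_affected = mean(b),
      delta = mean(b) - mean(a), test = if (welch) "welch" else "student",
      levene_p = lev_p, p_raw = tt$p.value)
  }
  if (!length(rows)) {
    return(data.frame(age_month = integer(0), mean_control = numeric(0),
                      mean_affected = numeric(0), delta = numeric(0),
                      test = character(0), levene_p = numeric(0),
                      p_raw = numeric(0), p_fdr = numeric(0),
                      significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_fdr < q
  out
}

#' Export a model-ready tidy table for multilevel fitting
#'
#' Writes one analysis-ready table per metric with columns
#' `value`, `genotype`, `age_month`, `mouse`, `channel`, suitable for any
#' multilevel fitter (e.g. a Bayesian model with mouse- and channel-level
#' intercepts).
#'
#' @param electrode_month data.frame from [weekly_to_monthly()].
#' @param file output path (tab-delimited).
#' @return the file path, invisibly.
#' @export
bmlm_export <- function(electrode_month, file) {
  out <- data.frame(value = electrode_month$value,
                    genotype = electrode_month$genotype,
                    age_month = electrode_month$age_month,
                    mouse = electrode_month$subject_id,
                    channel = electrode_month$channel)
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
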