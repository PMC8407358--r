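#' Pearson correlation with percentile-bootstrap confidence interval
#'
#' Sample Pearson r with a two-sided p-value from the t distribution and a
#' 95% percentile bootstrap confidence interval over paired (case) resamples.
#' A result is flagged significant only when BOTH p < .05 AND the bootstrap
#' interval excludes zero.
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap (default 1); a fixed seed gives
#'   identical intervals on re-run.
#' @param conf confidence level (default 0.95).
#' @return object of class `correlation_result`: list with `r`, `p`,
#'   `ci_low`, `ci_high`, `n`, `partial`, `covariate_name`, `significant`.
#' @export
pearson_with_bootstrap <- function(x, y, n_boot = 1000, seed = 1,
                                   conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y)
  set.seed(seed)
  rs <- boot_cor_pairs(x, y, n_boot)
  ci <- stats::quantile(rs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  new_correlation_result(unname(ct$estimate), ct$p.value, ci, n,
                         partial = FALSE, covariate_name = NULL)
}

new_correlation_result <- function(r, p, ci, n, partial, covariate_name) {
  significant <- is.finite(p) && is.finite(ci[1L]) && p < 0.05 &&
    (ci[1L] > 0 || ci[2L] < 0)
  structure(list(r = r, p = p, ci_low = ci[1L], ci_high = ci[2L], n = n,
                 partial = partial, covariate_name = covariate_name,
                 significant = significant),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s r = %.3f [%.3f %.3f], p = %.4g, n = %d%s%s\n",
              if (x$partial) "partial" else "Pearson",
              x$r, x$ci_low, x$ci_high, x$p, x$n,
              if (x$partial) paste0(" (adjusted for ", x$covariate_name, ")")
              else "",
              if (x$significant) " *" else ""))
  invisible(x)
}

# vectorised paired-resample bootstrap of Pearson r
boot_cor_pairs <- function(x, y, n_boot) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  xb <- matrix(x[idx], nrow = n)
  yb <- matrix(y[idx], nrow = n)
  mx <- colMeans(xb); my <- colMeans(yb)
  vx <- colMeans(xb * xb) - mx^2
  vy <- colMeans(yb * yb) - my^2
  cv <- colMeans(xb * yb) - mx * my
  r <- cv / sqrt(vx * vy)
  r[!is.finite(r)] <- NA_real_
  pmin(pmax(r, -1), 1)
}

#' Partial Pearson correlation adjusting for one covariate
#'
#' Correlation between `x` and `y` after linearly removing `z` from both,
#' computed with the closed form
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` (identical to
#' correlating the residuals of the two regressions on `z`). Two-sided p from
#' the t distribution on n - 3 degrees of freedom; percentile bootstrap over
#' resampled triples.
#'
#' @param x,y numeric vectors.
#' @param z covariate (e.g. an ordinal MRI injury score treated as numeric).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed (default 1).
#' @param conf confidence level (default 0.95).
#' @return a `correlation_result` (with `partial = TRUE`). A zero-variance
#'   covariate falls back to the plain Pearson correlation with a warning; a
#'   covariate collinear with `x` or `y` gives `r = NA` with a warning.
#' @export
partial_pearson <- function(x, y, z, n_boot = 1000, seed = 1, conf = 0.95) {
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete triples")
  if (stats::sd(z) == 0) {
    warning("covariate has zero variance; returning plain Pearson correlation")
    return(pearson_with_bootstrap(x, y, n_boot = n_boot, seed = seed,
                                  conf = conf))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den < 1e-12) {
    warning("degenerate residuals: covariate collinear with x or y")
    return(new_correlation_result(NA_real_, NA_real_, c(NA_real_, NA_real_),
                                  n, partial = TRUE,
                                  covariate_name = deparse(substitute(z))))
  }
  r <- (rxy - rxz * ryz) / sqrt(den)
  tt <- r * sqrt((n - 3) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 3)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  rs <- boot_partial(matrix(x[idx], nrow = n), matrix(y[idx], nrow = n),
                     matrix(z[idx], nrow = n))
  ci <- stats::quantile(rs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  new_correlation_result(r, p, ci, n, partial = TRUE,
                         covariate_name = deparse(substitute(z)))
}

boot_partial <- function(xb, yb, zb) {
  colcor <- function(a, b) {
    ma <- colMeans(a); mb <- colMeans(b)
    (colMeans(a * b) - ma * mb) /
      sqrt((colMeans(a * a) - ma^2) * (colMeans(b * b) - mb^2))
  }
  rxy <- colcor(xb, yb); rxz <- colcor(xb, zb); ryz <- colcor(yb, zb)
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r[!is.finite(r)] <- NA_real_
  pmin(pmax(r, -1), 1)
}

#' ROC analysis with a sensitivity-first cutoff rule
#'
#' Treats HIGHER predictor values as predicting the abnormal class (the
#' empirical direction for burst power and adverse outcome; the direction is
#' fixed, not auto-oriented, so null data cannot silently inflate the AUC).
#' The AUC is the rank (Mann-Whitney) statistic, identical to the trapezoidal
#' area and invariant to strictly monotone transforms of the predictor. The
#' reported cutoff attains maximal sensitivity and, among thresholds tied on
#' sensitivity, maximal specificity: the cutoff that catches every abnormal
#' case with the least trade-off in specificity. A case is called abnormal
#' when `predictor >= cutoff`.
#'
#' @param predictor numeric predictor values (e.g. uV^2 burst power).
#' @param abnormal logical labels, `TRUE` = abnormal outcome.
#' @return object of class `roc_result`: list with `auc`, `thresholds`,
#'   `sensitivities`, `specificities`, `chosen_cutoff`, `chosen_sensitivity`,
#'   `chosen_specificity`, `n_abnormal`, `n_normal`.
#' @export
roc_analysis <- function(predictor, abnormal) {
  ok <- stats::complete.cases(predictor, abnormal)
  predictor <- predictor[ok]; abnormal <- as.logical(abnormal[ok])
  n1 <- sum(abnormal); n0 <- sum(!abnormal)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  rk <- rank(predictor)
  auc <- (sum(rk[abnormal]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(sort(unique(predictor)), Inf)
  sens <- vapply(thr, function(t) mean(predictor[abnormal] >= t), numeric(1L))
  spec <- vapply(thr, function(t) mean(predictor[!abnormal] < t), numeric(1L))
  best <- which(sens == max(sens))
  pick <- best[which.max(spec[best])]
  structure(list(auc = auc, thresholds = thr, sensitivities = sens,
                 specificities = spec, chosen_cutoff = thr[pick],
                 chosen_sensitivity = sens[pick],
                 chosen_specificity = spec[pick],
                 n_abnormal = n1, n_normal = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d abnormal / %d normal); cutoff %.3g: sensitivity %.0f%%, specificity %.1f%%\n",
              x$auc, x$n_abnormal, x$n_normal, x$chosen_cutoff,
              100 * x$chosen_sensitivity, 100 * x$chosen_specificity))
  invisible(x)
}

#' Sample size to detect a correlation (Fisher z approximation)
#'
#' Smallest n for which a two-sided test of a Pearson correlation of
#' magnitude `sqrt(r2)` at level `alpha` has at least the stated power:
#' `n = ceiling(((z_{1-alpha/2} + z_{power}) / atanh(sqrt(r2)))^2 + 3)`.
#' For an expected effect of R^2 = 0.26 with 80% power at alpha = .05 this
#' gives 28 infants.
#'
#' @param r2 expected squared correlation, in (0, 1).
#' @param power target power, in (0, 1) (default 0.80).
#' @param alpha two-sided significance level (default 0.05).
#' @return integer sample size.
#' @export
required_sample_size <- function(r2, power = 0.80, alpha = 0.05) {
  if (r2 <= 0 || r2 >= 1) stop("r2 must lie in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  zr <- atanh(sqrt(r2))
  as.integer(ceiling(((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
                        zr)^2 + 3))
}

#' Full burst-power / outcome analysis over a cohort table
#'
#' For every (channel, outcome) pair computes the plain Pearson correlation
#' and, when a covariate is given, the partial correlation adjusted for it;
#' for every outcome with an `abnormal_<outcome>` flag column, runs the ROC
#' analysis of that channel's power against the binary outcome. Incomplete
#' rows are dropped pairwise per analysis. No multiple-testing correction is
#' applied by default (each association is reported at its nominal level); a
#' Benjamini-Hochberg option is available.
#'
#' @param cohort data.frame as produced by [simulate_cohort()] (or any table
#'   with `power_<channel>` columns, outcome score columns, an optional
#'   covariate column and optional `abnormal_<outcome>` logical columns).
#' @param channels channel labels to analyse (default: all `power_*`
#'   columns).
#' @param outcomes outcome column names (default cognitive, motor, language).
#' @param covariate covariate column name for partial correlations, or `NULL`
#'   to skip adjustment (default `"mri_score"`).
#' @param n_boot bootstrap resamples per correlation (default 1000).
#' @param seed base RNG seed; each correlation uses `seed + row index` so the
#'   whole table is reproducible (default 1).
#' @param p_adjust `"none"` (default, nominal per-test inference) or `"BH"`.
#' @return object of class `outcome_analysis`: list with `correlations`
#'   (long-format data.frame: `channel`, `outcome`, `adjusted`, `r`, `p`,
#'   `ci_low`, `ci_high`, `n`, `significant`) and `roc` (`outcome`,
#'   `channel`, `auc`, `cutoff_uv2`, `sensitivity`, `specificity`).
#' @export
run_outcome_analysis <- function(cohort, channels = NULL,
                                 outcomes = c("cognitive", "motor",
                                              "language"),
                                 covariate = "mri_score",
                                 n_boot = 1000, seed = 1,
                                 p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (nrow(cohort) < 3L) stop("cohort must contain at least 3 infants")
  pw_cols <- grep("^power_", names(cohort), value = TRUE)
  if (is.null(channels)) channels <- sub("^power_", "", pw_cols)
  missing_ch <- setdiff(paste0("power_", channels), names(cohort))
  if (length(missing_ch))
    stop("cohort lacks column(s): ", paste(missing_ch, collapse = ", "))
  missing_oc <- setdiff(outcomes, names(cohort))
  if (length(missing_oc))
    stop("cohort lacks outcome column(s): ", paste(missing_oc, collapse = ", "))
  if (!is.null(covariate) && !covariate %in% names(cohort))
    stop("cohort lacks covariate column: ", covariate)

  rows <- list()
  k <- 0L
  for (ch in channels) {
    pw <- cohort[[paste0("power_", ch)]]
    for (oc in outcomes) {
      y <- cohort[[oc]]
      k <- k + 1L
      plain <- pearson_with_bootstrap(pw, y, n_boot = n_boot, seed = seed + k)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, outcome = oc, adjusted = FALSE, r = plain$r,
        p = plain$p, ci_low = plain$ci_low, ci_high = plain$ci_high,
        n = plain$n, significant = plain$significant)
      if (!is.null(covariate)) {
        k <- k + 1L
        adj <- partial_pearson(pw, y, cohort[[covariate]],
                               n_boot = n_boot, seed = seed + k)
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, outcome = oc, adjusted = TRUE, r = adj$r,
          p = adj$p, ci_low = adj$ci_low, ci_high = adj$ci_high,
          n = adj$n, significant = adj$significant)
      }
    }
  }
  cors <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    cors$p <- stats::p.adjust(cors$p, method = "BH")
    cors$significant <- !is.na(cors$p) & cors$p < 0.05 &
      (cors$ci_low > 0 | cors$ci_high < 0)
  }

  roc_rows <- list()
  for (oc in outcomes) {
    flag_col <- paste0("abnormal_", oc)
    if (!flag_col %in% names(cohort)) next
    lab <- cohort[[flag_col]]
    if (length(unique(lab[!is.na(lab)])) < 2L) next
    for (ch in channels) {
      rr <- roc_analysis(cohort[[paste0("power_", ch)]], lab)
      roc_rows[[length(roc_rows) + 1L]] <- data.frame(
        outcome = oc, channel = ch, auc = rr$auc,
        cutoff_uv2 = rr$chosen_cutoff,
        sensitivity = rr$chosen_sensitivity,
        specificity = rr$chosen_specificity)
    }
  }
  roc <- if (length(roc_rows)) do.call(rbind, roc_rows)
         else data.frame(outcome = character(0), channel = character(0),
                         auc = numeric(0), cutoff_uv2 = numeric(0),
                         sensitivity = numeric(0), specificity = numeric(0))
  rownames(cors) <- NULL
  rownames(roc) <- NULL
  structure(list(correlations = cors, roc = roc), class = "outcome_analysis")
}

#' @export
print.outcome_analysis <- function(x, ...) {
  cat("<outcome_analysis>\n")
  cat(sprintf("  %d correlation rows (%d significant), %d ROC rows\n",
              nrow(x$correlations), sum(x$correlations$significant,
                                        na.rm = TRUE), nrow(x$roc)))
  invisible(x)
}
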