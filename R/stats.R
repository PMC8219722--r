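#' @include AllClasses.R
NULL

.STD_BIAS_LABELS <- c("small", "moderate", "large", "very large",
                      "extremely large")

.stdBiasLabel <- function(sb) {
  .STD_BIAS_LABELS[findInterval(abs(sb), c(0.3, 0.6, 1.0, 2.0)) + 1L]
}

#' Intraclass correlation for two paired trials
#'
#' ICC(3,1): two-way mixed model, single measures, consistency — the form
#' appropriate when the two "raters" (analysis methods, investigators or
#' repeated runs) are the only ones of interest. The 95% compatibility
#' interval uses the F-distribution bounds on the ratio of the
#' between-subject to the residual mean square.
#'
#' For a sequence of more than two trials, apply this to each consecutive
#' pair (see [iccConsecutivePairwise()]).
#'
#' @param m a [PairedMeasurements-class].
#' @param conf confidence level (default 0.95).
#' @return named numeric `c(est, lo, hi)`.
#' @export
iccPairwise <- function(m, conf = 0.95) {
  stopifnot(is(m, "PairedMeasurements"))
  x <- cbind(m@trialA, m@trialB)
  n <- nrow(x); k <- 2L
  gm <- mean(x)
  ssSubj  <- k * sum((rowMeans(x) - gm)^2)
  ssTrial <- n * sum((colMeans(x) - gm)^2)
  ssTot   <- sum((x - gm)^2)
  ssErr   <- max(0, ssTot - ssSubj - ssTrial)
  df1 <- n - 1L; df2 <- (n - 1L) * (k - 1L)
  msr <- ssSubj / df1
  mse <- ssErr / df2
  if (msr == 0 && mse == 0) {
    warning("zero variance in both trials; ICC undefined")
    return(c(est = NaN, lo = NaN, hi = NaN))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  if (mse == 0) return(c(est = 1, lo = 1, hi = 1))
  a <- (1 - conf) / 2
  f  <- msr / mse
  fl <- f / stats::qf(1 - a, df1, df2)
  fu <- f * stats::qf(1 - a, df2, df1)
  c(est = icc,
    lo = (fl - 1) / (fl + k - 1),
    hi = (fu - 1) / (fu + k - 1))
}

#' Consecutive-pairwise ICC over a trial matrix
#'
#' @param trials numeric matrix, subjects in rows, trials in columns
#'   (>= 2 columns).
#' @param conf confidence level.
#' @return list of `c(est, lo, hi)` vectors, one per consecutive pair,
#'   named `"1-2"`, `"2-3"`, ...
#' @export
iccConsecutivePairwise <- function(trials, conf = 0.95) {
  trials <- as.matrix(trials)
  stopifnot(ncol(trials) >= 2L)
  out <- lapply(seq_len(ncol(trials) - 1L), function(j)
    iccPairwise(pairedMeasurements(trials[, j], trials[, j + 1]), conf))
  stats::setNames(out, paste(seq_len(ncol(trials) - 1L),
                             2:ncol(trials), sep = "-"))
}

#' Standard error of measurement (typical error)
#'
#' `SEM = SD(trialA - trialB) / sqrt(2)` — the within-subject typical
#' error of a single measurement, in cm^2. For two trials this equals the
#' square root of the residual mean square of the two-way ANOVA. The 95%
#' compatibility interval uses the chi-square bounds on a standard
#' deviation with `n - 1` degrees of freedom.
#'
#' @param m a [PairedMeasurements-class].
#' @param conf confidence level.
#' @return named numeric `c(est, lo, hi)`.
#' @export
semTypicalError <- function(m, conf = 0.95) {
  stopifnot(is(m, "PairedMeasurements"))
  d <- m@trialA - m@trialB
  n <- length(d)
  sem <- stats::sd(d) / sqrt(2)
  a <- (1 - conf) / 2
  c(est = sem,
    lo = sem * sqrt((n - 1) / stats::qchisq(1 - a, n - 1)),
    hi = sem * sqrt((n - 1) / stats::qchisq(a, n - 1)))
}

#' Minimal detectable change
#'
#' `MDC = SEM * 1.96 * sqrt(2)`: the smallest change in ACSA that exceeds
#' measurement noise with 95% confidence. Rounding happens only at
#' presentation.
#'
#' @param sem standard error of measurement (>= 0), cm^2.
#' @return MDC in cm^2.
#' @export
mdc <- function(sem) {
  if (any(!is.finite(sem)) || any(sem < 0)) stop("sem must be non-negative")
  sem * 1.96 * sqrt(2)
}

#' Bland-Altman agreement analysis
#'
#' Differences `trialA - trialB` against subject means: the mean
#' difference (bias), the 95% limits of agreement at `bias +/- 1.96 * SD`,
#' and an ordinary-least-squares proportional-bias check (slope of the
#' differences on the means with its two-sided p-value).
#'
#' @param m a [PairedMeasurements-class].
#' @return list with `bias`, `loa` (`c(low, high)`), `propSlope`, `propP`
#'   and a `table` data frame of per-subject `(mean, diff)` pairs.
#' @export
blandAltman <- function(m) {
  stopifnot(is(m, "PairedMeasurements"))
  d <- m@trialA - m@trialB
  mn <- (m@trialA + m@trialB) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- c(low = bias - 1.96 * s, high = bias + 1.96 * s)
  if (s > 0 && stats::sd(mn) > 0) {
    fit <- stats::lm(d ~ mn)
    cf <- summary(fit)$coefficients
    slope <- cf[2, 1]; p <- cf[2, 4]
  } else {
    slope <- 0; p <- NA_real_
  }
  list(bias = bias, loa = loa, propSlope = slope, propP = p,
       table = data.frame(subjectId = m@subjectId, mean = mn, diff = d))
}

#' Standardized mean bias
#'
#' The Bland-Altman bias expressed in units of the pooled between-subject
#' standard deviation of the two trials, with the magnitude labels
#' small / moderate / large / very large / extremely large at the
#' thresholds 0.3, 0.6, 1.0 and 2.0 (values below 0.1 are unambiguously
#' small). The compatibility interval transfers the t-based interval of
#' the raw bias onto the standardized scale.
#'
#' @param m a [PairedMeasurements-class].
#' @param conf confidence level.
#' @return list with `est` (`c(est, lo, hi)`) and `label`.
#' @export
standardizedBias <- function(m, conf = 0.95) {
  stopifnot(is(m, "PairedMeasurements"))
  d <- m@trialA - m@trialB
  n <- length(d)
  pooled <- sqrt((stats::var(m@trialA) + stats::var(m@trialB)) / 2)
  if (pooled == 0) {
    warning("zero between-subject variance; standardized bias undefined")
    return(list(est = c(est = NaN, lo = NaN, hi = NaN), label = NA_character_))
  }
  bias <- mean(d)
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(d) / sqrt(n)
  est <- c(est = bias, lo = bias - half, hi = bias + half) / pooled
  list(est = est, label = .stdBiasLabel(est[["est"]]))
}

#' Full reliability report for paired ACSA measurements
#'
#' Assembles the whole agreement/reliability battery — ICC(3,1), SEM (also
#' as a percentage of the grand mean), MDC, Bland-Altman bias and limits
#' of agreement, proportional-bias check and standardized mean bias — into
#' one [ReliabilityReport-class].
#'
#' @param m a [PairedMeasurements-class].
#' @param conf confidence level for all intervals.
#' @return a [ReliabilityReport-class].
#' @examples
#' pm <- generatePairedMeasurements(n = 30, subjectSd = 4,
#'                                  typicalError = 0.6, seed = 7)
#' reliabilityReport(pm)
#' @export
reliabilityReport <- function(m, conf = 0.95) {
  icc <- iccPairwise(m, conf)
  sem <- semTypicalError(m, conf)
  ba <- blandAltman(m)
  sb <- suppressWarnings(standardizedBias(m, conf))
  gm <- mean(c(m@trialA, m@trialB))
  new("ReliabilityReport", n = length(m@trialA),
      icc = unname(icc), semCm2 = unname(sem),
      semPct = 100 * sem[["est"]] / gm, mdcCm2 = mdc(sem[["est"]]),
      biasCm2 = ba$bias, loa = unname(ba$loa), stdBias = unname(sb$est),
      stdBiasLabel = sb$label %||% NA_character_,
      propSlope = ba$propSlope, propP = ba$propP)
}

#' Read paired measurements from CSV
#'
#' Expects a header row with columns `subject_id`, `trial_a`, `trial_b`.
#'
#' @param path CSV file path.
#' @return a [PairedMeasurements-class].
#' @export
readPairedMeasurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_a", "trial_b")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  pairedMeasurements(df$trial_a, df$trial_b, df$subject_id)
}

#' Write a reliability report to CSV or JSON
#'
#' @param report a [ReliabilityReport-class].
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
writeReliabilityReport <- function(report, path) {
  row <- data.frame(
    n = report@n,
    icc = report@icc[1], icc_lo = report@icc[2], icc_hi = report@icc[3],
    sem_cm2 = report@semCm2[1], sem_lo = report@semCm2[2],
    sem_hi = report@semCm2[3], sem_pct = report@semPct,
    mdc_cm2 = report@mdcCm2, bias_cm2 = report@biasCm2,
    loa_low = report@loa[1], loa_high = report@loa[2],
    std_bias = report@stdBias[1], std_bias_lo = report@stdBias[2],
    std_bias_hi = report@stdBias[3], std_bias_label = report@stdBiasLabel,
    prop_slope = report@propSlope, prop_p = report@propP)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(row), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(row, path, row.names = FALSE)
  }
  invisible(path)
}

#' Bland-Altman plot
#'
#' Differences against means with the bias (solid) and 95% limits of
#' agreement (dashed) drawn as horizontal lines.
#'
#' @param m a [PairedMeasurements-class].
#' @param path optional PNG path; when given the plot is written there.
#' @param ... passed to [graphics::plot()].
#' @return the [blandAltman()] list, invisibly.
#' @export
plotBlandAltman <- function(m, path = NULL, ...) {
  ba <- blandAltman(m)
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(ba$table$mean, ba$table$diff,
                 xlab = expression(paste("mean ACSA [", cm^2, "]")),
                 ylab = expression(paste("difference [", cm^2, "]")),
                 pch = 19, col = "grey30", ...)
  graphics::abline(h = ba$bias, lwd = 2)
  graphics::abline(h = ba$loa, lty = 2)
  invisible(ba)
}
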