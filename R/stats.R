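#' Summarize replicate measurements of a condition
#'
#' Mean and standard error of the mean (`sd / sqrt(n)`) over biological
#' replicates, as reported per experimental condition.
#'
#' @param values numeric replicate measurements, `n >= 2` (a single
#'   replicate has no SEM and is refused).
#' @param label condition label, e.g. `"control"`.
#' @param statistic name of the summarized statistic, e.g. `"alpha"`.
#' @return An object of class `condition_summary`: list with `label`,
#'   `statistic`, `values`, `mean`, `sem`, `n`.
#' @examples
#' summarize_replicates(c(2, 4, 6), "control", "alpha")
#' @export
summarize_replicates <- function(values, label = "condition",
                                 statistic = "value") {
  stopifnot(is.numeric(values), all(is.finite(values)))
  n <- length(values)
  if (n < 2) stop("need at least 2 replicates to report a SEM")
  structure(list(label = label, statistic = statistic, values = values,
                 mean = mean(values), sem = stats::sd(values) / sqrt(n),
                 n = n),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("%s %s: %.4g +/- %.3g (SEM), n = %d\n",
              x$label, x$statistic, x$mean, x$sem, x$n))
  invisible(x)
}

#' Paired two-tailed t-test
#'
#' Textbook paired t statistic `t = mean(d) / (sd(d)/sqrt(n))` on the
#' replicate-wise differences `d = a - b`, with the two-tailed p-value
#' from the t distribution on `n - 1` degrees of freedom. Degenerate
#' inputs are flagged instead of raising, so batch pipelines complete:
#' identical vectors give `p = 1`, nonzero constant differences give
#' `p = 0`, both with `degenerate = TRUE`.
#'
#' @param a,b numeric vectors of equal length `n >= 2`, paired by
#'   replicate index.
#' @return List with `statistic`, `df`, `p_value`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b),
            length(a) >= 2, all(is.finite(a)), all(is.finite(b)))
  d <- a - b
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    degenerate_p <- if (all(d == 0)) 1 else 0
    return(list(statistic = NA_real_, df = n - 1, p_value = degenerate_p,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tstat <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  list(statistic = tstat, df = n - 1, p_value = p,
       mean_difference = mean(d), degenerate = FALSE)
}

#' Treated-over-control ratio of a statistic
#'
#' Ratio of condition means, e.g. alpha_treated / alpha_control as a
#' measure of the relative effect of a treatment. Scale-invariant:
#' rescaling all replicate values by a common factor leaves it
#' unchanged.
#'
#' @param treated,control [summarize_replicates()] objects or numeric
#'   replicate vectors.
#' @return Ratio of means (dimensionless).
#' @export
treatment_ratio <- function(treated, control) {
  mean_of <- function(x) {
    if (inherits(x, "condition_summary")) x$mean else mean(as.numeric(x))
  }
  mc <- mean_of(control)
  if (mc == 0) stop("control mean is zero: ratio undefined")
  mean_of(treated) / mc
}

#' Cell viability percentage
#'
#' `CV(%) = absorbance(test) / absorbance(control) * 100`, the standard
#' normalization of tetrazolium-reduction (MTT) readouts. Vectorized.
#' Group-wise ANOVA with post-hoc correction across dose/time panels is
#' deliberately not provided here; use `stats::aov` directly on the raw
#' absorbances if needed.
#'
#' @param abs_test absorbance of the test sample(s).
#' @param abs_control absorbance of the control, `> 0`.
#' @return Viability in percent.
#' @examples
#' viability_percent(0.25, 0.5)  # 50
#' @export
viability_percent <- function(abs_test, abs_control) {
  stopifnot(all(abs_control > 0))
  abs_test / abs_control * 100
}
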