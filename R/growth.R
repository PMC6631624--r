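#' Cell-count growth curve
#'
#' @param times strictly increasing sampling times (h).
#' @param counts positive cell counts, same length as `times`.
#' @return A data.frame with columns `time_h`, `count` and class
#'   `growth_curve`.
#' @export
growth_curve <- function(times, counts) {
  stopifnot(length(times) == length(counts), length(times) >= 1,
            all(diff(times) > 0), all(counts > 0))
  structure(data.frame(time_h = as.numeric(times),
                       count = as.numeric(counts)),
            class = c("growth_curve", "data.frame"))
}

#' Simulate an exponential growth curve
#'
#' Draws counts from the doubling law `n(t) = n0 * 2^(t/tau)` with
#' multiplicative lognormal noise of coefficient of variation
#' `noise_cv` (mean-one multipliers, so the expectation stays on the
#' doubling law). With `noise_cv = 0` the curve is exact.
#'
#' @param n0 initial cell count, `> 0`.
#' @param tau population doubling time (h), `> 0`.
#' @param times sampling times (h), strictly increasing, starting at the
#'   time `n0` refers to.
#' @param noise_cv coefficient of variation of the multiplicative noise,
#'   `>= 0`.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return A [growth_curve()].
#' @examples
#' simulate_growth_curve(100, tau = 24, times = c(0, 24, 48), noise_cv = 0)
#' @export
simulate_growth_curve <- function(n0, tau, times, noise_cv = 0, seed = 1L) {
  stopifnot(n0 > 0, tau > 0, noise_cv >= 0, length(times) >= 1,
            all(diff(times) > 0))
  mean_counts <- n0 * 2^((times - times[1]) / tau)
  if (noise_cv == 0) return(growth_curve(times, mean_counts))
  sdlog <- sqrt(log(1 + noise_cv^2))
  counts <- withr::with_seed(as.integer(seed), {
    mean_counts * stats::rlnorm(length(times),
                                meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })
  growth_curve(times, counts)
}

#' Write / read a growth curve as CSV
#'
#' Plain CSV with columns `time_h`, `count`.
#'
#' @param curve [growth_curve()].
#' @param path CSV path.
#' @return `path` (write) or a [growth_curve()] (read).
#' @export
write_growth_curve <- function(curve, path) {
  stopifnot(inherits(curve, "growth_curve"))
  utils::write.csv(as.data.frame(unclass(curve)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_curve
#' @export
read_growth_curve <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_h", "count") %in% names(df)))
  growth_curve(df$time_h, df$count)
}
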