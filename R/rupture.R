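#' Two-component model of paired-filament-complex rupture times
#'
#' Most tensed paired filament complexes (PFCs) rupture after dozens of
#' seconds (observed median 26-29 s), while a small population is long
#' lived, persisting for over six minutes. This is modelled as a mixture of
#' two exponential lifetimes parameterized by their medians.
#'
#' @param median_main Median of the main (short-lived) component, seconds.
#' @param tail_fraction Probability of drawing from the long-lived tail.
#' @param tail_scale Median of the long-lived component, seconds.
#' @return An object of class `rupture_model`.
#' @export
rupture_model <- function(median_main = 27, tail_fraction = 0.05,
                          tail_scale = 400) {
  check_scalar(median_main, "median_main", lower = 0, strict_lower = TRUE)
  check_scalar(tail_fraction, "tail_fraction", lower = 0, upper = 1)
  check_scalar(tail_scale, "tail_scale", lower = 0, strict_lower = TRUE)
  structure(list(median_main = median_main, tail_fraction = tail_fraction,
                 tail_scale = tail_scale), class = "rupture_model")
}

#' Sample PFC rupture times
#'
#' Draws `count` rupture times (seconds) from the exponential mixture of a
#' [rupture_model()]: with probability `1 - tail_fraction` from the main
#' component (median `median_main`), otherwise from the long-lived tail
#' (median `tail_scale`). An exponential with median m has rate log(2)/m.
#'
#' @param model A [rupture_model()].
#' @param count Number of draws (>= 1).
#' @param seed Integer seed; draws are reproducible.
#' @return Numeric vector of times in seconds.
#' @export
sample_rupture_times <- function(model, count, seed = 1L) {
  stopifnot(inherits(model, "rupture_model"))
  check_scalar(count, "count", lower = 1)
  count <- as.integer(count)
  with_seed(seed, {
    tail <- stats::runif(count) < model$tail_fraction
    med <- ifelse(tail, model$tail_scale, model$median_main)
    stats::rexp(count, rate = log(2) / med)
  })
}
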