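#' Census of filament complexes and rupture-time summary
#'
#' Summarizes per-object annotations of a field of view: how many
#' complexes are singly bound versus paired (PFCs), and the distribution
#' of PFC rupture times. Objects are annotated at a reference frame
#' (frame 10 by convention) and followed to the last frame where the
#' intact complex was observed; the rupture time is
#' `(last_intact_frame - reference_frame) * frame_interval` seconds.
#' Right-censored records (complexes still intact at the end of the
#' recording) enter the Kaplan-Meier survival estimate as censored.
#'
#' @param annotations Data frame with columns `type` (`"single"` or
#'   `"paired"`), `last_intact_frame`, optionally `censored` (logical,
#'   default all observed).
#' @param frame_interval Seconds per frame (default 2).
#' @param reference_frame Reference frame for time zero (default 10).
#' @return List with `n_total`, `n_single`, `n_paired`, `paired_fraction`,
#'   `rupture_times_s`, `median_rupture_s` (Kaplan-Meier median), and
#'   `survival` (data frame `time`, `surv`, `n_risk`, `n_event`).
#' @export
pfc_census <- function(annotations, frame_interval = 2, reference_frame = 10) {
  if (!all(c("type", "last_intact_frame") %in% names(annotations)))
    stopf("annotations need columns `type` and `last_intact_frame`")
  if (!all(annotations$type %in% c("single", "paired")))
    stopf("`type` must be 'single' or 'paired'")
  check_scalar(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  n_total <- nrow(annotations)
  n_paired <- sum(annotations$type == "paired")
  out <- list(n_total = n_total,
              n_single = n_total - n_paired,
              n_paired = n_paired,
              paired_fraction = if (n_total) n_paired / n_total else NA_real_)
  p <- annotations[annotations$type == "paired", , drop = FALSE]
  if (nrow(p)) {
    times <- (p$last_intact_frame - reference_frame) * frame_interval
    if (any(times < 0))
      stopf("negative rupture time: `last_intact_frame` before the reference frame")
    event <- if ("censored" %in% names(p)) !p$censored else rep(TRUE, nrow(p))
    fit <- survival::survfit(survival::Surv(times, event) ~ 1)
    st <- summary(fit)$table
    out$rupture_times_s <- times
    out$median_rupture_s <- unname(st["median"])
    out$survival <- data.frame(time = fit$time, surv = fit$surv,
                               n_risk = fit$n.risk, n_event = fit$n.event)
  } else {
    out$rupture_times_s <- numeric(0)
    out$median_rupture_s <- NA_real_
    out$survival <- data.frame(time = numeric(0), surv = numeric(0),
                               n_risk = numeric(0), n_event = numeric(0))
  }
  out
}
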