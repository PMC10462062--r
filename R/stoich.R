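# Filament stoichiometry and load-sharing helpers.

#' Actin subunits in a filament of given length
#'
#' F-actin adds one subunit per 2.73 nm of filament length (the rise
#' between subunits on adjacent strands of the double helix), so a
#' filament of `length` micrometres contains `1000 * length / rise`
#' subunits. An 8.6 um filament gives ~3150 subunits, i.e. approximately
#' 3,000 at one significant figure.
#'
#' @param length Filament length in micrometres (> 0).
#' @param rise Rise per subunit in nanometres (default 2.73).
#' @param rounding `"none"` (real count), `"nearest"` (nearest integer) or
#'   `"signif1"` (one significant figure).
#' @return Subunit count.
#' @examples
#' subunits_from_length(8.6, rounding = "signif1") # 3000
#' @export
subunits_from_length <- function(length, rise = 2.73,
                                 rounding = c("none", "nearest", "signif1")) {
  rounding <- match.arg(rounding)
  check_scalar(length, "length", lower = 0, strict_lower = TRUE)
  check_scalar(rise, "rise", lower = 0, strict_lower = TRUE)
  count <- 1000 * length / rise
  switch(rounding,
         none = count,
         nearest = round(count),
         signif1 = signif(count, 1))
}

#' Filament barbed-end concentration
#'
#' With one trackable barbed end per filament, the end concentration is
#' the total G-actin concentration used in polymerization divided by the
#' subunits per filament.
#'
#' @param total_actin_conc Actin concentration (molar, > 0).
#' @param subunits_per_filament Subunits per filament (> 0).
#' @return Barbed-end concentration (molar).
#' @examples
#' end_concentration(1e-6, 1000) # 1e-9 (1 nM)
#' @export
end_concentration <- function(total_actin_conc, subunits_per_filament) {
  check_scalar(total_actin_conc, "total_actin_conc", lower = 0,
               strict_lower = TRUE)
  check_scalar(subunits_per_filament, "subunits_per_filament", lower = 0,
               strict_lower = TRUE)
  total_actin_conc / subunits_per_filament
}

#' Load borne per filament in a bundle
#'
#' A bundle of `n` filaments under total tension `F_total` shares the load
#' equally, so each filament bears `F_total / n` — smaller bundles bear a
#' higher load per filament, the quantity hypothesized to drive
#' small-bundle enrichment of force-activated binders.
#'
#' @param F_total Total tension on the segment (>= 0).
#' @param n Filament count (>= 1). Vectorized.
#' @return Per-filament load.
#' @export
per_filament_load <- function(F_total, n) {
  if (any(!is.finite(F_total)) || any(F_total < 0))
    stopf("`F_total` must be finite and >= 0")
  if (any(!is.finite(n)) || any(n < 1)) stopf("`n` must be >= 1")
  F_total / n
}

#' Stoichiometry summary table
#'
#' Convenience table combining the helpers: subunit count for a median
#' filament length, the implied barbed-end concentration, and per-filament
#' loads for a range of bundle sizes.
#'
#' @param median_length_um Median filament length (um).
#' @param rise_nm Rise per subunit (nm).
#' @param actin_conc_M Polymerization actin concentration (molar).
#' @param F_total Total segment tension for the load column.
#' @param bundle_sizes Bundle sizes for the load column.
#' @return Data frame with one row per bundle size plus the scalar
#'   estimates as attributes `subunits` and `end_conc_M`.
#' @export
stoich_table <- function(median_length_um = 8.6, rise_nm = 2.73,
                         actin_conc_M = 1e-6, F_total = 6,
                         bundle_sizes = 1:6) {
  subs <- subunits_from_length(median_length_um, rise_nm)
  ec <- end_concentration(actin_conc_M, subs)
  out <- data.frame(n = bundle_sizes,
                    per_filament_load = per_filament_load(F_total, bundle_sizes))
  structure(out, subunits = subs, end_conc_M = ec)
}
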