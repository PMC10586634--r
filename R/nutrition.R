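# Feed-chemistry and marker-based digestibility arithmetic, on a dry-matter
# basis throughout.

#' Non-fibrous carbohydrates by difference
#'
#' `NFC = 1000 - (CP + EE + NDFap + ash)`, all in g/kg DM, so the proximate
#' composition closes to 1000 g/kg.
#'
#' @param cp Crude protein (g/kg DM).
#' @param ee Ether extract (g/kg DM).
#' @param ndfap Neutral detergent fiber corrected for ash and protein
#'   (g/kg DM).
#' @param ash Crude ash (g/kg DM).
#' @return NFC in g/kg DM (vectorized).
#' @examples
#' compute_nfc(116, 31, 364, 59)  # 430
#' @export
compute_nfc <- function(cp, ee, ndfap, ash) {
  inputs <- cbind(cp, ee, ndfap, ash)
  if (any(inputs < 0)) stop("composition fractions must be nonnegative")
  total <- cp + ee + ndfap + ash
  if (any(total > 1000))
    stop("impossible composition: components exceed 1000 g/kg DM")
  1000 - total
}

#' Fecal dry-matter excretion from an indigestible internal marker
#'
#' With indigestible NDF (iNDF) as an internal marker assumed fully recovered
#' in feces, fecal DM output is the marker intake divided by the fecal marker
#' concentration.
#'
#' @param indf_intake Marker (iNDF) intake, g/day.
#' @param fecal_indf_conc Fecal marker concentration, g/g fecal DM, in (0, 1].
#' @param marker_recovery Assumed fractional marker recovery (default 1, the
#'   standard assumption for 240-h iNDF).
#' @return Fecal DM excretion, g/day.
#' @export
fecal_dm_excretion <- function(indf_intake, fecal_indf_conc,
                               marker_recovery = 1) {
  if (any(indf_intake < 0)) stop("marker intake must be nonnegative")
  if (any(fecal_indf_conc <= 0))
    stop("fecal marker concentration must be strictly positive")
  indf_intake * marker_recovery / fecal_indf_conc
}

#' Apparent digestibility coefficient
#'
#' `digestibility = 1 - fecal output / intake` for a feed component. Fecal
#' output exceeding intake is clipped to intake with a warning (apparent
#' digestibility floored at 0).
#'
#' @param intake_component Component intake, g/day (> 0).
#' @param fecal_output_component Component fecal output, g/day.
#' @return Digestibility as a proportion (vectorized).
#' @export
digestibility <- function(intake_component, fecal_output_component) {
  if (any(intake_component <= 0)) stop("intake must be strictly positive")
  if (any(fecal_output_component < 0)) stop("fecal output must be nonnegative")
  over <- fecal_output_component > intake_component
  if (any(over)) {
    warning("fecal output exceeds intake for ", sum(over),
            " record(s); clipped to intake", call. = FALSE)
    fecal_output_component <- pmin(fecal_output_component, intake_component)
  }
  1 - fecal_output_component / intake_component
}

#' Total digestible nutrients
#'
#' `TDN = digestible CP + digestible NFC + digestible NDFap +
#' 2.25 x digestible EE`, the conventional energy proxy with the 2.25 fat
#' multiplier. Units follow the inputs (g/day in, g/day out).
#'
#' @param dig_cp,dig_nfc,dig_ndfap,dig_ee Digestible intakes of crude
#'   protein, non-fibrous carbohydrates, NDFap and ether extract.
#' @return TDN intake in the units of the inputs.
#' @export
tdn_intake <- function(dig_cp, dig_nfc, dig_ndfap, dig_ee) {
  if (any(c(dig_cp, dig_nfc, dig_ndfap, dig_ee) < 0))
    stop("digestible intakes must be nonnegative")
  dig_cp + dig_nfc + dig_ndfap + 2.25 * dig_ee
}

#' Per-animal digestibility and TDN from marker records
#'
#' Applies the full marker arithmetic to a table shaped like the `records`
#' element of [simulate_nutrition()]: fecal DM from the iNDF marker, then the
#' apparent digestibility of DM and each component from its fecal
#' concentration, then TDN intake.
#'
#' @param records Data frame with columns `intake_dm`, `intake_cp`,
#'   `intake_ee`, `intake_ndfap`, `intake_nfc`, `indf_intake`,
#'   `fecal_indf_conc` and `fecal_<comp>_conc` for each component.
#' @return The table augmented with `fecal_dm`, `dig_dm`, `dig_cp`, `dig_ee`,
#'   `dig_ndfap`, `dig_nfc` and `tdn_g_day`.
#' @export
digestibility_analysis <- function(records) {
  fecal_dm <- fecal_dm_excretion(records$indf_intake, records$fecal_indf_conc)
  out <- records
  out$fecal_dm <- fecal_dm
  out$dig_dm <- digestibility(records$intake_dm, fecal_dm)
  for (comp in c("cp", "ee", "ndfap", "nfc")) {
    fec <- fecal_dm * records[[paste0("fecal_", comp, "_conc")]]
    out[[paste0("dig_", comp)]] <-
      digestibility(records[[paste0("intake_", comp)]], fec)
  }
  out$tdn_g_day <- tdn_intake(out$dig_cp * records$intake_cp,
                              out$dig_nfc * records$intake_nfc,
                              out$dig_ndfap * records$intake_ndfap,
                              out$dig_ee * records$intake_ee)
  out
}
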