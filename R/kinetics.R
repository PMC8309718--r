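#' Mean tumor attenuation of one phase
#'
#' @param volume A `rccad_volume`.
#' @param mask An aligned `rccad_mask`.
#' @return Mean HU over the mask voxels.
#' @export
mean_attenuation <- function(volume, mask) {
  stopifnot(inherits(volume, "rccad_volume"), inherits(mask, "rccad_mask"))
  check_aligned(volume, mask)
  mean(volume$grid[mask$grid])
}

#' Three-phase enhancement curve
#'
#' Collects (acquisition time, mean tumor attenuation) samples for the
#' precontrast, portal-venous and delayed phases, time-ascending.
#'
#' @param volumes List of three `rccad_volume`s (any order; sorted by time).
#' @param mask The shared `rccad_mask`.
#' @return A tibble of class `rccad_curve` with columns `phase`, `time`
#'   (seconds) and `mean_hu`.
#' @export
enhancement_curve <- function(volumes, mask) {
  if (length(volumes) != 3) abort("an enhancement curve needs exactly 3 phases")
  tb <- tibble(
    phase = vapply(volumes, function(v) v$phase, character(1)),
    time = vapply(volumes, function(v) v$acquisition_time, numeric(1)),
    mean_hu = vapply(volumes, mean_attenuation, numeric(1), mask = mask)
  )
  tb <- dplyr::arrange(tb, .data$time)
  if (any(diff(tb$time) <= 0)) abort("acquisition times must be strictly increasing")
  if (any(!is.finite(tb$mean_hu))) abort("mean attenuations must be finite")
  class(tb) <- c("rccad_curve", class(tb))
  tb
}

#' Wash-in / wash-out enhancement slopes
#'
#' Wash-in is the rate of attenuation increase from the precontrast to the
#' portal-venous phase; wash-out the rate of decrease from portal-venous to
#' delayed (positive when attenuation falls; a negative wash-out flags a
#' still-enhancing lesion and is passed through, not clipped):
#' `wash_in = (HU_pv - HU_pre) / (t_pv - t_pre)`,
#' `wash_out = (HU_pv - HU_del) / (t_del - t_pv)`.
#' With the default 0 / 80 / 300 s protocol the denominators are 80 s and
#' 220 s. Both slopes depend only on attenuation differences, so they are
#' invariant to a constant HU offset.
#'
#' @param curve A `rccad_curve` (or 3-row data frame with `time`, `mean_hu`).
#' @return A one-row tibble with `wash_in` and `wash_out` (HU/s).
#' @examples
#' curve <- tibble::tibble(time = c(0, 80, 300), mean_hu = c(30, 110, 88))
#' kinetic_features(curve) # wash_in 1.0, wash_out 0.1
#' @export
kinetic_features <- function(curve) {
  if (nrow(curve) != 3) abort("an enhancement curve needs exactly 3 samples")
  curve <- curve[order(curve$time), ]
  if (any(diff(curve$time) <= 0)) abort("acquisition times must be strictly increasing")
  hu <- unname(curve$mean_hu)
  t <- unname(curve$time)
  tibble(wash_in = (hu[2] - hu[1]) / (t[2] - t[1]),
         wash_out = (hu[2] - hu[3]) / (t[3] - t[2]))
}
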