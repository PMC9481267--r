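#' Anatomical foot zones
#'
#' The ten anatomical zones that pressure-plate software segments a footprint
#' into: the hallux (toe 1), toes 2-5, the five metatarsal heads, the midfoot
#' and the medial/lateral heel. `forefoot_zones()` returns the subset (toes
#' and metatarsal heads) on which the synthetic injury effect acts.
#'
#' @return A character vector of zone identifiers.
#' @export
#' @examples
#' foot_zones()
foot_zones <- function() {
  c("toe_1", "toes_2_5",
    "metatarsal_1", "metatarsal_2", "metatarsal_3", "metatarsal_4",
    "metatarsal_5", "midfoot", "medial_heel", "lateral_heel")
}

#' @rdname foot_zones
#' @export
forefoot_zones <- function() {
  c("toe_1", "toes_2_5",
    "metatarsal_1", "metatarsal_2", "metatarsal_3", "metatarsal_4",
    "metatarsal_5")
}

.measurements <- c("peak_pressure", "mean_pressure", "mean_force")

#' Default zone activation templates
#'
#' One row per anatomical zone with its activation window as fractions of
#' stance duration, relative mean-pressure amplitude, ratio of peak to mean
#' pressure within the zone, and contact area in cm^2. The timing defaults
#' encode a heel-to-toe roll-off: heels load first (0-40% of stance), then
#' the midfoot (20-60%), the metatarsal heads (30-90%) and finally the toes
#' (55-100%). Amplitudes are relative weights; the absolute scale is
#' calibrated per subject so the simulated vertical-force peak hits the
#' configured multiple of body weight.
#'
#' @return A tibble with columns `zone`, `onset_frac`, `offset_frac`,
#'   `amplitude`, `peak_factor`, `area`.
#' @export
#' @examples
#' default_zone_templates()
default_zone_templates <- function() {
  tibble::tibble(
    zone = c("medial_heel", "lateral_heel", "midfoot",
             "metatarsal_1", "metatarsal_2", "metatarsal_3",
             "metatarsal_4", "metatarsal_5", "toe_1", "toes_2_5"),
    onset_frac  = c(0.00, 0.00, 0.20, 0.30, 0.30, 0.30, 0.30, 0.30, 0.55, 0.55),
    offset_frac = c(0.40, 0.40, 0.60, 0.90, 0.90, 0.90, 0.90, 0.90, 1.00, 1.00),
    amplitude   = c(1.00, 0.90, 0.35, 0.90, 1.00, 0.95, 0.80, 0.60, 0.85, 0.45),
    peak_factor = c(1.8,  1.8,  1.4,  2.1,  2.2,  2.1,  2.0,  2.0,  1.9,  1.9),
    area        = c(14,   13,   25,   7,    8,    8,    7,    6,    9,    12)
  )
}

check_zone_templates <- function(templates) {
  missing <- setdiff(foot_zones(), templates$zone)
  if (length(missing) > 0) {
    abort(paste0("zone template missing for: ", paste(missing, collapse = ", ")))
  }
  if (any(templates$onset_frac < 0) || any(templates$offset_frac > 1) ||
      any(templates$onset_frac >= templates$offset_frac)) {
    abort("zone templates must satisfy 0 <= onset_frac < offset_frac <= 1")
  }
  if (any(templates$area <= 0)) abort("zone areas must be positive")
  if (any(templates$peak_factor < 1)) abort("peak_factor must be >= 1")
  invisible(templates)
}
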