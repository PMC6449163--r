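# Published regression coefficients mapping three transverse-plane
# anatomical shape ratios (CA1, CA3, DG) to the relative longitudinal
# position of a slice on the dorsoventral axis, in mm (dorsal positive).
POSITION_COEF <- c(intercept = -7.23, ca1 = 0.43, ca3 = 0.50, dg = 0.34)

# Longitudinal zone bins (mm): four contiguous 1.5-mm bins reconstructed
# around the published dorsal (about 2 mm) and ventral (about -2.5 mm)
# midpoints; each bin is closed at its dorsal edge. Positions on the
# remainder of the ~8-mm axis fall "outside".
POSITION_ZONES <- data.frame(
  zone = c("dorsal", "dorsal-intermediate", "ventral-intermediate",
           "ventral"),
  lo = c(1.25, -0.25, -1.75, -3.25),
  hi = c(2.75, 1.25, -0.25, -1.75)
)

#' Longitudinal slice position from anatomical shape ratios
#'
#' Evaluates the published linear model
#' `position = -7.23 + 0.43*CA1 + 0.50*CA3 + 0.34*DG` (mm, dorsal
#' positive), where the three predictors are transverse-to-radial length
#' ratios measured in the slice for CA1, CA3, and the dentate gyrus.
#'
#' @param ca1,ca3,dg Anatomical shape ratios (finite, >= 0). Vectorized.
#' @return Predicted position(s) in mm.
#' @examples
#' longitudinal_position(0, 0, 0)   # the model intercept, -7.23 mm
#' @export
longitudinal_position <- function(ca1, ca3, dg) {
  r <- cbind(ca1, ca3, dg)
  if (any(!is.finite(r)) || any(r < 0))
    stop("longitudinal_position: ratios must be finite and >= 0")
  unname(POSITION_COEF["intercept"] + POSITION_COEF["ca1"] * ca1 +
         POSITION_COEF["ca3"] * ca3 + POSITION_COEF["dg"] * dg)
}

#' Classify a longitudinal position into a dorsoventral zone
#'
#' Bins the axis into four contiguous 1.5-mm zones — dorsal
#' \[1.25, 2.75\], dorsal-intermediate \[-0.25, 1.25), ventral-intermediate
#' \[-1.75, -0.25), ventral \[-3.25, -1.75) — with anything beyond the
#' binned 6-mm span labeled `"outside"`. Bins are closed at their dorsal
#' edge so boundary positions classify deterministically.
#'
#' @param position Position(s) in mm, dorsal positive.
#' @return Character vector of zone labels.
#' @export
classify_zone <- function(position) {
  vapply(position, function(p) {
    if (!is.finite(p)) stop("classify_zone: non-finite position")
    if (p >= POSITION_ZONES$lo[1] & p <= POSITION_ZONES$hi[1])
      return(POSITION_ZONES$zone[1])
    for (k in 2:nrow(POSITION_ZONES)) {
      if (p >= POSITION_ZONES$lo[k] && p < POSITION_ZONES$hi[k])
        return(POSITION_ZONES$zone[k])
    }
    "outside"
  }, character(1))
}

#' Full position estimate for one slice
#'
#' Combines [longitudinal_position()] and [classify_zone()]. The
#' `uncertainty_mm` field carries the published calibration accuracy of
#' the source model (+/-0.59 mm at 90% confidence); it is metadata, not
#' recomputed here.
#'
#' @param ca1,ca3,dg Anatomical shape ratios.
#' @return List with `position_mm`, `zone`, `uncertainty_mm`,
#'   `confidence`.
#' @export
position_estimate <- function(ca1, ca3, dg) {
  p <- longitudinal_position(ca1, ca3, dg)
  list(position_mm = p, zone = classify_zone(p),
       uncertainty_mm = 0.59, confidence = 0.90)
}
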