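#' Stem volume from DBH and height
#'
#' Species-specific individual-tree volume,
#' \eqn{V = 3.69 \times 10^{-5} \cdot DBH^2 \cdot H}, with DBH in cm and
#' height in m, giving m\eqn{^3}. The constant is treated as exact.
#'
#' @param dbh Diameter at breast height (cm), non-negative.
#' @param height Total tree height (m), non-negative.
#' @return Stem volume in m\eqn{^3}. Vectorized.
#' @examples
#' stem_volume(20.90, 19.5)  # 0.3143 m^3
#' @export
stem_volume <- function(dbh, height) {
  if (any(dbh < 0, na.rm = TRUE) || any(height < 0, na.rm = TRUE)) {
    stop("dbh and height must be non-negative", call. = FALSE)
  }
  3.69e-5 * dbh^2 * height
}

#' Wood basic density from the water-displacement measurements
#'
#' \eqn{WBD = w_2 / w_1}: oven-dry weight over green volume, where the
#' green volume is measured as displaced water (numerically equal in g and
#' cm\eqn{^3}), so the result is in g/cm\eqn{^3}.
#'
#' @param w1 Displaced-water measure (green volume), > 0.
#' @param w2 Oven-dry weight (g), >= 0.
#' @return Wood basic density (g/cm\eqn{^3}). Vectorized.
#' @export
wood_basic_density <- function(w1, w2) {
  if (any(w1 <= 0, na.rm = TRUE)) stop("w1 must be positive", call. = FALSE)
  if (any(w2 < 0, na.rm = TRUE)) stop("w2 must be non-negative", call. = FALSE)
  w2 / w1
}

#' Cellulose crystallinity from X-ray diffraction intensities
#'
#' \eqn{Cr = (I_u - I_a)/I_u \times 100\%}, where \eqn{I_u} is the
#' integrated intensity of the crystalline diffraction maximum near
#' 2\eqn{\theta} = 22 degrees and \eqn{I_a} the amorphous-scatter trough
#' near 18 degrees. Scale-invariant in (\eqn{I_u}, \eqn{I_a}).
#'
#' @param iu Integrated peak intensity, > 0.
#' @param ia Integrated trough intensity, in `[0, iu]`.
#' @return Crystallinity in percent. Vectorized.
#' @export
crystallinity <- function(iu, ia) {
  if (any(iu <= 0, na.rm = TRUE)) stop("iu must be positive", call. = FALSE)
  if (any(ia < 0 | ia > iu, na.rm = TRUE)) {
    stop("ia must lie in [0, iu]", call. = FALSE)
  }
  100 * (iu - ia) / iu
}

#' Slenderness ratios of a wood sample
#'
#' Adds the fiber and vessel slenderness ratios FL/FD and VL/VD, computed
#' per tree. Provenance means of ratio traits are means of per-tree ratios
#' (not ratios of means), the convention used throughout the package.
#'
#' @param sample Wood-schema `data.frame` with columns `fl`, `fd`, `vl`, `vd`.
#' @return `sample` with `fl_fd` and `vl_vd` columns filled in.
#' @export
trait_ratios <- function(sample) {
  if (any(sample$fd <= 0, na.rm = TRUE) || any(sample$vd <= 0, na.rm = TRUE)) {
    stop("fd and vd must be positive", call. = FALSE)
  }
  sample$fl_fd <- sample$fl / sample$fd
  sample$vl_vd <- sample$vl / sample$vd
  sample
}

#' Derive stem volume for a growth table
#'
#' Fills the `volume` column of growth-schema records from `dbh` and
#' `height`; dead trees keep NA.
#'
#' @param records Growth-schema `data.frame`.
#' @return `records` with a `volume` column (m\eqn{^3}).
#' @export
derive_volume <- function(records) {
  records$volume <- ifelse(records$alive & !is.na(records$dbh) &
                             !is.na(records$height),
                           stem_volume(ifelse(is.na(records$dbh), 0, records$dbh),
                                       ifelse(is.na(records$height), 0, records$height)),
                           NA_real_)
  records
}
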