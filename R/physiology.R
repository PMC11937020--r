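#' Photosynthetic pigment contents from extract absorbances
#'
#' Converts absorbances of an ethanol/acetone leaf extract at 474, 642 and
#' 665 nm into pigment concentrations (mg/L) with the standard
#' spectrophotometric equations
#' \deqn{C_a = 9.99 A_{665} - 0.0872 A_{642}}
#' \deqn{C_b = 17.7 A_{642} - 3.04 A_{665}}
#' \deqn{C_c = 4.92 A_{474} - 0.0255 C_a - 0.225 C_b}
#' and then into contents (mg per g fresh leaf) as `C * V / mass`.
#' Total chlorophyll is a + b; total pigment adds the carotenoids.
#'
#' Unusual absorbance combinations can yield a negative concentration; the
#' value is reported with a warning rather than truncated, to keep the
#' audit trail intact.
#'
#' @param A474,A642,A665 absorbances (dimensionless, >= 0); vectorised.
#' @param V extract volume in litres (default 0.015 L, the protocol's 15 mL).
#' @param mass leaf mass in grams (default 0.1 g).
#' @return data.frame with concentrations `Ca`, `Cb`, `Cc` (mg/L) and
#'   contents `chl_a`, `chl_b`, `total_chlorophyll`, `carotenoid`,
#'   `total_pigment` (mg/g).
#' @export
pigment_contents <- function(A474, A642, A665, V = 0.015, mass = 0.1) {
  stopifnot(all(A474 >= 0), all(A642 >= 0), all(A665 >= 0))
  if (any(V <= 0) || any(mass <= 0))
    stop("extract volume and leaf mass must be positive", call. = FALSE)
  Ca <- 9.99 * A665 - 0.0872 * A642
  Cb <- 17.7 * A642 - 3.04 * A665
  Cc <- 4.92 * A474 - 0.0255 * Ca - 0.225 * Cb
  if (any(c(Ca, Cb, Cc) < 0))
    warning("negative pigment concentration computed; reported unclamped")
  f <- V / mass                      # mg/L -> mg/g
  data.frame(Ca = Ca, Cb = Cb, Cc = Cc,
             chl_a = Ca * f, chl_b = Cb * f,
             total_chlorophyll = (Ca + Cb) * f,
             carotenoid = Cc * f,
             total_pigment = (Ca + Cb + Cc) * f)
}

#' Relative electrical conductivity (electrolyte leakage)
#'
#' Membrane-damage index `REC = (E2 - E1) / (E3 - E1)` from the
#' conductivity of the bathing water (`E1`), of the water with leaf discs
#' (`E2`) and after boiling (`E3`, total electrolyte release). Lies in
#' `[0, 1]` whenever `E1 <= E2 <= E3`.
#'
#' @param E1,E2,E3 conductivities in any common unit; `E3 > E1` required.
#' @return REC as a dimensionless fraction (vectorised).
#' @export
relative_conductivity <- function(E1, E2, E3) {
  if (any(E3 <= E1))
    stop("E3 must exceed E1 (undefined denominator)", call. = FALSE)
  (E2 - E1) / (E3 - E1)
}

#' Mitochondrial ROS production rate from fluorescence kinetics
#'
#' Fits ordinary least-squares lines to DCFH-DA fluorescence-vs-time
#' readings of the sample tube and the blank tube and returns
#' `v = 10 * (k1 - k2) / g` (u/s/g), where `k1`, `k2` are the two slopes
#' and `g` the tissue mass in grams. Adding a constant offset to either
#' tube's readings leaves the rate unchanged.
#'
#' @param sample_points,blank_points two-column data (time_s,
#'   fluorescence); at least 2 points each.
#' @param g sample mass in grams (> 0).
#' @return list with `k1`, `k2` (intensity/s) and `v` (u/s/g).
#' @export
ros_rate <- function(sample_points, blank_points, g) {
  if (g <= 0) stop("sample mass must be positive", call. = FALSE)
  slope <- function(pts, label) {
    pts <- as.data.frame(pts)
    names(pts)[1:2] <- c("time_s", "fluorescence")
    if (nrow(pts) < 2)
      stop("insufficient data: need >= 2 fluorescence points for the ",
           label, " tube", call. = FALSE)
    unname(stats::coef(stats::lm(fluorescence ~ time_s, data = pts))[2])
  }
  k1 <- slope(sample_points, "sample")
  k2 <- slope(blank_points, "blank")
  list(k1 = k1, k2 = k2, v = 10 * (k1 - k2) / g)
}
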