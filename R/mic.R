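#' Two-fold broth-microdilution concentration ladder
#'
#' Geometric series `top, top/2, ..., top/2^(n_wells-1)`, the serial
#' dilution produced by transferring half-volumes along a plate row. The
#' standard 8-well ladder from 1024 ug/mL ends at 8 ug/mL.
#'
#' @param top highest concentration (ug/mL, > 0).
#' @param n_wells number of wells (>= 1).
#' @return Descending numeric vector of length `n_wells`.
#' @examples
#' dilution_ladder(1024, 8)
#' @export
dilution_ladder <- function(top, n_wells) {
  if (top <= 0) stop("top concentration must be positive", call. = FALSE)
  if (n_wells < 1) stop("need at least one well", call. = FALSE)
  top / 2^(seq_len(n_wells) - 1)
}

#' Microdilution plate record
#'
#' One organism x extract row of a 96-well MIC plate: the drug wells on a
#' strictly two-fold descending ladder, plus growth (positive) and
#' sterility (negative) control wells.
#'
#' @param concentrations descending two-fold ladder, ug/mL.
#' @param od_wells OD600 per drug well (same order as `concentrations`).
#' @param od_positive OD600 of the growth control (medium + bacteria).
#' @param od_negative OD600 of the sterility control (medium + drug).
#' @param organism,group,replicate identifying metadata.
#' @return Object of class `mic_plate`.
#' @export
mic_plate <- function(concentrations, od_wells, od_positive, od_negative,
                      organism = NA_character_, group = NA_character_,
                      replicate = NA_integer_) {
  if (length(concentrations) != length(od_wells))
    stop("one OD per concentration required", call. = FALSE)
  if (length(concentrations) > 1) {
    r <- concentrations[-length(concentrations)] / concentrations[-1]
    if (any(abs(r - 2) > 1e-8))
      stop("ladder must be exactly two-fold descending", call. = FALSE)
  }
  if (any(od_wells < 0) || od_positive < 0 || od_negative < 0)
    stop("OD values must be >= 0", call. = FALSE)
  structure(list(concentrations = concentrations, od_wells = od_wells,
                 od_positive = od_positive, od_negative = od_negative,
                 organism = organism, group = group, replicate = replicate),
            class = "mic_plate")
}

#' Call the MIC from a microdilution plate
#'
#' Applies the 80%-of-growth-control endpoint: after subtracting the
#' sterility-control OD from every well, the MIC is the lowest
#' concentration whose corrected OD falls below
#' `endpoint_fraction x corrected positive-control OD`. If no well is
#' inhibited the call is censored above the top concentration
#' (`"> top"`); if every well is inhibited the lowest tested concentration
#' is returned flagged `"<="`. The rule is monotone: raising a
#' sub-threshold well's OD can only raise the called MIC.
#'
#' `rule = "closest"` provides the literal closest-OD-to-endpoint variant.
#'
#' @param plate a [mic_plate()].
#' @param endpoint_fraction endpoint as a fraction of the corrected growth
#'   control (default 0.8).
#' @param rule `"threshold"` (default) or `"closest"`.
#' @return list with `mic` (ug/mL, numeric; `Inf` when censored above),
#'   `censored` (`""`, `">"` or `"<="`) and `label` (printable call).
#' @examples
#' p <- mic_plate(dilution_ladder(1024, 8),
#'                c(0.05, 0.06, 0.07, 0.10, 0.60, 0.65, 0.70, 0.72),
#'                od_positive = 0.70, od_negative = 0)
#' call_mic(p)$mic   # 128
#' @export
call_mic <- function(plate, endpoint_fraction = 0.8,
                     rule = c("threshold", "closest")) {
  rule <- match.arg(rule)
  stopifnot(inherits(plate, "mic_plate"))
  if (plate$od_positive <= plate$od_negative)
    stop("invalid plate: growth control does not exceed sterility control",
         call. = FALSE)
  od <- plate$od_wells - plate$od_negative
  threshold <- endpoint_fraction * (plate$od_positive - plate$od_negative)
  conc <- plate$concentrations
  if (rule == "closest") {
    idx <- which.min(abs(od - threshold))
    return(list(mic = conc[idx], censored = "",
                label = format(conc[idx])))
  }
  inhibited <- od < threshold
  if (!any(inhibited))
    return(list(mic = Inf, censored = ">",
                label = paste0("> ", format(max(conc)))))
  mic <- min(conc[inhibited])
  if (all(inhibited))
    return(list(mic = mic, censored = "<=",
                label = paste0("<= ", format(mic))))
  list(mic = mic, censored = "", label = format(mic))
}

#' Consensus MIC over replicate plates
#'
#' Modal MIC across replicates; a tie between modes is resolved toward the
#' higher concentration (the conservative call for an inhibitory
#' concentration). The min-max range is retained.
#'
#' @param mics numeric vector of replicate MIC values (ug/mL).
#' @return list with `consensus`, `range = c(min, max)`, `n`.
#' @examples
#' summarize_mic(c(128, 256, 128, 128))$consensus   # 128
#' summarize_mic(c(128, 256))$consensus             # 256 (tie -> higher)
#' @export
summarize_mic <- function(mics) {
  if (length(mics) < 1) stop("need at least one replicate MIC", call. = FALSE)
  tab <- table(mics)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  list(consensus = max(modes), range = range(mics), n = length(mics))
}
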