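#' Background-corrected spontaneous-emission count rate (CPS)
#'
#' Summarises a spontaneous photon emission run as `CPS = N - n`, where `N`
#' is the mean bin count rate of the sample run and `n` the mean rate of an
#' instrument background run of the same bin width. A negative CPS (possible
#' on pure noise) is flagged, never clamped.
#'
#' @param spe_trace `photon_trace` with `run_kind = "SPE"`.
#' @param background_trace `photon_trace` with `run_kind = "background"`,
#'   same bin width.
#' @return Object of class `spe_summary`: list with `N`, `n`, `CPS`,
#'   `negative` flag, `normalized = FALSE`.
#' @export
compute_cps <- function(spe_trace, background_trace) {
  stopifnot(inherits(spe_trace, "photon_trace"),
            inherits(background_trace, "photon_trace"))
  if (spe_trace$run_kind != "SPE")
    stop("spe_trace must have run_kind 'SPE'", call. = FALSE)
  if (background_trace$run_kind != "background")
    stop("background_trace must have run_kind 'background'", call. = FALSE)
  if (length(spe_trace$counts) == 0 || length(background_trace$counts) == 0)
    stop("degenerate input: empty trace", call. = FALSE)
  if (!isTRUE(all.equal(spe_trace$bin_width, background_trace$bin_width)))
    stop("sample and background traces must share a bin width", call. = FALSE)
  N <- mean(spe_trace$counts) / spe_trace$bin_width
  n <- mean(background_trace$counts) / background_trace$bin_width
  cps <- N - n
  if (cps < 0)
    warning("CPS is negative (sample rate below background); flagged, not clamped")
  structure(list(N = N, n = n, CPS = cps, negative = cps < 0,
                 normalized = FALSE),
            class = "spe_summary")
}

#' @export
print.spe_summary <- function(x, ...) {
  cat(sprintf("SPE summary: N = %.4g, n = %.4g, CPS = %.4g counts/s%s\n",
              x$N, x$n, x$CPS, if (x$negative) " [negative]" else ""))
  invisible(x)
}

#' Normalise an intensity measure by leaf geometry
#'
#' Homogenises an intensity-type quantity (initial intensity I0, window
#' mean Iw, or CPS) across leaves of different size by multiplying by the
#' leaf thickness and dividing by its mass, giving counts*mm/(s*g). Shape
#' parameters (A, B, C) and the decay time T are never normalised.
#'
#' @param value intensity on the counts/s scale.
#' @param mass_g leaf mass in grams (> 0). Alternatively pass a one-row
#'   data.frame/list with `mass_g` and `thickness_mm` as `sample`.
#' @param thickness_mm leaf thickness in millimetres (> 0).
#' @param sample optional record carrying `mass_g` and `thickness_mm`.
#' @return Normalised value, counts*mm/(s*g).
#' @export
normalize_intensity <- function(value, mass_g = NULL, thickness_mm = NULL,
                                sample = NULL) {
  if (!is.null(sample)) {
    mass_g <- sample[["mass_g"]]; thickness_mm <- sample[["thickness_mm"]]
  }
  if (is.null(mass_g) || is.null(thickness_mm) ||
      any(!is.finite(mass_g)) || any(!is.finite(thickness_mm)) ||
      any(mass_g <= 0) || any(thickness_mm <= 0))
    stop("mass and thickness must be positive", call. = FALSE)
  value * thickness_mm / mass_g
}

#' Assemble the per-sample candidate-feature table
#'
#' Builds the matrix of the seven candidate photon parameters used for
#' screening: the kinetic parameters A, B, C, the derived I0, Iw, T and the
#' spontaneous-emission CPS. The strength measures I0, Iw and CPS are
#' geometry-normalised with [normalize_intensity()]; A, B, C and T are kept
#' as fitted.
#'
#' @param samples data.frame with `sample_id`, `group`, `mass_g`,
#'   `thickness_mm`.
#' @param fits named list (by sample_id) of `gu_fit` objects (replicate
#'   means).
#' @param cps named list (by sample_id) of `spe_summary` objects.
#' @param m,W decay factor and measurement window passed to
#'   [derive_dl_parameters()].
#' @return data.frame: `sample_id`, `group`, `A`, `B`, `C`, `I0`, `Iw`,
#'   `T`, `CPS` (I0/Iw/CPS normalised).
#' @export
assemble_features <- function(samples, fits, cps, m = 3, W = 300) {
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    f <- fits[[s$sample_id]]
    d <- derive_dl_parameters(f, m = m, W = W)
    k <- cps[[s$sample_id]]
    data.frame(
      sample_id = s$sample_id, group = s$group,
      A = f$A, B = f$B, C = f$C,
      I0 = normalize_intensity(d$I0, s$mass_g, s$thickness_mm),
      Iw = normalize_intensity(d$Iw, s$mass_g, s$thickness_mm),
      T = d$T,
      CPS = normalize_intensity(k$CPS, s$mass_g, s$thickness_mm),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
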