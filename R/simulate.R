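#' Simulation configuration for a stress-study dataset
#'
#' Builds the configuration object consumed by [simulate_study()] and
#' [simulate_assay_tables()]. The defaults describe a five-arm stress
#' experiment (control, three salinity levels, drought) with six replicate
#' runs per group, the standard acquisition protocol (300-s DL decay after
#' illumination, 600 one-second SPE bins, a 600-s dark background run) and
#' group effects that halve the initial DL intensity and the spontaneous
#' emission rate under severe stress while leaving the decay shape (B, C,
#' hence T) unchanged.
#'
#' @param n_per_group replicate runs per group (>= 2).
#' @param groups character vector of group labels; first element is the
#'   control arm.
#' @param dl_params named list with control-group Gu parameters `A`
#'   (counts/s scale), `B` (s), `C` (dimensionless), all > 0.
#' @param spe_rate control-group spontaneous emission rate, counts/s.
#' @param background_rate instrument dark-count rate, counts/s.
#' @param mass_distribution,thickness_distribution `c(mean, sd)` of leaf
#'   mass (g) and thickness (mm).
#' @param effect_table data.frame with one row per group and columns
#'   `group`, `dl_A_mult`, `spe_mult`, `compound_mult` columns per analyte
#'   (`hydroxyquinazoline`, `syringic_acid`, `tryptanthrin`, `indigo`,
#'   `indirubin`), `pigment_mult`, `rec_mult`, `ros_mult`,
#'   `mic_shift_ecoli`, `mic_shift_saureus` (two-fold ladder steps).
#'   `NULL` uses [default_effect_table()] for `groups`.
#' @param dl_duration,spe_bins,background_duration acquisition protocol:
#'   DL window (s), number of 1-s SPE bins, background run length (s).
#' @param biological_cv within-group lognormal coefficient of variation of
#'   the per-sample DL amplitude and SPE rate.
#' @param seed integer seed controlling every random stream derived from
#'   this configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 6,
                       groups = c("control", "salt_low", "salt_mid",
                                  "salt_high", "drought"),
                       dl_params = list(A = 2000, B = 15, C = 0.8),
                       spe_rate = 120,
                       background_rate = 30,
                       mass_distribution = c(mean = 0.5, sd = 0.05),
                       thickness_distribution = c(mean = 0.4, sd = 0.04),
                       effect_table = NULL,
                       dl_duration = 300,
                       spe_bins = 600,
                       background_duration = 600,
                       biological_cv = 0.08,
                       seed = 1L) {
  if (is.null(effect_table)) effect_table <- default_effect_table(groups)
  if (!setequal(effect_table$group, groups))
    stop("effect_table groups do not match config groups", call. = FALSE)
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  check_gu_params(dl_params$A, dl_params$B, dl_params$C)
  if (spe_rate < 0 || background_rate < 0)
    stop("rates must be >= 0", call. = FALSE)
  structure(list(
    n_per_group = as.integer(n_per_group), groups = groups,
    dl_params = dl_params, spe_rate = spe_rate,
    background_rate = background_rate,
    mass_distribution = mass_distribution,
    thickness_distribution = thickness_distribution,
    effect_table = effect_table,
    dl_duration = dl_duration, spe_bins = as.integer(spe_bins),
    background_duration = background_duration,
    biological_cv = biological_cv, seed = as.integer(seed)),
    class = "sim_config")
}

#' Default per-group effect multipliers
#'
#' Group effects applied by the simulator, chosen to mirror the qualitative
#' pattern of a salt/drought stress study on *Isatis indigotica* leaves:
#' severe stress halves the DL amplitude (hence the fitted initial intensity)
#' and the spontaneous emission rate; active-ingredient contents fall
#' (indirubin to 0.018% under high salinity, below the 0.02% pharmacopoeial
#' standard); pigments fall; relative conductivity and ROS production rise;
#' MIC shifts up the two-fold ladder. Unknown groups get neutral effects.
#'
#' @param groups group labels; unrecognised labels receive multiplier 1 and
#'   shift 0 (a null arm).
#' @return data.frame, one row per group.
#' @export
default_effect_table <- function(groups = c("control", "salt_low", "salt_mid",
                                            "salt_high", "drought")) {
  base <- data.frame(
    group        = c("control", "salt_low", "salt_mid", "salt_high", "drought"),
    dl_A_mult    = c(1, 0.9, 0.7, 0.5, 0.5),
    spe_mult     = c(1, 0.9, 0.7, 0.5, 0.5),
    hydroxyquinazoline = c(1, 1, 1, 1, 1),
    syringic_acid = c(1, 0.95, 0.6, 0.3, 0.5),
    tryptanthrin  = c(1, 0.95, 0.6, 0.3, 0.5),
    indigo        = c(1, 0.95, 0.6, 0.3, 0.5),
    indirubin     = c(1, 0.95, 0.5, 0.18, 0.46),
    pigment_mult  = c(1, 0.95, 0.75, 0.5, 0.6),
    rec_mult      = c(1, 1.2, 2.3633, 3.0078, 2.6767),
    ros_mult      = c(1, 1.1, 1.5, 2.2, 2.0),
    mic_shift_ecoli   = c(0, 0, 1, 2, 2),
    mic_shift_saureus = c(0, 0, 1, 1, 2),
    stringsAsFactors = FALSE)
  out <- base[match(groups, base$group), ]
  missing <- is.na(out$group)
  if (any(missing)) {
    out[missing, ] <- c(list(groups[missing]),
                        as.list(c(rep(1, 9), 0, 0)))
  }
  out$group <- groups
  rownames(out) <- NULL
  out
}

#' Null effect table (all groups exchangeable)
#'
#' All multipliers 1 and all MIC shifts 0: every group is drawn from the
#' control distribution. Used for type-I-error and null-screening checks.
#'
#' @inheritParams default_effect_table
#' @export
null_effect_table <- function(groups) {
  et <- default_effect_table(groups)
  mult_cols <- setdiff(names(et), c("group", "mic_shift_ecoli",
                                    "mic_shift_saureus"))
  et[mult_cols] <- 1
  et[c("mic_shift_ecoli", "mic_shift_saureus")] <- 0
  et
}

# Deterministic per-trace stream: polynomial string hash combined with the
# top-level seed and passed through a murmur3-style avalanche, so streams
# derived from nearby seeds are statistically unrelated. Result < 2^31 so
# set.seed() accepts it.
stream_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 4294967296
  h <- (h + as.numeric(seed) * 2246822519) %% 4294967296
  mul32 <- function(a, b) {
    a1 <- floor(a / 65536); a0 <- a %% 65536
    (((a1 * b) %% 65536) * 65536 + a0 * b) %% 4294967296
  }
  xorshift <- function(x, k) {
    # xor of two 32-bit values held in doubles
    hi <- floor(x / 65536); lo <- x %% 65536
    y <- floor(x / 2^k)
    yhi <- floor(y / 65536); ylo <- y %% 65536
    bitwXor(as.integer(hi), as.integer(yhi)) * 65536 +
      bitwXor(as.integer(lo), as.integer(ylo))
  }
  h <- xorshift(h, 16)
  h <- mul32(h, 2654435761)
  h <- xorshift(h, 13)
  h <- mul32(h, 2246822519)
  h <- xorshift(h, 16)
  as.integer(h %% 2147483647)
}

#' Simulate a delayed-luminescence photon-count trace
#'
#' Each 1-bin count is drawn from a Poisson law whose mean is the exact
#' integral of the Gu decay `A * csch^2(t/B + C)` over the bin (closed-form
#' antiderivative `-A*B*coth(t/B + C)`) plus `background_rate * bin_width`.
#' Time zero is the first detection instant after illumination ends; bins
#' are half-open `[k, k+1)` seconds.
#'
#' @inheritParams gu_intensity
#' @param background_rate dark-count rate, counts/s (>= 0).
#' @param duration total decay window, s (default 300).
#' @param bin_width counting bin width, s (default 1).
#' @param seed integer seed for the trace's own random stream.
#' @param sample_id identifier stored on the trace.
#' @return A `photon_trace` with `run_kind = "DL"`.
#' @export
simulate_dl_trace <- function(A, B, C, background_rate = 0, duration = 300,
                              bin_width = 1, seed = 1L,
                              sample_id = NA_character_) {
  check_gu_params(A, B, C)
  if (background_rate < 0) stop("background_rate must be >= 0", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  n_bins <- as.integer(round(duration / bin_width))
  t0 <- (seq_len(n_bins) - 1) * bin_width
  mu <- gu_bin_means(t0, bin_width, A, B, C) * bin_width +
    background_rate * bin_width
  counts <- with_seed(seed, stats::rpois(n_bins, mu))
  photon_trace(counts, bin_width = bin_width, run_kind = "DL",
               sample_id = sample_id)
}

#' Simulate a spontaneous-emission (or background) trace
#'
#' I.i.d. Poisson counts with mean `(rate + background_rate) * bin_width`.
#'
#' @param rate sample emission rate, counts/s (>= 0); 0 gives a pure
#'   background run.
#' @param background_rate dark-count rate, counts/s (>= 0).
#' @param n_bins number of bins (default 600, i.e. ten minutes of 1-s bins).
#' @param bin_width bin width, s.
#' @param seed integer seed.
#' @param run_kind `"SPE"` or `"background"`.
#' @param sample_id identifier stored on the trace.
#' @return A `photon_trace` of exactly `n_bins` bins.
#' @export
simulate_spe_trace <- function(rate, background_rate = 0, n_bins = 600,
                               bin_width = 1, seed = 1L,
                               run_kind = c("SPE", "background"),
                               sample_id = NA_character_) {
  run_kind <- match.arg(run_kind)
  if (rate < 0 || background_rate < 0)
    stop("rates must be >= 0", call. = FALSE)
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  counts <- with_seed(seed,
    stats::rpois(n_bins, (rate + background_rate) * bin_width))
  photon_trace(counts, bin_width = bin_width, run_kind = run_kind,
               sample_id = sample_id)
}

# run code under a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate the full photon-measurement arm of a study
#'
#' Generates, for every sample of every group: three replicate DL decay
#' runs, one SPE run and one background run, plus the sample metadata
#' (mass, thickness). Within-group biological variability is lognormal on
#' the DL amplitude and the SPE rate; every trace has its own random stream
#' derived from `(seed, sample_id, run)` so generation order does not
#' matter.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list with `samples` (data.frame: sample_id, group, mass_g,
#'   thickness_mm), `traces` (named list per sample: `dl` (list of 3),
#'   `spe`, `background`), and `truth` (per-sample true A, B, C, spe_rate).
#' @export
simulate_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  et <- config$effect_table
  samples <- NULL; traces <- list(); truth <- NULL
  for (g in config$groups) {
    eff <- et[et$group == g, ]
    for (i in seq_len(config$n_per_group)) {
      sid <- sprintf("%s_%02d", g, i)
      s_meta <- stream_seed(seed, sid, "meta")
      meta <- with_seed(s_meta, {
        m <- abs(stats::rnorm(1, config$mass_distribution[["mean"]],
                              config$mass_distribution[["sd"]]))
        th <- abs(stats::rnorm(1, config$thickness_distribution[["mean"]],
                               config$thickness_distribution[["sd"]]))
        bio <- stats::rlnorm(2, 0, config$biological_cv)
        list(mass = m, thickness = th, bio = bio)
      })
      A_i <- config$dl_params$A * eff$dl_A_mult * meta$bio[1]
      rate_i <- config$spe_rate * eff$spe_mult * meta$bio[2]
      dl <- lapply(1:3, function(r)
        simulate_dl_trace(A_i, config$dl_params$B, config$dl_params$C,
                          background_rate = config$background_rate,
                          duration = config$dl_duration,
                          seed = stream_seed(seed, sid, "DL", r),
                          sample_id = sid))
      spe <- simulate_spe_trace(rate_i, config$background_rate,
                                n_bins = config$spe_bins,
                                seed = stream_seed(seed, sid, "SPE"),
                                sample_id = sid)
      bg <- simulate_spe_trace(0, config$background_rate,
                               n_bins = as.integer(config$background_duration),
                               seed = stream_seed(seed, sid, "background"),
                               run_kind = "background", sample_id = sid)
      samples <- rbind(samples, data.frame(
        sample_id = sid, group = g, mass_g = meta$mass,
        thickness_mm = meta$thickness, stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        sample_id = sid, group = g, A = A_i, B = config$dl_params$B,
        C = config$dl_params$C, spe_rate = rate_i, stringsAsFactors = FALSE))
      traces[[sid]] <- list(dl = dl, spe = spe, background = bg)
    }
  }
  list(samples = samples, traces = traces, truth = truth)
}

#' Simulate per-sample assay tables for the quality endpoints
#'
#' Generates, with group effects from `config$effect_table`:
#' \itemize{
#'   \item `compounds`: five active-ingredient contents (% w/w) per sample;
#'   \item `pigments`: raw absorbances (A474, A642, A665) with the protocol
#'     extract volume (0.015 L) and leaf mass (0.1 g);
#'   \item `conductivity`: E1 <= E2 <= E3 conductivities per sample;
#'   \item `ros`: fluorescence-vs-time points for sample and blank tubes
#'     plus the tissue mass, from which the ROS production rate is
#'     recovered by linear regression;
#'   \item `mic_plates`: broth-microdilution plates (list of [mic_plate()])
#'     on the 1024..8 ug/mL two-fold ladder, four replicates per group and
#'     organism.
#' }
#' Multiplicative lognormal noise (5% CV) is applied within groups, so
#' configured group orderings (and the resulting correlation signs against
#' the photon parameters) are recoverable at the default sample sizes.
#'
#' @inheritParams simulate_study
#' @return list of data.frames / plate lists as described above.
#' @export
simulate_assay_tables <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  et <- config$effect_table
  compounds_base <- c(hydroxyquinazoline = 0.05, syringic_acid = 0.08,
                      tryptanthrin = 0.06, indigo = 0.20, indirubin = 0.10)
  abs_base <- c(A474 = 0.6, A642 = 0.4, A665 = 0.8)
  rec_base <- 0.15
  ros_base <- 4       # u/s/g at g = 0.1
  mic_base <- c(ecoli = 128, saureus = 256)
  cv <- 0.05
  comp <- pig <- cond <- ros <- NULL
  plates <- list()
  for (g in config$groups) {
    eff <- et[et$group == g, ]
    for (i in seq_len(config$n_per_group)) {
      sid <- sprintf("%s_%02d", g, i)
      s <- stream_seed(seed, sid, "assay")
      vals <- with_seed(s, {
        list(comp_noise = stats::rlnorm(length(compounds_base), 0, cv),
             abs_noise = stats::rlnorm(3, 0, cv),
             rec_noise = stats::rlnorm(1, 0, cv),
             ros_noise = stats::rlnorm(1, 0, cv),
             pt_noise = stats::rnorm(20, 0, 0.5))
      })
      cc <- compounds_base *
        unlist(eff[names(compounds_base)]) * vals$comp_noise
      comp <- rbind(comp, data.frame(sample_id = sid, group = g,
                                     t(cc), stringsAsFactors = FALSE))
      ab <- abs_base * eff$pigment_mult * vals$abs_noise
      pig <- rbind(pig, data.frame(sample_id = sid, group = g,
                                   A474 = ab[["A474"]], A642 = ab[["A642"]],
                                   A665 = ab[["A665"]], V_L = 0.015,
                                   mass_g = 0.1, stringsAsFactors = FALSE))
      rec <- min(rec_base * eff$rec_mult * vals$rec_noise, 0.98)
      E1 <- 2; E3 <- 60
      cond <- rbind(cond, data.frame(sample_id = sid, group = g, E1 = E1,
                                     E2 = E1 + rec * (E3 - E1), E3 = E3,
                                     stringsAsFactors = FALSE))
      # fluorescence time courses: v = 10 * (k1 - k2) / g with g = 0.1 g
      v_true <- ros_base * eff$ros_mult * vals$ros_noise
      g_mass <- 0.1
      k2 <- 0.05
      k1 <- k2 + v_true * g_mass / 10
      tt <- seq(0, 540, by = 60)
      ros <- rbind(ros,
        data.frame(sample_id = sid, group = g, tube = "sample", time_s = tt,
                   fluorescence = 100 + k1 * tt + vals$pt_noise[1:10],
                   mass_g = g_mass, stringsAsFactors = FALSE),
        data.frame(sample_id = sid, group = g, tube = "blank", time_s = tt,
                   fluorescence = 100 + k2 * tt + vals$pt_noise[11:20],
                   mass_g = g_mass, stringsAsFactors = FALSE))
    }
    for (org in c("ecoli", "saureus")) {
      shift <- eff[[paste0("mic_shift_", org)]]
      for (rep in 1:4) {
        s <- stream_seed(seed, g, org, "mic", rep)
        plates[[sprintf("%s_%s_%d", g, org, rep)]] <-
          with_seed(s, simulate_mic_plate(
            mic_true = mic_base[[org]] * 2^shift, organism = org,
            group = g, replicate = rep))
      }
    }
  }
  list(compounds = comp, pigments = pig, conductivity = cond, ros = ros,
       mic_plates = plates)
}

# One 96-well row: logistic dose-response around the target MIC, steep
# enough that the 80%-of-control endpoint lands on mic_true; occasional
# one-step-up jitter mimics replicate disagreement.
simulate_mic_plate <- function(mic_true, organism, group, replicate,
                               top = 1024, n_wells = 8, jitter_prob = 0.1) {
  if (stats::runif(1) < jitter_prob) mic_true <- mic_true * 2
  conc <- dilution_ladder(top, n_wells)
  od_pos <- 0.70
  od_neg <- 0.03
  ic50 <- mic_true / 1.4
  od <- od_neg + od_pos / (1 + (conc / ic50)^6) + stats::rnorm(n_wells, 0, 0.015)
  od <- pmax(od, 0)
  mic_plate(concentrations = conc, od_wells = od,
            od_positive = od_neg + od_pos + stats::rnorm(1, 0, 0.015),
            od_negative = od_neg + abs(stats::rnorm(1, 0, 0.005)),
            organism = organism, group = group, replicate = replicate)
}

#' Simulate a feature table with effects planted only through I0 and CPS
#'
#' Draws the seven candidate photon parameters (A, B, C, I0, Iw, T, CPS)
#' for each sample from lognormal within-group distributions. Group effect
#' multipliers act on I0 and CPS only; the remaining five features are
#' exchangeable across groups. Used to validate feature screening: a
#' correct screen should select I0 and CPS and nothing else systematically.
#'
#' @param n_per_group samples per group.
#' @param groups group labels.
#' @param i0_mult,cps_mult named multipliers per group (default: control 1,
#'   stressed 0.5).
#' @param cv within-group lognormal coefficient of variation.
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `group` and the seven feature columns.
#' @export
simulate_feature_table <- function(n_per_group = 6,
                                   groups = c("control", "stress"),
                                   i0_mult = NULL, cps_mult = NULL,
                                   cv = 0.12, seed = 1L) {
  if (is.null(i0_mult))
    i0_mult <- stats::setNames(c(1, rep(0.5, length(groups) - 1)), groups)
  if (is.null(cps_mult)) cps_mult <- i0_mult
  base <- c(A = 2000, B = 15, C = 0.8, I0 = 2535, Iw = 85, T = 4.7, CPS = 120)
  rows <- list()
  for (g in groups) for (i in seq_len(n_per_group)) {
    sid <- sprintf("%s_%02d", g, i)
    noise <- with_seed(stream_seed(seed, sid, "feat"),
                       stats::rlnorm(7, 0, cv))
    v <- base * noise
    v[["I0"]] <- v[["I0"]] * i0_mult[[g]]
    v[["CPS"]] <- v[["CPS"]] * cps_mult[[g]]
    rows[[sid]] <- data.frame(sample_id = sid, group = g, t(v),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
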