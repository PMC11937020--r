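#' Run the full quality-assessment pipeline on a simulated study
#'
#' End-to-end orchestration: simulate the photon-measurement arm and the
#' assay tables, fit the Gu model to every sample's replicate DL runs
#' (replicate-mean parameters), derive I0/T/Iw, compute CPS, normalise the
#' strength measures by leaf geometry, compute the physiological indices
#' (pigment contents, REC, ROS rate), call and summarise MICs, screen the
#' seven candidate parameters with cross-validated LASSO
#' (control vs stressed), run two-tailed pooled t-tests of I0/CPS/T for
#' each stress arm against control, build the Spearman correlation network
#' between photon parameters and endpoints, and classify group quality by
#' the indirubin standard.
#'
#' All randomness flows from `seed` (default `config$seed`), split into
#' independent per-trace streams, so a rerun with the same configuration
#' and seed reproduces every output exactly.
#'
#' @param config a [sim_config()].
#' @param seed integer seed overriding `config$seed`.
#' @param m,W decay factor and DL window for the derived parameters.
#' @param out_dir optional directory; when given, the stage outputs are
#'   written as CSV/GraphML and listed (with content hashes) in the
#'   manifest.
#' @return Object of class `biophoton_run`: list with `features`,
#'   `fit_details`, `physiology`, `mic`, `screening`, `ttests`, `network`,
#'   `quality`, and `manifest` (config snapshot, seed, file hashes).
#' @export
run_pipeline <- function(config = sim_config(), seed = config$seed,
                         m = 3, W = config$dl_duration, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  study <- simulate_study(config, seed = seed)
  assays <- simulate_assay_tables(config, seed = seed)

  fits <- list(); cps <- list(); fit_sd <- list()
  for (sid in study$samples$sample_id) {
    tr <- study$traces[[sid]]
    bg_rate <- mean(tr$background$counts) / tr$background$bin_width
    rep_fit <- fit_dl_replicates(tr$dl, background_rate = bg_rate)
    fits[[sid]] <- rep_fit$mean
    fit_sd[[sid]] <- rep_fit$sd
    cps[[sid]] <- compute_cps(tr$spe, tr$background)
  }
  features <- assemble_features(study$samples, fits, cps, m = m, W = W)

  # physiology indices per sample
  pig <- assays$pigments
  pigc <- cbind(pig[c("sample_id", "group")],
                pigment_contents(pig$A474, pig$A642, pig$A665,
                                 V = pig$V_L, mass = pig$mass_g))
  cond <- assays$conductivity
  rec <- data.frame(sample_id = cond$sample_id, group = cond$group,
                    REC = relative_conductivity(cond$E1, cond$E2, cond$E3),
                    stringsAsFactors = FALSE)
  ros <- do.call(rbind, lapply(split(assays$ros, assays$ros$sample_id),
    function(d) {
      sp <- d[d$tube == "sample", c("time_s", "fluorescence")]
      bp <- d[d$tube == "blank", c("time_s", "fluorescence")]
      r <- ros_rate(sp, bp, g = d$mass_g[1])
      data.frame(sample_id = d$sample_id[1], group = d$group[1],
                 ros_rate = r$v, stringsAsFactors = FALSE)
    }))
  rownames(ros) <- NULL

  # MIC calls and per-group consensus
  mic_calls <- do.call(rbind, lapply(assays$mic_plates, function(p) {
    cl <- call_mic(p)
    data.frame(group = p$group, organism = p$organism,
               replicate = p$replicate, mic = cl$mic,
               censored = cl$censored, stringsAsFactors = FALSE)
  }))
  rownames(mic_calls) <- NULL
  mic_consensus <- do.call(rbind, lapply(
    split(mic_calls, mic_calls[c("group", "organism")]),
    function(d) data.frame(group = d$group[1], organism = d$organism[1],
                           consensus = summarize_mic(d$mic)$consensus,
                           min = min(d$mic), max = max(d$mic),
                           stringsAsFactors = FALSE)))
  rownames(mic_consensus) <- NULL

  # LASSO screen: control vs all stressed arms
  control <- config$groups[1]
  response <- factor(ifelse(features$group == control, "control", "stressed"),
                     levels = c("control", "stressed"))
  screening <- lasso_screen(features, response, seed = seed)

  # per-arm t-tests on the three headline parameters
  ttests <- NULL
  for (g in setdiff(config$groups, control)) {
    for (par in c("I0", "CPS", "T")) {
      tt <- group_ttest(features[[par]][features$group == control],
                        features[[par]][features$group == g])
      ttests <- rbind(ttests, data.frame(
        parameter = par, comparison = paste(control, "vs", g),
        t = tt$t, df = tt$df, p = tt$p,
        significant = tt$p <= 0.05, stringsAsFactors = FALSE))
    }
  }
  rownames(ttests) <- NULL

  # endpoint table aligned to the feature rows, then the network
  merge_ep <- function(a, b) merge(a, b, by = c("sample_id", "group"))
  endpoints <- Reduce(merge_ep, list(
    assays$compounds,
    pigc[c("sample_id", "group", "total_chlorophyll", "carotenoid",
           "total_pigment")],
    rec, ros))
  endpoints <- merge_ep(endpoints, data.frame(
    sample_id = features$sample_id, group = features$group,
    MIC_E = mic_consensus$consensus[match(
      paste(features$group, "ecoli"),
      paste(mic_consensus$group, mic_consensus$organism))],
    MIC_S = mic_consensus$consensus[match(
      paste(features$group, "saureus"),
      paste(mic_consensus$group, mic_consensus$organism))],
    stringsAsFactors = FALSE))
  endpoints <- endpoints[match(features$sample_id, endpoints$sample_id), ]
  network <- spearman_network(features[c("I0", "CPS", "T")],
                              endpoints, threshold = 0.05)

  # quality classification on group-mean indirubin content
  grp_ind <- stats::aggregate(indirubin ~ group, data = assays$compounds,
                              FUN = mean)
  quality <- classify_quality(grp_ind)

  result <- structure(list(
    features = features, fit_details = list(fits = fits, sd = fit_sd),
    physiology = list(pigments = pigc, rec = rec, ros = ros),
    mic = list(calls = mic_calls, consensus = mic_consensus),
    screening = screening, ttests = ttests, network = network,
    quality = quality, endpoints = endpoints,
    manifest = list(config = config, seed = as.integer(seed), m = m, W = W,
                    files = NULL)),
    class = "biophoton_run")
  if (!is.null(out_dir)) result$manifest$files <- write_run(result, out_dir)
  result
}

#' @export
print.biophoton_run <- function(x, ...) {
  cat("Biophoton quality-assessment run\n")
  cat(sprintf("  %d samples in %d groups; seed %d\n",
              nrow(x$features), length(unique(x$features$group)),
              x$manifest$seed))
  cat(sprintf("  LASSO selection (lambda_min): {%s}\n",
              paste(x$screening$selected_features$lambda_min, collapse = ", ")))
  cat(sprintf("  network edges at P <= %g: %d\n", x$network$threshold,
              nrow(x$network$edges)))
  cat(sprintf("  quality: %d/%d groups pass the indirubin standard\n",
              sum(x$quality$pass), nrow(x$quality)))
  invisible(x)
}

# write stage outputs as CSV/GraphML; returns data.frame(path, md5)
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[[length(paths) + 1L]] <<- p
  }
  wcsv(run$features, "features.csv")
  wcsv(run$physiology$pigments, "pigments.csv")
  wcsv(run$physiology$rec, "rec.csv")
  wcsv(run$physiology$ros, "ros.csv")
  wcsv(run$mic$calls, "mic_calls.csv")
  wcsv(run$mic$consensus, "mic_consensus.csv")
  wcsv(run$ttests, "ttests.csv")
  wcsv(run$network$edges, "network_edges.csv")
  wcsv(run$quality, "quality.csv")
  gp <- file.path(out_dir, "network.graphml")
  if (nrow(run$network$edges) > 0) {
    write_network_graphml(run$network, gp)
    paths[[length(paths) + 1L]] <- gp
  }
  sp <- file.path(out_dir, "screening.json")
  jsonlite::write_json(list(
    lambda_min = run$screening$lambda_min,
    lambda_1se = run$screening$lambda_1se,
    selected_lambda_min = run$screening$selected_features$lambda_min,
    selected_lambda_1se = run$screening$selected_features$lambda_1se,
    coefficients = run$screening$coefficients$lambda_min),
    sp, auto_unbox = TRUE, digits = NA)
  paths[[length(paths) + 1L]] <- sp
  data.frame(path = unlist(paths),
             md5 = vapply(unlist(paths), function(p)
               unname(tools::md5sum(p)), character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
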