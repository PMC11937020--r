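# Assemble per-sample endpoint values from simulated assay tables, in the
# row order of the compounds table (shared by the network-recovery checks).
assemble_endpoints <- function(assays) {
  pigc <- pigment_contents(assays$pigments$A474, assays$pigments$A642,
                           assays$pigments$A665)
  rec <- relative_conductivity(assays$conductivity$E1,
                               assays$conductivity$E2,
                               assays$conductivity$E3)
  ros <- vapply(split(assays$ros, assays$ros$sample_id), function(d)
    ros_rate(d[d$tube == "sample", c("time_s", "fluorescence")],
             d[d$tube == "blank", c("time_s", "fluorescence")],
             g = d$mass_g[1])$v, numeric(1))
  ros <- ros[assays$compounds$sample_id]
  mics <- vapply(assays$mic_plates, function(p) call_mic(p)$mic, numeric(1))
  consensus <- function(org) vapply(assays$compounds$group, function(g)
    summarize_mic(mics[grep(paste0("^", g, "_", org, "_"),
                            names(mics))])$consensus, numeric(1))
  data.frame(
    assays$compounds[c("syringic_acid", "tryptanthrin", "indigo", "indirubin")],
    total_pigment = pigc$total_pigment, REC = rec, ROS = ros,
    MIC_E = consensus("ecoli"), MIC_S = consensus("saureus"))
}

# TRUE when every planted parameter-endpoint edge is significant with the
# planted sign for both I0 and CPS
planted_signs_recovered <- function(net) {
  want_pos <- c("syringic_acid", "tryptanthrin", "indigo", "indirubin",
                "total_pigment")
  want_neg <- c("REC", "ROS", "MIC_E", "MIC_S")
  e <- net$edges
  for (p in c("I0", "CPS")) {
    for (tg in want_pos)
      if (nrow(e[e$source == p & e$target == tg & e$sign == 1, ]) != 1)
        return(FALSE)
    for (tg in want_neg)
      if (nrow(e[e$source == p & e$target == tg & e$sign == -1, ]) != 1)
        return(FALSE)
  }
  TRUE
}
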