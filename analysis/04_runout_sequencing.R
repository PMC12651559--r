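#!/usr/bin/env Rscript
# Replication run-out sequencing profiles on the circular chromosome.
#
# Renders three population states -- exponential growth (marker-frequency
# pyramid), completed run-out (flat), and a head-on collision locus with
# fork rear-ending (degradation tract) -- normalizes them (CPM, corrected
# for terminus copy number), and summarizes origin:terminus ratios,
# replicore asymmetry at the collision locus, and the degradation plateau.

library(replireset)

dir.create("results", showWarnings = FALSE)
gm <- genome_NC000913()
# Collision locus placed mid-replichore so the trailing round of the
# steady-state fork ladder reaches the stalled fork within the run-out
# (origin-proximal barriers are only rear-ended under hyper-initiation,
# i.e. initiation intervals shorter than the steady-state spacing modelled
# here; see the methods vignette).
stall <- replichore_coord(gm, 0.55, "left")

render <- function(truth, n_cells, at, seed) {
  cells <- simulate_replication_cells(truth, n_cells, seed = seed)
  suppressWarnings(render_runout_coverage(cells, bin_width = 1000,
                                          depth = 400, at = at,
                                          seed = seed + 1))
}

## exponential-phase pyramid (2 fork generations) and completed run-out
tr_exp <- replication_truth(gm, generations_overlap = 1)
cov_exp <- render(tr_exp, 2000, "exponential", 401)
cov_flat <- render(tr_exp, 300, "runout", 403)

## localized head-on collisions with and without DNA-end protection
tr_deg <- replication_truth(gm, generations_overlap = 3, stall_locus = stall,
                            p_stall = 1, p_rearend_given_stall = 1,
                            gam_mode = FALSE)
tr_gam <- replication_truth(gm, generations_overlap = 3, stall_locus = stall,
                            p_stall = 1, p_rearend_given_stall = 1,
                            gam_mode = TRUE)
cov_deg <- render(tr_deg, 400, "reset", 405)
cov_gam <- render(tr_gam, 400, "reset", 407)

tracks <- list(exponential = cov_exp, runout = cov_flat,
               collision_reset = cov_deg, collision_gam = cov_gam)
# asymmetry probe: midway between the stall fraction and the sister-fork
# fraction, the band where degradation depresses only one replichore
probe <- replichore_coord(gm, (tr_deg$geometry$stall_fraction +
                                 tr_deg$geometry$sister_fraction) / 2, "right")
summaries <- lapply(names(tracks), function(nm) {
  nt <- normalize_track(tracks[[nm]], gm, "cpm+terminus")
  write_bedgraph(nt, sprintf("results/runout_%s.bedgraph", nm),
                 chrom = "NC_000913.3")
  sm <- smooth_and_trim(nt, span = 0.02)
  write_bedgraph(sm, sprintf("results/runout_%s_smoothed.bedgraph", nm),
                 chrom = "NC_000913.3")
  data.frame(track = nm,
             ori_ter_ratio = origin_terminus_ratio(nt, gm, window = 20000),
             tract_band_asymmetry = replicore_asymmetry(nt, gm, probe))
})
summary_tab <- do.call(rbind, summaries)
write.table(summary_tab, "results/runout_summaries.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## degradation plateau: boundaries vs the planted event geometry
pl <- detect_degradation_plateau(normalize_track(cov_deg, gm, "cpm"), gm)
pl_gam <- detect_degradation_plateau(normalize_track(cov_gam, gm, "cpm"), gm)
write.table(pl, "results/runout_plateaus.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("ori:ter ratio %.2f in exponential phase, %.2f after run-out\n",
            summary_tab$ori_ter_ratio[1], summary_tab$ori_ter_ratio[2]))
if (nrow(pl) == 1) {
  cat(sprintf(
    "degradation plateau %.0f-%.0f bp (planted rear-end %.0f, sister fork %.0f); %d plateau(s) with Gam\n",
    pl$start, pl$end %% gm$length, tr_deg$geometry$rear_end_locus,
    tr_deg$geometry$sister_fork_locus, nrow(pl_gam)))
}
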