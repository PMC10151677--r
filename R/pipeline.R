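# End-to-end studies: the wax-slab port-effect benchmark, the RS1-vs-RS2
# strategy comparison, and the breast-phantom arc DVH study.

## fixed analysis windows for the wax-slab scene (mm; slab spans y 15-32)
.SLAB_EXIT_Y <- 32
.DISTAL_SEARCH <- c(34, 130)   # where the maximum underdose is read
.DISTAL_FALLOFF <- c(34, 82)   # averaging window for strategy differences

#' Wax-slab port-effect study
#'
#' Builds the wax-slab scene for one expander model, runs the Monte Carlo
#' engine with the port present and with the port substituted by wax (same
#' 6 MV AP 15 x 10 cm^2 beam, 500 MU), and quantifies the port effect on
#' the depth profile through the magnet center: maximum distal underdose
#' beyond the slab, maximum proximal (backscatter) overdose upstream of the
#' magnet with its decay distance, and the per-voxel statistical quality of
#' the run.
#'
#' @param model expander model.
#' @param histories MC histories per run.
#' @param seed integer seed (the no-port run uses `seed + 1`).
#' @param spacing grid spacing, mm.
#' @param histories_are_total unused placeholder for future splitting.
#' @return list with `port_effect` (a [port_effect()] object),
#'   `underdose`, `backscatter`, `quality` (median relative uncertainty
#'   in the >50% dose region, percent), and the two `tte_dose` runs.
#' @export
slab_port_study <- function(model, histories = 4e6, seed = 1L, spacing = 2) {
  scene <- wax_slab_scene(model)
  ph <- voxelize(scene, spacing)
  beam <- beam_spec(field = c(15, 10), mu = 500, spectrum = spectrum_6mv(),
                    ssd = 100, gantry = 0, ref = c(0, 0, 0))
  g_with <- truth_grid(ph)
  g_without <- no_port_grid(ph)
  ## paired runs: same seed and shared majorant, so histories are
  ## identical until they reach the port region
  with_port <- mc_dose(g_with, beam, histories = histories, seed = seed,
                       majorant_from = g_without)
  no_port <- mc_dose(g_without, beam, histories = histories, seed = seed,
                     majorant_from = g_with)
  pe <- port_effect(no_port, with_port, axis = "y",
                    through = scene$profile_point, lateral_avg_mm = 10,
                    smooth = 3L)
  under <- max_underdose(pe, .DISTAL_SEARCH)
  ## proximal window: from 4 mm depth to just above the port assembly
  tpl <- scene$template
  assembly_top <- scene$iso[2] - max(vapply(scene$solids[scene$port_solid_idx],
    function(s) s$half_height + abs(s$center[2] - scene$iso[2]), 0))
  over <- max_overdose(pe, c(4, assembly_top - 1))
  ## decay: overdose compatible with zero at >= 5 mm upstream of its peak
  p <- pe$profile
  sel <- p$position <= over$position - 5 & p$position >= 4
  decayed <- if (any(sel)) {
    i <- max(which(sel))
    abs(p$diff_pct[i]) < 2 * p$unc_pct[i]
  } else NA
  hi <- with_port$dose$data > 0.5 * max(with_port$dose$data)
  quality <- 100 * stats::median(with_port$relunc$data[hi])
  list(model = model, port_effect = pe, underdose = under,
       backscatter = c(over, list(decayed_within_5mm = decayed)),
       quality = quality,
       with_port = with_port, no_port = no_port, phantom = ph)
}

#' Wax-slab RS1-vs-RS2 strategy study
#'
#' Synthesizes the CT of the wax-slab scene (with artifact bloom), derives
#' the RS1 and RS2 density grids, computes the dose for both with the same
#' engine, beam and monitor units, and reports the central-axis percentage
#' difference `100 (D_RS1 - D_RS2) / D_RS1` averaged over the distal
#' falloff region beyond the slab (positive: RS1 hotter).
#'
#' @inheritParams slab_port_study
#' @param engine "mc" or "raytrace".
#' @return list with `distal_diff_pct`, `distal_diff_unc`, `pose` (the RS2
#'   registration), the two dose runs and the grids.
#' @export
slab_strategy_study <- function(model, histories = 4e6, seed = 1L,
                                spacing = 2, engine = "mc") {
  scene <- wax_slab_scene(model)
  ph <- voxelize(scene, spacing)
  ct <- synthesize_ct(ph, saturation = 2.5, bloom = TRUE)
  g1 <- rs1_override(ct)
  r2 <- rs2_register(ct, scene$template)
  beam <- beam_spec(field = c(15, 10), mu = 500, spectrum = spectrum_6mv(),
                    ssd = 100, gantry = 0, ref = c(0, 0, 0))
  run <- function(g, s, other) {
    if (engine == "mc") mc_dose(g, beam, histories = histories, seed = s,
                                majorant_from = other)
    else raytrace_dose(g, beam)
  }
  d1 <- run(g1, seed, r2$grid)
  d2 <- run(r2$grid, seed, g1)
  pe <- port_effect(d1, d2, axis = "y", through = scene$profile_point,
                    lateral_avg_mm = 10, smooth = 3L)
  p <- pe$profile
  sel <- p$position >= .DISTAL_FALLOFF[1] & p$position <= .DISTAL_FALLOFF[2]
  list(model = model,
       distal_diff_pct = mean(p$diff_pct[sel]),
       distal_diff_unc = sqrt(sum(p$unc_pct[sel]^2)) / sum(sel),
       pose = r2$pose, port_effect = pe,
       rs1 = d1, rs2 = d2, grids = list(rs1 = g1, rs2 = r2$grid),
       phantom = ph)
}

#' Breast-phantom arc DVH study
#'
#' Builds the breast scene for a dual-port model, generates its synthetic
#' CT (with bloom), derives the no-port, RS1 and RS2 density grids, runs
#' the 6 MV 3 x 3 cm^2 conformal arc (gantry 90 to 270 counterclockwise,
#' 355 MU) on each with the Monte Carlo engine, and tabulates the DVH
#' differences (D1/D10/mean) on the four 3-mm shell contours.
#'
#' @inheritParams slab_port_study
#' @param histories total MC histories per run, split over control points.
#' @param cp_spacing control-point spacing, degrees.
#' @return list with `report` (a [dvh_difference_report()]), `contours`,
#'   the three dose runs and the phantom.
#' @export
breast_dvh_study <- function(model, histories = 6e6, seed = 1L, spacing = 2,
                             cp_spacing = 2) {
  scene <- breast_scene(model)
  ph <- voxelize(scene, spacing)
  contours <- make_shell_contours(ph)
  ct <- synthesize_ct(ph, saturation = 2.5, bloom = TRUE)
  ## the no-port baseline lives in the same planning (override) context as
  ## RS1/RS2 so the differences isolate the port representation itself
  grids <- list(noport = no_port_override(ct),
                rs1 = rs1_override(ct),
                rs2 = rs2_register(ct, scene$template)$grid)
  arc <- arc_spec(start = 90, stop = 270, direction = "ccw",
                  spacing = cp_spacing, field = c(3, 3), mu = 355,
                  spectrum = spectrum_6mv())
  runs <- list()
  for (i in seq_along(grids)) {
    runs[[names(grids)[i]]] <- arc_dose(grids[[i]], arc, engine = "mc",
                                        histories = histories, seed = seed,
                                        majorant_from = grids[-i])
  }
  shells <- contours[c("C_Anterior", "C_Posterior", "C_Left", "C_Right")]
  report <- dvh_difference_report(runs, shells)
  list(model = model, report = report, contours = contours, runs = runs,
       arc = arc, phantom = ph)
}

#' Run the full characterization and write its artifacts
#'
#' Chains the three studies for all applicable models and writes the
#' port-effect profiles, the strategy comparison and the DVH report tables
#' as CSV files (plus a JSON summary with seeds and configuration hash)
#' under `outdir`.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param histories_slab histories per wax-slab run.
#' @param histories_arc total histories per arc run.
#' @param models expander models for the slab studies.
#' @param arc_models dual-port models for the breast study.
#' @return named list with all study results, invisibly; files under
#'   `outdir`.
#' @export
reproduce_study <- function(outdir, seed = 1L, histories_slab = 4e6,
                            histories_arc = 6e6,
                            models = TTE_MODELS,
                            arc_models = c("AlloX2", "AlloX2-Pro")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(seed = seed, histories_slab = histories_slab,
              histories_arc = histories_arc, models = models,
              arc_models = arc_models, version = "0.1.0")
  hash <- config_hash(cfg)
  summary <- list(config = cfg, config_hash = hash)
  out <- list()
  for (m in models) {
    message("slab port-effect study: ", m)
    st <- slab_port_study(m, histories = histories_slab, seed = seed)
    out$slab[[m]] <- st
    write_report_csv(st$port_effect$profile,
                     file.path(outdir, paste0("port_effect_", gsub("-", "_", m), ".csv")),
                     meta = list(model = m, engine = "mc", seed = seed,
                                 histories = histories_slab,
                                 config_hash = hash,
                                 normalization = "percent of the no-port dose"))
    summary$port_effect[[m]] <- list(
      max_underdose_pct = st$underdose$value,
      position_mm = st$underdose$position,
      backscatter_pct = st$backscatter$value,
      quality_pct = st$quality)
  }
  for (m in c("DermaSpan", "AlloX2-Pro")) {
    message("slab strategy study: ", m)
    ss <- slab_strategy_study(m, histories = histories_slab, seed = seed + 11L)
    out$strategy[[m]] <- ss
    summary$strategy[[m]] <- list(distal_diff_pct = ss$distal_diff_pct,
                                  unc = ss$distal_diff_unc)
  }
  for (m in arc_models) {
    message("breast arc DVH study: ", m)
    bs <- breast_dvh_study(m, histories = histories_arc, seed = seed + 29L)
    out$breast[[m]] <- bs
    write_report_csv(bs$report,
                     file.path(outdir, paste0("dvh_report_", gsub("-", "_", m), ".csv")),
                     meta = list(model = m, engine = "mc-arc", seed = seed,
                                 histories = histories_arc,
                                 config_hash = hash,
                                 normalization = attr(bs$report, "normalization")))
    summary$dvh[[m]] <- as.list(bs$report[bs$report$contour == "C_Posterior",
                                          c("noport_minus_rs2_D10",
                                            "rs1_minus_rs2_D10")])
  }
  write_config(summary, file.path(outdir, "summary.json"))
  invisible(out)
}
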