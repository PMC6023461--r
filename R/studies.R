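# Parameter-recovery studies at the emulated screening regimes. Each one
# generates a synthetic screen at the study's published conditions, runs the
# full analysis chain, and compares the recovered quantity with the
# generator's truth. They back both the test suite and the reproduction
# script.

study_model <- function() {
  fit_phenotype_model(read_training_csv(
    system.file("extdata", "training_features_synthetic.csv",
                package = "spotscreen", mustWork = TRUE)))
}

#' Spindle-fraction recovery at the cell-array regime
#'
#' Renders a cell-array screen (9 spots x 3 replicas, ~156 cells/spot, one
#' image per spot) whose true spindle mixture component is the ~30%
#' monopolar-spindle frequency observed on cell arrays at the 24-30 h
#' time point, runs segmentation, classification and spot aggregation, and
#' reports the grand mean spindle percentage over all spots.
#'
#' @param seed master seed.
#' @param spindle_frac true spindle mixture component.
#' @param spots,replicates,cells_per_spot design of the synthetic screen.
#' @return A list: `estimate_pct`, `true_pct`, `n_positions`, `positions`.
#' @export
spindle_recovery_study <- function(seed = 42, spindle_frac = 0.30,
                                   spots = 9, replicates = 3,
                                   cells_per_spot = 156) {
  mix <- c(normal = 1 - spindle_frac - 0.05, spindle = spindle_frac,
           cytokinesis = 0.05)
  lay <- build_layout("array_spot", "siKIF11",
                      positions_per_condition = spots,
                      replicates = replicates)
  scr <- generate_screen(lay, list(siKIF11 = condition_effect(mix)),
                         seed = seed,
                         base = scene_spec(expected_cells = cells_per_spot))
  readouts <- analyze_screen(scr, study_model())
  check_conservation(readouts)
  list(estimate_pct = 100 * mean(readouts$positions$frac_spindle),
       true_pct = 100 * spindle_frac,
       n_positions = nrow(readouts$positions),
       positions = readouts$positions)
}

#' Per-spot cell-count recovery at the cell-array density
#'
#' Renders spot fields at the per-spot density of the cell-cycle assay on
#' arrays (~156 cells/spot), detects nuclei, restricts them to the detected
#' spot ROI, and reports the mean detected count per spot.
#'
#' @param seed master seed.
#' @param cells_per_spot configured per-spot expectation.
#' @param spots,replicates design of the synthetic screen.
#' @return A list: `mean_detected`, `expected`, `n_positions`, `positions`.
#' @export
cell_density_study <- function(seed = 7, cells_per_spot = 156, spots = 9,
                               replicates = 3) {
  lay <- build_layout("array_spot", "NC", positions_per_condition = spots,
                      replicates = replicates)
  scr <- generate_screen(lay, list(NC = condition_effect()), seed = seed,
                         base = scene_spec(expected_cells = cells_per_spot))
  readouts <- analyze_screen(scr, study_model())
  list(mean_detected = mean(readouts$positions$n_cells),
       expected = cells_per_spot,
       n_positions = nrow(readouts$positions),
       positions = readouts$positions)
}

#' EGF-uptake knockdown recovery
#'
#' Renders the EGF internalization assay on arrays (5 spots x 3 replicas per
#' condition, ~93 cells/spot) with a configurable true reduction of the
#' perinuclear ring intensity under receptor knockdown (the emulated study
#' reports 60-70%), quantifies perinuclear EGF per spot, and reports the
#' recovered percent reduction plus the Games-Howell comparison against the
#' negative control on spot-level means.
#'
#' @param seed master seed.
#' @param reduction true fractional reduction of ring intensity (0.65 =
#'   65%).
#' @param spots,replicates,cells_per_spot design of the synthetic screen.
#' @return A list: `estimated_reduction_pct`, `true_reduction_pct`,
#'   `gh_p_value`, `positions`.
#' @export
egf_knockdown_study <- function(seed = 1, reduction = 0.65, spots = 5,
                                replicates = 3, cells_per_spot = 93) {
  lay <- build_layout("array_spot", c("NC", "siEGFR"),
                      positions_per_condition = spots,
                      replicates = replicates)
  eff <- list(NC = condition_effect(cargo_mult = 1),
              siEGFR = condition_effect(cargo_mult = 1 - reduction))
  scr <- generate_screen(lay, eff, seed = seed,
                         base = scene_spec(expected_cells = cells_per_spot,
                                           cargo = cargo_model()))
  readouts <- analyze_screen(scr, study_model())
  pos <- readouts$positions
  m_nc <- mean(pos$mean_egf[pos$condition == "NC"])
  m_kd <- mean(pos$mean_egf[pos$condition == "siEGFR"])
  gh <- games_howell(pos$mean_egf, pos$condition)
  list(estimated_reduction_pct = 100 * (1 - m_kd / m_nc),
       true_reduction_pct = 100 * reduction,
       gh_p_value = gh$p.value[1],
       positions = pos)
}
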