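#' Per-class nucleus geometry and photometry model
#'
#' Describes how each phenotype class is drawn by [render_field()]. Sizes are
#' in micrometres so the same geometry holds at any pixel size.
#'
#' * `normal`: a single ellipse; semi-axes sampled around 6.5 x 4.5 um
#'   (a ~13 x 9 um interphase HeLa nucleus).
#' * `spindle`: one near-circular condensed nucleus at ~60% of the normal
#'   area and ~1.8x the base intensity (condensed mitotic chromatin of a
#'   monopolar-spindle arrest).
#' * `cytokinesis`: 2-4 overlapping elliptical lobes forming one connected
#'   footprint with total area ~1.5-2x normal (multi-/binucleated cells
#'   after failed division).
#'
#' @param semi_axes_um,semi_axes_sd_um mean and s.d. of the normal-class
#'   ellipse semi-axes (major, minor), micrometres.
#' @param base_intensity nuclear base intensity of the normal class (16-bit
#'   counts).
#' @param texture_sd per-pixel Gaussian chromatin-texture s.d. (counts).
#' @param spindle_area_frac,spindle_intensity_mult spindle area as a fraction
#'   of the mean normal area, and its intensity multiplier.
#' @param cyto_lobes admissible lobe counts for the cytokinesis class.
#' @param cyto_area_range total cytokinesis footprint area, as a (lo, hi)
#'   multiple of the mean normal area.
#' @return A list of class `"class_geometry"`.
#' @export
class_geometry <- function(semi_axes_um = c(6.5, 4.5),
                           semi_axes_sd_um = c(0.45, 0.35),
                           base_intensity = 8000,
                           texture_sd = 500,
                           spindle_area_frac = 0.6,
                           spindle_intensity_mult = 1.8,
                           cyto_lobes = 2:4,
                           cyto_area_range = c(1.5, 2.0)) {
  structure(list(semi_axes_um = semi_axes_um,
                 semi_axes_sd_um = semi_axes_sd_um,
                 base_intensity = base_intensity,
                 texture_sd = texture_sd,
                 spindle_area_frac = spindle_area_frac,
                 spindle_intensity_mult = spindle_intensity_mult,
                 cyto_lobes = cyto_lobes,
                 cyto_area_range = cyto_area_range),
            class = "class_geometry")
}

#' Acquisition noise model
#'
#' Noise is applied in a fixed order: background plane, object rendering,
#' optional Poisson shot noise, additive Gaussian read noise, then clipping
#' to the 16-bit range and rounding (integer-quantised rendering, so a fixed
#' seed gives bit-identical images).
#'
#' @param gaussian_sd additive Gaussian read-noise s.d. (counts).
#' @param background constant background level of the nuclei channel.
#' @param background_gradient linear background slope (counts/pixel) along
#'   (rows, cols); `c(0, 0)` for a flat plane.
#' @param shot_noise logical; replace each pre-noise pixel value by a
#'   Poisson draw with that mean.
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(gaussian_sd = 120, background = 400,
                        background_gradient = c(0, 0), shot_noise = TRUE) {
  structure(list(gaussian_sd = gaussian_sd, background = background,
                 background_gradient = background_gradient,
                 shot_noise = shot_noise),
            class = "noise_model")
}

#' Perinuclear cargo (EGF) rendering model
#'
#' Each cell receives a true perinuclear ring intensity drawn from
#' `N(ring_mean, ring_sd)` (truncated at 0); the cargo channel paints an
#' annulus of that intensity around the true nucleus footprint, plus a few
#' bright punctate granules (endosomal clusters) inside the annulus.
#'
#' @param ring_mean,ring_sd mean and between-cell s.d. of the true ring
#'   intensity (counts).
#' @param ring_render_width_px width of the rendered annulus, pixels. Keep it
#'   a little wider than the measurement ring so small segmentation
#'   differences stay inside the rendered signal.
#' @param granule_rate Poisson mean number of granules per cell.
#' @param granule_radius_px granule radius, pixels.
#' @param granule_intensity_mult granule intensity as a multiple of the
#'   cell's ring intensity.
#' @param background cargo-channel background level (counts).
#' @return A list of class `"cargo_model"`.
#' @export
cargo_model <- function(ring_mean = 3000, ring_sd = 450,
                        ring_render_width_px = 10, granule_rate = 2,
                        granule_radius_px = 1, granule_intensity_mult = 1.5,
                        background = 150) {
  structure(list(ring_mean = ring_mean, ring_sd = ring_sd,
                 ring_render_width_px = ring_render_width_px,
                 granule_rate = granule_rate,
                 granule_radius_px = granule_radius_px,
                 granule_intensity_mult = granule_intensity_mult,
                 background = background),
            class = "cargo_model")
}

#' Fluorescent spot-marker model
#'
#' The labelled-siRNA (Cy3) marker of an array spot: a bright disk on a dim
#' background. Cells are placed only inside the disk (cells reverse-transfect
#' on the spot), and the analysis re-detects the disk as its region of
#' interest.
#'
#' @param center_px disk centre `(row, col)` in 0-based pixels, or `NULL` for
#'   the field centre.
#' @param radius_px disk radius in pixels, or `NULL` for 150 um divided by
#'   the scene pixel size (a 300 um printed spot).
#' @param intensity,background marker foreground/background levels (counts).
#' @return A list of class `"marker_spot"`.
#' @export
marker_spot <- function(center_px = NULL, radius_px = NULL, intensity = 4000,
                        background = 200) {
  structure(list(center_px = center_px, radius_px = radius_px,
                 intensity = intensity, background = background),
            class = "marker_spot")
}

#' Specify one synthetic imaging field
#'
#' A `scene_spec` fully determines one rendered field: geometry, expected
#' cell count, phenotype mixture, cargo and marker models, noise, and seed.
#' Defaults emulate the cell-array cell-cycle assay: a 300-um spot imaged at
#' 0.65 um/px in a 512 x 512 field, ~156 cells per spot, and the
#' negative-control phenotype mixture observed on arrays (9.7% spindle,
#' 8% cytokinesis).
#'
#' @param field_shape image shape `(rows, cols)`, pixels.
#' @param pixel_size pixel size, um/px.
#' @param platform `"array_spot"`, `"well96"` or `"well384"`. Well platforms
#'   have no marker spot and place cells across the whole field.
#' @param expected_cells Poisson mean of the number of cells in the field
#'   (inside the spot for `array_spot`).
#' @param phenotype_mix named probabilities `(normal, spindle, cytokinesis)`;
#'   must sum to 1.
#' @param geometry a [class_geometry()].
#' @param cargo a [cargo_model()] or `NULL` for no cargo channel.
#' @param marker a [marker_spot()], `NULL` for none; defaults to a centred
#'   spot for `array_spot` and none otherwise.
#' @param noise a [noise_model()].
#' @param seed integer seed; fixed seed means bit-identical output.
#' @param allow_touching if `FALSE` (default) placement rejects footprints
#'   that touch an existing cell (8-adjacency, 1-px gap); `TRUE` disables the
#'   check for stress tests.
#' @param max_place_attempts placement attempts per cell before it is
#'   dropped with a warning.
#' @return A validated list of class `"scene_spec"`.
#' @export
scene_spec <- function(field_shape = c(512L, 512L),
                       pixel_size = 0.65,
                       platform = c("array_spot", "well96", "well384"),
                       expected_cells = 156,
                       phenotype_mix = c(normal = 0.823, spindle = 0.097,
                                         cytokinesis = 0.080),
                       geometry = class_geometry(),
                       cargo = NULL,
                       marker = if (match.arg(platform) == "array_spot")
                         marker_spot() else NULL,
                       noise = noise_model(),
                       seed = 1L,
                       allow_touching = FALSE,
                       max_place_attempts = 300L) {
  platform <- match.arg(platform)
  spec <- structure(list(field_shape = as.integer(field_shape),
                         pixel_size = pixel_size, platform = platform,
                         expected_cells = expected_cells,
                         phenotype_mix = phenotype_mix, geometry = geometry,
                         cargo = cargo, marker = marker, noise = noise,
                         seed = as.integer(seed),
                         allow_touching = isTRUE(allow_touching),
                         max_place_attempts = as.integer(max_place_attempts)),
                    class = "scene_spec")
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  stopifnot(length(spec$field_shape) == 2, all(spec$field_shape >= 8),
            spec$pixel_size > 0)
  mix <- spec$phenotype_mix
  if (length(mix) != 3 || is.null(names(mix)) ||
      !setequal(names(mix), c("normal", "spindle", "cytokinesis")))
    stop("phenotype_mix must be named (normal, spindle, cytokinesis)")
  if (any(mix < 0) || any(mix > 1))
    stop("phenotype_mix entries must lie in [0, 1]")
  if (abs(sum(mix) - 1) > 1e-12)
    stop("phenotype_mix must sum to 1 (got ", format(sum(mix), digits = 15),
         ")")
  if (spec$expected_cells < 0) stop("expected_cells must be non-negative")
  if (!is.null(spec$marker)) {
    r <- spot_radius_px(spec)
    if (r > min(spec$field_shape) / 2)
      stop("marker radius ", round(r, 1), " px exceeds half the field size")
  }
  spec
}

spot_radius_px <- function(spec) {
  if (is.null(spec$marker)) return(NA_real_)
  if (!is.null(spec$marker$radius_px)) spec$marker$radius_px
  else 150 / spec$pixel_size
}

spot_center_px <- function(spec) {
  if (!is.null(spec$marker$center_px)) spec$marker$center_px
  else (spec$field_shape - 1) / 2
}
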