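# End-to-end analysis of a screen: segmentation, optional spot-ROI
# restriction, phenotype classification, optional EGF quantification,
# and aggregation to the position (spot/well) level.

#' Analyse one field
#'
#' @param field a `field_image`.
#' @param model a fitted `phenotype_model`.
#' @param params a [seg_params()].
#' @param ring_width_px perinuclear ring width (pixels) for the cargo
#'   readout.
#' @return A list: `labels` (after ROI restriction), `features`, `classes`,
#'   `roi` (or `NULL`), `egf` (per-cell data.frame or `NULL`), `row` (one
#'   subposition-level readout row).
#' @export
analyze_field <- function(field, model, params = seg_params(),
                          ring_width_px = 8) {
  seg <- segment_field(field$channels$nuclei, params)
  labels <- seg$labels
  features <- seg$features
  roi <- NULL
  if (!is.null(field$channels$marker) &&
      identical(field$meta$platform, "array_spot")) {
    ps <- field$meta$pixel_size
    if (is.null(ps)) ps <- 0.65
    roi <- detect_spot_roi(field$channels$marker, ps)
    labels <- restrict_to_roi(labels, roi)
    kept <- attr(labels, "kept")
    features <- features[kept, , drop = FALSE]
    if (nrow(features) > 0) features$label <- seq_len(nrow(features))
    rownames(features) <- NULL
  }
  classes <- classify_nuclei(model, features)
  fr <- phenotype_fractions(classes)

  egf <- NULL
  egf_n <- 0L
  egf_sum <- 0
  if (!is.null(field$channels$cargo) && max(labels) > 0) {
    rings <- make_perinuclear_rings(labels, ring_width_px)
    egf <- measure_cargo(rings, field$channels$cargo)
    egf_n <- nrow(egf)
    egf_sum <- sum(egf$mean_intensity)
  }

  meta <- field$meta
  row <- data.frame(replicate = meta$replicate %||% NA,
                    platform = meta$platform %||% NA,
                    position = meta$position %||% NA,
                    subposition = meta$subposition %||% NA,
                    condition = meta$condition %||% NA,
                    n_cells = fr$n_cells,
                    n_normal = sum(classes == "normal"),
                    n_spindle = sum(classes == "spindle"),
                    n_cytokinesis = sum(classes == "cytokinesis"),
                    frac_normal = fr$frac_normal,
                    frac_spindle = fr$frac_spindle,
                    frac_cytokinesis = fr$frac_cytokinesis,
                    egf_n = egf_n, egf_sum = egf_sum,
                    mean_egf = if (egf_n > 0) egf_sum / egf_n else NA_real_,
                    stringsAsFactors = FALSE)
  list(labels = labels, features = features, classes = classes, roi = roi,
       egf = egf, row = row)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyse a whole screen
#'
#' Runs [analyze_field()] over every field and pools subpositions into
#' position-level rows with [aggregate_position()].
#'
#' @param screen a `synthetic_screen` (from [generate_screen()] or
#'   [read_dataset()]).
#' @param model a fitted `phenotype_model`.
#' @param params a [seg_params()].
#' @param ring_width_px perinuclear ring width, pixels.
#' @return A list of class `"screen_readouts"`: `fields` (subposition-level
#'   table) and `positions` (position-level table).
#' @export
analyze_screen <- function(screen, model, params = seg_params(),
                           ring_width_px = 8) {
  rows <- vector("list", length(screen$fields))
  for (i in seq_along(screen$fields)) {
    rows[[i]] <- analyze_field(screen$fields[[i]], model, params,
                               ring_width_px)$row
  }
  fields <- do.call(rbind, rows)
  key <- interaction(fields$replicate, fields$position, drop = TRUE)
  positions <- do.call(rbind, lapply(split(fields, key), aggregate_position))
  positions <- positions[order(positions$replicate, positions$position), ]
  rownames(positions) <- NULL
  structure(list(fields = fields, positions = positions),
            class = "screen_readouts")
}

#' Check row-count conservation of a screen readout
#'
#' Verifies that position-level cell counts are exactly the sums of their
#' subposition-level counts, that pooled class counts add up to the cell
#' count, and that fractions sum to 1 wherever cells were found.
#'
#' @param readouts an [analyze_screen()] result.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
check_conservation <- function(readouts) {
  f <- readouts$fields
  p <- readouts$positions
  for (i in seq_len(nrow(p))) {
    sel <- f$replicate == p$replicate[i] & f$position == p$position[i]
    if (sum(f$n_cells[sel]) != p$n_cells[i])
      stop("cell-count conservation violated at position ", p$position[i])
  }
  bad <- which(f$n_cells != f$n_normal + f$n_spindle + f$n_cytokinesis)
  if (length(bad) > 0)
    stop("class counts do not sum to n_cells in field row ", bad[1])
  ok <- p$n_cells > 0
  s <- p$frac_normal[ok] + p$frac_spindle[ok] + p$frac_cytokinesis[ok]
  if (any(abs(s - 1) > 1e-9))
    stop("position-level fractions do not sum to 1")
  invisible(TRUE)
}

#' @export
print.screen_readouts <- function(x, ...) {
  cat("screen_readouts:", nrow(x$fields), "fields,", nrow(x$positions),
      "positions\n")
  print(utils::head(x$positions, 10))
  invisible(x)
}
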