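# Spot-ROI detection, ROI restriction, and aggregation of per-field
# readouts into per-position (spot/well) tables.

#' Detect the spot region of interest from the marker channel
#'
#' Otsu-thresholds the labelled-siRNA marker image and takes the largest
#' connected component: its centroid is the spot centre and its
#' equivalent-circle radius the spot radius. A fallback ROI -- centred in
#' the field with radius 150 um divided by the pixel size (a 300-um printed
#' spot) -- is returned when the marker carries no usable spot: foreground
#' below 1% or above 90% of the field (blank or saturated marker), or an
#' Otsu split whose class separation is under 2 pooled within-class
#' standard deviations (a threshold cutting through featureless noise
#' rather than a labelled spot).
#'
#' @param marker numeric marker-channel matrix.
#' @param pixel_size um/px, used for the fallback radius.
#' @return A list of class `"spot_roi"`: `center` (0-based row, col),
#'   `radius` (px), `source` (`"detected"` or `"fallback"`).
#' @export
detect_spot_roi <- function(marker, pixel_size = 0.65) {
  fallback <- structure(list(center = (dim(marker) - 1) / 2,
                             radius = 150 / pixel_size,
                             source = "fallback"), class = "spot_roi")
  thr <- tryCatch(otsu_threshold(marker), error = function(e) NULL)
  if (is.null(thr)) return(fallback)
  fg <- marker > thr
  frac <- mean(fg)
  if (frac < 0.01 || frac > 0.9) return(fallback)
  sep <- mean(marker[fg]) - mean(marker[!fg])
  spread <- sd(marker[fg]) + sd(marker[!fg])
  if (!is.finite(sep) || !is.finite(spread) || sep < 2 * spread)
    return(fallback)
  lab <- label_components(fg, 8)
  sizes <- tabulate(lab[lab > 0])
  k <- which.max(sizes)
  idx <- which(lab == k)
  rows0 <- (idx - 1) %% nrow(marker)
  cols0 <- (idx - 1) %/% nrow(marker)
  structure(list(center = c(mean(rows0), mean(cols0)),
                 radius = sqrt(sizes[k] / pi), source = "detected"),
            class = "spot_roi")
}

#' Restrict a label map to an ROI
#'
#' Keeps nuclei whose pixel centroid lies inside the ROI disc and relabels
#' the survivors contiguously.
#'
#' @param labels integer label matrix.
#' @param roi a [detect_spot_roi()] result.
#' @return Integer label matrix with attribute `kept` mapping new labels to
#'   the original ones (`kept[new] = old`).
#' @export
restrict_to_roi <- function(labels, roi) {
  K <- max(labels)
  if (K == 0) {
    attr(labels, "kept") <- integer(0)
    return(labels)
  }
  nr <- nrow(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  f <- factor(lab, levels = seq_len(K))
  crow <- tapply((idx - 1) %% nr, f, mean)
  ccol <- tapply((idx - 1) %/% nr, f, mean)
  inside <- (crow - roi$center[1])^2 + (ccol - roi$center[2])^2 <=
    roi$radius^2
  out <- labels
  out[out %in% which(!inside)] <- 0L
  rl <- relabel(out)
  out <- rl$labels
  attr(out, "kept") <- rl$map
  out
}

#' Pool per-field readouts into one position row
#'
#' Phenotype fractions and the EGF mean are pooled cell-weighted over all
#' subpositions of one (replicate, position): total class counts over total
#' cells, so pooling equals recomputation from the concatenated per-cell
#' labels.
#'
#' @param field_rows data.frame of per-field rows sharing one
#'   (replicate, position): columns `replicate`, `platform`, `position`,
#'   `condition`, `n_cells`, `n_normal`, `n_spindle`, `n_cytokinesis`, and
#'   optionally `egf_n`, `egf_sum`.
#' @return A one-row data.frame; zero total cells give NA fractions plus a
#'   warning.
#' @export
aggregate_position <- function(field_rows) {
  stopifnot(nrow(field_rows) >= 1,
            length(unique(field_rows$position)) == 1,
            length(unique(field_rows$replicate)) == 1)
  n <- sum(field_rows$n_cells)
  has_egf <- all(c("egf_n", "egf_sum") %in% names(field_rows))
  egf_n <- if (has_egf) sum(field_rows$egf_n) else 0L
  out <- data.frame(replicate = field_rows$replicate[1],
                    platform = field_rows$platform[1],
                    position = field_rows$position[1],
                    condition = field_rows$condition[1],
                    n_subpositions = nrow(field_rows),
                    n_cells = n,
                    frac_normal = NA_real_, frac_spindle = NA_real_,
                    frac_cytokinesis = NA_real_,
                    mean_egf = NA_real_, egf_n = egf_n,
                    stringsAsFactors = FALSE)
  if (n == 0) {
    warning("position ", field_rows$position[1], " replicate ",
            field_rows$replicate[1], " has zero cells; flagged")
    return(out)
  }
  out$frac_normal <- sum(field_rows$n_normal) / n
  out$frac_spindle <- sum(field_rows$n_spindle) / n
  out$frac_cytokinesis <- sum(field_rows$n_cytokinesis) / n
  if (has_egf && egf_n > 0) out$mean_egf <- sum(field_rows$egf_sum) / egf_n
  out
}

#' Normalise EGF readouts to a percentage scale
#'
#' @param positions position-level readout table (from [analyze_screen()]).
#' @param mode `"percent_of_nc"` (default: 100 x mean_egf over the
#'   replicate's negative-control mean), `"percent_of_max_position"`, or
#'   `"raw"`.
#' @param nc negative-control condition label.
#' @return The table with an extra `mean_egf_pct` column.
#' @export
normalize_egf <- function(positions,
                          mode = c("percent_of_nc", "percent_of_max_position",
                                   "raw"),
                          nc = "NC") {
  mode <- match.arg(mode)
  if (mode == "raw") {
    positions$mean_egf_pct <- positions$mean_egf
    return(positions)
  }
  positions$mean_egf_pct <- NA_real_
  for (rep_ in unique(positions$replicate)) {
    sel <- positions$replicate == rep_
    baseline <- if (mode == "percent_of_nc") {
      nc_sel <- sel & positions$condition == nc
      if (!any(nc_sel)) stop("no '", nc, "' positions in replicate ", rep_)
      mean(positions$mean_egf[nc_sel], na.rm = TRUE)
    } else {
      max(positions$mean_egf[sel], na.rm = TRUE)
    }
    if (!is.finite(baseline) || baseline == 0)
      stop("zero or undefined EGF baseline in replicate ", rep_)
    positions$mean_egf_pct[sel] <- 100 * positions$mean_egf[sel] / baseline
  }
  positions
}

#' Cell counts as percent of the negative control
#'
#' Within each selected replicate, the per-condition mean cell count is
#' divided by the negative-control mean; the percentages are then averaged
#' over the selected replicates (the emulated study used two of its three
#' replicates for this analysis).
#'
#' @param positions position-level readout table.
#' @param nc negative-control condition label.
#' @param replicates replicates to include (default all).
#' @return data.frame (`condition`, `cells_pct`).
#' @export
normalize_cell_counts <- function(positions, nc = "NC", replicates = NULL) {
  if (is.null(replicates)) replicates <- unique(positions$replicate)
  positions <- positions[positions$replicate %in% replicates, ]
  if (!nc %in% positions$condition)
    stop("negative control '", nc, "' absent from table")
  conds <- unique(positions$condition)
  per_rep <- lapply(replicates, function(rep_) {
    sel <- positions$replicate == rep_
    base <- mean(positions$n_cells[sel & positions$condition == nc])
    if (!any(sel & positions$condition == nc))
      stop("negative control '", nc, "' missing in replicate ", rep_)
    sapply(conds, function(cn)
      100 * mean(positions$n_cells[sel & positions$condition == cn]) / base)
  })
  data.frame(condition = conds,
             cells_pct = rowMeans(do.call(cbind, per_rep)),
             stringsAsFactors = FALSE)
}
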