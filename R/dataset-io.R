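# Disk round trip for synthetic screens: one 16-bit grayscale TIFF per
# channel per field, plus layout.csv / truth_cells.csv / truth_fields.csv.

write_channel_tiff <- function(raster, path) {
  tiff::writeTIFF(raster / 65535, path, bits.per.sample = 16L,
                  compression = "none")
}

read_channel_tiff <- function(path) {
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) stop("failed to read TIFF '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  storage.mode(img) <- "double"
  img
}

#' Write a synthetic screen to a directory
#'
#' Layout: `<replicate>_<position>_<subposition>_<channel>.tif` (16-bit
#' grayscale), `layout.csv` with per-field file references, `truth_cells.csv`
#' (one row per rendered cell) and `truth_fields.csv` (one row per field).
#'
#' @param screen a [generate_screen()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(screen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layout <- screen$layout
  paths <- list(nuclei = character(nrow(layout)),
                marker = character(nrow(layout)),
                cargo = character(nrow(layout)))
  for (i in seq_len(nrow(layout))) {
    fld <- screen$fields[[i]]
    stem <- sprintf("%d_%s_%d", layout$replicate[i], layout$position[i],
                    layout$subposition[i])
    for (ch in names(fld$channels)) {
      fn <- paste0(stem, "_", ch, ".tif")
      write_channel_tiff(fld$channels[[ch]], file.path(dir, fn))
      paths[[ch]][i] <- fn
    }
  }
  lay <- cbind(layout, nuclei_path = paths$nuclei,
               marker_path = paths$marker, cargo_path = paths$cargo)
  write.csv(lay, file.path(dir, "layout.csv"), row.names = FALSE)

  cells <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    tc <- screen$truths[[i]]$cells
    if (nrow(tc) == 0) return(NULL)
    cbind(replicate = layout$replicate[i], position = layout$position[i],
          subposition = layout$subposition[i], tc)
  }))
  if (is.null(cells))
    cells <- data.frame(replicate = integer(), position = character(),
                        subposition = integer(), cell = integer(),
                        class = character(), centroid_row = numeric(),
                        centroid_col = numeric(), footprint_px = integer(),
                        ring_intensity = numeric())
  write.csv(cells, file.path(dir, "truth_cells.csv"), row.names = FALSE)

  flds <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    tf <- screen$truths[[i]]$field
    data.frame(replicate = layout$replicate[i], position = layout$position[i],
               subposition = layout$subposition[i], n_cells = tf$n_cells,
               frac_normal = tf$frac_normal, frac_spindle = tf$frac_spindle,
               frac_cytokinesis = tf$frac_cytokinesis,
               mean_cargo = tf$mean_cargo)
  }))
  write.csv(flds, file.path(dir, "truth_fields.csv"), row.names = FALSE)
  invisible(dir)
}

validate_layout_csv <- function(lay, path) {
  required <- c("replicate", "platform", "position", "subposition",
                "condition", "nuclei_path")
  miss <- setdiff(required, names(lay))
  if (length(miss) > 0)
    stop("layout CSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!lay$platform %in% c("array_spot", "well96", "well384") |
                 is.na(lay$replicate) | is.na(lay$subposition) |
                 is.na(lay$position) | lay$nuclei_path == "")
  if (length(bad) > 0)
    stop("layout CSV '", path, "' is malformed at row ", bad[1],
         " (bad platform, missing field address, or missing nuclei path)")
  lay
}

#' Read a screen dataset from a directory
#'
#' Inverse of [write_dataset()]: images are read back bit-exactly and the
#' ground-truth tables are reattached when present.
#'
#' @param dir dataset directory containing `layout.csv`.
#' @return A list of class `"synthetic_screen"` (without `base_spec`); the
#'   `truths` element is `NULL` when no truth CSVs are present.
#' @export
read_dataset <- function(dir) {
  lay_path <- file.path(dir, "layout.csv")
  if (!file.exists(lay_path)) stop("no layout.csv in '", dir, "'")
  lay <- validate_layout_csv(read.csv(lay_path, stringsAsFactors = FALSE),
                             lay_path)
  fields <- vector("list", nrow(lay))
  for (i in seq_len(nrow(lay))) {
    channels <- list(nuclei = read_channel_tiff(file.path(dir,
                                                          lay$nuclei_path[i])))
    if (!is.na(lay$marker_path[i]) && nzchar(lay$marker_path[i]))
      channels$marker <- read_channel_tiff(file.path(dir, lay$marker_path[i]))
    if (!is.na(lay$cargo_path[i]) && nzchar(lay$cargo_path[i]))
      channels$cargo <- read_channel_tiff(file.path(dir, lay$cargo_path[i]))
    fields[[i]] <- structure(list(channels = channels,
                                  meta = list(replicate = lay$replicate[i],
                                              position = lay$position[i],
                                              subposition = lay$subposition[i],
                                              condition = lay$condition[i],
                                              platform = lay$platform[i])),
                             class = "field_image")
  }
  names(fields) <- paste(lay$replicate, lay$position, lay$subposition,
                         sep = "_")
  truths <- NULL
  tc_path <- file.path(dir, "truth_cells.csv")
  tf_path <- file.path(dir, "truth_fields.csv")
  if (file.exists(tc_path) && file.exists(tf_path)) {
    tc <- read.csv(tc_path, stringsAsFactors = FALSE)
    tf <- read.csv(tf_path, stringsAsFactors = FALSE)
    truths <- lapply(seq_len(nrow(lay)), function(i) {
      sel <- tc$replicate == lay$replicate[i] &
        tc$position == lay$position[i] & tc$subposition == lay$subposition[i]
      fsel <- tf$replicate == lay$replicate[i] &
        tf$position == lay$position[i] & tf$subposition == lay$subposition[i]
      structure(list(cells = tc[sel, setdiff(names(tc),
                                             c("replicate", "position",
                                               "subposition"))],
                     field = as.list(tf[fsel, c("n_cells", "frac_normal",
                                                "frac_spindle",
                                                "frac_cytokinesis",
                                                "mean_cargo")])),
                class = "ground_truth")
    })
    names(truths) <- names(fields)
  }
  layout <- lay[, c("replicate", "platform", "position", "subposition",
                    "condition")]
  class(layout) <- c("layout_spec", "data.frame")
  structure(list(layout = layout, fields = fields, truths = truths),
            class = "synthetic_screen")
}
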