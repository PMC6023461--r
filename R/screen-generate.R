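# Screen-level generation: a layout (which fields exist) plus per-condition
# effects (phenotype mixture, cargo strength, cell density) drive repeated
# calls to render_field() with deterministically derived per-field seeds.

#' Build a screening layout
#'
#' One row per imaged field. Array spots carry exactly one image per spot;
#' 96-well plates are imaged at 25 subpositions per well and 384-well plates
#' at 9 (so e.g. 6 wells per siRNA in a 384-well plate yield 54 images per
#' condition per replicate).
#'
#' @param platform `"array_spot"`, `"well96"` or `"well384"`.
#' @param conditions character vector of condition (siRNA) labels.
#' @param positions_per_condition spots or wells per condition (9 spots per
#'   siRNA on the arrays of the emulated study).
#' @param replicates number of independent replicates.
#' @param subpositions images per position; defaults to 1 (array), 25
#'   (96-well) or 9 (384-well).
#' @return A data.frame of class `"layout_spec"` with columns `replicate`,
#'   `platform`, `position`, `subposition`, `condition`.
#' @export
build_layout <- function(platform = c("array_spot", "well96", "well384"),
                         conditions, positions_per_condition = 9,
                         replicates = 3, subpositions = NULL) {
  platform <- match.arg(platform)
  if (is.null(subpositions))
    subpositions <- c(array_spot = 1L, well96 = 25L, well384 = 9L)[[platform]]
  if (platform == "array_spot" && subpositions != 1L)
    stop("array_spot layouts have exactly 1 subposition per spot")
  grid <- expand.grid(subposition = seq_len(subpositions),
                      position_index = seq_len(positions_per_condition),
                      condition = conditions,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  out <- data.frame(replicate = grid$replicate, platform = platform,
                    position = sprintf("%s_%02d", grid$condition,
                                       grid$position_index),
                    subposition = grid$subposition,
                    condition = grid$condition, stringsAsFactors = FALSE)
  key <- paste(out$replicate, out$position, out$subposition)
  stopifnot(!anyDuplicated(key))
  out <- out[order(out$replicate, out$position, out$subposition), ]
  rownames(out) <- NULL
  class(out) <- c("layout_spec", "data.frame")
  out
}

#' Describe the effect of one condition (siRNA)
#'
#' @param phenotype_mix named `(normal, spindle, cytokinesis)` probabilities
#'   for cells under this condition.
#' @param cargo_mult multiplier on the cargo ring mean intensity (e.g. 0.35
#'   for a 65% EGF-uptake knockdown).
#' @param density_mult multiplier on the expected cell count (reduced cell
#'   numbers under mitotic-arrest conditions).
#' @return A list of class `"condition_effect"`.
#' @export
condition_effect <- function(phenotype_mix = c(normal = 0.823,
                                               spindle = 0.097,
                                               cytokinesis = 0.080),
                             cargo_mult = 1, density_mult = 1) {
  structure(list(phenotype_mix = phenotype_mix, cargo_mult = cargo_mult,
                 density_mult = density_mult), class = "condition_effect")
}

#' Generate a full synthetic screen
#'
#' Renders one field per layout row. Per-field seeds are derived from the
#' master seed and the field address with [field_seed()], so the same layout
#' and seed give bit-identical images regardless of rendering order.
#'
#' @param layout a [build_layout()] data.frame.
#' @param effects named list of [condition_effect()]s, one entry per
#'   condition appearing in the layout.
#' @param seed master integer seed.
#' @param base a [scene_spec()] providing everything the effects do not
#'   override (field shape, geometry, noise, cargo and marker models,
#'   expected cells).
#' @return A list of class `"synthetic_screen"`: `layout`, `fields` (list of
#'   `field_image`), `truths` (list of `ground_truth`), `base_spec`.
#' @export
generate_screen <- function(layout, effects, seed, base = scene_spec()) {
  missing <- setdiff(unique(layout$condition), names(effects))
  if (length(missing) > 0)
    stop("no condition_effect given for condition(s): ",
         paste(missing, collapse = ", "))
  fields <- vector("list", nrow(layout))
  truths <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    eff <- effects[[row$condition]]
    spec <- base
    spec$platform <- row$platform
    if (row$platform != "array_spot") spec$marker <- NULL
    spec$phenotype_mix <- eff$phenotype_mix
    spec$expected_cells <- base$expected_cells * eff$density_mult
    if (!is.null(spec$cargo))
      spec$cargo$ring_mean <- base$cargo$ring_mean * eff$cargo_mult
    spec$seed <- field_seed(seed, row$replicate, row$position,
                            row$subposition)
    fr <- render_field(spec, meta = list(replicate = row$replicate,
                                         position = row$position,
                                         subposition = row$subposition,
                                         condition = row$condition))
    fields[[i]] <- fr$field
    truths[[i]] <- fr$truth
  }
  names(fields) <- names(truths) <-
    paste(layout$replicate, layout$position, layout$subposition, sep = "_")
  structure(list(layout = layout, fields = fields, truths = truths,
                 base_spec = base), class = "synthetic_screen")
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat("synthetic_screen:", nrow(x$layout), "fields,",
      length(unique(x$layout$condition)), "conditions,",
      length(unique(x$layout$replicate)), "replicate(s),",
      "platform", x$layout$platform[1], "\n")
  invisible(x)
}
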