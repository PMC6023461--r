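# Synthetic field rendering: cells are placed by reject-and-resample so that
# footprints of distinct cells never touch (the downstream pipeline has no
# splitting step), painted onto a background plane, then degraded by optional
# Poisson shot noise and Gaussian read noise, clipped to [0, 65535] and
# rounded.

# Pixels of a (possibly rotated) ellipse; returns 1-based (row, col) matrix.
ellipse_pixels <- function(center, a, b, theta) {
  ext <- ceiling(max(a, b)) + 1L
  rows <- floor(center[1] - ext):ceiling(center[1] + ext)
  cols <- floor(center[2] - ext):ceiling(center[2] + ext)
  g <- expand.grid(row = rows, col = cols)
  dr <- g$row - center[1]
  dc <- g$col - center[2]
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = g$row[inside], col = g$col[inside])
}

# Sample the footprint (pixel set) and per-pixel intensity of one cell.
sample_cell <- function(class, center, geom, pixel_size) {
  mean_area_px <- pi * prod(geom$semi_axes_um / pixel_size)
  if (class == "normal") {
    a <- max(2, rnorm(1, geom$semi_axes_um[1], geom$semi_axes_sd_um[1]))
    b <- max(1.5, rnorm(1, geom$semi_axes_um[2], geom$semi_axes_sd_um[2]))
    px <- ellipse_pixels(center, a / pixel_size, b / pixel_size,
                         runif(1, 0, pi))
    base <- geom$base_intensity
  } else if (class == "spindle") {
    area <- max(10, rnorm(1, geom$spindle_area_frac * mean_area_px,
                          0.08 * geom$spindle_area_frac * mean_area_px))
    aspect <- runif(1, 1, 1.15)
    b <- sqrt(area / (pi * aspect))
    px <- ellipse_pixels(center, aspect * b, b, runif(1, 0, pi))
    base <- geom$base_intensity * geom$spindle_intensity_mult
  } else {
    m <- if (length(geom$cyto_lobes) == 1) geom$cyto_lobes
         else sample(geom$cyto_lobes, 1)
    total <- runif(1, geom$cyto_area_range[1], geom$cyto_area_range[2]) *
      mean_area_px
    px <- NULL
    prev_center <- center
    prev_b <- NA
    for (j in seq_len(m)) {
      area_j <- (total / m) * runif(1, 0.9, 1.1)
      aspect <- runif(1, 1.1, 1.5)
      b <- sqrt(area_j / (pi * aspect))
      if (j == 1) ctr <- center
      else {
        # keep lobes chained: centre-to-centre distance below b_prev + b_cur
        # guarantees the elliptical lobes overlap into one connected footprint
        ang <- runif(1, 0, 2 * pi)
        d <- 0.8 * (prev_b + b)
        ctr <- prev_center + d * c(cos(ang), sin(ang))
      }
      px <- rbind(px, ellipse_pixels(ctr, aspect * b, b, runif(1, 0, pi)))
      prev_center <- ctr
      prev_b <- b
    }
    px <- px[!duplicated(px), , drop = FALSE]
    base <- geom$base_intensity
  }
  list(pixels = px,
       values = base + rnorm(nrow(px), 0, geom$texture_sd))
}

# 8-neighbourhood inflation of a pixel set (used to enforce the 1-px gap).
inflate_pixels <- function(px, shape) {
  dr <- c(-1, -1, -1, 0, 0, 0, 1, 1, 1)
  dc <- c(-1, 0, 1, -1, 0, 1, -1, 0, 1)
  rows <- rep(px[, 1], each = 9) + dr
  cols <- rep(px[, 2], each = 9) + dc
  ok <- rows >= 1 & rows <= shape[1] & cols >= 1 & cols <= shape[2]
  cbind(rows[ok], cols[ok])
}

apply_noise <- function(raster, noise) {
  if (isTRUE(noise$shot_noise)) {
    v <- as.numeric(raster)
    raster[] <- rpois(length(v), pmax(v, 0))
  }
  raster <- raster + rnorm(length(raster), 0, noise$gaussian_sd)
  raster[] <- round(pmin(pmax(raster, 0), 65535))
  raster
}

background_plane <- function(shape, level, gradient) {
  plane <- matrix(level, shape[1], shape[2])
  if (any(gradient != 0)) {
    plane <- plane + outer((seq_len(shape[1]) - 1) * gradient[1],
                           (seq_len(shape[2]) - 1) * gradient[2], `+`)
  }
  plane
}

#' Render one synthetic field with ground truth
#'
#' Draws a Poisson number of cells, assigns each a phenotype class from the
#' scene's mixture, places the cells without touching (inside the marker disk
#' when a marker is present), renders the nuclei / marker / cargo channels,
#' and returns both the image and the generator's ground truth.
#'
#' @param spec a [scene_spec()].
#' @param meta optional named list of metadata (replicate, position,
#'   subposition, condition) attached to the field.
#' @return A list with elements
#'   \describe{
#'     \item{field}{class `"field_image"`: `channels` (named list of integer
#'       rasters; `nuclei` always present) and `meta`.}
#'     \item{truth}{class `"ground_truth"`: `cells` (one row per rendered
#'       cell: class, 0-based centroid, footprint pixel count, true ring
#'       intensity) and `field` (true fractions, true mean cargo intensity,
#'       `n_cells`).}
#'   }
#' @examples
#' fr <- render_field(scene_spec(field_shape = c(128, 128), expected_cells = 8,
#'                               marker = NULL, platform = "well384", seed = 1))
#' fr$truth$field$n_cells
#' @export
render_field <- function(spec, meta = list()) {
  spec <- validate_scene_spec(spec)
  local_seed(spec$seed, {
    shape <- spec$field_shape
    nuc <- background_plane(shape, spec$noise$background,
                            spec$noise$background_gradient)
    n_target <- if (spec$expected_cells == 0) 0L
                else rpois(1, spec$expected_cells)
    classes_drawn <- if (n_target > 0)
      sample(c("normal", "spindle", "cytokinesis"), n_target, replace = TRUE,
             prob = spec$phenotype_mix) else character(0)

    has_marker <- !is.null(spec$marker)
    if (has_marker) {
      ctr <- spot_center_px(spec) + 1  # 1-based internal
      rad <- spot_radius_px(spec)
    }
    margin <- 15
    if (!has_marker && (shape[1] <= 2 * margin || shape[2] <= 2 * margin))
      stop("field too small to place any nucleus")

    blocked <- matrix(FALSE, shape[1], shape[2])
    footprint_any <- matrix(FALSE, shape[1], shape[2])
    cells <- list()
    dropped <- 0L
    for (i in seq_len(n_target)) {
      placed <- FALSE
      for (att in seq_len(spec$max_place_attempts)) {
        if (has_marker) {
          rr <- (rad - 3) * sqrt(runif(1))
          th <- runif(1, 0, 2 * pi)
          center <- ctr + rr * c(cos(th), sin(th))
        } else {
          center <- c(runif(1, margin, shape[1] - margin),
                      runif(1, margin, shape[2] - margin))
        }
        cell <- sample_cell(classes_drawn[i], center, spec$geometry,
                            spec$pixel_size)
        px <- cell$pixels
        if (any(px[, 1] < 1 | px[, 1] > shape[1] |
                px[, 2] < 1 | px[, 2] > shape[2])) next
        idx <- px[, 1] + (px[, 2] - 1) * shape[1]
        if (!spec$allow_touching && any(blocked[idx])) next
        nuc[idx] <- cell$values
        footprint_any[idx] <- TRUE
        blocked[inflate_pixels(px, shape)] <- TRUE
        cells[[length(cells) + 1]] <- list(class = classes_drawn[i],
                                           pixels = px, idx = idx)
        placed <- TRUE
        break
      }
      if (!placed) dropped <- dropped + 1L
    }
    if (dropped > 0)
      warning(dropped, " cell(s) could not be placed without touching and ",
              "were dropped")

    n_cells <- length(cells)
    ring_int <- rep(NA_real_, n_cells)
    if (!is.null(spec$cargo) && n_cells > 0)
      ring_int <- pmax(0, rnorm(n_cells, spec$cargo$ring_mean,
                                spec$cargo$ring_sd))

    channels <- list()
    if (has_marker) {
      mk <- matrix(spec$marker$background, shape[1], shape[2])
      g <- expand.grid(row = seq_len(shape[1]), col = seq_len(shape[2]))
      inside <- (g$row - ctr[1])^2 + (g$col - ctr[2])^2 <= rad^2
      mk[cbind(g$row[inside], g$col[inside])] <- spec$marker$intensity
      channels$marker <- mk
    }
    if (!is.null(spec$cargo)) {
      channels$cargo <- render_cargo(spec, shape, cells, ring_int,
                                     footprint_any)
    }

    truth_cells <- data.frame(cell = seq_len(n_cells),
                              class = vapply(cells, `[[`, "", "class"),
                              centroid_row = vapply(cells, function(cl)
                                mean(cl$pixels[, 1]) - 1, 0),
                              centroid_col = vapply(cells, function(cl)
                                mean(cl$pixels[, 2]) - 1, 0),
                              footprint_px = vapply(cells, function(cl)
                                nrow(cl$pixels), 0L),
                              ring_intensity = ring_int,
                              stringsAsFactors = FALSE)
    if (n_cells == 0)
      truth_cells <- truth_cells[0, ]
    fr <- if (n_cells > 0)
      as.numeric(table(factor(truth_cells$class,
                              c("normal", "spindle", "cytokinesis")))) / n_cells
    else rep(NA_real_, 3)

    nuc <- apply_noise(nuc, spec$noise)
    if (has_marker) channels$marker <- apply_noise(channels$marker, spec$noise)
    if (!is.null(spec$cargo))
      channels$cargo <- apply_noise(channels$cargo, spec$noise)

    field <- structure(list(channels = c(list(nuclei = nuc), channels),
                            meta = c(meta, list(platform = spec$platform,
                                                pixel_size = spec$pixel_size,
                                                seed = spec$seed))),
                       class = "field_image")
    truth <- structure(list(cells = truth_cells,
                            field = list(frac_normal = fr[1],
                                         frac_spindle = fr[2],
                                         frac_cytokinesis = fr[3],
                                         mean_cargo = if (n_cells > 0)
                                           mean(ring_int) else NA_real_,
                                         n_cells = n_cells)),
                       class = "ground_truth")
    list(field = field, truth = truth)
  })
}

# Paint perinuclear annuli (and punctate granules) into the cargo channel.
# Pixels claimed by several annuli go to the nearer nucleus centroid, which
# mirrors the measurement-side partition rule.
render_cargo <- function(spec, shape, cells, ring_int, footprint_any) {
  cargo <- matrix(spec$cargo$background, shape[1], shape[2])
  if (length(cells) == 0) return(cargo)
  w <- spec$cargo$ring_render_width_px
  best <- matrix(Inf, shape[1], shape[2])
  painted <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    px <- cells[[i]]$pixels
    r1 <- max(1, min(px[, 1]) - w); r2 <- min(shape[1], max(px[, 1]) + w)
    c1 <- max(1, min(px[, 2]) - w); c2 <- min(shape[2], max(px[, 2]) + w)
    win <- matrix(0, r2 - r1 + 1, c2 - c1 + 1)
    win[cbind(px[, 1] - r1 + 1, px[, 2] - c1 + 1)] <- 1
    dil <- cpp_disc_morph(win, w + 0.5, TRUE, TRUE) > 0
    cand <- which(dil & win == 0)
    rows <- (cand - 1) %% nrow(win) + r1
    cols <- (cand - 1) %/% nrow(win) + c1
    idx <- rows + (cols - 1) * shape[1]
    keep <- !footprint_any[idx]
    rows <- rows[keep]; cols <- cols[keep]; idx <- idx[keep]
    ctr <- c(mean(px[, 1]), mean(px[, 2]))
    d2 <- (rows - ctr[1])^2 + (cols - ctr[2])^2
    take <- d2 < best[idx]
    cargo[idx[take]] <- ring_int[i]
    best[idx[take]] <- d2[take]
    painted[[i]] <- idx[take]
  }
  for (i in seq_along(cells)) {
    ng <- rpois(1, spec$cargo$granule_rate)
    if (ng == 0 || length(painted[[i]]) == 0) next
    centers <- sample(painted[[i]], min(ng, length(painted[[i]])))
    gr <- spec$cargo$granule_radius_px
    for (ci in centers) {
      r0 <- (ci - 1) %% shape[1] + 1
      c0 <- (ci - 1) %/% shape[1] + 1
      gg <- expand.grid(row = (r0 - gr):(r0 + gr), col = (c0 - gr):(c0 + gr))
      gg <- gg[(gg$row - r0)^2 + (gg$col - c0)^2 <= gr^2 &
                 gg$row >= 1 & gg$row <= shape[1] &
                 gg$col >= 1 & gg$col <= shape[2], ]
      gidx <- gg$row + (gg$col - 1) * shape[1]
      gidx <- gidx[!footprint_any[gidx]]
      cargo[gidx] <- ring_int[i] * spec$cargo$granule_intensity_mult
    }
  }
  cargo
}
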