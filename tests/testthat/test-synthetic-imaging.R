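small_spec <- function(...) {
  args <- list(...)
  base <- list(field_shape = c(160, 160), platform = "well384",
               expected_cells = 10, seed = 1)
  base[names(args)] <- args
  do.call(scene_spec, base)
}

test_that("scene_spec validates its invariants", {
  expect_s3_class(small_spec(), "scene_spec")
  expect_error(small_spec(phenotype_mix = c(normal = 0.6, spindle = 0.3,
                                            cytokinesis = 0.2)),
               "sum to 1")
  expect_error(small_spec(phenotype_mix = c(normal = 1.2, spindle = -0.2,
                                            cytokinesis = 0)),
               "\\[0, 1\\]")
  expect_error(scene_spec(field_shape = c(100, 100),
                          marker = marker_spot(radius_px = 80)),
               "exceeds half the field")
  expect_error(render_field(scene_spec(field_shape = c(20, 20),
                                       platform = "well384", marker = NULL,
                                       expected_cells = 5)),
               "too small")
})

test_that("an expected count of zero renders a background-only field", {
  fr <- render_field(small_spec(expected_cells = 0))
  expect_equal(fr$truth$field$n_cells, 0)
  expect_equal(nrow(fr$truth$cells), 0)
  # background plane + noise only: nothing near the nuclear intensity
  expect_lt(max(fr$field$channels$nuclei), 2000)
})

test_that("a degenerate mixture yields a single class", {
  fr <- render_field(small_spec(expected_cells = 50,
                                field_shape = c(400, 400),
                                phenotype_mix = c(normal = 1, spindle = 0,
                                                  cytokinesis = 0),
                                seed = 7))
  expect_true(all(fr$truth$cells$class == "normal"))
})

test_that("class fractions follow the configured mixture", {
  mix <- c(normal = 0.6, spindle = 0.3, cytokinesis = 0.1)
  fr <- render_field(scene_spec(field_shape = c(1024, 1024),
                                platform = "well384", marker = NULL,
                                expected_cells = 500, phenotype_mix = mix,
                                seed = 1))
  n <- fr$truth$field$n_cells
  expect_gt(n, 400)
  emp <- table(factor(fr$truth$cells$class, names(mix))) / n
  se <- sqrt(mix * (1 - mix) / n)
  expect_true(all(abs(as.numeric(emp) - mix) <= 3 * se))
})

test_that("empirical fractions over many fields converge to the mixture", {
  mix <- c(normal = 0.55, spindle = 0.25, cytokinesis = 0.2)
  classes <- character(0)
  for (i in 1:12) {
    fr <- render_field(scene_spec(field_shape = c(1024, 1024),
                                  platform = "well384", marker = NULL,
                                  expected_cells = 850, phenotype_mix = mix,
                                  seed = 100 + i, cargo = cargo_model()))
    classes <- c(classes, fr$truth$cells$class)
  }
  n <- length(classes)
  expect_gte(n, 1e4)
  emp <- as.numeric(table(factor(classes, names(mix)))) / n
  se <- sqrt(mix * (1 - mix) / n)
  expect_true(all(abs(emp - mix) <= 3 * se))
})

test_that("true ring intensities follow the cargo model", {
  vals <- numeric(0)
  for (i in 1:8) {
    fr <- render_field(small_spec(expected_cells = 150,
                                  field_shape = c(512, 512),
                                  cargo = cargo_model(ring_mean = 3000,
                                                      ring_sd = 450),
                                  seed = 30 + i))
    vals <- c(vals, fr$truth$cells$ring_intensity)
  }
  expect_gte(length(vals), 1e3)
  expect_lt(abs(mean(vals) - 3000), 3 * 450 / sqrt(length(vals)))
})

test_that("ground truth is internally consistent", {
  fr <- render_field(small_spec(expected_cells = 40,
                                field_shape = c(400, 400), seed = 5))
  tf <- fr$truth$field
  expect_equal(tf$n_cells, nrow(fr$truth$cells))
  expect_equal(tf$frac_normal + tf$frac_spindle + tf$frac_cytokinesis, 1)
  counts <- table(factor(fr$truth$cells$class,
                         c("normal", "spindle", "cytokinesis")))
  expect_equal(as.numeric(counts) / tf$n_cells,
               c(tf$frac_normal, tf$frac_spindle, tf$frac_cytokinesis))
})

test_that("cells transfect only on the marker spot", {
  fr <- render_field(scene_spec(expected_cells = 120, seed = 3))
  ctr <- (dim(fr$field$channels$nuclei) - 1) / 2
  rad <- 150 / 0.65
  d <- sqrt((fr$truth$cells$centroid_row - ctr[1])^2 +
              (fr$truth$cells$centroid_col - ctr[2])^2)
  expect_true(all(d <= rad))
})

test_that("distinct cells never touch by default", {
  fr <- render_field(small_spec(expected_cells = 60,
                                field_shape = c(400, 400), seed = 9,
                                noise = noise_model(gaussian_sd = 0,
                                                    shot_noise = FALSE)))
  # with noise off, every nucleus pixel is far above background; the number
  # of 8-connected components must equal the number of placed cells
  mask <- fr$field$channels$nuclei > 4000
  lab <- label_components(mask, 8)
  expect_equal(max(lab), fr$truth$field$n_cells)
})

test_that("fixed seeds give bit-identical fields", {
  a <- render_field(small_spec(expected_cells = 30, seed = 11,
                               cargo = cargo_model()))
  b <- render_field(small_spec(expected_cells = 30, seed = 11,
                               cargo = cargo_model()))
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth, b$truth)
})

test_that("layouts count fields as the experiment design dictates", {
  lay <- build_layout("array_spot", c("NC", "KIF11", "PLK1", "INCENP"),
                      positions_per_condition = 9, replicates = 3)
  expect_equal(nrow(lay), 108)
  expect_true(all(table(lay$condition, lay$replicate) == 9))

  lay384 <- build_layout("well384", "KIF11", positions_per_condition = 6,
                         replicates = 1)
  expect_equal(nrow(lay384), 54)  # 6 wells x 9 subpositions per siRNA
  lay96 <- build_layout("well96", "NC", positions_per_condition = 1,
                        replicates = 1)
  expect_equal(nrow(lay96), 25)
  expect_error(build_layout("array_spot", "NC", subpositions = 3),
               "exactly 1 subposition")
})

test_that("generate_screen derives per-field seeds deterministically", {
  lay <- build_layout("well384", c("NC", "KIF11"),
                      positions_per_condition = 1, replicates = 1,
                      subpositions = 2)
  eff <- list(NC = condition_effect(),
              KIF11 = condition_effect(c(normal = 0.6, spindle = 0.35,
                                         cytokinesis = 0.05),
                                       density_mult = 0.6))
  base <- scene_spec(field_shape = c(160, 160), platform = "well384",
                     marker = NULL, expected_cells = 10)
  s1 <- generate_screen(lay, eff, seed = 5, base)
  s2 <- generate_screen(lay, eff, seed = 5, base)
  expect_identical(lapply(s1$fields, `[[`, "channels"),
                   lapply(s2$fields, `[[`, "channels"))
  s3 <- generate_screen(lay, eff, seed = 6, base)
  expect_false(identical(s1$fields[[1]]$channels,
                         s3$fields[[1]]$channels))
  expect_error(generate_screen(lay, eff["NC"], seed = 5, base),
               "KIF11")
})

test_that("datasets round-trip through disk bit-exactly", {
  lay <- build_layout("array_spot", "NC", positions_per_condition = 3,
                      replicates = 1)
  base <- scene_spec(field_shape = c(128, 128), expected_cells = 4,
                     marker = marker_spot(radius_px = 40),
                     cargo = cargo_model())
  scr <- generate_screen(lay, list(NC = condition_effect()), seed = 2, base)
  dir <- withr::local_tempdir()
  write_dataset(scr, dir)
  back <- read_dataset(dir)
  expect_equal(nrow(back$layout), 3)
  for (i in 1:3) {
    expect_identical(back$fields[[i]]$channels$nuclei,
                     scr$fields[[i]]$channels$nuclei)
    expect_identical(back$fields[[i]]$channels$cargo,
                     scr$fields[[i]]$channels$cargo)
  }
  # truth CSV row count equals total rendered cells
  tc <- read.csv(file.path(dir, "truth_cells.csv"))
  expect_equal(nrow(tc), sum(vapply(scr$truths, function(t)
    t$field$n_cells, 0)))

  # corrupt TIFF errors with the file name
  bad <- file.path(dir, read.csv(file.path(dir, "layout.csv"))$nuclei_path[1])
  writeLines("not a tiff", bad)
  expect_error(read_dataset(dir), basename(bad))
})

test_that("malformed layout CSVs report the offending row", {
  dir <- withr::local_tempdir()
  df <- data.frame(replicate = c(1, 1), platform = c("array_spot", "moon"),
                   position = c("NC_01", "NC_02"), subposition = c(1, 1),
                   condition = "NC", nuclei_path = c("a.tif", "b.tif"))
  write.csv(df, file.path(dir, "layout.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "row 2")
})
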