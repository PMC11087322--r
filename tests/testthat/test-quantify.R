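# End-to-end runs over synthetic plates written to disk.

write_screen_images <- function(dir, conditions, radii_by_cond, seed = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    radii <- radii_by_cond[[i]]
    spec <- make_screen_spec(radii = radii, target_b = -12, noise_sigma = 2)
    res <- generate_plate(spec, seed = seed + i)
    paths[i] <- file.path(dir, sprintf("plate_T%g_d%g.png",
                                       conditions$temperature_C[i],
                                       conditions$day[i]))
    write_plate_png(res$image, paths[i])
  }
  paths
}

clone12 <- sprintf("LP%d", 1:12)

base_config <- function(dir, paths, conditions) {
  list(images = data.frame(path = paths,
                           temperature_C = conditions$temperature_C,
                           day = conditions$day),
       layout = list(n_rows = 4, n_cols = 3, clone_labels = clone12,
                     cell_size = c(100, 100)),
       calibration = list(pixel_length = 100, physical_length_mm = 13),
       out_dir = file.path(dir, "out"))
}

test_that("run_quantify recovers synthetic areas and writes all outputs", {
  dir <- withr::local_tempdir()
  conditions <- data.frame(temperature_C = c(37, 45), day = 1)
  # condition 1: 5 halos; condition 2: 3 halos (cells r1c1..)
  paths <- write_screen_images(dir, conditions,
                               list(c(20, 15, 25, 18, 22), c(14, 16, 20)))
  res <- run_quantify(base_config(dir, paths, conditions))
  expect_true(all(file.exists(unlist(res$paths))))
  dm <- res$density_matrix
  expect_equal(dim(dm), c(12, 2))
  expect_equal(sum(dm[, "T37_d1"] > 0), 5)
  expect_equal(sum(dm[, "T45_d1"] > 0), 3)
  # areas match the ground truth within a few percent at noise_sigma 2
  spec <- make_screen_spec(radii = c(20, 15, 25, 18, 22), target_b = -12)
  gt <- generate_plate(spec, seed = 1)$ground_truth
  lay <- plate_layout(spec, clone12)
  gt_clone <- unname(lay$clone_labels[gt$halos$cell_id])
  got <- dm[gt_clone, "T37_d1"]
  expect_lt(max(abs(got / gt$halos$area_cm2 - 1)), 0.05)
  # summary counts clones positive anywhere
  expect_equal(res$summary$n_positive, 5)
  expect_identical(res$summary$hit_rate_percent, 41.7)  # 5/12
})

test_that("re-running on identical inputs produces byte-identical CSVs", {
  dir <- withr::local_tempdir()
  conditions <- data.frame(temperature_C = 37, day = 1)
  paths <- write_screen_images(dir, conditions, list(c(18, 24)))
  cfg <- base_config(dir, paths, conditions)
  run_quantify(cfg)
  first <- lapply(list.files(cfg$out_dir, full.names = TRUE), readBin,
                  what = "raw", n = 1e6)
  run_quantify(cfg)
  second <- lapply(list.files(cfg$out_dir, full.names = TRUE), readBin,
                   what = "raw", n = 1e6)
  expect_identical(first, second)
})

test_that("an empty plate gives a zero matrix and a 0.0% hit rate", {
  dir <- withr::local_tempdir()
  conditions <- data.frame(temperature_C = 25, day = 1)
  paths <- write_screen_images(dir, conditions, list(numeric(0)))
  res <- run_quantify(base_config(dir, paths, conditions))
  expect_true(all(res$density_matrix == 0))
  expect_identical(res$summary$hit_rate_percent, 0)
  expect_equal(res$summary$n_positive, 0)
})

test_that("manual circular masks stand in for failed automatic detection", {
  dir <- withr::local_tempdir()
  conditions <- data.frame(temperature_C = 37, day = 1)
  paths <- write_screen_images(dir, conditions, list(c(20, 15)))
  cfg <- base_config(dir, paths, conditions)
  # manual circle over cell r1c2 (center 150,50), generous radius
  cfg$manual_masks <- data.frame(path = paths[1], cell_id = "r1c2",
                                 cx = 150, cy = 50, r = 22)
  res <- run_quantify(cfg)
  reg <- res$regions
  expect_identical(reg$method[reg$cell_id == "r1c2"], "manual")
  expect_identical(reg$method[reg$cell_id == "r1c1"], "auto")
  # both routes see the same blue disk, so areas should be close
  expect_lt(abs(reg$area_cm2[reg$cell_id == "r1c2"] /
                reg$area_cm2[reg$cell_id == "r1c1"] *
                (20 / 15)^2 - 1), 0.1)
})

test_that("bad configurations fail with informative errors", {
  dir <- withr::local_tempdir()
  conditions <- data.frame(temperature_C = 37, day = 1)
  paths <- write_screen_images(dir, conditions, list(18))
  cfg <- base_config(dir, paths, conditions)
  expect_error(run_quantify(file.path(dir, "nope.json")), "nope.json")
  cfg_missing <- cfg; cfg_missing$layout <- NULL
  expect_error(run_quantify(cfg_missing), "layout")
  cfg_badimg <- cfg
  cfg_badimg$images$path <- file.path(dir, "ghost.png")
  expect_error(run_quantify(cfg_badimg), "ghost.png")
})

test_that("config given as a JSON file runs identically to a list", {
  dir <- withr::local_tempdir()
  conditions <- data.frame(temperature_C = 37, day = 1)
  paths <- write_screen_images(dir, conditions, list(c(20)))
  cfg <- base_config(dir, paths, conditions)
  res1 <- run_quantify(cfg)
  jpath <- file.path(dir, "config.json")
  cfg$out_dir <- file.path(dir, "out2")
  jsonlite::write_json(cfg, jpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  res2 <- run_quantify(jpath)
  expect_equal(unclass(res1$density_matrix), unclass(res2$density_matrix))
})
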