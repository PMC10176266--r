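make_field <- function(blue, green, ...) {
  field(list(blue = blue, green = green), um_per_px = 0.62, ...)
}
stain_cfg <- segmentation_config(method = "global", threshold = 10,
                                 min_area_px = 1, fill_holes = FALSE)

test_that("stain masks carry per-component means over original intensities", {
  g <- matrix(0, 20, 20)
  g[5:6, 5:9] <- 150                       # one 10-px blob
  f <- make_field(matrix(0, 20, 20), g)
  st <- build_stain_mask(f, "green", stain_cfg)
  expect_equal(length(st$comp_mean), 1)
  expect_equal(st$comp_mean, 150)

  g2 <- matrix(0, 20, 20)
  g2[2:3, 2:3] <- 100; g2[12:13, 12:13] <- 200
  st2 <- build_stain_mask(make_field(matrix(0, 20, 20), g2), "green", stain_cfg)
  expect_equal(sort(st2$comp_mean), c(100, 200))

  st0 <- build_stain_mask(make_field(matrix(0, 20, 20), matrix(0, 20, 20)),
                          "green", stain_cfg)
  expect_equal(length(st0$comp_mean), 0)
})

test_that("nearest-stain assignment averages the whole nearest component", {
  blue <- matrix(0, 12, 12); blue[4:6, 4:6] <- 200   # centroid (5,5)
  g <- matrix(0, 12, 12); g[5, 7] <- 100; g[5, 8] <- 200
  f <- make_field(blue, g)
  nuc <- segment_field(f, segmentation_config(method = "global", threshold = 100,
                                              min_area_px = 1))
  res <- assign_nearest_stain(nuc, build_stain_mask(f, "green", stain_cfg),
                              fallback_value = 0)
  expect_equal(res$raw, 150)
  expect_false(res$fallback)
})

test_that("a field with no stain pixels assigns the fallback value everywhere", {
  sp <- field_spec(n_colonies = 1, n_single_cells = 2, noise_sd = 0,
                   background = 0, seed = 14)
  iso <- generate_isotype_field(sp)
  nuc <- segment_field(iso$field)
  st <- build_stain_mask(iso$field, "green", stain_cfg)
  res <- assign_nearest_stain(nuc, st, fallback_value = 12)
  expect_true(all(res$fallback))
  expect_true(all(res$raw == 12))
})

test_that("a neighbor's stain triggers fallback exactly when the distance rule says so", {
  blue <- matrix(0, 24, 60)
  blue[trophoquant:::.disk_pixels(24, 60, 10, 10, 5)] <- 200
  blue[trophoquant:::.disk_pixels(24, 60, 10, 40, 5)] <- 200
  g <- matrix(0, 24, 60)
  g[trophoquant:::.disk_pixels(24, 60, 10, 38, 2)] <- 180
  f <- make_field(blue, g)
  nuc <- segment_field(f, segmentation_config(method = "global", threshold = 100,
                                              min_area_px = 5))
  st <- build_stain_mask(f, "green", stain_cfg)
  res <- assign_nearest_stain(nuc, st, fallback_value = 7)
  oracle <- nearest_stain_scan_oracle(nuc, st, fallback_value = 7)
  expect_equal(res, oracle)
  # A (centroid col 10) is closer to B's nucleus rim than to the blob -> falls back
  expect_true(res$fallback[1]); expect_equal(res$raw[1], 7)
  expect_false(res$fallback[2]); expect_equal(res$raw[2], 180)
})

test_that("nearest-stain assignment matches the exhaustive pixel scan on random fields", {
  for (seed in 1:60) {
    rf <- random_oracle_field(seed)
    for (rule in c("other_nucleus", "any_blue")) {
      got <- assign_nearest_stain(rf$nuclei, rf$stain, fallback_value = 3,
                                  rule = rule)
      want <- nearest_stain_scan_oracle(rf$nuclei, rf$stain, fallback_value = 3,
                                        rule = rule)
      expect_equal(got, want, info = sprintf("seed %d rule %s", seed, rule))
    }
  }
})

test_that("the literal any-blue reading degenerates to fallback for every cell", {
  rf <- random_oracle_field(99)
  res <- assign_nearest_stain(rf$nuclei, rf$stain, fallback_value = 5,
                              rule = "any_blue")
  expect_true(all(res$fallback))           # own nucleus is always nearer
})

test_that("nuclear mode averages original values over the cell's own pixel set", {
  blue <- matrix(0, 10, 10); blue[4, 4:6] <- 200
  g <- matrix(0, 10, 10); g[4, 4:6] <- c(10, 20, 30)
  f <- make_field(blue, g)
  nuc <- segment_field(f, segmentation_config(method = "global", threshold = 100,
                                              min_area_px = 1, fill_holes = FALSE))
  expect_equal(nuclear_intensity(nuc, f, "green")$raw, 20)
  f0 <- make_field(blue, matrix(0, 10, 10))
  expect_equal(nuclear_intensity(nuc, f0, "green")$raw, 0)
})

test_that("nuclear recovery is exact when blobs cover the whole nucleus", {
  sp <- field_spec(n_colonies = 2, n_single_cells = 3, noise_sd = 0,
                   background = 0, stain_radius_px = 7,
                   nucleus_radius_px = c(4, 6), seed = 17)
  g <- generate_field(sp)
  nuc <- segment_field(g$field)
  res <- nuclear_intensity(nuc, g$field, "green")
  m <- match_truth(nuc$table, g$truth)
  expect_equal(res$raw, g$truth$true_green[m])
})

test_that("the isotype reference pools cells across fields", {
  expect_equal(isotype_reference(c(10, 10, 10, 10))$mean, 10)
  r <- isotype_reference(list(c(5, 5), c(15, 15)))
  expect_equal(r$mean, 10)
  expect_equal(r$n, 4)
  # pooling weights by cell count; the per-field option does not
  r2 <- isotype_reference(list(c(0, 0, 0), c(30)))
  expect_equal(r2$mean, 7.5)
  expect_equal(isotype_reference(list(c(0, 0, 0), c(30)),
                                 method = "per_field")$mean, 15)
  expect_error(isotype_reference(list(numeric(0))), "zero isotype cells")
})

test_that("isotype fields quantified against their own reference normalize to exactly 1", {
  sp <- field_spec(n_colonies = 1, n_single_cells = 2, noise_sd = 0,
                   background = 7, seed = 23)
  iso <- generate_isotype_field(sp)
  nuc <- segment_field(iso$field)
  ref <- isotype_reference(nuclear_intensity(nuc, iso$field, "green")$raw)
  expect_equal(ref$mean, 7)                # nuclear baseline equals background
  cells <- quantify_field(iso$field, references = list(green = ref))
  expect_true(all(cells$fallback_green))
  expect_identical(unique(cells$norm_green), 1)
})

test_that("normalized values recover truth exactly on noise-free two-population fields", {
  sp <- field_spec(n_colonies = 2, n_single_cells = 3, noise_sd = 0,
                   background = 2, seed = 11)
  g <- generate_field(sp)
  cells <- quantify_field(g$field, references = list(green = 2, red = 2),
                          config = list(stain = segmentation_config(
                            method = "global", threshold = 20, min_area_px = 5)))
  m <- match_truth(cells, g$truth)
  expect_equal(cells$norm_green, g$truth$true_green[m] / 2)
  expect_equal(cells$norm_red, g$truth$true_red[m] / 2)
  expect_false(any(cells$fallback_green))
})

test_that("scaling a stain channel scales non-fallback intensities and keeps flags", {
  sp <- field_spec(n_colonies = 2, n_single_cells = 2, noise_sd = 0,
                   background = 0, seed = 29)
  g <- generate_field(sp)
  nuc <- segment_field(g$field)
  cfg1 <- segmentation_config(method = "global", threshold = 20, min_area_px = 5)
  cfg3 <- segmentation_config(method = "global", threshold = 60, min_area_px = 5)
  r1 <- assign_nearest_stain(nuc, build_stain_mask(g$field, "green", cfg1), 0)
  f3 <- g$field; f3$channels$green <- f3$channels$green * 3
  r3 <- assign_nearest_stain(nuc, build_stain_mask(f3, "green", cfg3), 0)
  expect_identical(r1$fallback, r3$fallback)
  keep <- !r1$fallback
  expect_equal(r3$raw[keep], 3 * r1$raw[keep])
})

test_that("quantify_field validates references and normalizes by them", {
  sp <- field_spec(n_colonies = 0, n_single_cells = 2, colony_radius_um = 12,
                   noise_sd = 0, background = 0,
                   populations = data.frame(name = "p", prob = 1,
                                            green_mean = 30, green_sd = 0),
                   seed = 37)
  g <- generate_field(sp)
  cells <- quantify_field(g$field, references = list(green = 10),
                          config = list(stain = segmentation_config(
                            method = "global", threshold = 10, min_area_px = 1)))
  expect_equal(unique(cells$norm_green), 3)
  expect_error(quantify_field(g$field, references = list(green = 0)), "> 0")
  expect_error(quantify_field(g$field, references = list(30)), "named")
})
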