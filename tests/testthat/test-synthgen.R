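one_pop <- function(mean_g = 100, mean_r = 0) {
  data.frame(name = "p", prob = 1,
             green_mean = mean_g, green_sd = 0,
             red_mean = mean_r, red_sd = 0)
}

test_that("generation is deterministic under a fixed seed and varies across seeds", {
  sp <- field_spec(n_colonies = 2, n_single_cells = 3, seed = 42)
  a <- generate_field(sp)
  b <- generate_field(sp)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth, b$truth)
  c <- generate_field(field_spec(n_colonies = 2, n_single_cells = 3, seed = 43))
  expect_false(identical(a$field$channels$blue, c$field$channels$blue))
})

test_that("layout invariants hold: in-bounds, non-overlapping, correct spatial classes", {
  sp <- field_spec(n_colonies = 3, cells_per_colony = c(3, 6),
                   n_single_cells = 6, noise_sd = 0, seed = 7)
  g <- generate_field(sp)
  tr <- g$truth
  expect_equal(tr$cell_id, seq_len(nrow(tr)))
  expect_true(all(tr$true_row - tr$radius_px >= 1 &
                  tr$true_row + tr$radius_px <= sp$image_height_px))
  expect_true(all(tr$true_col - tr$radius_px >= 1 &
                  tr$true_col + tr$radius_px <= sp$image_width_px))
  d <- as.matrix(dist(cbind(tr$true_row, tr$true_col)))
  diag(d) <- Inf
  expect_true(all(d > 2 * sp$nucleus_radius_px[2]))
  # spatial classes match the generator's own radius rule
  rad_px <- sp$colony_radius_um / sp$um_per_px
  expect_identical(tr$true_spatial_class,
                   brute_force_spatial(tr$true_row, tr$true_col, rad_px))
})

test_that("all cells are single when no colonies are requested", {
  g <- generate_field(field_spec(n_colonies = 0, n_single_cells = 5, seed = 3))
  expect_identical(unique(g$truth$true_spatial_class), "single")
})

test_that("noise-free single-nucleus field renders one blue component with exact stain mean", {
  sp <- field_spec(n_colonies = 0, n_single_cells = 1, colony_radius_um = 10,
                   noise_sd = 0, background = 0, populations = one_pop(100),
                   seed = 5)
  g <- generate_field(sp)
  expect_equal(max(flood_fill_labels(g$field$channels$blue > 0)), 1)
  blob <- g$field$channels$green > 0
  expect_true(any(blob))
  expect_equal(mean(g$field$channels$green[blob]), 100)
  expect_equal(g$truth$true_green, 100)
})

test_that("rendered nucleus count equals the ground-truth row count at noise 0", {
  for (seed in 1:3) {
    sp <- field_spec(n_colonies = 2, n_single_cells = 4, noise_sd = 0,
                     background = 0, seed = seed)
    g <- generate_field(sp)
    expect_equal(max(flood_fill_labels(g$field$channels$blue > 0)),
                 nrow(g$truth))
  }
})

test_that("quantize option yields integer pixels, default stays exact floating point", {
  spq <- field_spec(n_colonies = 0, n_single_cells = 2, colony_radius_um = 10,
                    quantize = TRUE, seed = 2)
  g <- generate_field(spq)
  expect_true(all(g$field$channels$green == round(g$field$channels$green)))
})

test_that("isotype fields carry background-only stain channels over the same nuclei", {
  sp <- field_spec(n_colonies = 1, n_single_cells = 2, noise_sd = 0,
                   background = 10, seed = 9)
  iso <- generate_isotype_field(sp)
  expect_true(all(iso$field$channels$green == 10))
  expect_true(all(iso$field$channels$red == 10))
  expect_true(iso$field$is_isotype)
  expect_equal(iso$truth$true_green, rep(10, nrow(iso$truth)))
  exp_field <- generate_field(sp)
  expect_equal(iso$truth$true_row, exp_field$truth$true_row)
  expect_identical(generate_isotype_field(sp)$field$channels,
                   iso$field$channels)
})

test_that("membrane fields hit the requested fusion index within 1/T", {
  for (target in c(0, 0.4, 0.9)) {
    sp <- field_spec(n_colonies = 0, n_single_cells = 20, noise_sd = 0,
                     seed = 11)
    m <- generate_membrane_field(sp, target)
    fi <- fusion_index(m$counts)
    expect_lte(abs(fi - target), 1 / 20 + 1e-12)
    # recomputable from the truth's syncytium assignments
    syn <- table(m$truth$true_syncytium_id)
    N <- sum(syn); S <- length(syn)
    expect_equal((N - S) / nrow(m$truth), fi)
    if (target == 0) {
      expect_equal(m$counts$N, 0L)
      expect_equal(fi, 0)
    }
  }
  # all nuclei in one region reaches (T-1)/T
  m <- generate_membrane_field(
    field_spec(n_colonies = 0, n_single_cells = 10, seed = 12), 0.9)
  expect_equal(m$counts$S, 1L)
  expect_equal(fusion_index(m$counts), 0.9)
})

test_that("unreachable fusion targets and infeasible packings fail loudly", {
  sp10 <- field_spec(n_colonies = 0, n_single_cells = 10, seed = 1)
  expect_error(generate_membrane_field(sp10, 0.97), "unreachable")
  expect_error(
    generate_field(field_spec(image_height_px = 48, image_width_px = 48,
                              n_colonies = 0, n_single_cells = 40, seed = 1)),
    "infeasible packing")
})

test_that("Ct tables encode fold changes so the pipeline can recover them", {
  lfc <- cbind(day0 = c(0, 0), day4 = c(2, 0))
  ct <- generate_ct_table(c("G", "H"), c("day0", "day4"), replicates = 2,
                          true_log2fc = lfc, ct_noise_sd = 0, seed = 1)
  g0 <- ct$ct[ct$gene == "G" & ct$condition == "day0"][1]
  g4 <- ct$ct[ct$gene == "G" & ct$condition == "day4"][1]
  expect_equal(g4, g0 - 2)          # upregulation amplifies 2 cycles earlier
  hk <- ct[ct$role == "housekeeping", ]
  expect_equal(length(unique(hk$ct[hk$gene == "GAPDH"])), 1)
  # all-zero fold changes give identical Cts across conditions
  ct0 <- generate_ct_table("G", c("day0", "day4"), 2,
                           cbind(day0 = 0, day4 = 0), 0, 1)
  expect_equal(unique(as.numeric(tapply(ct0$ct[ct0$gene == "G"],
                                        ct0$condition[ct0$gene == "G"], mean))),
               unique(ct0$ct[ct0$gene == "G"]))
  expect_error(generate_ct_table("G", "day0", 2, cbind(day0 = 1), 0, 1),
               "reference")
})

test_that("field specs round-trip through YAML", {
  sp <- field_spec(n_colonies = 1, n_single_cells = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_field_spec(sp, path)
  sp2 <- read_field_spec(path)
  expect_identical(generate_field(sp)$truth, generate_field(sp2)$truth)
})
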