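# Synthetic generators: plant renderer ground truth and trait-table
# variance structure.

test_that("horizontal rectangular leaf rasterizes to its exact pixel area", {
  sp <- plant_spec(tibble::tibble(length_mm = 100, width_mm = 10,
                                  inclination_deg = 90, azimuth_deg = 0))
  r <- render_plant(sp, "top", seed = 1)
  expect_equal(r$truth$foreground_pixel_count, 1000L)
  expect_equal(r$truth$projected_area_mm2, 1000)
  expect_equal(r$truth$hull_area_mm2, 99 * 9) # pixel-center polygon
  expect_equal(r$truth$calliper_length_mm, sqrt(99 ^ 2 + 9 ^ 2))
})

test_that("rendering is deterministic: same spec and seed give identical bytes", {
  sp <- random_plant_spec(5, noise_sd = 6)
  r1 <- render_plant(sp, "top", seed = 9)
  r2 <- render_plant(sp, "top", seed = 9)
  expect_identical(r1$image, r2$image)
  dir <- withr::local_tempdir()
  write_plant_image(r1, file.path(dir, "a.png"))
  write_plant_image(r2, file.path(dir, "b.png"))
  sums <- tools::md5sum(file.path(dir, c("a.png", "b.png")))
  expect_identical(unname(sums[1L]), unname(sums[2L]))
  r3 <- render_plant(sp, "top", seed = 10)
  expect_false(identical(r1$image, r3$image)) # noise differs across seeds
})

test_that("ground truth matches brute-force geometry of the rendered mask", {
  for (seed in c(2, 3, 4)) {
    sp <- random_plant_spec(seed)
    r <- render_plant(sp, "top", seed = seed)
    pts <- which(r$mask, arr.ind = TRUE) - 1
    hull <- convex_hull(pts)
    expect_equal(r$truth$foreground_pixel_count, nrow(pts))
    expect_equal(r$truth$hull_area_mm2,
                 polygon_area(hull) * sp$scale_mm_per_px ^ 2)
    expect_equal(r$truth$calliper_length_mm,
                 bf_max_pairwise_distance(hull) * sp$scale_mm_per_px,
                 tolerance = 1e-9)
    # MEC diameter always bounds the calliper for a point set
    expect_gte(r$truth$mec_diameter_mm, r$truth$calliper_length_mm - 1e-9)
  }
})

test_that("side views carry exact leaf-angle landmarks", {
  sp <- random_plant_spec(6)
  r <- render_plant(sp, "front", seed = 1)
  la <- r$truth$leaf_angles
  expect_equal(nrow(la), nrow(sp$leaves))
  measured <- leaf_angle(cbind(la$joint_row, la$joint_col),
                         cbind(la$blade_row, la$blade_col))
  expect_equal(measured, la$angle_deg, tolerance = 1e-9)
  expect_equal(la$angle_deg, sp$leaves$inclination_deg)
})

test_that("a leaf exceeding the canvas is reported by name", {
  sp <- plant_spec(tibble::tibble(length_mm = c(100, 4000),
                                  width_mm = c(10, 10),
                                  inclination_deg = c(90, 90),
                                  azimuth_deg = c(0, 90)))
  expect_error(render_plant(sp, "top"), "leaf 2")
})

test_that("the default segmentation recovers the rendered foreground exactly", {
  sp <- random_plant_spec(8)
  r <- render_plant(sp, "top", seed = 1)
  expect_identical(segment_plant(r$image), r$mask)
})

test_that("degenerate noise-free simulation reproduces mu and the shift", {
  m <- sim_model(n_genotypes = 4, n_reps = 2, mu = 10, sigma2_g = 0,
                 sigma2_gc = 0, conc_effect = -2, sigma2_e = 0, seed = 1)
  tab <- simulate_trait_table(m, "y")$table
  expect_true(all(tab$y[tab$treatment == "control"] == 10))
  expect_true(all(tab$y[tab$treatment == "deficient"] == 8))
  expect_equal(nrow(tab), 4L * 2L * 2L)
})

test_that("simulation is deterministic under a fixed seed", {
  m <- sim_model(n_genotypes = 6, seed = 42)
  s1 <- simulate_trait_table(m, c("a", "b"))
  s2 <- simulate_trait_table(m, c("a", "b"))
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth, s2$truth)
})

test_that("replication below two is rejected", {
  expect_error(sim_model(n_reps = 1), "heritability")
})

test_that("realized effects converge to the model variances at scale", {
  m <- sim_model(n_genotypes = 500, n_reps = 3, mu = 50, sigma2_g = 4,
                 sigma2_gc = 0.5, conc_effect = -5, sigma2_e = 1, seed = 99)
  sim <- simulate_trait_table(m, "y")
  g_var <- stats::var(sim$truth$g_effect)
  gc_var <- stats::var(c(sim$truth$gc_control, sim$truth$gc_deficient))
  expect_lt(abs(g_var - 4) / 4, 0.10)
  expect_lt(abs(gc_var - 0.5) / 0.5, 0.10)
  # residual variance via the within-cell mean squares
  resid_var <- sim$table |>
    dplyr::group_by(genotype, treatment) |>
    dplyr::summarise(v = stats::var(y), .groups = "drop") |>
    dplyr::pull(v) |>
    mean()
  expect_lt(abs(resid_var - 1), 0.10)
})
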