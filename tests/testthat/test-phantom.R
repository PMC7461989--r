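test_that("the dose-response model matches its closed form", {
  grid <- c(2, 2, 2)
  pre <- volume(array(5, grid), c(2, 2, 2), modality = "PET")
  d20 <- volume(array(20, grid), c(2, 2, 2), modality = "DOSE")
  p <- response_params(alpha_per_gy = 0.05, background_suv = 1)

  post <- apply_response(pre, d20, p)
  expect_equal(post$values[1, 1, 1], 1 + 4 * exp(-1), tolerance = 1e-12)

  # zero decay rate is the identity, for above- and below-background voxels
  mixed <- volume(array(c(0, 0.5, 1, 5), c(4, 1, 1)), c(1, 1, 1), modality = "PET")
  dd <- volume(array(30, c(4, 1, 1)), c(1, 1, 1), modality = "DOSE")
  p0 <- response_params(0, 1)
  expect_equal(apply_response(mixed, dd, p0)$values, mixed$values)

  # huge dose drives above-background voxels to the background floor
  dbig <- volume(array(1e6, grid), c(2, 2, 2), modality = "DOSE")
  expect_equal(apply_response(pre, dbig, p)$values[1], 1, tolerance = 1e-10)

  bad <- volume(array(5, c(3, 2, 2)), c(2, 2, 2), modality = "PET")
  expect_error(apply_response(bad, d20, p), "grid")
})

test_that("case generation is a pure function of config and index", {
  cfg <- tiny_phantom_config(seed = 7)
  a <- generate_case(cfg, 0)
  b <- generate_case(cfg, 0)
  expect_identical(a$pet_pre$values, b$pet_pre$values)
  expect_identical(a$dose$values, b$dose$values)
  expect_identical(a$pet_intra_truth$values, b$pet_intra_truth$values)
  expect_identical(a$params, b$params)
  # different indices differ
  c2 <- generate_case(cfg, 1)
  expect_false(identical(a$pet_pre$values, c2$pet_pre$values))
})

test_that("masks are strictly nested with increasing voxel counts", {
  cfg <- tiny_phantom_config(seed = 3, noise_sd_suv = 0.05)
  for (i in 0:2) {
    cs <- generate_case(cfg, i)
    g <- sum(cs$rois$gtv$values); c_ <- sum(cs$rois$ctv$values)
    b <- sum(cs$rois$body$values)
    expect_true(g > 0 && g < c_ && c_ < b)
    expect_true(all(cs$rois$gtv$values <= cs$rois$ctv$values))
    expect_true(all(cs$rois$ctv$values <= cs$rois$body$values))
  }
})

test_that("noise-free null response reproduces the pre-treatment PET", {
  cfg <- tiny_phantom_config(seed = 11, response_alpha_per_gy = c(0, 0))
  cs <- generate_case(cfg, 0)
  expect_equal(cs$pet_intra_truth$values, cs$pet_pre$values, tolerance = 1e-12)
})

test_that("noise-free response never increases above-background uptake", {
  cfg <- tiny_phantom_config(seed = 13)
  cs <- generate_case(cfg, 1)
  expect_true(all(cs$pet_intra_truth$values <= cs$pet_pre$values + 1e-12))
  expect_true(all(cs$pet_intra_truth$values >= 0))
})

test_that("mean dose inside the CTV equals the plateau value", {
  cfg <- tiny_phantom_config(seed = 17)
  cs <- generate_case(cfg, 0)
  expect_equal(mean_suv(cs$dose, cs$rois$ctv), cfg$delivered_dose_gy,
               tolerance = 0.01)
})

test_that("infeasible geometry is rejected, not silently clipped", {
  expect_error(phantom_config(grid_shape = c(16, 16, 8),
                              tumor_radius_range_mm = c(20, 30)),
               "does not fit")
})

test_that("cohorts write a deterministic manifest with a disjoint split", {
  cfg <- tiny_phantom_config(seed = 19, n_cases = 8,
                             split = c(train = 0.5, val = 0.25, test = 0.25))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  co1 <- generate_cohort(cfg, out_dir = d1)
  co2 <- generate_cohort(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))

  splits <- vapply(co1$manifest$cases, `[[`, "", "split")
  expect_equal(sum(splits == "train"), 4)
  expect_equal(sum(splits == "val"), 2)
  expect_equal(sum(splits == "test"), 2)
  expect_equal(length(unique(vapply(co1$manifest$cases, `[[`, "", "case_id"))), 8)

  # refuses to clobber without the overwrite flag
  expect_error(generate_cohort(cfg, out_dir = d1), "overwrite")
  expect_no_error(generate_cohort(cfg, out_dir = d1, overwrite = TRUE))
})

test_that("empty cohorts are rejected", {
  cfg <- tiny_phantom_config(seed = 1)
  cfg$n_cases <- 0L
  expect_error(generate_cohort(cfg), "n_cases")
})

test_that("cohorts round-trip through the on-disk layout", {
  cfg <- tiny_phantom_config(seed = 23, n_cases = 2,
                             split = c(train = 0.5, val = 0.5, test = 0))
  dir <- withr::local_tempdir()
  co <- generate_cohort(cfg, out_dir = dir)
  back <- load_cohort(dir)
  for (id in names(co$cases)) {
    expect_equal(back$cases[[id]]$pet_pre$values, co$cases[[id]]$pet_pre$values)
    expect_equal(back$cases[[id]]$dose$values, co$cases[[id]]$dose$values)
    expect_equal(back$cases[[id]]$rois$gtv$values, co$cases[[id]]$rois$gtv$values)
    expect_equal(back$cases[[id]]$params$alpha_per_gy,
                 co$cases[[id]]$params$alpha_per_gy)
  }
})
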