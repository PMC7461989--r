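test_that("mean_suv is the arithmetic mean over the mask support", {
  v <- volume(array(2, c(4, 4, 2)), c(2, 2, 2), modality = "PET")
  m <- full_body_mask(c(4, 4, 2))
  expect_equal(mean_suv(v, m), 2)

  v2 <- volume(array(0, c(4, 4, 2)), c(2, 2, 2), modality = "PET")
  v2$values[1, 1, 1] <- 1; v2$values[2, 1, 1] <- 3
  m2 <- volume(array(0, c(4, 4, 2)), c(2, 2, 2), modality = "MASK")
  m2$values[1:2, 1, 1] <- 1
  expect_equal(mean_suv(v2, m2), 2)

  empty <- volume(array(0, c(4, 4, 2)), c(2, 2, 2), modality = "MASK")
  expect_error(mean_suv(v, empty), "empty")
})

test_that("Otsu splits a bimodal population exactly between the modes", {
  x <- c(rep(1.0, 50), rep(5.0, 50))
  thr <- otsu_threshold(x)
  expect_gt(thr, 1); expect_lt(thr, 5)

  dims <- c(10, 10, 1)
  vals <- array(1.0, dims)
  vals[1:50] <- 5.0
  v <- volume(vals, c(2, 2, 2), modality = "PET")
  gtv <- full_body_mask(dims)
  hu <- otsu_high_uptake(v, gtv)
  expect_equal(sum(hu$values), 50)
  expect_true(all(v$values[hu$values == 1] == 5.0))
  expect_true(all(hu$values <= gtv$values))

  # minimal bimodal case
  v2 <- volume(array(c(1, 5), c(2, 1, 1)), c(1, 1, 1), modality = "PET")
  g2 <- volume(array(1, c(2, 1, 1)), c(1, 1, 1), modality = "MASK")
  h2 <- otsu_high_uptake(v2, g2)
  expect_equal(c(h2$values), c(0, 1))

  const <- volume(array(2, dims), c(2, 2, 2), modality = "PET")
  expect_error(otsu_high_uptake(const, gtv), "constant")
})

test_that("Otsu equals exhaustive between-class-variance search", {
  set.seed(73)
  for (rep in 1:50) {
    # seeded bimodal histogram with random mode locations and mixing
    n1 <- sample(10:60, 1); n2 <- sample(10:60, 1)
    x <- c(rnorm(n1, 2, 0.3), rnorm(n2, 6, 0.5))
    expect_equal(otsu_threshold(x), naive_otsu(x), tolerance = 1e-12)
  }
})

test_that("identical volumes give gamma 0 and 100% pass everywhere", {
  ref <- random_volume(dims = c(8, 8, 4), seed = 79)
  body <- full_body_mask(c(8, 8, 4))
  for (mode in c("2D", "3D")) {
    g <- gamma_map(ref, ref, body, gamma_criteria(5, 5), mode = mode)
    expect_true(all(g$gamma_map$values[!is.na(g$gamma_map$values)] == 0))
    expect_equal(g$pass_rate_body, 100)
  }
})

test_that("a voxel exactly at the SUV tolerance has gamma 1 and passes", {
  dims <- c(9, 9, 5)
  ref <- volume(array(2, dims), c(2, 2, 2), modality = "PET")
  ref$values[5, 5, 3] <- 10  # global max -> delta_suv_abs = 1 at 10%
  ev <- ref
  ev$values[2, 2, 2] <- ref$values[2, 2, 2] + 1
  body <- full_body_mask(dims)
  g <- gamma_map(ref, ev, body, gamma_criteria(10, 2), mode = "3D")
  # neighbours of (2,2,2) differ, so zero shift is the best candidate
  expect_equal(g$gamma_map$values[2, 2, 2], 1, tolerance = 1e-12)
  expect_equal(g$pass_rate_body, 100)
})

test_that("a one-voxel shift is recovered through the distance term", {
  # hotspot shifted by one 2 mm voxel. At zero shift the intensity term is
  # 99/50 = 1.98, so the best candidate is the exact match one voxel away:
  # gamma = 2 mm / 2 mm = 1 at the hotspot, which still passes. Verified by
  # the exhaustive enumeration oracle as well.
  dims <- c(11, 9, 5)
  ref <- volume(array(1, dims), c(2, 2, 2), modality = "PET")
  ref$values[6, 5, 3] <- 100
  ev <- volume(array(1, dims), c(2, 2, 2), modality = "PET")
  ev$values[7, 5, 3] <- 100
  body <- full_body_mask(dims)
  crit <- gamma_criteria(50, 2)  # delta_suv_abs = 50% of max = 50
  g <- gamma_map(ref, ev, body, crit, mode = "3D")
  expect_equal(g$gamma_map$values[6, 5, 3], 1, tolerance = 1e-12)
  expect_equal(g$pass_rate_body, 100)
  o <- gamma_brute_force(ref, ev, body, crit, mode = "3D")
  expect_identical(g$gamma_map$values, o$gamma_map$values)
})

test_that("optimized gamma equals the exhaustive oracle", {
  set.seed(83)
  body <- full_body_mask(c(8, 8, 4))
  for (rep in 1:4) {
    ref <- random_volume(dims = c(8, 8, 4), seed = NULL)
    ev <- ref
    ev$values <- pmax(ev$values + array(rnorm(256, 0, 0.25), c(8, 8, 4)), 0)
    for (mode in c("2D", "3D")) {
      for (crit in default_gamma_criteria()) {
        a <- gamma_map(ref, ev, body, crit, mode = mode)
        o <- gamma_brute_force(ref, ev, body, crit, mode = mode)
        expect_identical(a$gamma_map$values, o$gamma_map$values)
        expect_identical(a$pass_rate_body, o$pass_rate_body)
      }
    }
  }
})

test_that("gamma is scale invariant under global normalization", {
  set.seed(89)
  ref <- random_volume(dims = c(8, 8, 4), seed = NULL)
  ev <- ref
  ev$values <- pmax(ev$values + array(rnorm(256, 0, 0.3), c(8, 8, 4)), 0)
  body <- full_body_mask(c(8, 8, 4))
  g1 <- gamma_map(ref, ev, body, gamma_criteria(5, 5))
  ref2 <- ref; ref2$values <- ref$values * 7.5
  ev2 <- ev; ev2$values <- ev$values * 7.5
  g2 <- gamma_map(ref2, ev2, body, gamma_criteria(5, 5))
  expect_equal(g1$gamma_map$values, g2$gamma_map$values, tolerance = 1e-12)
})

test_that("gamma is zero only at exact zero-shift matches", {
  dims <- c(6, 6, 3)
  ref <- random_volume(dims = dims, seed = 97)
  ev <- ref
  ev$values[3, 3, 2] <- ev$values[3, 3, 2] + 0.5
  body <- full_body_mask(dims)
  g <- gamma_map(ref, ev, body, gamma_criteria(10, 5), mode = "3D")
  zero_here <- g$gamma_map$values == 0
  exact_match <- ev$values == ref$values
  expect_identical(zero_here, exact_match)
})

test_that("evaluate_case emits the full criteria sweep in table order", {
  cfg <- tiny_phantom_config(seed = 101)
  cs <- generate_case(cfg, 0)
  ev <- evaluate_case(cs$pet_intra_truth, cs$pet_intra_truth, cs$rois)
  expect_equal(length(ev$gamma), 8)  # 4 criteria x 2 modes
  expect_equal(nrow(ev$gamma_table), 8)
  expect_equal(names(ev$gamma_table)[5:7],
               c("pass_body", "pass_ctv", "pass_gtv"))
  expect_true(all(ev$gamma_table$pass_body == 100))
  expect_true(all(ev$gamma_table$pass_ctv == 100))
  expect_true(all(ev$gamma_table$pass_gtv == 100))
  expect_equal(ev$suv$predicted, ev$suv$truth)
  expect_equal(ev$suv$region, c("GTV", "CTV", "high_uptake"))
  # the high-uptake region lies inside the GTV by construction
  hu <- otsu_high_uptake(cs$pet_intra_truth, cs$rois$gtv)
  expect_true(all(hu$values <= cs$rois$gtv$values))
})

test_that("pass rates are monotone in the criteria and mode", {
  set.seed(103)
  cfg <- tiny_phantom_config(seed = 103, noise_sd_suv = 0.05)
  cs <- generate_case(cfg, 0)
  pred <- cs$pet_intra_truth
  pred$values <- pmax(pred$values +
                        array(rnorm(length(pred$values), 0, 0.15),
                              dim(pred$values)), 0)
  ev <- evaluate_case(pred, cs$pet_intra_truth, cs$rois)
  tab <- ev$gamma_table
  for (mode in c("2D", "3D")) {
    m <- tab[tab$mode == mode, ]
    for (col in c("pass_body", "pass_ctv", "pass_gtv")) {
      r <- function(crit) m[[col]][m$criteria == crit]
      expect_gte(r("10%/5 mm"), r("5%/5 mm"))
      expect_gte(r("5%/10 mm"), r("5%/5 mm"))
      expect_gte(r("10%/10 mm"), r("10%/5 mm"))
      expect_gte(r("10%/10 mm"), r("5%/10 mm"))
    }
  }
  for (crit in unique(tab$criteria)) {
    for (col in c("pass_body", "pass_ctv", "pass_gtv")) {
      expect_gte(tab[[col]][tab$mode == "3D" & tab$criteria == crit],
                 tab[[col]][tab$mode == "2D" & tab$criteria == crit])
    }
  }
})

test_that("case-averaged reports aggregate per case or per voxel", {
  cfg <- tiny_phantom_config(seed = 107)
  evs <- lapply(0:1, function(i) {
    cs <- generate_case(cfg, i)
    evaluate_case(cs$pet_intra_truth, cs$pet_intra_truth, cs$rois)
  })
  avg <- average_evaluations(evs)
  expect_true(all(avg$gamma$pass_body == 100))
  avg2 <- average_evaluations(evs, body_voxels = c(100, 300),
                              weighting = "voxel")
  expect_true(all(avg2$gamma$pass_gtv == 100))

  dir <- withr::local_tempdir()
  paths <- write_evaluation_reports(avg, dir)
  expect_true(file.exists(file.path(dir, "mean_suv.csv")))
  expect_true(file.exists(file.path(dir, "gamma_pass_rates_2d.csv")))
  expect_true(file.exists(file.path(dir, "gamma_pass_rates_3d.csv")))
  tab <- utils::read.csv(file.path(dir, "gamma_pass_rates_3d.csv"))
  expect_equal(names(tab), c("criteria", "whole_body_pct", "ctv_region_pct",
                             "gtv_region_pct"))
})
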