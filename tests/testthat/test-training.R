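test_that("the weighted loss matches the worked 2x2 example", {
  # four voxels, all with error 1; two in the non-target region, two in the
  # CTV of which one is also GTV: 2*1 + 3*2 + 6*1 = 14
  pred <- matrix(1, 2, 2)
  truth <- matrix(0, 2, 2)
  non <- matrix(c(1, 1, 0, 0), 2, 2)
  ctv <- matrix(c(0, 0, 1, 1), 2, 2)
  gtv <- matrix(c(0, 0, 1, 0), 2, 2)
  expect_equal(mmse_loss(pred, truth, gtv, ctv, non), 14.0)
})

test_that("the loss equals naive triple-loop summation on random slices", {
  set.seed(53)
  for (rep in 1:25) {
    pred <- matrix(runif(64, 0, 2), 8, 8)
    truth <- matrix(runif(64, 0, 2), 8, 8)
    body <- matrix(rbinom(64, 1, 0.8), 8, 8)
    ctv <- body * matrix(rbinom(64, 1, 0.4), 8, 8)
    gtv <- ctv * matrix(rbinom(64, 1, 0.5), 8, 8)
    non <- body * (1 - ctv)
    # agreement to the non-associativity of floating-point addition
    expect_equal(mmse_loss(pred, truth, gtv, ctv, non),
                 naive_mmse(pred, truth, gtv, ctv, non, 3.0, 6.0),
                 tolerance = 1e-13)
  }
})

test_that("zero weights reduce the loss to the non-target SSE", {
  set.seed(59)
  pred <- matrix(runif(64), 8, 8); truth <- matrix(runif(64), 8, 8)
  body <- matrix(rbinom(64, 1, 0.9), 8, 8)
  ctv <- body * matrix(rbinom(64, 1, 0.4), 8, 8)
  gtv <- ctv * matrix(rbinom(64, 1, 0.5), 8, 8)
  non <- body * (1 - ctv)
  got <- mmse_loss(pred, truth, gtv, ctv, non, loss_weights(0, 0))
  expect_equal(got, sum(non * (pred - truth)^2), tolerance = 1e-14)
})

test_that("perfect predictions have zero loss; contracts are enforced", {
  x <- matrix(runif(16), 4, 4)
  m1 <- matrix(1, 4, 4); m0 <- matrix(0, 4, 4)
  expect_equal(mmse_loss(x, x, m1, m1, m0), 0)
  expect_error(mmse_loss(x, x, m1 * 0.5, m1, m0), "binary")
  expect_error(mmse_loss(x, matrix(0, 2, 2), m1, m1, m0), "shape")
})

test_that("GTV voxels accrue both the CTV and GTV penalty terms", {
  w <- petresponse:::mmse_weight_map(gtv = matrix(1), ctv = matrix(1),
                                     non = matrix(0), loss_weights())
  expect_equal(c(w), 1 * 0 + 3 + 6)
  wx <- petresponse:::mmse_weight_map(gtv = matrix(1), ctv = matrix(1),
                                      non = matrix(0), loss_weights(),
                                      exclusive = TRUE)
  expect_equal(c(wx), 6)
})

test_that("training is reproducible and decreases the loss", {
  cfg <- tiny_phantom_config(seed = 61)
  co <- generate_cohort(cfg)
  spec <- tiny_network_spec()
  tc <- training_config(epochs = 4, seed = 9, batch_size = 4)
  tr1 <- train_model(co, spec, tc)
  tr2 <- train_model(co, spec, tc)
  expect_equal(tr1$log$train_loss, tr2$log$train_loss, tolerance = 1e-12)
  expect_equal(tr1$log$val_loss, tr2$log$val_loss, tolerance = 1e-12)
  expect_lt(tr1$log$train_loss[4], tr1$log$train_loss[1])
  expect_equal(nrow(tr1$log), 4)
})

test_that("training contracts: epochs, channel mode, empty splits", {
  expect_error(training_config(epochs = 0), "epochs")
  cfg <- tiny_phantom_config(seed = 67)
  co <- generate_cohort(cfg)
  # 3-channel spec with dose disabled is inconsistent
  expect_error(train_model(co, tiny_network_spec(3),
                           training_config(epochs = 1, use_dose = FALSE)),
               "channels")
  # no validation cases
  cfg2 <- tiny_phantom_config(seed = 67, split = c(train = 1, val = 0, test = 0))
  co2 <- generate_cohort(cfg2)
  expect_error(train_model(co2, tiny_network_spec(),
                           training_config(epochs = 1)), "split")
})

test_that("prediction lives on the case grid in restored SUV units", {
  cfg <- tiny_phantom_config(seed = 71)
  co <- generate_cohort(cfg)
  spec <- tiny_network_spec()
  tr <- train_model(co, spec, training_config(epochs = 2, seed = 3))
  cs <- co$cases[[cohort_split(co, "test")[1]]]
  pred <- predict_case(tr, cs)
  expect_true(same_grid(pred, cs$pet_pre))
  expect_true(all(pred$values >= 0))
  expect_equal(pred$modality, "PET")

  # a zero-weight model predicts exactly zero everywhere
  tr0 <- tr
  tr0$model <- build_network(spec, init = "zero")
  p0 <- predict_case(tr0, cs)
  expect_true(all(p0$values == 0))
})
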