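test_that("the default architecture matches its stated design", {
  spec <- network_spec()
  expect_equal(spec$n_conv_layers, 8L)
  expect_equal(spec$kernel_size, c(3L, 3L))
  expect_equal(spec$filters_per_layer[1], 32L)
  expect_equal(max(spec$filters_per_layer), 256L)
  expect_equal(spec$filters_per_layer[spec$n_conv_layers], 1L)
  expect_equal(spec$input_channels, 3L)
})

test_that("spec invariants are enforced", {
  expect_error(network_spec(filters_per_layer = c(32, 64, 1)), "one entry per")
  expect_error(network_spec(n_conv_layers = 3, filters_per_layer = c(32, 64, 2)),
               "collapse")
  expect_error(network_spec(kernel_size = c(5, 5)), "3x3")
  expect_no_error(network_spec(kernel_size = c(5, 5), allow_nonstandard = TRUE))
  expect_error(network_spec(input_channels = 4), "channels")
})

test_that("parameter count is the closed-form sum over layers", {
  # independently: sum over layers of 9 * c_in * c_out + c_out
  spec <- network_spec()
  cin <- c(3, 32, 64, 128, 256, 256, 128, 64)
  cout <- c(32, 64, 128, 256, 256, 128, 64, 1)
  expect_equal(count_parameters(spec), sum(9 * cin * cout + cout))
  expect_equal(count_parameters(spec), 1347905)

  small <- tiny_network_spec()
  m <- build_network(small)
  expect_equal(sum(lengths(m$W)) + sum(lengths(m$b)), count_parameters(small))
})

test_that("spatial shape is preserved for arbitrary input sizes", {
  set.seed(21)
  m <- build_network(network_spec())
  for (hw in list(c(64, 64), c(48, 80))) {
    x <- array(runif(hw[1] * hw[2] * 3), c(hw[1], hw[2], 3, 1))
    p <- petresponse:::network_forward(m, x)
    expect_equal(dim(p), c(hw[1], hw[2], 1L))
    expect_true(all(p >= 0))  # final ReLU enforces SUV semantics
  }
})

test_that("the zero-initialized network outputs exactly zero", {
  m <- build_network(tiny_network_spec(), init = "zero")
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 2))
  p <- petresponse:::network_forward(m, x)
  expect_true(all(p == 0))
})

test_that("the all-convolutional design is translation covariant", {
  # shifting the input by whole voxels shifts the output identically in the
  # interior, beyond a border margin of one voxel per layer
  set.seed(31)
  spec <- tiny_network_spec()
  m <- build_network(spec)
  H <- 24; W <- 24; s <- 3
  x <- array(0, c(H, W, 3, 1))
  x[8:14, 8:14, , 1] <- runif(7 * 7 * 3)
  xs <- array(0, c(H, W, 3, 1))
  xs[(8:14) + s, (8:14) + s, , 1] <- x[8:14, 8:14, , 1]
  p <- petresponse:::network_forward(m, x)
  ps <- petresponse:::network_forward(m, xs)
  margin <- spec$n_conv_layers
  inner_r <- (1 + margin):(H - margin - s)
  inner_c <- (1 + margin):(W - margin - s)
  expect_equal(ps[inner_r + s, inner_c + s, 1], p[inner_r, inner_c, 1],
               tolerance = 1e-12)
})

test_that("forward/backward gradients agree with finite differences", {
  set.seed(41)
  spec <- network_spec(n_conv_layers = 3, filters_per_layer = c(4, 4, 1),
                       input_channels = 2)
  m <- build_network(spec)
  x <- array(runif(6 * 5 * 2 * 2), c(6, 5, 2, 2))
  y <- array(runif(6 * 5 * 2), c(6, 5, 2))
  w <- array(rbinom(6 * 5 * 2, 1, 0.8), c(6, 5, 2))
  lossfun <- function(mm) {
    p <- petresponse:::network_forward(mm, x)
    sum(w * (p - y)^2)
  }
  fw <- petresponse:::network_forward(m, x, keep_cache = TRUE)
  g <- petresponse:::network_backward(m, fw$cache, fw$pred, 2 * w * (fw$pred - y))
  eps <- 1e-6
  base <- lossfun(m)
  for (l in 1:3) {
    for (i in sample(length(m$W[[l]]), 4)) {
      m2 <- m
      m2$W[[l]][i] <- m2$W[[l]][i] + eps
      fd <- (lossfun(m2) - base) / eps
      expect_equal(g$dW[[l]][i], fd, tolerance = 1e-4)
    }
    m2 <- m
    m2$b[[l]][1] <- m2$b[[l]][1] + eps
    expect_equal(g$db[[l]][1], (lossfun(m2) - base) / eps, tolerance = 1e-4)
  }
})

test_that("assemble_input stacks normalized channels in fixed order", {
  cfg <- tiny_phantom_config(seed = 29)
  cs <- generate_case(cfg, 0)
  nc <- normalize_case(cs, dose_scale = cfg$delivered_dose_gy)
  x3 <- assemble_input(nc, 6, use_dose = TRUE)
  x2 <- assemble_input(nc, 6, use_dose = FALSE)
  expect_equal(dim(x3)[3], 3L)
  expect_equal(dim(x2)[3], 2L)
  expect_true(min(x3) >= 0 && max(x3) <= 1)
  # the PET channel is the normalized PET slice, untouched
  expect_identical(x3[, , 1], nc$pet$values[, , 6])
  expect_error(assemble_input(nc, 99), "extent")

  # unnormalized volumes are refused
  raw <- list(pet = cs$pet_pre, ct = cs$ct, dose = cs$dose)
  expect_error(assemble_input(raw, 6), "normalized")
})
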