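#' Architecture of the convolutional regression network
#'
#' The predictor is a small all-convolutional network mapping a multi-channel
#' 2D axial slice (pre-treatment PET, CT and — unless ablated — the planned
#' dose, each normalized to \[0,1\]) to a same-sized predicted PET slice.
#' Eight 3x3 convolutions, each followed by a ReLU; the filter count ramps up
#' from 32 to 256 and then collapses back to a single output map. Zero
#' padding preserves the spatial shape at every layer, so any slice size can
#' be processed, and the final ReLU keeps predictions nonnegative, matching
#' SUV semantics.
#'
#' @param n_conv_layers number of convolutional layers (default 8).
#' @param kernel_size integer length-2 kernel; only 3x3 is supported unless
#'   `allow_nonstandard = TRUE`.
#' @param filters_per_layer output channels per layer; the last entry must
#'   be 1. The default ramp is `c(32, 64, 128, 256, 256, 128, 64, 1)`.
#' @param input_channels 3 for (PET, CT, dose) or 2 for the dose-ablated
#'   (PET, CT) variant.
#' @param final_activation `"relu"` (default; enforces nonnegative output)
#'   or `"identity"` for ablation experiments.
#' @param allow_nonstandard permit kernels other than 3x3.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_conv_layers = 8,
                         kernel_size = c(3, 3),
                         filters_per_layer = c(32, 64, 128, 256, 256, 128, 64, 1),
                         input_channels = 3,
                         final_activation = c("relu", "identity"),
                         allow_nonstandard = FALSE) {
  final_activation <- match.arg(final_activation)
  if (length(filters_per_layer) != n_conv_layers) {
    stop("filters_per_layer must have one entry per convolutional layer",
         call. = FALSE)
  }
  if (filters_per_layer[n_conv_layers] != 1) {
    stop("the last layer must collapse to a single output map (filters = 1)",
         call. = FALSE)
  }
  if (any(filters_per_layer < 1)) stop("filter counts must be >= 1", call. = FALSE)
  if (!identical(as.integer(kernel_size), c(3L, 3L)) && !allow_nonstandard) {
    stop("kernel_size must be 3x3 (set allow_nonstandard = TRUE to override)",
         call. = FALSE)
  }
  if (!input_channels %in% c(2, 3)) {
    stop("input_channels must be 3 (PET, CT, dose) or 2 (PET, CT)", call. = FALSE)
  }
  structure(
    list(n_conv_layers = as.integer(n_conv_layers),
         kernel_size = as.integer(kernel_size),
         filters_per_layer = as.integer(filters_per_layer),
         input_channels = as.integer(input_channels),
         activation = "relu",
         final_activation = final_activation),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d conv layers, %dx%d kernels, channels %d -> %s\n",
              x$n_conv_layers, x$kernel_size[1], x$kernel_size[2],
              x$input_channels, paste(x$filters_per_layer, collapse = " -> ")))
  cat(sprintf("  activation ReLU (final: %s), zero padding, shape-preserving\n",
              x$final_activation))
  invisible(x)
}

#' Number of trainable parameters implied by a network spec
#'
#' Each layer has `kh * kw * c_in * c_out` weights plus `c_out` biases.
#'
#' @param spec a [network_spec()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  cin <- c(spec$input_channels, utils::head(spec$filters_per_layer, -1))
  k <- prod(spec$kernel_size)
  sum(k * cin * spec$filters_per_layer + spec$filters_per_layer)
}

#' Build (initialize) the convolutional network
#'
#' Allocates the weight matrices of the architecture described by `spec`.
#' Weights use He-normal initialization (suited to ReLU nonlinearities),
#' biases start at zero; `init = "zero"` produces the null network used in
#' contract tests. Initialization draws from the current R RNG stream, so
#' seeding `set.seed()` before calling makes the build reproducible.
#'
#' Internally layer `l` stores its kernel as a `(kh*kw*c_in) x c_out` matrix
#' so the convolution is an im2col patch-matrix multiplication (BLAS gemm).
#'
#' @param spec a [network_spec()].
#' @param init `"he"` or `"zero"`.
#' @return An object of class `conv_network` with elements `spec`, `W`, `b`,
#'   `n_parameters`.
#' @export
build_network <- function(spec, init = c("he", "zero")) {
  init <- match.arg(init)
  stopifnot(inherits(spec, "network_spec"))
  k <- prod(spec$kernel_size)
  cin <- c(spec$input_channels, utils::head(spec$filters_per_layer, -1))
  W <- vector("list", spec$n_conv_layers)
  b <- vector("list", spec$n_conv_layers)
  for (l in seq_len(spec$n_conv_layers)) {
    fan_in <- k * cin[l]
    W[[l]] <- if (init == "zero") {
      matrix(0, fan_in, spec$filters_per_layer[l])
    } else {
      matrix(stats::rnorm(fan_in * spec$filters_per_layer[l], 0,
                          sqrt(2 / fan_in)),
             fan_in, spec$filters_per_layer[l])
    }
    b[[l]] <- numeric(spec$filters_per_layer[l])
  }
  structure(list(spec = spec, W = W, b = b,
                 n_parameters = count_parameters(spec)),
            class = "conv_network")
}

#' @export
print.conv_network <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %s trainable parameters\n",
              format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

# --- internal batched convolution machinery ---------------------------------
# Activations are (H, W, B, C) arrays; each layer is an im2col patch-matrix
# multiplication. The heavy lifting (patch gather/scatter and the BLAS gemm
# calls) lives in src/convnet.cpp; these wrappers handle the channel-last
# external layout and the cache the backward pass consumes.

# forward pass; x is (H, W, C, B). Returns the (H, W, B) prediction, or with
# keep_cache = TRUE the per-layer activations needed for backpropagation.
network_forward <- function(model, x, keep_cache = FALSE) {
  spec <- model$spec
  d <- dim(x)
  if (length(d) != 4L || d[3] != spec$input_channels) {
    stop(sprintf("input must be (H, W, %d, batch)", spec$input_channels),
         call. = FALSE)
  }
  A <- aperm(x, c(1, 2, 4, 3))  # -> (H, W, B, C)
  acts <- conv_net_forward_cpp(A, model$W, model$b,
                               spec$final_activation == "relu")
  pred <- array(acts[[spec$n_conv_layers + 1]], d[c(1, 2, 4)])
  if (keep_cache) list(pred = pred, cache = acts) else pred
}

# backpropagation given d(loss)/d(pred) as (H, W, B); returns weight/bias
# gradients matching the layout of model$W / model$b.
network_backward <- function(model, cache, pred, dpred) {
  conv_net_backward_cpp(cache, model$W, dpred,
                        model$spec$final_activation == "relu")
}

#' Assemble the network input tensor for one axial slice
#'
#' Extracts the given axial slice from the normalized PET, CT and (unless
#' `use_dose = FALSE`) dose volumes of a case and stacks them as channels in
#' the fixed order (PET, CT, dose). All inputs must already be normalized to
#' \[0,1\]; see [normalize_case()].
#'
#' @param norm_case a normalized case, as returned by [normalize_case()].
#' @param slice_index 1-based axial slice index.
#' @param use_dose include the dose channel? `FALSE` gives the 2-channel
#'   ablation input.
#' @return An `(H, W, C)` array with values in \[0,1\].
#' @export
assemble_input <- function(norm_case, slice_index, use_dose = TRUE) {
  nz <- dim(norm_case$pet$values)[3]
  if (slice_index < 1 || slice_index > nz) {
    stop(sprintf("slice_index %d outside volume extent [1, %d]", slice_index, nz),
         call. = FALSE)
  }
  chans <- list(norm_case$pet$values[, , slice_index],
                norm_case$ct$values[, , slice_index])
  if (use_dose) chans <- c(chans, list(norm_case$dose$values[, , slice_index]))
  x <- simplify2array(chans)
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9) {
    stop("input volumes are not normalized to [0,1]; call normalize_case() first",
         call. = FALSE)
  }
  x
}

#' Normalize the input volumes of a case
#'
#' Applies the modality normalization schemes of [normalize_volume()] to the
#' pre-treatment PET, CT and dose of a case and keeps the records needed to
#' restore predictions to SUV units.
#'
#' @param case a `phantom_case` (or any list with `pet_pre`, `ct`, `dose`).
#' @param dose_scale plan-level reference dose in Gy for the fixed dose
#'   scale (typically the delivered dose).
#' @return List with normalized `pet`, `ct`, `dose` volumes and `records`.
#' @export
normalize_case <- function(case, dose_scale) {
  np <- normalize_volume(case$pet_pre)
  nc <- normalize_volume(case$ct)
  nd <- normalize_volume(case$dose, scale = dose_scale)
  # dose may exceed the reference scale slightly (heterogeneity knob); the
  # network contract wants [0,1], so clip and record the fixed scale
  nd$volume$values <- pmin(nd$volume$values, 1)
  list(pet = np$volume, ct = nc$volume, dose = nd$volume,
       records = list(pet = np$record, ct = nc$record, dose = nd$record))
}
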