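test_that("parameter counting follows the weights-plus-biases convention", {
  spec <- network_spec()
  expect_identical(count_parameters(spec),
                   c(2560L, 163968L, 41024L, 577L, 601L))
  tiny <- tiny_spec()
  # 3 units: 3*1*4+4, 4*4*3+3, 5*3*1+1
  expect_identical(count_parameters(tiny), c(16L, 51L, 16L))
})

test_that("building a network is reproducible and validated", {
  m1 <- build_network(seed = 42)
  m2 <- build_network(seed = 42)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_network(seed = 43)
  expect_false(identical(m1$layers[[1]]$W, m3$layers[[1]]$W))
  expect_error(network_spec(n_filters = c(4, 2), filter_widths = c(3)), "length")
  expect_error(network_spec(input_length = 100, filter_widths = c(9, 5, 5, 9, 600)),
               "exceed")
})

test_that("compiled forward pass matches an independent R implementation", {
  set.seed(3)
  # tiny_spec covers the direct small-kernel paths; wino_spec routes its
  # width-5 unit through the Winograd schedule
  for (spec in list(tiny_spec(), wino_spec())) {
    model <- build_network(spec, seed = 7)
    for (i in 1:3) {
      x <- runif(24, 0, 4)
      expect_equal(denoise(model, x), ref_forward(model, x), tolerance = 1e-10)
    }
  }
  # and the spectrum-wide single-channel kernel at full length
  wide <- build_network(network_spec(input_length = 600L,
                                     n_filters = c(6L, 1L),
                                     filter_widths = c(5L, 600L)), seed = 9)
  x <- runif(600, 0, 4)
  expect_equal(denoise(wide, x), ref_forward(wide, x), tolerance = 1e-9)
})

test_that("forward pass preserves the spectrum width at every depth", {
  # truncated stacks of the published architecture: each feature map keeps
  # the 600-sample width under same padding at stride 1
  full <- network_spec()
  for (depth in 1:5) {
    spec <- network_spec(input_length = 600L,
                         n_filters = full$layers$n_filters[seq_len(depth)],
                         filter_widths = full$layers$filter_width[seq_len(depth)],
                         batchnorm_relu = full$layers$has_batchnorm_relu[seq_len(depth)])
    spec$layers$in_channels <- full$layers$in_channels[seq_len(depth)]
    model <- build_network(spec, seed = 1)
    out <- denoise(model, matrix(runif(600 * 2, 0, 1), 2, 600))
    expect_identical(dim(out), c(2L, 600L))
  }
})

test_that("inference is deterministic and batches preserve order", {
  model <- build_network(tiny_spec(), seed = 5)
  X <- matrix(runif(24 * 7, 0, 2), 7, 24)
  out1 <- denoise(model, X)
  out2 <- denoise(model, X)
  expect_identical(out1, out2)
  for (s in c(1L, 4L, 7L))
    expect_equal(out1[s, ], denoise(model, X[s, ]), tolerance = 1e-12)
  expect_error(denoise(model, runif(23)), "23")
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(42)
  B <- 3L; N <- 24L
  X <- matrix(runif(N * B, 0, 2), N, B)
  Y <- matrix(runif(N * B, 0, 2), N, B)
  pk <- c(8L, 12L, 15L); nw <- c(2L, 3L, 2L)
  for (spec in list(tiny_spec(), wino_spec())) {
    model <- build_network(spec, seed = 7)
    lg <- ramanclean:::cpp_cnn_loss_grad(model$layers, X, Y, pk, nw, 50, 1)
    expect_gt(lg$loss, 0)
    fd <- function(li, field, idx, eps = 1e-5) {
      up <- model$layers; up[[li]][[field]][idx] <- up[[li]][[field]][idx] + eps
      dn <- model$layers; dn[[li]][[field]][idx] <- dn[[li]][[field]][idx] - eps
      (ramanclean:::cpp_cnn_loss_grad(up, X, Y, pk, nw, 50, 1)$loss -
         ramanclean:::cpp_cnn_loss_grad(dn, X, Y, pk, nw, 50, 1)$loss) / (2 * eps)
    }
    for (li in 1:3) {
      fields <- intersect(c("W", "gamma", "beta", "b"), names(lg$grads[[li]]))
      for (field in fields) {
        g <- as.numeric(lg$grads[[li]][[field]])
        for (idx in unique(round(seq(1, length(g), length.out = 3)))) {
          numeric_grad <- fd(li, field, idx)
          if (abs(numeric_grad) < 1e-7 && abs(g[idx]) < 1e-7) next
          expect_equal(g[idx], numeric_grad, tolerance = 1e-4,
                       label = sprintf("layer %d %s[%d] analytic", li, field, idx))
        }
      }
    }
  }
})

test_that("models survive a save/load round trip with a provenance sidecar", {
  model <- build_network(tiny_spec(), seed = 3)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$layers, model$layers)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$input_length, 24L)
  expect_equal(unlist(side$parameters_per_unit), count_parameters(tiny_spec()))
  x <- runif(24)
  expect_identical(denoise(back, x), denoise(model, x))
})
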