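model <- build_echo_net(network_config("reduced"))
ishape <- model$config$input_shape

rand_inputs <- function(seed = 1L) {
  set.seed(seed)
  f <- matrix(runif(prod(ishape)), ishape[1L], ishape[2L])
  m <- matrix(0, ishape[1L], ishape[2L])
  m[20:40, 50:80] <- 1
  list(main = build_stream_input(f, m),
       ref = build_stream_input(matrix(runif(prod(ishape)), ishape[1L]), m))
}

test_that("the fused pyramid has five levels at the configured width", {
  inp <- rand_inputs()
  main_x <- echoseg:::new_node(NULL, array(inp$main, c(dim(inp$main), 1L)))
  ref_x <- echoseg:::new_node(NULL, array(inp$ref, c(dim(inp$ref), 1L)))
  fused <- echoseg:::fused_pyramid(NULL, model, main_x, ref_x)
  expect_length(fused, 5L)
  pc <- model$config$pyramid_channels
  strides <- model$config$anchors$strides
  for (i in seq_along(fused)) {
    d <- dim(fused[[i]]$val)
    expect_identical(d[3L], pc)
    expect_identical(d[1L], as.integer(ceiling(ishape[1L] / strides[i])))
    expect_identical(d[2L], as.integer(ceiling(ishape[2L] / strides[i])))
  }
  ## classification head: A sigmoid outputs per location; regression: 4A
  pn <- echoseg:::wrap_params(NULL, model$params)
  cls <- echoseg:::head_forward(NULL, pn$cls, fused[[1L]], sigmoid = TRUE)
  reg <- echoseg:::head_forward(NULL, pn$reg, fused[[1L]])
  A <- model$config$anchors$A
  expect_identical(dim(cls$val)[3L], A)
  expect_identical(dim(reg$val)[3L], 4L * A)
  expect_true(all(cls$val >= 0 & cls$val <= 1))
})

test_that("an untrained model still yields a valid, deterministic frame result", {
  inp <- rand_inputs(5L)
  fr1 <- forward_frame(model, inp$main, inp$ref)
  fr2 <- forward_frame(model, inp$main, inp$ref)
  expect_s3_class(fr1, "frame_result")
  expect_identical(dim(fr1$mask), dim(inp$main[, , 1L]))
  expect_true(all(fr1$mask %in% c(0, 1)))
  expect_identical(fr1$mask, fr2$mask)
  expect_identical(fr1$best_score, fr2$best_score)
})

test_that("an empty detection set falls back to the guidance mask", {
  ## silence the classifier head entirely: every anchor scores the prior
  ## probability 0.01, far below the 0.5 threshold
  quiet <- model
  quiet$params$cls$out$w[] <- 0
  inp <- rand_inputs(6L)
  fr <- forward_frame(quiet, inp$main, inp$ref)
  expect_true(fr$fallback_used)
  expect_true(is.na(fr$best_score))
  expect_identical(fr$mask, inp$main[, , 2L])
})

test_that("training reduces the loss and learning rate 0 is inert", {
  dataset <- phantom_train_set(n_frames = 6L)[1:2]
  fit0 <- train_echo_net(model, dataset[1L],
                         train_config(learning_rate = 0, iterations = 2L,
                                      seed = 4L))
  expect_identical(fit0$model$params, model$params)
  expect_equal(fit0$losses[1L], fit0$losses[2L], tolerance = 1e-12)

  fit <- train_echo_net(model, dataset,
                        train_config(learning_rate = 3e-3, iterations = 20L,
                                     seed = 4L))
  expect_lt(mean(tail(fit$losses, 5L)), mean(head(fit$losses, 5L)))
  expect_true(all(is.finite(fit$losses)))
  expect_error(train_echo_net(model, list(), train_config()), "empty")
})

test_that("teacher-forced loss on a single sequence is reducible", {
  ps <- generate_phantom_sequence(phantom_spec(n_frames = 5L, seed = 41L))
  fit <- train_echo_net(model, list(ps),
                        train_config(learning_rate = 3e-3, iterations = 12L,
                                     seed = 2L))
  expect_lt(fit$losses[12L], fit$losses[1L])
})

test_that("backbone transfer copies the encoder and keeps heads random", {
  src <- build_echo_net(network_config("reduced", seed = 7L))
  tgt <- build_echo_net(network_config("reduced", seed = 8L))
  out <- transfer_backbone(tgt, src)
  expect_identical(out$params$stem1, src$params$stem1)
  expect_identical(out$params$stages, src$params$stages)
  expect_identical(out$params$cls, tgt$params$cls)
  expect_false(identical(out$params$stages, tgt$params$stages))
})

test_that("sequence segmentation honours the semi-supervised contract", {
  ps <- generate_phantom_sequence(phantom_spec(n_frames = 4L, seed = 17L))
  ms <- segment_sequence(model, ps, ps$masks[[1L]])
  expect_length(ms$masks, 4L)
  expect_identical(ms$masks[[1L]], ps$masks[[1L]])
  for (m in ms$masks) expect_true(all(m %in% c(0, 1)))
  expect_error(segment_sequence(model, ps$frames[1L], ps$masks[[1L]]),
               "at least 2")
})
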