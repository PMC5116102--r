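ns <- asNamespace("actisleep")

numeric_grad <- function(spec, params, batch, y, eps = 1e-6) {
  lossf <- function(pl) {
    fw <- ns$nn_forward(spec, pl, batch, NULL)
    ns$bce_loss(ns$sigmoid(fw$z), y)
  }
  g <- lapply(params, function(p) p * 0)
  for (nm in names(params)) {
    for (i in seq_along(params[[nm]])) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- lossf(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      g[[nm]][i] <- (up - lossf(pp)) / (2 * eps)
    }
  }
  g
}

grad_gap <- function(arch, ...) {
  spec <- model_spec(arch, ...)
  m <- build_model(spec, seed = 3)
  set.seed(5)
  batch <- if (arch %in% c("lr", "mlp", "cnn")) {
    list(x = matrix(stats::rnorm(4 * spec$input_length), 4))
  } else {
    ns$stack_sequences(lapply(c(6, 4, 9, 9),
                              function(t) matrix(stats::rnorm(t * spec$input_dim),
                                                 t, spec$input_dim)))
  }
  y <- c(1, 0, 1, 0)
  fw <- ns$nn_forward(spec, m$params, batch, NULL)
  dz <- (ns$sigmoid(fw$z) - y) / 4
  ga <- ns$nn_backward(spec, m$params, fw$cache, dz)
  gn <- numeric_grad(spec, m$params, batch, y)
  max(unlist(Map(function(a, b) max(abs(a - b)), ga[names(gn)], gn)))
}

test_that("analytic gradients match finite differences for every architecture", {
  # includes the tiny logistic-regression case checked to 1e-5 absolute
  expect_lt(grad_gap("lr", input_length = 5L), 1e-5)
  expect_lt(grad_gap("mlp", input_length = 12L, hidden_size = 5L), 1e-5)
  expect_lt(grad_gap("cnn", input_length = 20L, conv_filters = 3L), 1e-5)
  expect_lt(grad_gap("rnn", hidden_size = 4L), 1e-5)
  expect_lt(grad_gap("lstm", hidden_size = 4L), 1e-5)
  expect_lt(grad_gap("tb_lstm", hidden_size = 4L, time_batch_window = 3L), 1e-5)
})

test_that("parameter counts are pure functions of the specification", {
  expect_equal(n_params(build_model(model_spec("lr"))), 961L)
  expect_equal(n_params(build_model(model_spec("mlp"))), 960L * 15L + 15L + 15L + 1L)
  # 25 filters of length 5 + biases, then 239*25 pooled features to one unit
  expect_equal(n_params(build_model(model_spec("cnn"))),
               5L * 25L + 25L + 239L * 25L + 1L)
  expect_equal(n_params(build_model(model_spec("rnn"))),
               75L + 75L * 75L + 75L + 75L + 1L)
  expect_equal(n_params(build_model(model_spec("lstm"))),
               101L * 400L + 400L + 100L + 1L)
  expect_equal(n_params(build_model(model_spec("tb_lstm"))),
               115L * 400L + 400L + 100L + 1L)
})

test_that("an MLP without hidden units predicts identically to logistic regression", {
  set.seed(21)
  inst <- toy_instances(15, len = 40L)
  split <- stratified_split(inst, seed = 2)
  lr <- build_model(model_spec("lr", input_length = 40L), seed = 9)
  lr <- train_model(lr, inst[split$train], inst[split$validation],
                    train_config("lr", max_epochs = 3, seed = 9))
  mlp0 <- build_model(model_spec("mlp", hidden_size = 0L, input_length = 40L), seed = 1)
  mlp0$params <- lr$params
  mlp0$standardize <- lr$standardize
  expect_equal(predict(mlp0, inst[split$test]), predict(lr, inst[split$test]))
})

test_that("predictions are confidences in [0,1], deterministic, and 0.5 at zero weights", {
  set.seed(22)
  inst <- toy_instances(10, len = 30L)
  m <- build_model(model_spec("tb_lstm", time_batch_window = 5L), seed = 2)
  m$standardize <- list(mu = 10, sd = 3)
  p1 <- predict(m, inst)
  expect_true(all(p1$confidence >= 0 & p1$confidence <= 1))
  expect_identical(p1, predict(m, inst))
  expect_equal(p1$label, ifelse(p1$confidence >= 0.5, "good", "poor"))

  z <- build_model(model_spec("lr", input_length = 30L), seed = 2)
  z$params$W[] <- 0; z$params$b <- 0
  z$standardize <- list(mu = 10, sd = 3)
  expect_equal(predict(z, inst)$confidence, rep(0.5, length(inst)))
})

test_that("training separates a linearly separable toy problem", {
  set.seed(30)
  inst <- toy_instances(10, len = 30L, gap = 4)
  m <- build_model(model_spec("lr", input_length = 30L), seed = 7)
  m <- train_model(m, inst, inst, train_config("lr", max_epochs = 50, seed = 7))
  pred <- predict(m, inst)
  truth <- vapply(inst, function(z) z$label, character(1))
  expect_equal(mean(pred$label == truth), 1.0)
  expect_lte(nrow(m$log), 50L)
})

test_that("training obeys max_epochs and is seed-reproducible", {
  set.seed(31)
  inst <- toy_instances(12, len = 25L)
  split <- stratified_split(inst, seed = 3)
  cfg <- train_config("mlp", max_epochs = 1, seed = 5)
  spec <- model_spec("mlp", input_length = 25L, hidden_size = 4L)
  m1 <- train_model(build_model(spec, seed = 5), inst[split$train],
                    inst[split$validation], cfg)
  expect_equal(nrow(m1$log), 1L)

  cfg2 <- train_config("mlp", max_epochs = 6, seed = 5)
  a <- train_model(build_model(spec, seed = 5), inst[split$train],
                   inst[split$validation], cfg2)
  b <- train_model(build_model(spec, seed = 5), inst[split$train],
                   inst[split$validation], cfg2)
  expect_identical(a$params, b$params)
  expect_identical(a$log, b$log)
})

test_that("early stopping restores the best validation accuracy seen", {
  set.seed(32)
  # noisy labels force validation accuracy to fluctuate and trigger stopping
  inst <- toy_instances(25, len = 20L, gap = 0.3)
  split <- stratified_split(inst, seed = 4)
  for (sd_ in 1:4) {
    m <- train_model(build_model(model_spec("mlp", input_length = 20L,
                                            hidden_size = 3L), seed = sd_),
                     inst[split$train], inst[split$validation],
                     train_config("mlp", max_epochs = 25, seed = sd_))
    k <- nrow(m$log) - as.integer(isTRUE(m$stopped_early))
    expect_gte(m$log$val_accuracy[k], max(m$log$val_accuracy[seq_len(k)]))
    expect_lte(nrow(m$log), 25L)
    if (isTRUE(m$stopped_early)) {
      expect_lt(m$log$val_accuracy[nrow(m$log)], m$log$val_accuracy[k])
    }
  }
})

test_that("model checkpoints survive a JSON round trip", {
  set.seed(33)
  inst <- toy_instances(12, len = 20L)
  split <- stratified_split(inst, seed = 6)
  m <- train_model(build_model(model_spec("cnn", input_length = 20L,
                                          conv_filters = 3L), seed = 2),
                   inst[split$train], inst[split$validation],
                   train_config("cnn", max_epochs = 2, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, inst[split$test]), predict(m, inst[split$test]))
  expect_equal(n_params(m2), n_params(m))
})
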