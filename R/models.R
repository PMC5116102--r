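# User-facing model interface: architecture specifications, per-architecture
# training hyper-parameter defaults, RMSprop training with accuracy-based
# early stopping, and prediction.

ARCHITECTURES <- c("lr", "mlp", "cnn", "rnn", "lstm", "tb_lstm")

default_hidden_size <- c(lr = 0L, mlp = 15L, cnn = 0L, rnn = 75L,
                         lstm = 100L, tb_lstm = 100L)
default_mini_batch <- c(lr = 5L, mlp = 20L, cnn = 5L, rnn = 5L,
                        lstm = 5L, tb_lstm = 5L)
default_dropout <- c(lr = 0.5, mlp = 0.1, cnn = 0.0, rnn = 0.1,
                     lstm = 0.5, tb_lstm = 0.5)

#' Model specification
#'
#' Describes one of the six classifier architectures together with its
#' structural hyper-parameters. Defaults are each architecture's tuned
#' optimum: MLP hidden size 15; CNN with 25 filters of length 5 and pooling
#' length 4; RNN hidden size 75; LSTM and time-batched LSTM hidden size 100.
#' Hidden units are rectified-linear in the feed-forward architectures; the
#' recurrent state uses tanh (and the usual sigmoid/tanh gates in the LSTM)
#' for numerical stability over sequences hundreds of steps long. Every
#' model ends in a single sigmoid output unit whose value is the confidence
#' that the following sleep is good quality.
#'
#' @param architecture One of `"lr"`, `"mlp"`, `"cnn"`, `"rnn"`, `"lstm"`,
#'   `"tb_lstm"`.
#' @param hidden_size Hidden-layer width; `NULL` uses the architecture
#'   default. `mlp` with `hidden_size = 0` is exactly logistic regression.
#' @param conv_filters,filter_length,pool_length CNN structure (25, 5, 4).
#' @param input_length Fixed input length in minutes for `lr`/`mlp`/`cnn`
#'   (default 960, i.e. the most recent 16 h of awake activity).
#' @param time_batch_window Minutes merged per step for `tb_lstm`
#'   (default 15).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(architecture = ARCHITECTURES, hidden_size = NULL,
                       conv_filters = 25L, filter_length = 5L,
                       pool_length = 4L, input_length = 960L,
                       time_batch_window = 15L) {
  architecture <- match.arg(architecture)
  hidden_size <- as.integer(hidden_size %||% default_hidden_size[[architecture]])
  if (hidden_size < 0L) stop("'hidden_size' must be >= 0")
  if (architecture %in% c("rnn", "lstm", "tb_lstm") && hidden_size == 0L) {
    stop("recurrent architectures need a positive hidden size")
  }
  input_dim <- switch(architecture, tb_lstm = as.integer(time_batch_window), 1L)
  structure(list(architecture = architecture, hidden_size = hidden_size,
                 conv_filters = as.integer(conv_filters),
                 filter_length = as.integer(filter_length),
                 pool_length = as.integer(pool_length),
                 input_length = as.integer(input_length),
                 time_batch_window = as.integer(time_batch_window),
                 input_dim = input_dim),
            class = "model_spec")
}

#' Training configuration
#'
#' RMSprop hyper-parameters with each architecture's tuned optimum as
#' default: mini-batch size 5 (20 for MLP) and dropout 0.5 (0.1 for MLP and
#' RNN, 0 for CNN); at most 50 epochs; training stops the first time
#' validation accuracy drops below the previous epoch's, restoring the
#' previous epoch's parameters. The learning rate (default 0.001) is a free
#' knob.
#'
#' @param architecture Architecture name used for defaults, or `NULL` to
#'   require explicit values.
#' @param mini_batch_size Instances per gradient step.
#' @param dropout_ratio Fraction of pre-output feature units dropped during
#'   training (in `[0, 1)`).
#' @param max_epochs Maximum passes over the training set (default 50).
#' @param learning_rate RMSprop step size (default 0.001).
#' @param rho RMSprop decay of the squared-gradient average (default 0.9).
#' @param epsilon RMSprop stabiliser (default 1e-8).
#' @param seed Integer seed controlling initial weights, shuffling and
#'   dropout; identical seed, data and config reproduce training exactly.
#' @return Object of class `train_config`.
#' @export
train_config <- function(architecture = NULL, mini_batch_size = NULL,
                         dropout_ratio = NULL, max_epochs = 50L,
                         learning_rate = 0.001, rho = 0.9, epsilon = 1e-8,
                         seed = 1L) {
  if (!is.null(architecture)) architecture <- match.arg(architecture, ARCHITECTURES)
  mini_batch_size <- mini_batch_size %||%
    if (is.null(architecture)) stop("'mini_batch_size' required without an architecture") else
      default_mini_batch[[architecture]]
  dropout_ratio <- dropout_ratio %||%
    if (is.null(architecture)) 0 else default_dropout[[architecture]]
  if (dropout_ratio < 0 || dropout_ratio >= 1) stop("'dropout_ratio' must be in [0, 1)")
  if (max_epochs < 1L) stop("'max_epochs' must be >= 1")
  structure(list(architecture = architecture,
                 mini_batch_size = as.integer(mini_batch_size),
                 dropout_ratio = dropout_ratio, max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained model
#'
#' Parameters are initialised from fan-in-scaled normal draws under `seed`;
#' the parameter count is a pure function of the specification and input
#' shape.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the initial weights.
#' @return Object of class `sleep_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  structure(list(spec = spec, params = nn_init(spec), standardize = NULL,
                 log = NULL, init_seed = as.integer(seed)),
            class = "sleep_model")
}

#' Number of trainable parameters
#'
#' @param model A `sleep_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "sleep_model"))
  nn_n_params(model$params)
}

#' @export
print.sleep_model <- function(x, ...) {
  cat(sprintf("<sleep_model> %s, %d parameters%s\n", x$spec$architecture,
              n_params(x), if (is.null(x$log)) " (untrained)" else ""))
  if (!is.null(x$log)) {
    cat(sprintf("trained %d epoch(s), final validation accuracy %.4f\n",
                nrow(x$log), x$log$val_accuracy[nrow(x$log)]))
  }
  invisible(x)
}

# Convert raw instances into the model's input representation.
# Standardization stats must already be attached to the model.
prepare_inputs <- function(model, instances) {
  spec <- model$spec
  st <- model$standardize
  if (is.null(st)) stop("model has no standardization stats; train it first")
  scale1 <- function(v) (v - st$mu) / st$sd
  if (!is_recurrent(spec$architecture)) {
    padded <- pad_or_truncate(instances, spec$input_length)
    x <- scale1(padded$x)
    x[!padded$mask] <- 0
    list(fixed = TRUE, x = x)
  } else if (spec$architecture == "tb_lstm") {
    list(fixed = FALSE,
         seqs = lapply(instances, function(z) time_batch(scale1(z$x), spec$time_batch_window)))
  } else {
    list(fixed = FALSE,
         seqs = lapply(instances, function(z) matrix(scale1(z$x), ncol = 1L)))
  }
}

slice_batch <- function(prepared, idx) {
  if (prepared$fixed) list(x = prepared$x[idx, , drop = FALSE])
  else stack_sequences(prepared$seqs[idx])
}

forward_prob <- function(model, batch, drop_mask = NULL, need_cache = TRUE) {
  fw <- nn_forward(model$spec, model$params, batch, drop_mask, need_cache)
  list(p = sigmoid(fw$z), cache = fw$cache, z = fw$z)
}

instance_labels <- function(instances) {
  as.integer(vapply(instances, function(z) z$label, character(1)) == "good")
}

#' Train a model with RMSprop and early stopping
#'
#' Minimises mean binary cross-entropy over shuffled mini-batches. After
#' every epoch the model is evaluated on the validation set; the first time
#' validation accuracy falls below the previous epoch's value, training
#' stops and the previous epoch's parameters are restored (ties continue).
#' Input standardization statistics (mean/sd of the training activity
#' values) are computed here, stored on the model and reapplied at
#' prediction time.
#'
#' @param model An untrained (or previously trained) `sleep_model`.
#' @param train_instances,val_instances Instance lists from
#'   [segment_awake_pairs()] with both classes present in each.
#' @param cfg A [train_config()].
#' @return The trained `sleep_model`, with a `log` data frame (`epoch`,
#'   `train_loss`, `val_accuracy`) and `stopped_early` flag.
#' @export
train_model <- function(model, train_instances, val_instances,
                        cfg = train_config(model$spec$architecture)) {
  stopifnot(inherits(model, "sleep_model"), inherits(cfg, "train_config"))
  if (length(train_instances) == 0L || length(val_instances) == 0L) {
    stop("training and validation sets must be non-empty")
  }
  vals <- unlist(lapply(train_instances, function(z) z$x))
  st <- list(mu = mean(vals), sd = max(stats::sd(vals), 1e-8))
  model$standardize <- st
  xtr <- prepare_inputs(model, train_instances)
  ytr <- instance_labels(train_instances)
  xval <- prepare_inputs(model, val_instances)
  yval <- instance_labels(val_instances)
  set.seed(cfg$seed)
  n <- length(ytr)
  state <- lapply(model$params, function(p) p * 0)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_accuracy = numeric())
  prev_params <- model$params
  prev_acc <- -Inf
  stopped_early <- FALSE
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$mini_batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + cfg$mini_batch_size - 1L, n)]
      batch <- slice_batch(xtr, idx)
      y <- ytr[idx]
      dm <- make_dropout_mask(feature_dim(model$spec, length(idx)), cfg$dropout_ratio)
      fw <- forward_prob(model, batch, dm)
      loss <- bce_loss(fw$p, y)
      if (!is.finite(loss)) stop("training diverged (non-finite loss) at epoch ", epoch)
      losses[bi] <- loss
      dz <- (fw$p - y) / length(y)
      grads <- nn_backward(model$spec, model$params, fw$cache, dz)
      upd <- rmsprop_step(model$params, grads, state,
                          cfg$learning_rate, cfg$rho, cfg$epsilon)
      model$params <- upd$params
      state <- upd$state
    }
    val_p <- forward_prob(model, slice_batch(xval, seq_along(yval)),
                          need_cache = FALSE)$p
    val_acc <- mean((val_p >= 0.5) == (yval == 1))
    log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(losses),
                                 val_accuracy = val_acc))
    if (val_acc < prev_acc) {
      model$params <- prev_params
      stopped_early <- TRUE
      break
    }
    prev_params <- model$params
    prev_acc <- val_acc
  }
  model$log <- log
  model$stopped_early <- stopped_early
  model$train_config <- cfg
  model
}

#' Predict sleep quality for instances
#'
#' Deterministic at inference: dropout is off and the same model always
#' returns the same confidences.
#'
#' @param object A trained `sleep_model`.
#' @param instances Instance list from [segment_awake_pairs()].
#' @param threshold Decision threshold on the confidence (default 0.5).
#' @param ... Unused.
#' @return Data frame with `confidence` (probability of good sleep, in
#'   `[0, 1]`) and `label` (`"good"`/`"poor"`).
#' @export
predict.sleep_model <- function(object, instances, threshold = 0.5, ...) {
  prepared <- prepare_inputs(object, instances)
  p <- forward_prob(object, slice_batch(prepared, seq_along(instances)),
                    need_cache = FALSE)$p
  data.frame(confidence = p,
             label = ifelse(p >= threshold, "good", "poor"))
}

#' Save / load a model checkpoint as JSON
#'
#' Weights, spec, standardization stats and the training log are stored in a
#' plain-text JSON file.
#'
#' @param model A `sleep_model`.
#' @param path Checkpoint path.
#' @return `path` invisibly, or the restored `sleep_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sleep_model"))
  out <- list(
    spec = unclass(model$spec),
    params = lapply(model$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p)) else list(data = p)),
    standardize = model$standardize,
    log = model$log, init_seed = model$init_seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(model_spec, raw$spec[c("architecture", "hidden_size",
                                         "conv_filters", "filter_length",
                                         "pool_length", "input_length",
                                         "time_batch_window")])
  params <- lapply(raw$params, function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  log <- if (!is.null(raw$log) && length(raw$log)) as.data.frame(raw$log) else NULL
  structure(list(spec = spec, params = params, standardize = raw$standardize,
                 log = log, init_seed = raw$init_seed),
            class = "sleep_model")
}
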