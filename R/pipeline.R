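# End-to-end orchestration: simulate -> score -> build dataset -> train ->
# evaluate. Stages communicate only through serialized artifacts (CSV/JSON)
# in the run directory, so each stage is independently inspectable and
# re-runnable.

#' Run the full analysis pipeline on a simulated cohort
#'
#' Generates a cohort, scores every recording, builds the labeled
#' awake/sleep dataset, makes a stratified 70/15/15 split, trains the
#' requested architectures and evaluates each on the held-out test set.
#' All stochastic stages derive their seeds from `seed`, so re-running with
#' an identical configuration reproduces every artifact.
#'
#' @param out_dir Run directory (created; existing files overwritten).
#' @param sim A [sim_config()]; its own `seed` is overridden by `seed`.
#' @param scoring A [scoring_config()].
#' @param architectures Character vector of architectures to train.
#' @param min_awake_min Minimum awake-vector length (minutes).
#' @param ratios Train/validation/test fractions.
#' @param max_epochs Training epoch cap applied to every architecture.
#' @param learning_rate RMSprop step size.
#' @param seed Global integer seed.
#' @return Invisibly, a data frame with one row per architecture and its
#'   test-set metrics; artifacts are written under `out_dir`.
#' @export
run_pipeline <- function(out_dir,
                         sim = sim_config(),
                         scoring = scoring_config(),
                         architectures = ARCHITECTURES,
                         min_awake_min = 60L,
                         ratios = c(0.70, 0.15, 0.15),
                         max_epochs = 50L,
                         learning_rate = 0.001,
                         seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), inherits(scoring, "scoring_config"))
  architectures <- match.arg(architectures, ARCHITECTURES, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  sim$seed <- seed

  cohort <- generate_cohort(sim)
  periods_path <- file.path(out_dir, "sleep_periods.csv")
  instances <- list()
  first <- TRUE
  for (s in cohort$series) {
    periods <- score_recording(s, scoring)
    write_sleep_periods_csv(periods, periods_path, append = !first)
    first <- FALSE
    instances <- c(instances, segment_awake_pairs(periods, s, min_awake_min))
  }
  if (length(instances) < 20L) stop("pipeline stage 'build-dataset': too few instances scored")
  split <- stratified_split(instances, ratios, seed = seed + 1L)
  write_instances_csv(instances, file.path(out_dir, "instances.csv"))
  jsonlite::write_json(
    list(split = split[c("train", "validation", "test")], ratios = ratios,
         seed = seed, n_instances = length(instances)),
    file.path(out_dir, "split.json"), auto_unbox = TRUE, digits = NA)

  results <- list()
  for (arch in architectures) {
    spec <- model_spec(arch)
    cfg <- train_config(arch, max_epochs = max_epochs,
                        learning_rate = learning_rate, seed = seed + 2L)
    model <- build_model(spec, seed = seed + 2L)
    model <- train_model(model, instances[split$train],
                         instances[split$validation], cfg)
    pred <- predict(model, instances[split$test])
    rep <- evaluate_predictions(instance_labels(instances[split$test]),
                                pred$confidence)
    write_metrics_report(rep, file.path(out_dir, paste0("metrics_", arch, ".json")),
                         file.path(out_dir, paste0("roc_", arch, ".csv")))
    save_model(model, file.path(out_dir, paste0("model_", arch, ".json")))
    results[[arch]] <- data.frame(
      architecture = arch, epochs = nrow(model$log),
      accuracy = rep$accuracy, precision = rep$precision,
      recall_sensitivity = rep$recall_sensitivity,
      specificity = rep$specificity, f1 = rep$f1, auc = rep$auc)
  }
  summary <- do.call(rbind, results)
  rownames(summary) <- NULL
  utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, package_version = as.character(utils::packageVersion("actisleep")),
         r_version = R.version.string,
         sim = unclass(sim), scoring = unclass(scoring),
         architectures = architectures, max_epochs = max_epochs,
         learning_rate = learning_rate),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Serialize labeled instances as a wide CSV
#'
#' One row per instance: `id`, `subject_id`, `label`, `T`, then the awake
#' activity right-aligned in `x_1..x_L` (zero left padding), `L` being the
#' longest instance.
#'
#' @param instances Instance list from [segment_awake_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instances_csv <- function(instances, path) {
  L <- max(vapply(instances, function(z) length(z$x), integer(1)))
  padded <- t(vapply(instances, function(z) c(rep(0, L - length(z$x)), z$x),
                     numeric(L)))
  df <- data.frame(
    id = seq_along(instances),
    subject_id = vapply(instances, function(z) z$subject_id, character(1)),
    label = vapply(instances, function(z) z$label, character(1)),
    T = vapply(instances, function(z) z$T, integer(1)))
  colnames(padded) <- paste0("x_", seq_len(L))
  utils::write.csv(cbind(df, padded), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read labeled instances back from a wide CSV
#'
#' Inverse of [write_instances_csv()]: the left zero padding is stripped
#' using the stored true length `T`.
#'
#' @param path Path written by [write_instances_csv()].
#' @return List of instances as produced by [segment_awake_pairs()].
#' @export
read_instances_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  xcols <- grep("^x_", names(df))
  lapply(seq_len(nrow(df)), function(i) {
    x <- as.numeric(df[i, xcols])
    list(subject_id = df$subject_id[i],
         x = utils::tail(x, df$T[i]),
         label = df$label[i],
         T = as.integer(df$T[i]))
  })
}
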