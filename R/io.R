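#' Read a multichannel trial
#'
#' Delimited trials are comma-separated numeric matrices (rows = samples,
#' columns = channels) with a header row of channel labels; a sampling
#' rate must be supplied since the format carries none. EDF input is not
#' supported in this build (no EDF reader is available) and raises an
#' informative error.
#'
#' @param path file path.
#' @param rate sampling rate in Hz (required for delimited input).
#' @param format `"delimited"` or `"edf"`.
#' @return list of [eeg_signal] objects, one per channel.
#' @export
read_trial <- function(path, rate = NULL, format = c("delimited", "edf")) {
  format <- match.arg(format)
  if (format == "edf")
    stop("EDF input is not supported in this build; convert to delimited text",
         call. = FALSE)
  if (is.null(rate))
    stop("a sampling rate is required for delimited input", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   stop("parse error in ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  if (nrow(df) == 0 || ncol(df) == 0)
    stop("parse error: ", path, " contains no data", call. = FALSE)
  lapply(seq_len(ncol(df)), function(j)
    eeg_signal(df[[j]], rate, names(df)[j]))
}

#' Write a multichannel trial
#'
#' @param mat samples x channels numeric matrix with column names.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = FALSE)
  invisible(path)
}

#' Write a decomposition to delimited text plus a JSON sidecar
#'
#' The matrix has columns `IMF1..IMFm, residue`; the sidecar records
#' method, ensemble size, noise ratio, seed and rate.
#'
#' @param dec an `imf_decomposition`.
#' @param prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return the CSV path, invisibly.
#' @export
write_decomposition <- function(dec, prefix) {
  stopifnot(inherits(dec, "imf_decomposition"))
  out <- cbind(dec$imfs, residue = dec$residue)
  utils::write.csv(as.data.frame(out), paste0(prefix, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(method = dec$method,
                            ensemble_size = dec$ensemble_size,
                            noise_ratio = dec$noise_ratio, seed = dec$seed,
                            rate = dec$rate, label = dec$label),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".csv"))
}

#' Declarative run configuration
#'
#' One document holding every tunable of the pipeline; round-trips
#' losslessly through JSON and is written next to every run's outputs.
#'
#' @param n_trials,n_channels,class_effect generator settings.
#' @param ensemble_size,noise_ratio EEMD settings.
#' @param reference_epochs,quantile_pair noise-reference settings.
#' @param confidence spread-line percentile.
#' @param spp an [spp_config()].
#' @param k_folds cross-validation folds (0 = single 75/25 split).
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_trials = 40L, n_channels = 8L, class_effect = 1.5,
                       ensemble_size = 50L, noise_ratio = 0.3,
                       reference_epochs = 1000L,
                       quantile_pair = c(0.025, 0.975), confidence = 0.99,
                       spp = spp_config(), k_folds = 0L, seed = 1L) {
  structure(list(n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels),
                 class_effect = class_effect,
                 ensemble_size = as.integer(ensemble_size),
                 noise_ratio = noise_ratio,
                 reference_epochs = as.integer(reference_epochs),
                 quantile_pair = quantile_pair, confidence = confidence,
                 spp = spp, k_folds = as.integer(k_folds),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  utils::str(unclass(x), max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(spp, path) {
  x <- unclass(spp)
  x$spp <- unclass(x$spp)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_pairs <- function(p) {
    if (is.matrix(p)) lapply(seq_len(nrow(p)), function(i) as.integer(p[i, ]))
    else lapply(p, as.integer)
  }
  s$spp$conv_kernels <- fix_pairs(s$spp$conv_kernels)
  s$spp$conv_strides <- fix_pairs(s$spp$conv_strides)
  class(s$spp) <- "spp_config"
  class(s) <- "run_config"
  s
}

#' Decompose, select, and featurize every trial of a dataset
#'
#' Runs the selection procedure channel-by-channel on each trial and
#' stacks the 21-feature descriptors of the selected IMFs into one raw
#' (un-normalized) feature map per trial; the classifier applies
#' training-corpus normalization later.
#'
#' @param dataset list of `list(data = samples x channels matrix,
#'   label = )`, e.g. from [make_labeled_dataset()].
#' @param reference a [build_noise_reference()] at the trial length.
#' @param rate sampling rate in Hz.
#' @param ensemble_size,noise_ratio,confidence selection parameters.
#' @param seed decomposition seed (per trial/channel seeds derive from it).
#' @param progress print a dot per trial.
#' @return list of `list(map = matrix, label = )` ready for [spp_train()].
#' @export
featurize_dataset <- function(dataset, reference, rate = 500,
                              ensemble_size = 50L, noise_ratio = 0.3,
                              confidence = 0.99, seed = 1L,
                              progress = FALSE) {
  raw_norm <- list(mean = rep(0, 21L), sd = rep(1, 21L))
  out <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    trial <- dataset[[i]]
    chans <- colnames(trial$data)
    if (is.null(chans)) chans <- paste0("ch", seq_len(ncol(trial$data)))
    sels <- lapply(seq_len(ncol(trial$data)), function(j) {
      deemd_select(eeg_signal(trial$data[, j], rate, chans[j]), reference,
                   confidence = confidence, ensemble_size = ensemble_size,
                   noise_ratio = noise_ratio,
                   seed = (seed * 1000L + i * 100L + j) %%
                     .Machine$integer.max)
    })
    names(sels) <- chans
    map <- build_feature_map(sels, rate = rate, normalization = raw_norm)
    out[[i]] <- list(map = map$matrix, label = trial$label)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  out
}

#' Run the full pipeline on synthetic data
#'
#' Stage order: simulate trials, build the white-noise reference,
#' decompose + select + featurize, then train and evaluate the classifier
#' (stratified 75/25 split by default, or k-fold when `k_folds >= 2`).
#' Each stage's output is persisted under `out_dir` and reused on rerun:
#' deleting `features.json` (or any later artifact) recomputes from that
#' stage onward only.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @param verbose print stage timing.
#' @return list with `metrics` (and the artifact paths), invisibly the
#'   same structure written to `metrics.json`.
#' @export
pipeline_run <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(out_dir, "config.json"))
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() Sys.time()

  spec <- trial_spec(n_channels = config$n_channels,
                     class_effect = config$class_effect)

  trials_dir <- file.path(out_dir, "trials")
  labels_path <- file.path(out_dir, "labels.csv")
  if (!file.exists(labels_path)) {
    t0 <- tic()
    dir.create(trials_dir, showWarnings = FALSE)
    dataset <- make_labeled_dataset(spec, config$n_trials, 0.5, config$seed)
    for (i in seq_along(dataset))
      write_trial(dataset[[i]]$data,
                  file.path(trials_dir, sprintf("trial_%03d.csv", i)))
    utils::write.csv(data.frame(trial = seq_along(dataset),
                                label = vapply(dataset, `[[`, integer(1),
                                               "label")),
                     labels_path, row.names = FALSE)
    say("simulate: %.1f s", as.numeric(tic()) - as.numeric(t0))
  }
  labels <- utils::read.csv(labels_path)

  ref_path <- file.path(out_dir, "reference.json")
  if (!file.exists(ref_path)) {
    t0 <- tic()
    ref <- build_noise_reference(spec$n_samples,
                                 n_epochs = config$reference_epochs,
                                 quantile_pair = config$quantile_pair,
                                 seed = config$seed)
    write_noise_reference(ref, ref_path)
    say("reference: %.1f s", as.numeric(tic()) - as.numeric(t0))
  }
  ref <- read_noise_reference(ref_path)

  feat_path <- file.path(out_dir, "features.json")
  if (!file.exists(feat_path)) {
    t0 <- tic()
    dataset <- lapply(seq_len(nrow(labels)), function(i) {
      df <- utils::read.csv(file.path(trials_dir,
                                      sprintf("trial_%03d.csv", i)),
                            check.names = FALSE)
      list(data = as.matrix(df), label = labels$label[i])
    })
    feats <- featurize_dataset(dataset, ref, rate = spec$rate,
                               ensemble_size = config$ensemble_size,
                               noise_ratio = config$noise_ratio,
                               confidence = config$confidence,
                               seed = config$seed)
    jsonlite::write_json(lapply(feats, function(f)
      list(map = as.data.frame(f$map), label = f$label)),
      feat_path, digits = NA, dataframe = "columns")
    say("features: %.1f s", as.numeric(tic()) - as.numeric(t0))
  }
  feats <- read_feature_sets(feat_path)

  metrics_path <- file.path(out_dir, "metrics.json")
  if (!file.exists(metrics_path)) {
    t0 <- tic()
    cfg <- config$spp
    if (config$k_folds >= 2L) {
      cv <- cross_validate(feats, cfg, k = config$k_folds,
                           seed = config$seed)
      metrics <- list(mode = sprintf("%d-fold", config$k_folds),
                      fold_accuracy = cv$fold_accuracy,
                      accuracy = cv$mean_accuracy)
    } else {
      labs <- vapply(feats, function(f) as.character(f$label), character(1))
      fold <- stratified_folds(labs, 4L, config$seed)
      te <- fold == 1L
      model <- spp_train(feats[!te], cfg)
      pred <- predict(model, lapply(feats[te], `[[`, "map"))
      metrics <- list(mode = "75/25 split",
                      accuracy = mean(pred$class == labs[te]),
                      n_test = sum(te))
      write_spp_model(model, file.path(out_dir, "model.json"))
    }
    jsonlite::write_json(metrics, metrics_path, auto_unbox = TRUE,
                         digits = NA)
    say("classify: %.1f s", as.numeric(tic()) - as.numeric(t0))
  }
  metrics <- jsonlite::read_json(metrics_path, simplifyVector = TRUE)
  invisible(list(metrics = metrics, out_dir = out_dir))
}


# read the per-trial feature maps + labels persisted by pipeline_run
read_feature_sets <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(el) {
    map <- vapply(el$map, function(col) as.numeric(unlist(col)),
                  numeric(length(el$map[[1]])))
    colnames(map) <- names(el$map)
    list(map = map, label = unlist(el$label))
  })
}

# ---- command-line interface ---------------------------------------------

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        out[[key]] <- args[i + 1L]; i <- i + 2L
      } else { out[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  out
}

cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `build-reference`, `decompose`, `select`,
#' `features`, `train`, `evaluate`, `pipeline`. Invoke from a shell as
#' `Rscript -e 'deemd::deemd_cli()' <subcommand> --flag value ...` or via
#' the installed `inst/cli/deemd` script. Global flags: `--seed`, `--out`.
#'
#' @param args character vector of arguments; defaults to the process
#'   command line.
#' @return exit-style integer, invisibly (0 on success).
#' @export
deemd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: deemd <simulate|build-reference|decompose|select|features|",
        "train|evaluate|pipeline> [--flags]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_args(args[-1])
  seed <- as.integer(cli_num(opts, "seed", 1))
  out <- if (is.null(opts$out)) "." else opts$out
  rate <- cli_num(opts, "rate", 500)
  switch(cmd,
    "simulate" = {
      spec <- trial_spec(n_channels = as.integer(cli_num(opts, "channels", 8)),
                         class_effect = cli_num(opts, "effect", 1.5))
      ds <- make_labeled_dataset(spec, as.integer(cli_num(opts, "n-trials", 40)),
                                 0.5, seed)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_along(ds))
        write_trial(ds[[i]]$data, file.path(out, sprintf("trial_%03d.csv", i)))
      utils::write.csv(data.frame(trial = seq_along(ds),
                                  label = vapply(ds, `[[`, integer(1), "label")),
                       file.path(out, "labels.csv"), row.names = FALSE)
      message("wrote ", length(ds), " trials to ", out)
    },
    "build-reference" = {
      ref <- build_noise_reference(as.integer(cli_num(opts, "length", 2500)),
                                   n_epochs = as.integer(cli_num(opts, "epochs", 10000)),
                                   seed = seed)
      path <- if (is.null(opts$out)) "reference.json" else opts$out
      write_noise_reference(ref, path)
      message("wrote ", path)
    },
    "decompose" = {
      sigs <- read_trial(opts$input, rate = rate)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      for (s in sigs) {
        dec <- eemd(s, ensemble_size = as.integer(cli_num(opts, "ensemble", 100)),
                    noise_ratio = cli_num(opts, "noise-ratio", 0.3), seed = seed)
        write_decomposition(dec, file.path(out, s$label))
      }
      message("decomposed ", length(sigs), " channels into ", out)
    },
    "select" = {
      sigs <- read_trial(opts$input, rate = rate)
      ref <- read_noise_reference(opts$reference)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      for (s in sigs) {
        sel <- deemd_select(s, ref,
                            confidence = cli_num(opts, "confidence", 0.99),
                            ensemble_size = as.integer(cli_num(opts, "ensemble", 100)),
                            noise_ratio = cli_num(opts, "noise-ratio", 0.3),
                            seed = seed)
        utils::write.csv(sel$verdicts,
                         file.path(out, paste0(s$label, "_verdicts.csv")),
                         row.names = FALSE)
        utils::write.csv(as.data.frame(sel$selected),
                         file.path(out, paste0(s$label, "_selected.csv")),
                         row.names = FALSE)
      }
      message("selection written to ", out)
    },
    "features" = {
      sigs <- read_trial(opts$input, rate = rate)
      ref <- read_noise_reference(opts$reference)
      sels <- lapply(sigs, function(s)
        deemd_select(s, ref, ensemble_size = as.integer(cli_num(opts, "ensemble", 100)),
                     seed = seed))
      names(sels) <- vapply(sigs, `[[`, character(1), "label")
      map <- build_feature_map(sels, rate = rate,
                               normalization = list(mean = rep(0, 21),
                                                    sd = rep(1, 21)))
      path <- if (is.null(opts$out)) "features.csv" else opts$out
      utils::write.csv(as.data.frame(map$matrix), path, row.names = FALSE)
      message("wrote ", path)
    },
    "pipeline" = {
      cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
             else run_config(seed = seed,
                             n_trials = as.integer(cli_num(opts, "n-trials", 40)),
                             n_channels = as.integer(cli_num(opts, "channels", 8)))
      res <- pipeline_run(cfg, out, verbose = TRUE)
      message("accuracy: ", res$metrics$accuracy)
    },
    "train" = {
      feats <- read_feature_sets(opts$features)
      cfg <- spp_config(seed = seed,
                        epochs = as.integer(cli_num(opts, "epochs", 30)),
                        lr = cli_num(opts, "lr", 0.01))
      model <- spp_train(feats, cfg)
      path <- if (is.null(opts$out)) "model.json" else opts$out
      write_spp_model(model, path)
      message("trained on ", length(feats), " trials; wrote ", path)
    },
    "evaluate" = {
      feats <- read_feature_sets(opts$features)
      if (!is.null(opts$model)) {
        model <- read_spp_model(opts$model)
        pred <- predict(model, lapply(feats, `[[`, "map"))
        labs <- vapply(feats, function(f) as.character(f$label),
                       character(1))
        metrics <- list(mode = "holdout", accuracy =
                          mean(pred$class == labs))
      } else {
        cfg <- spp_config(seed = seed,
                          epochs = as.integer(cli_num(opts, "epochs", 30)))
        cv <- cross_validate(feats, cfg,
                             k = as.integer(cli_num(opts, "k", 5)),
                             seed = seed)
        metrics <- list(mode = sprintf("%d-fold",
                                       as.integer(cli_num(opts, "k", 5))),
                        fold_accuracy = cv$fold_accuracy,
                        accuracy = cv$mean_accuracy)
      }
      path <- if (is.null(opts$out)) "metrics.json" else opts$out
      jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
      message("accuracy: ", metrics$accuracy, "; wrote ", path)
    },
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
  invisible(0L)
}
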