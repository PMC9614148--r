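#' Full pipeline configuration
#'
#' Collects every tunable of the preprocess -> detect -> segment ->
#' features -> select -> train -> evaluate pipeline, with the package
#' defaults. The object round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param fs Sampling rate, Hz.
#' @param notch Notch settings: `f1`, `N`, `Q`.
#' @param lowpass Low-pass settings: `f2`, `N`.
#' @param detector Detector settings passed to [detect_peaks()].
#' @param window_beats,step_beats Segmentation window and step, beats.
#' @param entropy [entropy_config()] settings as a list.
#' @param rf Random-forest settings: `ntree`, `mtry` (`NULL` = auto), `k`
#'   selected features.
#' @param classifier `"dt"`, `"elm"` or `"bpnn"`.
#' @param classifier_args Extra arguments for the trainer.
#' @param n_rep,test_frac Evaluation protocol (default 100 repetitions,
#'   80/20).
#' @param synthetic Synthetic dataset settings for [make_dataset()]
#'   (`n_segments_per_class`, `n_beats`).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 250,
                            notch = list(f1 = 50, N = 2, Q = 64),
                            lowpass = list(f2 = 62.5, N = 2),
                            detector = list(refractory = 0.2,
                                            threshold_k = 1.0),
                            window_beats = 16, step_beats = 1,
                            entropy = list(),
                            rf = list(ntree = 100, mtry = NULL, k = 15),
                            classifier = c("dt", "elm", "bpnn"),
                            classifier_args = list(),
                            n_rep = 100, test_frac = 0.2,
                            synthetic = list(n_segments_per_class = 100,
                                             n_beats = 120),
                            seed = 1) {
  classifier <- match.arg(classifier)
  structure(
    list(fs = fs, notch = notch, lowpass = lowpass, detector = detector,
         window_beats = window_beats, step_beats = step_beats,
         entropy = entropy, rf = rf, classifier = classifier,
         classifier_args = classifier_args, n_rep = n_rep,
         test_frac = test_frac, synthetic = synthetic, seed = seed),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Extract labeled PRV segments from ABP records
#'
#' Applies preprocessing, peak detection, PRV computation and windowing to
#' each record; records where detection fails are skipped with a message.
#'
#' @param records A list of [abp_record()]s, optionally named (names become
#'   provenance); each may carry a `label` attribute.
#' @param config A [pipeline_config()].
#' @return A segment tibble as produced by [segment_prv()], rows bound over
#'   records.
#' @export
extract_segments <- function(records, config = pipeline_config()) {
  stopifnot(is.list(records))
  ids <- names(records) %||% sprintf("record-%03d", seq_along(records))
  segs <- purrr::imap(records, function(rec, i) {
    id <- if (is.character(i)) i else ids[[i]]
    notch <- design_notch(abp_fs(rec), config$notch$f1, config$notch$N,
                          config$notch$Q)
    lowp <- design_lowpass(abp_fs(rec), config$lowpass$f2, config$lowpass$N)
    filt <- preprocess(rec, notch, lowp)
    beats <- suppressWarnings(
      do.call(detect_peaks, c(list(filt), config$detector))
    )
    if (nrow(beats) < config$window_beats + 1L) {
      message("skipping record ", id, ": too few beats detected")
      return(NULL)
    }
    series <- compute_prv(beats, label = attr(rec, "label") %||% NA,
                          source = id)
    segment_prv(series, config$window_beats, config$step_beats)
  })
  segs <- purrr::compact(segs)
  if (!length(segs)) stop("peak detection failed on every record")
  dplyr::bind_rows(segs)
}

#' Run the complete detection pipeline
#'
#' Orchestrates the six stages end to end: obtain labeled segments (from
#' the synthetic generator by default, or from supplied records), extract
#' the 19-feature matrix, rank features with the random forest, select the
#' top `k`, and evaluate the chosen classifier under the repeated hold-out
#' protocol. A final model is also fitted on the full feature matrix. The
#' run is deterministic under the master seed for the `dt` and `elm`
#' classifiers.
#'
#' @param config A [pipeline_config()].
#' @param records Optional list of labeled [abp_record()]s; `NULL` uses the
#'   synthetic dataset defined by `config$synthetic`.
#' @return A list of class `pipeline_result`: `features`, `importance`,
#'   `selected`, `model`, `report`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg_ent <- do.call(entropy_config, config$entropy)
  features <- if (is.null(records)) {
    make_dataset(
      n_segments_per_class = config$synthetic$n_segments_per_class,
      n_beats = config$synthetic$n_beats, fs = config$fs,
      window_beats = config$window_beats, step_beats = config$step_beats,
      cfg = cfg_ent, seed = config$seed
    )
  } else {
    segs <- extract_segments(records, config)
    extract_features(segs, cfg_ent)
  }
  y <- features$label
  if (nlevels(droplevels(factor(y[!is.na(y)]))) < 2L) {
    stop("at least 2 classes are required after segmentation")
  }

  imp <- rf_importance(features, ntree = config$rf$ntree,
                       mtry = config$rf$mtry, seed = config$seed)
  imp <- select_features(imp, k = min(config$rf$k, nrow(imp)))
  keep <- selected_features(imp)
  slim <- features[c("label", keep)]

  trainer <- switch(config$classifier,
    dt = function(data, label_col = "label", seed = NULL) {
      do.call(train_dt, c(list(data, label_col = label_col, seed = seed),
                          config$classifier_args))
    },
    elm = function(data, label_col = "label", seed = NULL) {
      do.call(train_elm, c(list(data, label_col = label_col, seed = seed),
                           config$classifier_args))
    },
    bpnn = function(data, label_col = "label", seed = NULL) {
      do.call(train_bpnn, c(list(data, label_col = label_col, seed = seed),
                            config$classifier_args))
    }
  )
  report <- repeated_holdout(slim, trainer = trainer,
                             n_rep = config$n_rep,
                             test_frac = config$test_frac,
                             seed = config$seed)
  model <- trainer(slim, seed = config$seed)
  structure(
    list(features = features, importance = imp, selected = keep,
         model = model, report = report, config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d segments, %d/%d features selected, %s classifier>\n",
              nrow(x$features), length(x$selected),
              nrow(x$importance), toupper(x$config$classifier)))
  print(x$report)
  invisible(x)
}
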