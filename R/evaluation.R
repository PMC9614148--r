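#' Confusion matrix over a fixed label universe
#'
#' @param truth,estimate Vectors of true and predicted labels.
#' @param levels Label universe; defaults to the union of levels found in
#'   both vectors. Classes absent from the data keep zero rows/columns.
#' @return A square count matrix `Q` of class `confusion_matrix` with
#'   `Q[t, u]` = number of samples of true class `t` predicted as `u`.
#' @export
confusion <- function(truth, estimate, levels = NULL) {
  if (is.null(levels)) {
    levels <- union(
      if (is.factor(truth)) base::levels(truth) else unique(as.character(truth)),
      if (is.factor(estimate)) base::levels(estimate) else unique(as.character(estimate))
    )
  }
  truth <- factor(truth, levels = levels)
  estimate <- factor(estimate, levels = levels)
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` must have equal length")
  }
  cm <- unclass(table(truth = truth, estimate = estimate))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Overall classification accuracy, in percent
#'
#' The multi-class generalization `100 * trace(Q) / total`; for two classes
#' this reduces to the familiar `(TN + TP) / (TN + FP + TP + FN)` form.
#'
#' @param cm A [confusion()] matrix.
#' @return Accuracy in percent.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  100 * sum(diag(cm)) / sum(cm)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p1 - p2) / (1 - p2)` with observed
#' agreement `p1 = sum(Q_tt) / M` and chance agreement
#' `p2 = sum(Q_t+ Q_+t) / M^2`, where the sums run over classes and `M` is
#' the total sample count. A degenerate `p2 == 1` returns `NA`.
#'
#' @param cm A [confusion()] matrix.
#' @return Kappa in `[-1, 1]`, or `NA`.
#' @export
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  M <- sum(cm)
  p1 <- sum(diag(cm)) / M
  p2 <- sum(rowSums(cm) * colSums(cm)) / M^2
  if (abs(1 - p2) < .Machine$double.eps * 4) return(NA_real_)
  (p1 - p2) / (1 - p2)
}

#' Per-class kappa
#'
#' For class `i`, with proportions `P_tt = Q_tt / M`, `P_t+ = Q_t+ / M`
#' (row), `P_+t = Q_+t / M` (column):
#' `kappa(i) = (P_tt - P_t+ P_+t) / (P_+t - P_t+ P_+t)`. The denominator is
#' asymmetric in the row/column proportions; it is implemented exactly in
#' this form. A zero denominator (class never predicted, or never true and
#' never predicted) returns `NA`.
#'
#' @param cm A [confusion()] matrix.
#' @param i Class label or index; `NULL` for all classes.
#' @return Named numeric vector of per-class kappa values.
#' @export
per_class_kappa <- function(cm, i = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  M <- sum(cm)
  lev <- rownames(cm)
  k_one <- function(t) {
    ptt <- cm[t, t] / M
    pt_row <- sum(cm[t, ]) / M
    pt_col <- sum(cm[, t]) / M
    den <- pt_col - pt_row * pt_col
    if (abs(den) < .Machine$double.eps * 4) return(NA_real_)
    (ptt - pt_row * pt_col) / den
  }
  if (!is.null(i)) {
    t <- if (is.character(i)) match(i, lev) else as.integer(i)
    stopifnot(!is.na(t), t >= 1, t <= nrow(cm))
    out <- k_one(t)
    names(out) <- lev[t]
    return(out)
  }
  out <- vapply(seq_along(lev), k_one, numeric(1))
  names(out) <- lev
  out
}

#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(unclass(x))
  tibble::tibble(
    truth = rep(rownames(x), ncol(x)),
    estimate = rep(colnames(x), each = nrow(x)),
    n = as.vector(unclass(x))
  )
}

#' Repeated random hold-out evaluation
#'
#' The protocol used for all classifier comparisons: `n_rep` times, a
#' uniform random `1 - test_frac` / `test_frac` split of the segments
#' (default 80/20, unstratified), the trainer fitted on the training part
#' and evaluated on the held-out part. Accuracy, kappa and per-class kappa
#' are recorded per repetition and summarized as mean +/- sd.
#'
#' @param data Feature tibble including the label column.
#' @param trainer Function `(data, label_col, seed) -> prv_model`, e.g.
#'   [train_dt()].
#' @param label_col Name of the label column.
#' @param n_rep Number of repetitions (default 100).
#' @param test_frac Held-out fraction (default 0.2).
#' @param seed Master seed; per-repetition seeds derive from it.
#' @param stratify Stratify splits by class (off by default; the protocol
#'   splits uniformly at random).
#' @return An `eval_report`: list with `metrics` (one row per repetition:
#'   `rep`, `accuracy`, `kappa`, `kappa_<class>`), `summary` (mean, sd per
#'   metric), `n_rep`, `elapsed` (informational wall-clock seconds).
#' @export
repeated_holdout <- function(data, trainer = train_dt, label_col = "label",
                             n_rep = 100, test_frac = 0.2, seed = NULL,
                             stratify = FALSE) {
  stopifnot(n_rep >= 1, test_frac > 0, test_frac < 1)
  y_all <- data[[label_col]]
  if (!is.factor(y_all)) y_all <- factor(y_all)
  lev <- levels(droplevels(y_all))
  n <- nrow(data)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_rep)
  t0 <- proc.time()[["elapsed"]]
  rows <- purrr::map(seq_len(n_rep), function(r) {
    set.seed(rep_seeds[r])
    test_idx <- if (stratify) {
      unlist(lapply(split(seq_len(n), y_all), function(ix) {
        sample(ix, max(1L, round(test_frac * length(ix))))
      }), use.names = FALSE)
    } else {
      sample.int(n, max(1L, round(test_frac * n)))
    }
    train <- data[-test_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]
    model <- trainer(train, label_col = label_col, seed = rep_seeds[r])
    pred <- predict(model, test)
    cm <- confusion(test[[label_col]], pred, levels = lev)
    ck <- per_class_kappa(cm)
    out <- c(rep = r, accuracy = accuracy(cm), kappa = cohen_kappa(cm), ck)
    names(out) <- c("rep", "accuracy", "kappa", paste0("kappa_", lev))
    out
  })
  metrics <- tibble::as_tibble(do.call(rbind, rows))
  summary <- tibble::tibble(
    metric = setdiff(names(metrics), "rep"),
    mean = unname(vapply(metrics[-1], mean, numeric(1), na.rm = TRUE)),
    sd = unname(vapply(metrics[-1], stats::sd, numeric(1), na.rm = TRUE))
  )
  structure(
    list(metrics = metrics, summary = summary, n_rep = n_rep,
         test_frac = test_frac, levels = lev,
         elapsed = proc.time()[["elapsed"]] - t0),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Repeated hold-out evaluation (%d repetitions, %.0f/%.0f split)\n",
              x$n_rep, 100 * (1 - x$test_frac), 100 * x$test_frac))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    k <- if (s$metric[i] == "accuracy") 1 else 100 # kappas reported in %
    cat(sprintf("  %-14s %6.2f +/- %.2f %%\n", s$metric[i],
                s$mean[i] * k, s$sd[i] * k))
  }
  cat(sprintf("  time: %.2f s\n", x$elapsed))
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$summary

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  s <- x$summary
  acc <- s[s$metric == "accuracy", ]
  kap <- s[s$metric == "kappa", ]
  tibble::tibble(
    accuracy_mean = acc$mean, accuracy_sd = acc$sd,
    kappa_mean = kap$mean, kappa_sd = kap$sd,
    n_rep = x$n_rep, elapsed = x$elapsed
  )
}

#' JSON export of an evaluation report
#' @param x An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path) {
  stopifnot(inherits(x, "eval_report"))
  jsonlite::write_json(
    list(n_rep = x$n_rep, test_frac = x$test_frac,
         summary = x$summary, metrics = x$metrics),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
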