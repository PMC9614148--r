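#' Random-forest feature importance
#'
#' Fits a random forest and reports the two importance scores used for
#' dimensionality reduction: mean decrease in accuracy (out-of-bag
#' permutation importance, unscaled) and mean decrease in Gini (total
#' impurity decrease). Defaults: 100 trees and
#' `mtry = floor(sqrt(n_features))` (4 for the 19-feature battery).
#'
#' @param data Feature tibble; all numeric columns except `label_col` and
#'   provenance columns (`source`, `start_beat`, `class_id`) are used.
#' @param label_col Name of the class label column (factor).
#' @param ntree Number of trees.
#' @param mtry Predictors sampled per split; `NULL` for the default.
#' @param seed RNG seed for reproducibility.
#' @return A tibble of class `importance_tbl`: `feature`, `mda`, `gini`,
#'   `h` (selection flag, all 1 until [select_features()] is applied).
#' @export
rf_importance <- function(data, label_col = "label", ntree = 100,
                          mtry = NULL, seed = NULL) {
  stopifnot(ntree >= 1)
  xy <- split_xy(data, label_col)
  if (nlevels(droplevels(xy$y)) < 2L) {
    stop("at least two classes are required for importance ranking")
  }
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(xy$X))))
  stopifnot(mtry >= 1, mtry <= ncol(xy$X))
  X <- impute_apply(xy$X, impute_fit(xy$X))
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(
    x = X, y = droplevels(xy$y), ntree = ntree, mtry = mtry,
    importance = TRUE
  )
  imp <- randomForest::importance(rf, scale = FALSE)
  out <- tibble::tibble(
    feature = rownames(imp),
    mda = unname(imp[, "MeanDecreaseAccuracy"]),
    gini = unname(imp[, "MeanDecreaseGini"]),
    h = 1L
  )
  class(out) <- c("importance_tbl", class(out))
  out
}

#' Select the top-k features by combined importance rank
#'
#' Features are ranked separately by mean decrease in accuracy and by mean
#' decrease in Gini; the combined score is the mean of the two ranks, with
#' ties broken by the accuracy score. The selection flag `h` is set to 1
#' for kept features and 0 for rejected ones.
#'
#' @param tbl An `importance_tbl` from [rf_importance()].
#' @param k Number of features to keep (default 15).
#' @return The table with `h` updated, rows in original order.
#' @seealso [selected_features()]
#' @export
select_features <- function(tbl, k = 15) {
  stopifnot(inherits(tbl, "importance_tbl"), k >= 1, k <= nrow(tbl))
  rank_mda <- rank(-tbl$mda, ties.method = "average")
  rank_gini <- rank(-tbl$gini, ties.method = "average")
  combined <- (rank_mda + rank_gini) / 2
  keep <- order(combined, -tbl$mda)[seq_len(k)]
  tbl$h <- as.integer(seq_len(nrow(tbl)) %in% keep)
  tbl
}

#' Names of the selected features
#' @param tbl An `importance_tbl` after [select_features()].
#' @return Character vector of feature names with `h == 1`.
#' @export
selected_features <- function(tbl) tbl$feature[tbl$h == 1L]

split_xy <- function(data, label_col) {
  stopifnot(is.data.frame(data), label_col %in% names(data))
  y <- data[[label_col]]
  if (!is.factor(y)) y <- factor(y)
  drop <- c(label_col, "source", "start_beat", "class_id")
  X <- data[setdiff(names(data), drop)]
  X <- X[vapply(X, is.numeric, logical(1))]
  if (!ncol(X)) stop("no numeric feature columns found")
  list(X = as.data.frame(X), y = y)
}

# training-set median imputation for NA feature sentinels
impute_fit <- function(X) {
  med <- vapply(X, function(col) stats::median(col, na.rm = TRUE), numeric(1))
  med[!is.finite(med)] <- 0
  med
}

impute_apply <- function(X, medians) {
  n_na <- 0L
  for (j in names(medians)) {
    na <- is.na(X[[j]])
    if (any(na)) {
      X[[j]][na] <- medians[[j]]
      n_na <- n_na + sum(na)
    }
  }
  attr(X, "n_imputed") <- n_na
  X
}

new_prv_model <- function(kind, fit, feature_names, levels, medians, seed,
                          extra = list()) {
  structure(
    c(list(kind = kind, fit = fit, feature_names = feature_names,
           levels = levels, medians = medians, seed = seed), extra),
    class = c(paste0("prv_model_", kind), "prv_model")
  )
}

#' Train a decision-tree classifier
#'
#' A CART classification tree with the Gini split criterion, grown to
#' purity (no complexity pruning, minimum split 2, minimum leaf 1). These
#' defaults are exposed through `control`.
#'
#' @param data Feature tibble including the label column.
#' @param label_col Name of the label column.
#' @param seed RNG seed (tie-breaking in surrogate ordering).
#' @param control An [rpart::rpart.control()] list.
#' @return A `prv_model` object.
#' @export
train_dt <- function(data, label_col = "label", seed = NULL,
                     control = rpart::rpart.control(
                       cp = 0, minsplit = 2, minbucket = 1, xval = 0
                     )) {
  xy <- split_xy(data, label_col)
  med <- impute_fit(xy$X)
  X <- impute_apply(xy$X, med)
  if (!is.null(seed)) set.seed(seed)
  df <- cbind(.label = xy$y, X)
  fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                      parms = list(split = "gini"), control = control)
  new_prv_model("dt", fit, names(X), levels(xy$y), med, seed)
}

#' Train an extreme learning machine classifier
#'
#' A single-hidden-layer network with fixed random weights: input weights
#' `IW ~ U[-1, 1]` (`n_hidden x n_features`), hidden thresholds
#' `B ~ U[0, 1]`, sinusoidal hidden activations `H = sin(X IW' + B)`, and
#' output weights `LW = pinv(H) T` solved in closed form against the
#' one-hot label matrix `T` (minimum-norm least squares via the
#' Moore-Penrose pseudo-inverse). Prediction takes the class with the
#' maximum output. Features are standardized with training-set statistics
#' before entering the random projection.
#'
#' @inheritParams train_dt
#' @param n_hidden Hidden layer width (default 300).
#' @return A `prv_model` with elements `IW`, `B`, `LW` in `fit`.
#' @export
train_elm <- function(data, label_col = "label", n_hidden = 300,
                      seed = NULL) {
  if (n_hidden < 1) stop("`n_hidden` must be at least 1")
  xy <- split_xy(data, label_col)
  med <- impute_fit(xy$X)
  X <- as.matrix(impute_apply(xy$X, med))
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(Xs)
  IW <- matrix(stats::runif(n_hidden * p, -1, 1), n_hidden, p)
  B <- stats::runif(n_hidden, 0, 1)
  H <- sin(sweep(Xs %*% t(IW), 2, B, "+"))
  Tm <- one_hot(xy$y)
  LW <- pinv_solve(H, Tm)
  new_prv_model("elm", list(IW = IW, B = B, LW = LW), colnames(X),
                levels(xy$y), med, seed,
                extra = list(standardize = std, n_hidden = n_hidden))
}

#' Train a back-propagation neural network classifier
#'
#' A feed-forward network with two sigmoid hidden layers (default 15 and
#' 15 units), a softmax output over the class labels, and cross-entropy
#' loss, trained by BFGS quasi-Newton iterations with analytic gradients.
#' Training stops at `max_iter` iterations or when the loss falls below
#' `tol`; a model that reaches neither is returned with
#' `converged = FALSE` and a warning. Features are standardized with
#' training-set statistics.
#'
#' @inheritParams train_dt
#' @param hidden Integer vector of hidden layer widths.
#' @param max_iter Maximum training iterations (default 3000).
#' @param tol Target loss (default 0.001).
#' @param lr Learning rate for the plain gradient-descent fallback used
#'   when `method = "gd"` (default 0.1).
#' @param method `"bfgs"` (default) or `"gd"`.
#' @return A `prv_model`; `fit$weights` holds the flattened weight vector
#'   and `fit$converged` the convergence flag.
#' @export
train_bpnn <- function(data, label_col = "label", hidden = c(15, 15),
                       max_iter = 3000, tol = 0.001, lr = 0.1,
                       seed = NULL, method = c("bfgs", "gd")) {
  method <- match.arg(method)
  xy <- split_xy(data, label_col)
  med <- impute_fit(xy$X)
  X <- as.matrix(impute_apply(xy$X, med))
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  Tm <- one_hot(xy$y)
  sizes <- c(ncol(Xs), hidden, ncol(Tm))
  if (!is.null(seed)) set.seed(seed)
  w0 <- stats::runif(n_weights(sizes), -0.5, 0.5)

  loss_fn <- function(w) bpnn_loss_grad(w, sizes, Xs, Tm)$loss
  grad_fn <- function(w) bpnn_loss_grad(w, sizes, Xs, Tm)$grad

  converged <- FALSE
  w <- w0
  if (max_iter > 0) {
    if (method == "bfgs") {
      opt <- stats::optim(w0, loss_fn, grad_fn, method = "BFGS",
                          control = list(maxit = max_iter, reltol = 1e-10))
      w <- opt$par
      converged <- opt$value <= tol || opt$convergence == 0
    } else {
      for (i in seq_len(max_iter)) {
        g <- grad_fn(w)
        w <- w - lr * g
        if (loss_fn(w) <= tol) break
      }
      converged <- loss_fn(w) <= tol
    }
    if (!converged) warning("BPNN training did not reach the target loss")
  }
  new_prv_model("bpnn", list(weights = w, sizes = sizes,
                             converged = converged),
                colnames(X), levels(xy$y), med, seed,
                extra = list(standardize = std))
}

n_weights <- function(sizes) {
  sum((sizes[-length(sizes)] + 1) * sizes[-1])
}

unpack_weights <- function(w, sizes) {
  layers <- list()
  off <- 0L
  for (l in seq_len(length(sizes) - 1L)) {
    nin <- sizes[l] + 1L
    nout <- sizes[l + 1L]
    layers[[l]] <- matrix(w[off + seq_len(nin * nout)], nin, nout)
    off <- off + nin * nout
  }
  layers
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bpnn_forward <- function(w, sizes, X) {
  layers <- unpack_weights(w, sizes)
  acts <- list(X)
  a <- X
  nl <- length(layers)
  for (l in seq_len(nl)) {
    z <- cbind(1, a) %*% layers[[l]]
    a <- if (l < nl) sigmoid(z) else {
      zz <- z - apply(z, 1, max)
      ez <- exp(zz)
      ez / rowSums(ez)
    }
    acts[[l + 1L]] <- a
  }
  list(layers = layers, acts = acts)
}

bpnn_loss_grad <- function(w, sizes, X, Tm) {
  fw <- bpnn_forward(w, sizes, X)
  acts <- fw$acts
  layers <- fw$layers
  n <- nrow(X)
  nl <- length(layers)
  out <- acts[[nl + 1L]]
  loss <- -sum(Tm * log(pmax(out, 1e-12))) / n
  grads <- vector("list", nl)
  delta <- (out - Tm) / n # softmax + cross-entropy
  for (l in nl:1) {
    grads[[l]] <- t(cbind(1, acts[[l]])) %*% delta
    if (l > 1L) {
      a <- acts[[l]]
      delta <- (delta %*% t(layers[[l]][-1, , drop = FALSE])) * a * (1 - a)
    }
  }
  list(loss = loss, grad = unlist(lapply(grads, as.vector)))
}

# minimum-norm least squares via the Moore-Penrose pseudo-inverse,
# truncating at the standard max(dim) * eps * sigma_max tolerance
pinv_solve <- function(H, Tm) {
  sv <- svd(H)
  tol <- max(dim(H)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% Tm) / sv$d[pos])
}

one_hot <- function(y) {
  lev <- levels(y)
  Tm <- matrix(0, length(y), length(lev), dimnames = list(NULL, lev))
  Tm[cbind(seq_along(y), as.integer(y))] <- 1
  Tm
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, std) {
  scale(X, center = std$center, scale = std$scale)[, , drop = FALSE]
}

#' Predict class labels from a trained model
#'
#' New data are aligned to the training feature schema by name (column
#' order is irrelevant); unknown or missing features raise an error.
#' Missing values are imputed with the training-set medians stored in the
#' model.
#'
#' @param object A `prv_model`.
#' @param newdata Data frame containing the training feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.prv_model <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing)) {
    stop("newdata is missing feature(s): ", paste(missing, collapse = ", "))
  }
  X <- as.data.frame(newdata[object$feature_names])
  bad <- !vapply(X, is.numeric, logical(1))
  if (any(bad)) stop("non-numeric feature column(s) in newdata")
  X <- impute_apply(X, object$medians)
  scores <- switch(object$kind,
    dt = {
      pr <- predict(object$fit, newdata = X, type = "class")
      return(factor(as.character(pr), levels = object$levels))
    },
    elm = {
      Xs <- standardize_apply(as.matrix(X), object$standardize)
      H <- sin(sweep(Xs %*% t(object$fit$IW), 2, object$fit$B, "+"))
      H %*% object$fit$LW
    },
    bpnn = {
      Xs <- standardize_apply(as.matrix(X), object$standardize)
      fw <- bpnn_forward(object$fit$weights, object$fit$sizes, Xs)
      fw$acts[[length(fw$acts)]]
    },
    stop("unknown model kind")
  )
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.prv_model <- function(x, ...) {
  cat(sprintf("<prv_model: %s, %d features, classes: %s>\n",
              toupper(x$kind), length(x$feature_names),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' @method glance prv_model
#' @export
glance.prv_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_features = length(x$feature_names),
    n_classes = length(x$levels),
    seed = x$seed %||% NA_integer_,
    converged = if (x$kind == "bpnn") x$fit$converged else TRUE
  )
}

#' Save / load a trained model
#'
#' Serializes the model (kind, fitted parameters, feature schema, seed) to
#' a versioned RDS file.
#'
#' @param model A `prv_model`.
#' @param path File path.
#' @return `path` (write) or the model (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "prv_model"))
  saveRDS(list(format = "prvdetect-model-1", model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "prvdetect-model-1")) {
    stop("not a recognized prvdetect model file")
  }
  obj$model
}
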