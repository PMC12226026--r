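# --- regression-tree learner -------------------------------------------------
# Exact greedy least-squares trees: at each node every feature is scanned at
# every distinct-value boundary and the split with the largest sum-of-squares
# reduction wins (ties -> lowest feature index, then smallest threshold).
# Thresholds are midpoints between adjacent observed values. Fully
# deterministic: no subsampling, no randomness.

best_split <- function(xcol, y) {
  n <- length(y)
  ord <- order(xcol, method = "radix")
  xs <- xcol[ord]
  ys <- y[ord]
  cs <- cumsum(ys)
  cs2 <- cumsum(ys^2)
  tot <- cs[n]
  tot2 <- cs2[n]
  i <- seq_len(n - 1)
  valid <- xs[i] < xs[i + 1]
  if (!any(valid)) {
    return(NULL)
  }
  sse_l <- cs2[i] - cs[i]^2 / i
  sse_r <- (tot2 - cs2[i]) - (tot - cs[i])^2 / (n - i)
  sse <- ifelse(valid, sse_l + sse_r, Inf)
  k <- which.min(sse)
  list(
    threshold = (xs[k] + xs[k + 1]) / 2,
    sse = sse[k],
    improvement = (tot2 - tot^2 / n) - sse[k]
  )
}

fit_tree <- function(X, y, max_depth = 3, min_split = 2) {
  nodes <- list()
  pred <- numeric(nrow(X))
  grow <- function(rows, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(node = id) # reserve slot; overwritten below
    leaf <- function() {
      nodes[[id]] <<- list(
        node = id, depth = depth, is_leaf = TRUE, feature = NA_character_,
        threshold = NA_real_, left = NA_integer_, right = NA_integer_,
        value = mean(y[rows]), n = length(rows), improvement = 0
      )
      pred[rows] <<- mean(y[rows])
      id
    }
    if (depth >= max_depth || length(rows) < min_split) {
      return(leaf())
    }
    best <- NULL
    best_j <- 0L
    for (j in seq_len(ncol(X))) {
      sp <- best_split(X[rows, j], y[rows])
      if (is.null(sp)) next
      better <- is.null(best) || sp$sse < best$sse - 1e-12
      if (better && sp$improvement > 1e-12) {
        best <- sp
        best_j <- j
      }
    }
    if (is.null(best)) {
      return(leaf())
    }
    go_l <- rows[X[rows, best_j] <= best$threshold]
    go_r <- rows[X[rows, best_j] > best$threshold]
    l <- grow(go_l, depth + 1L)
    r <- grow(go_r, depth + 1L)
    nodes[[id]] <<- list(
      node = id, depth = depth, is_leaf = FALSE,
      feature = colnames(X)[best_j], threshold = best$threshold,
      left = l, right = r, value = NA_real_, n = length(rows),
      improvement = best$improvement
    )
    id
  }
  grow(seq_len(nrow(X)), 0L)
  list(nodes = dplyr::bind_rows(nodes), pred = pred)
}

predict_tree <- function(nodes, X) {
  ord <- order(nodes$node)
  is_leaf <- nodes$is_leaf[ord]
  fcol <- match(nodes$feature[ord], colnames(X))
  thr <- nodes$threshold[ord]
  left <- nodes$left[ord]
  right <- nodes$right[ord]
  val <- nodes$value[ord]
  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    id <- 1L
    while (!is_leaf[id]) {
      id <- if (X[i, fcol[id]] <= thr[id]) left[id] else right[id]
    }
    out[i] <- val[id]
  }
  out
}

as_feature_matrix <- function(data, feature_names) {
  miss <- setdiff(feature_names, colnames(data))
  if (length(miss) > 0) {
    abort(sprintf(
      "feature contract mismatch; model expects missing column(s): %s",
      paste(head(miss, 5), collapse = ", ")
    ))
  }
  X <- as.matrix(as.data.frame(data)[, feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) abort("features contain missing values")
  X
}

# --- gradient boosting -------------------------------------------------------

#' Fit a gradient-boosted regression-tree ensemble
#'
#' Least-squares gradient boosting: starting from the label mean, each
#' shallow tree is fit to the residuals of the current ensemble and added
#' with a shrinkage factor (the learning rate). The splits are exact
#' greedy and the fit uses no subsampling, so refitting with the same data
#' and settings is bit-for-bit reproducible. Intended for *small*
#' interpretable ensembles (the default is 13 trees of depth 3), whose
#' full ruleset can be exported and read.
#'
#' @param data data frame: feature columns plus a label column; a
#'   `complex_id` column, if present, is ignored as a feature.
#' @param label name of the label column (binding free energy in kcal/mol
#'   for affinity models; 0/1 for binder/decoy scores).
#' @param features feature column names, default every numeric column
#'   except the label and `complex_id`.
#' @param n_trees,max_depth,learning_rate boosting hyperparameters.
#'   Defaults (13 trees, depth 3, rate 0.1) mirror the reference
#'   interpretable affinity model; depth and rate are recorded in the
#'   model as `paper_verified = FALSE` since the reference publication
#'   pins only the tree count.
#' @param task `"affinity"` or `"binder_score"`; recorded in the model and
#'   checked by [predict_affinity()] / [score_binder()].
#' @param seed accepted for interface symmetry; the fit itself is
#'   deterministic and uses no randomness.
#' @return object of class `gbr_model`: trees, learning rate, base
#'   prediction, feature names, task, hyperparameters, training RMSE.
#' @examples
#' tab <- make_training_table(200, seed = 1)
#' m <- fit_gbr(tab, n_trees = 20, learning_rate = 0.5)
#' glance(m)
#' @export
fit_gbr <- function(data, label = "label", features = NULL, n_trees = 13,
                    max_depth = 3, learning_rate = 0.1,
                    task = c("affinity", "binder_score"), seed = 1) {
  task <- match.arg(task)
  stopifnot(n_trees >= 0, max_depth >= 1, learning_rate > 0)
  if (!(label %in% names(data))) abort(sprintf("no label column '%s'", label))
  if (nrow(data) < 2) abort("need at least 2 training rows")
  if (is.null(features)) {
    features <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(label, "complex_id")
    )
  }
  y <- data[[label]]
  if (!all(is.finite(y))) abort("labels must be finite")
  X <- as_feature_matrix(data, features)

  base <- mean(y)
  trees <- list()
  fit_vals <- rep(base, length(y))
  if (sd(y) == 0) {
    warn("labels are constant; returning a base-prediction-only model")
  } else {
    for (t in seq_len(n_trees)) {
      tr <- fit_tree(X, y - fit_vals, max_depth = max_depth)
      trees[[t]] <- tr$nodes
      fit_vals <- fit_vals + learning_rate * tr$pred
    }
  }
  structure(
    list(
      trees = trees, learning_rate = learning_rate, base_prediction = base,
      feature_names = features, task = task,
      params = list(
        n_trees = length(trees), max_depth = max_depth,
        learning_rate = learning_rate, seed = seed, paper_verified = FALSE
      ),
      training_rmse = sqrt(mean((y - fit_vals)^2)), n_train = length(y)
    ),
    class = "gbr_model"
  )
}

#' Predict with a boosted ensemble
#'
#' @param object `gbr_model`.
#' @param newdata data frame containing the model's feature columns.
#' @param ... unused.
#' @return numeric vector: base + learning_rate * sum of tree outputs.
#' @export
predict.gbr_model <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$feature_names)
  out <- rep(object$base_prediction, nrow(X))
  for (tr in object$trees) out <- out + object$learning_rate * predict_tree(tr, X)
  out
}

#' @export
print.gbr_model <- function(x, ...) {
  cat(sprintf(
    "<gbr_model: %s> %d trees (depth <= %d), learning rate %g, base %.4f\n",
    x$task, length(x$trees), x$params$max_depth, x$learning_rate,
    x$base_prediction
  ))
  cat(sprintf(
    "  %d features, trained on %d rows (training RMSE %.4f)\n",
    length(x$feature_names), x$n_train, x$training_rmse
  ))
  invisible(x)
}

#' Mean-decrease-in-impurity feature importance
#'
#' Sums, per feature, the squared-error reduction achieved by every split
#' on that feature across all trees (weighted implicitly by node size via
#' the raw sum-of-squares), normalized to sum to one.
#'
#' @param model `gbr_model`.
#' @return tibble with columns `feature`, `importance`, sorted descending;
#'   features never split on get importance 0.
#' @export
gbr_importance <- function(model) {
  imp <- setNames(rep(0, length(model$feature_names)), model$feature_names)
  for (tr in model$trees) {
    sp <- tr[!tr$is_leaf, , drop = FALSE]
    for (k in seq_len(nrow(sp))) imp[sp$feature[k]] <- imp[sp$feature[k]] + sp$improvement[k]
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- tibble(feature = names(imp), importance = unname(imp))
  out[order(-out$importance, out$feature), ]
}

#' @rdname gbr_importance
#' @param x `gbr_model`.
#' @param ... unused.
#' @return `tidy()` returns one row per tree node with tree index, node
#'   id, depth, split feature/threshold or leaf value; `glance()` a
#'   one-row model summary.
#' @export
tidy.gbr_model <- function(x, ...) {
  purrr::imap_dfr(x$trees, function(tr, i) dplyr::mutate(tr, tree = i, .before = 1))
}

#' @rdname gbr_importance
#' @export
glance.gbr_model <- function(x, ...) {
  tibble(
    task = x$task, n_trees = length(x$trees),
    max_depth = x$params$max_depth, learning_rate = x$learning_rate,
    base_prediction = x$base_prediction, n_features = length(x$feature_names),
    n_train = x$n_train, training_rmse = x$training_rmse,
    n_leaves = sum(tidy(x)$is_leaf)
  )
}

# --- human-readable export / import -----------------------------------------

#' Export a boosted ensemble as a human-readable JSON ruleset
#'
#' Interpretability is the point of a 13-tree model, so serialization is
#' plain JSON: every tree's split features (by name), thresholds, and leaf
#' values, plus the learning rate and base prediction. Re-importing
#' reproduces identical predictions.
#'
#' @param model `gbr_model`.
#' @param path optional file to write; with `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
export_trees <- function(model, path = NULL) {
  obj <- list(
    format = "topobind-gbr-1",
    task = model$task,
    base_prediction = model$base_prediction,
    learning_rate = model$learning_rate,
    feature_names = model$feature_names,
    params = model$params,
    trees = purrr::map(model$trees, function(tr) as.data.frame(tr))
  )
  # I(17) significant digits: doubles survive the decimal round trip exactly
  json <- jsonlite::toJSON(obj,
    auto_unbox = TRUE, digits = I(17), pretty = TRUE,
    na = "null"
  )
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' @rdname export_trees
#' @param json JSON string or path to a file written by [export_trees()].
#' @return `import_trees()` returns the reconstructed `gbr_model`.
#' @export
import_trees <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json), collapse = "\n")
  }
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  if (!identical(obj$format, "topobind-gbr-1")) abort("unrecognized model format")
  trees <- purrr::map(obj$trees, function(tr) {
    tr <- as_tibble(tr)
    tr$node <- as.integer(tr$node)
    tr$left <- as.integer(tr$left)
    tr$right <- as.integer(tr$right)
    tr$is_leaf <- as.logical(tr$is_leaf)
    tr
  })
  structure(
    list(
      trees = trees, learning_rate = obj$learning_rate,
      base_prediction = obj$base_prediction,
      feature_names = obj$feature_names, task = obj$task,
      params = obj$params,
      training_rmse = NA_real_, n_train = NA_integer_
    ),
    class = "gbr_model"
  )
}
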