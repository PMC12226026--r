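#' Convert a dissociation constant to binding free energy
#'
#' `dG = R * T * ln(Kd)` with the gas constant
#' R = 1.98720425e-3 kcal/(mol K). A sub-molar Kd gives a negative free
#' energy; a micromolar binder at 298.15 K comes out near -8.2 kcal/mol.
#'
#' @param kd dissociation constant, molar (> 0); vectorized.
#' @param temperature Kelvin (> 0).
#' @return binding free energy, kcal/mol.
#' @examples
#' kd_to_dg(1e-6) # about -8.18
#' @export
kd_to_dg <- function(kd, temperature = 298.15) {
  if (any(!is.finite(kd)) || any(kd <= 0)) abort("kd must be positive and finite")
  if (any(temperature <= 0)) abort("temperature must be positive")
  1.98720425e-3 * temperature * log(kd)
}

fingerprint_to_row <- function(fp) {
  if (is.data.frame(fp) && all(c("feature", "value") %in% names(fp))) {
    return(as_tibble(setNames(as.list(fp$value), fp$feature)))
  }
  if (is.data.frame(fp) && all(c("feature", "density") %in% names(fp))) {
    return(as_tibble(setNames(as.list(fp$density), fp$feature)))
  }
  if (is.numeric(fp) && !is.null(names(fp))) {
    return(as_tibble(as.list(fp)))
  }
  as_tibble(fp)
}

#' Predict binding free energy from a persistence fingerprint
#'
#' @param model `gbr_model` with task `"affinity"`.
#' @param fp fingerprint tibble from [compute_fingerprint()] (long form
#'   with `feature`/`value`), a named numeric vector, or a wide data frame
#'   whose columns cover the model's features.
#' @return predicted binding free energy, kcal/mol. Note an ensemble of
#'   regression trees can only emit a finite set of values — the leaf
#'   combinations of its trees.
#' @export
predict_affinity <- function(model, fp) {
  if (!inherits(model, "gbr_model") || model$task != "affinity") {
    abort("`model` must be a gbr_model with task 'affinity'")
  }
  predict(model, fingerprint_to_row(fp))
}

#' Score a complex as binder vs decoy from its IPC stack
#'
#' Applies a binder/decoy ensemble to the flattened discretized-IPC stack
#' of a (radius-truncated) complex. Higher scores mean more binder-like;
#' thresholding and ROC construction are the caller's concern.
#'
#' @param model `gbr_model` with task `"binder_score"`.
#' @param stack long tibble from [ipc_stack()] (typically of
#'   `truncate_complex(atoms, 15)`), or an already-flattened wide row.
#' @return numeric score.
#' @export
score_binder <- function(model, stack) {
  if (!inherits(model, "gbr_model") || model$task != "binder_score") {
    abort("`model` must be a gbr_model with task 'binder_score'")
  }
  predict(model, fingerprint_to_row(stack))
}

#' Area under the ROC curve for binder scores
#'
#' @param labels 0/1 vector (1 = binder).
#' @param scores numeric scores, higher = more binder-like.
#' @return AUC in [0, 1] (direction fixed: score of a random binder
#'   exceeding a random decoy counts toward 1).
#' @export
roc_auc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
}

#' Two-stage feature selection: impurity ranking then iterative ablation
#'
#' Stage 1 fits a boosted ensemble on all columns and keeps the `top_k`
#' features by mean decrease in impurity. Stage 2 repeatedly refits on a
#' fixed train/validation split, dropping the currently least-important
#' surviving feature, until the validation RMSE degrades by more than
#' `tol` relative to the best seen; the surviving set (before the
#' degrading drop) is returned in importance order.
#'
#' @param X data frame or matrix of named feature columns.
#' @param y numeric response.
#' @param top_k stage-1 cut (default 77); skipped when there are fewer
#'   columns.
#' @param n_trees,max_depth,learning_rate hyperparameters for the
#'   selection fits. Selection needs converged fits, so the defaults here
#'   (50 trees, rate 0.3) are deliberately hotter than the final model's.
#' @param val_fraction validation share of the split (default 0.1, i.e. a
#'   90:10 split).
#' @param tol relative validation-RMSE degradation that stops the
#'   ablation (default 0.01 = 1%).
#' @param seed seed for the train/validation split.
#' @return character vector of surviving feature names, importance order;
#'   attribute `"trace"` holds a tibble of the ablation path (step,
#'   number of features, validation RMSE).
#' @export
select_features <- function(X, y, top_k = 77, n_trees = 50, max_depth = 3,
                            learning_rate = 0.3, val_fraction = 0.1,
                            tol = 0.01, seed = 1) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y), !is.null(colnames(X)))
  fit_on <- function(dat, feats) {
    fit_gbr(dat,
      label = ".y", features = feats, n_trees = n_trees,
      max_depth = max_depth, learning_rate = learning_rate, seed = seed
    )
  }
  dat <- dplyr::bind_cols(as_tibble(X), tibble(.y = y))

  feats <- colnames(X)
  if (length(feats) > top_k) {
    m0 <- fit_on(dat, feats)
    imp <- gbr_importance(m0)
    feats <- imp$feature[seq_len(top_k)]
  }

  set.seed(seed)
  n <- nrow(dat)
  val_idx <- sort(sample.int(n, size = max(1, round(val_fraction * n))))
  train <- dat[-val_idx, , drop = FALSE]
  val <- dat[val_idx, , drop = FALSE]
  val_rmse <- function(m) sqrt(mean((val$.y - predict(m, val))^2))

  trace <- list()
  best_rmse <- Inf
  current <- feats
  repeat {
    m <- fit_on(train, current)
    rmse <- val_rmse(m)
    trace[[length(trace) + 1]] <- tibble(
      step = length(trace) + 1L, n_features = length(current), rmse = rmse
    )
    if (rmse > best_rmse * (1 + tol)) {
      # this drop hurt: roll back to the previous (accepted) set
      current <- previous
      break
    }
    best_rmse <- min(best_rmse, rmse)
    imp <- gbr_importance(m)
    imp <- imp[imp$feature %in% current, , drop = FALSE]
    ranked <- imp$feature
    previous <- ranked
    if (length(current) <= 1) {
      current <- ranked
      break
    }
    current <- ranked[-length(ranked)] # drop the least important
  }
  structure(current, trace = dplyr::bind_rows(trace))
}
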