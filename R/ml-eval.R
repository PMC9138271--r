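#' Window-level MI feature table for stage classification
#'
#' One row per analysis window: the modulation index of each band pair on
#' each EEG channel (four features with the default pairs), labelled with the
#' sleep stage of the window's epoch. Windows spanning a stage change are
#' dropped, mirroring [stage_mi()].
#'
#' @param decomposition A `band_decomposition`.
#' @param hyp A `hypnogram`.
#' @param pairs Band pairs as in [default_pairs()].
#' @param window_s,overlap,n_bins Windowing/binning parameters.
#' @return Data frame with a `stage` column and one MI column per
#'   pair x channel (`mi.<pair>.<channel>`).
#' @export
window_feature_table <- function(decomposition, hyp, pairs = default_pairs(),
                                 window_s = 5, overlap = 0.5, n_bins = 20) {
  fs <- attr(decomposition, "fs")
  feat <- NULL
  for (pname in names(pairs)) {
    pr <- pairs[[pname]]
    for (ch in names(decomposition)) {
      bands <- decomposition[[ch]]
      w <- windowed_mi(bands[[pr[1]]], bands[[pr[2]]], fs = fs,
                       window_s = window_s, overlap = overlap, n_bins = n_bins)
      col <- paste("mi", pname, ch, sep = ".")
      if (is.null(feat)) {
        feat <- data.frame(start = w$start, end = w$end)
      }
      feat[[col]] <- w$mi
    }
  }
  e0 <- floor(feat$start / hyp$epoch_s)
  e1 <- floor((feat$end - 1 / fs) / hyp$epoch_s)
  keep <- e0 < length(hyp$stages) & e1 < length(hyp$stages)
  feat <- feat[keep, , drop = FALSE]; e0 <- e0[keep]; e1 <- e1[keep]
  same <- vapply(seq_along(e0), function(i) {
    length(unique(hyp$stages[(e0[i]:e1[i]) + 1L])) == 1L
  }, logical(1))
  feat <- feat[same, , drop = FALSE]
  feat$stage <- hyp$stages[e0[same] + 1L]
  feat
}

#' Subject-level MI feature table for clinical prediction
#'
#' One row per subject: per-stage, per-pair aggregate MI (from [stage_mi()])
#' joined to the clinical metadata columns.
#'
#' @param stage_mi_list Named list (by subject id) of [stage_mi()] results.
#' @param subjects Metadata data frame with an `id` column.
#' @return Data frame with `mi.<pair>.<stage>` feature columns plus metadata.
#' @export
subject_feature_table <- function(stage_mi_list, subjects) {
  rows <- lapply(names(stage_mi_list), function(id) {
    sm <- stage_mi_list[[id]]
    vals <- stats::setNames(sm$mi, paste("mi", sm$pair, sm$stage, sep = "."))
    as.data.frame(c(list(id = id), as.list(vals)), stringsAsFactors = FALSE,
                  check.names = FALSE)
  })
  feat <- do.call(rbind, rows)
  merge(subjects, feat, by = "id", sort = FALSE)
}

stratified_split <- function(labels, train_frac, max_redraw = 20) {
  n <- length(labels)
  for (attempt in seq_len(max_redraw)) {
    tr <- unlist(lapply(split(seq_len(n), labels), function(idx) {
      k <- max(1L, round(train_frac * length(idx)))
      sample(idx, k)
    }), use.names = FALSE)
    te <- setdiff(seq_len(n), tr)
    if (length(te) > 0 &&
        all(unique(labels) %in% labels[tr])) {
      return(list(train = sort(tr), test = sort(te), redraws = attempt - 1L))
    }
  }
  stop("could not draw a split containing every class in training")
}

svm_grid_search <- function(x_tr, y_tr, degrees, costs, gamma, type,
                            epsilon = 0.1) {
  # inner stratified (or plain, for regression) 75/25 holdout on the training
  # portion only; all model selection happens inside the training data
  if (is.factor(y_tr)) {
    sp <- stratified_split(y_tr, 0.75)
  } else {
    k <- max(2L, round(0.75 * length(y_tr)))
    tr <- sample(seq_along(y_tr), k)
    sp <- list(train = sort(tr), test = sort(setdiff(seq_along(y_tr), tr)))
  }
  best <- NULL; best_score <- -Inf
  for (d in degrees) {
    for (co in costs) {
      fit <- e1071::svm(x_tr[sp$train, , drop = FALSE], y_tr[sp$train],
                        type = type, kernel = "polynomial", degree = d,
                        gamma = gamma, coef0 = 1, cost = co, scale = TRUE,
                        epsilon = epsilon)
      pred <- stats::predict(fit, x_tr[sp$test, , drop = FALSE])
      score <- if (is.factor(y_tr)) {
        mean(pred == y_tr[sp$test])
      } else {
        -stats::median(abs(pred - y_tr[sp$test]))
      }
      if (score > best_score) {
        best_score <- score
        best <- c(degree = d, cost = co)
      }
    }
  }
  best
}

#' SVM sleep-stage classification with repeated 75/25 evaluation
#'
#' Polynomial-kernel support-vector classification of stage labels from MI
#' features. The protocol is 10 repeated stratified random splits with 75% of
#' rows for training and 25% for testing; on each split the polynomial degree
#' and cost are selected by grid search over the integers 1-10 using an inner
#' holdout of the training portion only (kernel coefficient fixed at 0.25),
#' the model is refit on the full training portion and scored on the held-out
#' test rows.
#'
#' @param features Data frame of feature columns plus the label column.
#' @param label_col Name of the class label column.
#' @param feature_cols Feature column names (default: all `mi.` columns).
#' @param n_splits Number of repeated splits.
#' @param train_frac Training fraction.
#' @param degrees,costs Grid-search ranges.
#' @param gamma Polynomial kernel coefficient.
#' @param seed Integer seed (controls split draws and grid holdouts).
#' @return List with `accuracy` (per-split %), `mean_accuracy`, `confusion`
#'   (pooled counts, truth in rows), `params` (selected degree/cost per
#'   split), `redraws`.
#' @export
classify_stages <- function(features, label_col = "stage",
                            feature_cols = grep("^mi\\.", names(features),
                                                value = TRUE),
                            n_splits = 10, train_frac = 0.75,
                            degrees = 1:10, costs = 1:10, gamma = 0.25,
                            seed = 1) {
  y <- factor(features[[label_col]])
  if (nlevels(y) < 2) stop("need at least two classes")
  if (nrow(features) < 40) stop("need at least 40 rows")
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  if (anyNA(x)) stop("missing values in feature columns")
  acc <- numeric(n_splits)
  params <- matrix(NA_real_, n_splits, 2,
                   dimnames = list(NULL, c("degree", "cost")))
  conf <- matrix(0L, nlevels(y), nlevels(y),
                 dimnames = list(truth = levels(y), predicted = levels(y)))
  redraws <- 0L
  for (s in seq_len(n_splits)) {
    set.seed(seed + s)
    sp <- stratified_split(y, train_frac)
    redraws <- redraws + sp$redraws
    best <- svm_grid_search(x[sp$train, , drop = FALSE], y[sp$train],
                            degrees, costs, gamma, "C-classification")
    fit <- e1071::svm(x[sp$train, , drop = FALSE], y[sp$train],
                      type = "C-classification", kernel = "polynomial",
                      degree = best["degree"], gamma = gamma, coef0 = 1,
                      cost = best["cost"], scale = TRUE)
    pred <- stats::predict(fit, x[sp$test, , drop = FALSE])
    acc[s] <- 100 * mean(pred == y[sp$test])
    conf <- conf + table(truth = y[sp$test], predicted = pred)
    params[s, ] <- best
  }
  list(accuracy = acc, mean_accuracy = mean(acc), confusion = conf,
       params = as.data.frame(params), redraws = redraws)
}

#' SVR prediction of a clinical score from MI features
#'
#' Support-vector regression (polynomial kernel, same grid-search protocol as
#' [classify_stages()]) of a continuous target such as RDI or ESS. Per test
#' split the prediction accuracy is reported. The default definition is a
#' median-error skill score against the naive predictor (the training
#' median): `100 * (1 - median(|yhat - y|) / median(|median(y_train) - y|))`,
#' so an uninformative model scores near 0 and a perfect one 100.
#' Alternatives: `"range_mae"` (`100 * (1 - median(|yhat - y| /
#' range(y_train)))`), `"r2"` (100 x coefficient of determination, floored at
#' 0) and `"tolerance"` (percent of predictions within `tol_frac` of the
#' training range).
#'
#' @param features Data frame with feature and target columns.
#' @param target Name of the continuous target column.
#' @param feature_cols Feature column names (default: all `mi.` columns).
#' @param method Accuracy definition (see above).
#' @param tol_frac Tolerance fraction for `method = "tolerance"`.
#' @param epsilon SVR epsilon-tube width (on the internally scaled target).
#' @param n_splits,train_frac,degrees,costs,gamma,seed As in
#'   [classify_stages()].
#' @return List with `accuracy` (per-split %), `mean_accuracy`, `params`.
#' @export
predict_clinical <- function(features, target,
                             feature_cols = grep("^mi\\.", names(features),
                                                 value = TRUE),
                             method = c("median_skill", "range_mae", "r2",
                                        "tolerance"),
                             tol_frac = 0.25, epsilon = 0.1, n_splits = 10,
                             train_frac = 0.75, degrees = 1:10, costs = 1:10,
                             gamma = 0.25, seed = 1) {
  method <- match.arg(method)
  y <- features[[target]]
  if (!is.numeric(y)) stop("target must be continuous")
  if (stats::var(y) == 0) stop("target has zero variance: accuracy undefined")
  if (nrow(features) < 40) stop("need at least 40 subjects")
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  if (anyNA(x)) stop("missing values in feature columns")
  acc <- numeric(n_splits)
  params <- matrix(NA_real_, n_splits, 2,
                   dimnames = list(NULL, c("degree", "cost")))
  for (s in seq_len(n_splits)) {
    set.seed(seed + s)
    k <- max(2L, round(train_frac * length(y)))
    tr <- sort(sample(seq_along(y), k))
    te <- setdiff(seq_along(y), tr)
    best <- svm_grid_search(x[tr, , drop = FALSE], y[tr],
                            degrees, costs, gamma, "eps-regression", epsilon)
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "eps-regression",
                      kernel = "polynomial", degree = best["degree"],
                      gamma = gamma, coef0 = 1, cost = best["cost"],
                      scale = TRUE, epsilon = epsilon)
    pred <- stats::predict(fit, x[te, , drop = FALSE])
    rng <- diff(range(y[tr]))
    acc[s] <- switch(method,
      median_skill = {
        naive <- stats::median(abs(stats::median(y[tr]) - y[te]))
        100 * (1 - stats::median(abs(pred - y[te])) / naive)
      },
      range_mae = 100 * (1 - stats::median(abs(pred - y[te]) / rng)),
      r2 = {
        ss_res <- sum((y[te] - pred)^2)
        ss_tot <- sum((y[te] - mean(y[te]))^2)
        100 * max(0, 1 - ss_res / ss_tot)
      },
      tolerance = 100 * mean(abs(pred - y[te]) <= tol_frac * rng))
    params[s, ] <- best
  }
  list(accuracy = acc, mean_accuracy = mean(acc),
       params = as.data.frame(params))
}

#' Highest-density interval of a sample
#'
#' Narrowest interval containing at least `mass` of the empirical
#' distribution, found by scanning windows of fixed rank width over the
#' sorted sample.
#'
#' @param x Numeric sample.
#' @param mass Probability mass, in (0, 1).
#' @return Named vector `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0,1)")
  x <- sort(unname(x[is.finite(x)]))
  n <- length(x)
  if (n < 2) return(c(lower = x[1], upper = x[1]))
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Empirical HDI of the MI distribution and the decision threshold
#'
#' Computes the highest-density interval containing `hdi_mass` of all
#' observed modulation indices (all stages, both groups pooled) and reports
#' it with the configured prediction-accuracy decision threshold. The
#' threshold is configuration, not derived from the interval.
#'
#' @param mi_values All stage-MI values (>= 100 recommended).
#' @param hdi_mass HDI probability mass.
#' @param threshold Accuracy decision threshold, percent.
#' @return List with `hdi_lower`, `hdi_upper`, `threshold`.
#' @export
accuracy_threshold <- function(mi_values, hdi_mass = 0.95, threshold = 75) {
  h <- hdi(mi_values, hdi_mass)
  list(hdi_lower = unname(h["lower"]), hdi_upper = unname(h["upper"]),
       threshold = threshold)
}
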