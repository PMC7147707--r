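#' Data-split protocol for the classical classifiers
#'
#' The feature-based classifiers use an 85/5/10 train/validation/test split
#' combined with stratified k-fold cross-validation: the folds define the
#' test portions, and within each fold's training portion the 85/5 ratio
#' carves out a validation set.
#'
#' @param train_frac,val_frac,test_frac split fractions summing to 1.
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param seed RNG seed for fold assignment.
#' @return A `split_protocol` object.
#' @export
split_protocol <- function(train_frac = 0.85, val_frac = 0.05,
                           test_frac = 0.10, cv_folds = 10L, seed = 1L) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9)
    stop_validation("split fractions must sum to 1")
  if (cv_folds < 2L) stop_validation("cv_folds must be >= 2")
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "split_protocol")
}

#' Stratified fold assignment
#'
#' Assigns each sample to exactly one fold, keeping class proportions as
#' even as the counts allow.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' One-vs-one pair tasks
#'
#' Builds one binary task per unordered class pair. For k classes this
#' yields choose(k, 2) tasks, ordered by decreasing class separation
#' `|a - b|` and, within equal separation, by decreasing lower class — for
#' five classes: 1-5, 2-5, 1-4, 3-5, 2-4, 1-3, 4-5, 3-4, 2-3, 1-2.
#'
#' @param features numeric matrix or data.frame of feature vectors (rows =
#'   samples).
#' @param labels integer class labels.
#' @return List of `pair_task` objects (`class_a`, `class_b`, `x`, `y` with
#'   `y = 1` for `class_b`, the higher-change class). Pairs where a class
#'   has no samples are skipped with a warning.
#' @export
make_ovo_tasks <- function(features, labels) {
  features <- as.matrix(features)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop_validation("need at least two classes")
  pairs <- t(utils::combn(classes, 2L))
  ord <- order(-(pairs[, 2] - pairs[, 1]), -pairs[, 1])
  pairs <- pairs[ord, , drop = FALSE]
  tasks <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    sel <- labels %in% c(a, b)
    if (!any(labels == a) || !any(labels == b)) {
      warning("skipping pair ", a, "-", b, ": a class has no samples")
      next
    }
    tasks[[paste0(a, "-", b)]] <- structure(
      list(class_a = a, class_b = b,
           x = features[sel, , drop = FALSE],
           y = as.integer(labels[sel] == b)),
      class = "pair_task")
  }
  tasks
}

# z-score standardization fitted on the training portion only.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
apply_scaler <- function(x, s) sweep(sweep(x, 2L, s$mu), 2L, s$sd, "/")

#' Fit the 3-layer MLP baseline on a pair task
#'
#' A feed-forward network with a single hidden layer (input-hidden-output,
#' i.e. three layers) trained on the protocol's training portion; the
#' validation portion is held out and its accuracy reported.
#'
#' @param task a `pair_task` from [make_ovo_tasks()].
#' @param protocol a [split_protocol()].
#' @param hidden_units hidden layer width (default 10).
#' @return List with the fitted `nnet` model, the scaler, split indices and
#'   `val_accuracy`/`test_accuracy`.
#' @export
fit_mlp <- function(task, protocol = split_protocol(), hidden_units = 10L) {
  sp <- make_split(length(task$y), task$y, protocol)
  sc <- fit_scaler(task$x[sp$train, , drop = FALSE])
  x <- apply_scaler(task$x, sc)
  fit <- with_seed(protocol$seed, nnet::nnet(
    x[sp$train, , drop = FALSE], task$y[sp$train], size = hidden_units,
    entropy = TRUE, maxit = 500, trace = FALSE))
  pred <- function(idx) as.integer(stats::predict(fit, x[idx, , drop = FALSE]) > 0.5)
  list(model = fit, scaler = sc, split = sp,
       val_accuracy = if (length(sp$val)) mean(pred(sp$val) == task$y[sp$val]) else NA,
       test_accuracy = if (length(sp$test)) mean(pred(sp$test) == task$y[sp$test]) else NA,
       predict_scores = function(newx)
         as.numeric(stats::predict(fit, apply_scaler(as.matrix(newx), sc))))
}

#' Fit the linear-kernel SVM baseline on a pair task
#'
#' @inheritParams fit_mlp
#' @return As [fit_mlp()], with an `e1071::svm` model; scores are decision
#'   values oriented so larger means class `class_b`.
#' @export
fit_svm <- function(task, protocol = split_protocol()) {
  sp <- make_split(length(task$y), task$y, protocol)
  sc <- fit_scaler(task$x[sp$train, , drop = FALSE])
  x <- apply_scaler(task$x, sc)
  fit <- e1071::svm(x[sp$train, , drop = FALSE],
                    factor(task$y[sp$train], levels = c(0, 1)),
                    kernel = "linear", scale = FALSE)
  score <- function(idx) {
    dv <- attr(stats::predict(fit, x[idx, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    sgn <- if (grepl("^0/", colnames(dv)[1])) -1 else 1
    sgn * as.numeric(dv)
  }
  pred <- function(idx) as.integer(score(idx) > 0)
  list(model = fit, scaler = sc, split = sp,
       val_accuracy = if (length(sp$val)) mean(pred(sp$val) == task$y[sp$val]) else NA,
       test_accuracy = if (length(sp$test)) mean(pred(sp$test) == task$y[sp$test]) else NA,
       predict_scores = function(newx) {
         xx <- apply_scaler(as.matrix(newx), sc)
         dv <- attr(stats::predict(fit, xx, decision.values = TRUE),
                    "decision.values")
         sgn <- if (grepl("^0/", colnames(dv)[1])) -1 else 1
         sgn * as.numeric(dv)
       })
}

# Stratified train/val/test indices per the protocol fractions.
make_split <- function(n, y, protocol) {
  with_seed(protocol$seed, {
    train <- integer(); val <- integer(); test <- integer()
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      n_test <- max(1L, round(protocol$test_frac * length(idx)))
      n_val <- max(1L, round(protocol$val_frac * length(idx)))
      if (n_test + n_val >= length(idx))
        stop_validation("class ", cl, " too small for the split")
      test <- c(test, idx[seq_len(n_test)])
      val <- c(val, idx[n_test + seq_len(n_val)])
      train <- c(train, idx[-seq_len(n_test + n_val)])
    }
    list(train = sort(train), val = sort(val), test = sort(test))
  })
}

#' Cross-validated one-vs-one evaluation of a classical baseline
#'
#' For each pair task, runs stratified k-fold cross-validation (folds are
#' the test portions; the remainder is split 85/5 train/validation per the
#' protocol), pools the out-of-fold predictions into confusion counts and
#' computes the six metrics including score-based AUC.
#'
#' @param features,labels dataset (rows = samples).
#' @param model `"svm"` or `"mlp"`.
#' @param protocol a [split_protocol()].
#' @param hidden_units MLP hidden width.
#' @return A [pair_table()] data.frame (one row per pair plus Average).
#' @export
evaluate_baseline <- function(features, labels, model = c("svm", "mlp"),
                              protocol = split_protocol(),
                              hidden_units = 10L) {
  model <- match.arg(model)
  tasks <- make_ovo_tasks(features, labels)
  rows <- list()
  for (nm in names(tasks)) {
    task <- tasks[[nm]]
    folds <- stratified_folds(task$y, protocol$cv_folds, seed = protocol$seed)
    scores <- numeric(length(task$y))
    for (f in seq_len(protocol$cv_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      if (!length(te) || length(unique(task$y[tr])) < 2L) next
      sub <- structure(list(class_a = task$class_a, class_b = task$class_b,
                            x = task$x[tr, , drop = FALSE], y = task$y[tr]),
                       class = "pair_task")
      inner <- split_protocol(protocol$train_frac / (1 - protocol$test_frac),
                              1 - protocol$train_frac / (1 - protocol$test_frac),
                              0, cv_folds = protocol$cv_folds,
                              seed = protocol$seed + f)
      fitted <- if (model == "svm") fit_svm_inner(sub, inner) else
        fit_mlp_inner(sub, inner, hidden_units)
      scores[te] <- fitted$predict_scores(task$x[te, , drop = FALSE])
    }
    pred <- as.integer(scores > if (model == "svm") 0 else 0.5)
    cc <- confusion_counts(tp = sum(pred == 1 & task$y == 1),
                           fp = sum(pred == 1 & task$y == 0),
                           tn = sum(pred == 0 & task$y == 0),
                           fn = sum(pred == 0 & task$y == 1))
    rows[[nm]] <- metrics_from_counts(cc, auc = roc_auc(scores, task$y)$auc)
  }
  pair_table(rows)
}

# Inner fits without a test carve-out (the CV fold is the test set).
fit_mlp_inner <- function(task, protocol, hidden_units) {
  sc <- fit_scaler(task$x)
  x <- apply_scaler(task$x, sc)
  fit <- with_seed(protocol$seed, nnet::nnet(
    x, task$y, size = hidden_units, entropy = TRUE, maxit = 500, trace = FALSE))
  list(predict_scores = function(newx)
    as.numeric(stats::predict(fit, apply_scaler(as.matrix(newx), sc))))
}

fit_svm_inner <- function(task, protocol) {
  sc <- fit_scaler(task$x)
  x <- apply_scaler(task$x, sc)
  fit <- e1071::svm(x, factor(task$y, levels = c(0, 1)), kernel = "linear",
                    scale = FALSE)
  list(predict_scores = function(newx) {
    dv <- attr(stats::predict(fit, apply_scaler(as.matrix(newx), sc),
                              decision.values = TRUE), "decision.values")
    sgn <- if (grepl("^0/", colnames(dv)[1])) -1 else 1
    sgn * as.numeric(dv)
  })
}
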