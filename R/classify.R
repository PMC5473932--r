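#' Random train/test split assignment
#'
#' Each snapshot is independently assigned to the training or test set with
#' probability 1/2 (so the two sets are of almost equal size), deterministic
#' given the seed.
#'
#' @param n number of snapshots (>= 2).
#' @param seed integer seed.
#' @return character vector of `"train"`/`"test"` with attribute `seed`.
#' @export
split_train_test <- function(n, seed) {
  if (n < 2) .stopf("need at least 2 snapshots")
  split <- .with_seed(seed, ifelse(stats::runif(n) < 0.5, "train", "test"))
  attr(split, "seed") <- as.integer(seed)
  split
}

.split_masks <- function(split, n) {
  if (is.null(split)) {
    list(train = rep(TRUE, n), test = rep(TRUE, n))
  } else {
    if (length(split) != n) .stopf("split length must match the data")
    list(train = split == "train", test = split == "test")
  }
}

#' Optimal single-threshold (linear) discriminator for one feature
#'
#' Finds the separating value V_sep that best discriminates the two state
#' labels from a single structural feature: candidate thresholds are the
#' midpoints of consecutive sorted unique training values plus the two
#' extremes, both inequality directions are scanned, and the training-accuracy
#' maximizer is chosen. Ties are broken in favor of the largest margin
#' (distance to the nearest training value), then the direction that puts the
#' positive label above the threshold, then the smallest threshold. Accuracy
#' is reported on the test split (on all data when `split` is `NULL`).
#'
#' @param values numeric feature vector, one value per snapshot.
#' @param labels state labels, exactly two distinct values; `positive` is the
#'   label predicted on the chosen side of the threshold.
#' @param split optional [split_train_test()] assignment.
#' @param positive the positive-class label (default `"ox"` when present,
#'   otherwise the last label in sort order).
#' @param feature optional feature name carried into the result.
#' @return A `LinearDiscriminator`: list with `feature`, `threshold`
#'   (V_sep), `direction` (`"above"` if the positive class lies above),
#'   `positive`, `train_accuracy`, `test_accuracy`.
#' @export
fit_linear_threshold <- function(values, labels, split = NULL,
                                 positive = NULL, feature = NULL) {
  if (length(values) != length(labels)) .stopf("values/labels length mismatch")
  if (anyNA(values)) .stopf("feature values contain NA")
  labs <- sort(unique(as.character(labels)))
  if (length(labs) < 2) .stopf("single-class input: only label '%s' present", labs)
  if (length(labs) > 2) .stopf("need exactly two state labels, got %d", length(labs))
  if (is.null(positive)) positive <- if ("ox" %in% labs) "ox" else labs[2]
  if (!positive %in% labs) .stopf("positive label '%s' not present", positive)
  masks <- .split_masks(split, length(values))
  v_tr <- values[masks$train]
  y_tr <- as.character(labels)[masks$train] == positive
  if (length(unique(y_tr)) < 2) .stopf("training set contains a single class")

  ord <- order(v_tr)
  v_s <- v_tr[ord]
  y_s <- y_tr[ord]
  u <- unique(v_s)
  # candidate cut positions: after the last occurrence of each unique value,
  # plus the empty cut (threshold below everything)
  last_of <- cumsum(tabulate(match(v_s, u), length(u)))
  cuts <- c(0L, last_of)
  thr <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  margin <- c(0, (u[-1] - u[-length(u)]) / 2, 0)
  n_pos <- sum(y_s)
  n_neg <- length(y_s) - n_pos
  cum_pos <- c(0, cumsum(y_s))
  # direction "above": predict positive for v > thr
  correct_above <- (cuts - cum_pos[cuts + 1]) + (n_pos - cum_pos[cuts + 1])
  # direction "below": predict positive for v <= thr
  correct_below <- length(y_s) - correct_above
  cand <- data.frame(
    threshold = c(thr, thr),
    direction = rep(c("above", "below"), each = length(thr)),
    margin = c(margin, margin),
    correct = c(correct_above, correct_below)
  )
  pref_above <- cand$direction == "above"
  best <- order(-cand$correct, -cand$margin, -pref_above, cand$threshold)[1]
  threshold <- cand$threshold[best]
  direction <- cand$direction[best]
  acc_of <- function(mask) {
    v <- values[mask]
    truth <- as.character(labels)[mask] == positive
    pred <- if (direction == "above") v > threshold else v <= threshold
    mean(pred == truth)
  }
  structure(list(feature = feature, threshold = threshold,
                 direction = direction, positive = positive,
                 train_accuracy = cand$correct[best] / length(y_s),
                 test_accuracy = acc_of(masks$test)),
            class = "LinearDiscriminator")
}

#' @export
print.LinearDiscriminator <- function(x, ...) {
  cat(sprintf(
    "LinearDiscriminator%s: '%s' %s V_sep = %.4g; accuracy train %.1f%%, test %.1f%%\n",
    if (is.null(x$feature)) "" else paste0(" [", x$feature, "]"),
    x$positive, if (x$direction == "above") ">" else "<=", x$threshold,
    100 * x$train_accuracy, 100 * x$test_accuracy))
  invisible(x)
}

#' Predict state labels with a fitted linear discriminator
#' @param object a `LinearDiscriminator`.
#' @param newdata numeric feature values.
#' @param ... unused.
#' @return logical vector, `TRUE` where the positive class is predicted.
#' @export
predict.LinearDiscriminator <- function(object, newdata, ...) {
  if (object$direction == "above") newdata > object$threshold
  else newdata <= object$threshold
}

#' Radial-basis SVM test accuracy for one or more features
#'
#' Trains a support vector machine with radial-basis kernel and default
#' hyperparameters (cost 1, gamma = 1/n_features) on the training split and
#' reports accuracy on the test split. This is the non-linear companion to
#' [fit_linear_threshold()]: on unimodal features the two agree, while
#' features that are bimodal in one state are only separable by the SVM.
#'
#' @param features numeric vector, matrix or data frame of feature columns.
#' @param labels state labels (two classes).
#' @param split optional [split_train_test()] assignment (`NULL`: train and
#'   evaluate on all data).
#' @return test-set accuracy (fraction), with `cost` and `gamma` attributes.
#' @export
evaluate_svm_rbf <- function(features, labels, split = NULL) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- factor(as.character(labels))
  if (nlevels(y) != 2) .stopf("need exactly two state labels")
  masks <- .split_masks(split, nrow(x))
  y_tr <- y[masks$train]
  if (length(unique(y_tr)) < 2) .stopf("training set contains a single class")
  fit <- e1071::svm(x = x[masks$train, , drop = FALSE], y = y_tr,
                    kernel = "radial")
  pred <- stats::predict(fit, x[masks$test, , drop = FALSE])
  acc <- mean(pred == y[masks$test])
  attr(acc, "cost") <- fit$cost
  attr(acc, "gamma") <- fit$gamma
  acc
}

#' Residue-pair discrimination-accuracy matrix
#'
#' For every residue pair (i, j), the test accuracy of the optimal linear
#' threshold on the CA-CA distance d_ij, classifying frames of the two
#' ensembles. Diagonal entries are 0.5 (d_ii carries no signal). High-accuracy
#' off-diagonal blocks expose the residue pairs whose geometry differs most
#' consistently between the states.
#'
#' @param ds_a,ds_b `ResidueDistanceSeries` (see [residue_distance_series()])
#'   for the two ensembles, over the same residue set.
#' @param labels length-2 character: the state labels of `ds_a` and `ds_b`
#'   (default `c("ox", "red")`).
#' @param split optional [split_train_test()] assignment over the
#'   concatenated frames; built from `seed` when `NULL` and `seed` is given.
#' @param seed seed used to build the split when `split` is `NULL`.
#' @return symmetric accuracy matrix in \[0.5, 1\] with residue dimnames.
#' @export
residue_discrimination_matrix <- function(ds_a, ds_b,
                                          labels = c("ox", "red"),
                                          split = NULL, seed = NULL) {
  if (!identical(ds_a$resid, ds_b$resid)) {
    .stopf("the two ensembles cover different residue sets")
  }
  n <- length(ds_a$resid)
  na <- dim(ds_a$d)[1]
  nb <- dim(ds_b$d)[1]
  y <- c(rep(labels[1], na), rep(labels[2], nb))
  if (is.null(split) && !is.null(seed)) {
    split <- split_train_test(na + nb, seed)
  }
  M <- matrix(0.5, n, n, dimnames = list(ds_a$resid, ds_a$resid))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- c(ds_a$d[, i, j], ds_b$d[, i, j])
      fit <- fit_linear_threshold(v, y, split = split, positive = labels[1])
      M[i, j] <- M[j, i] <- max(fit$test_accuracy, 1 - fit$test_accuracy)
    }
  }
  M
}
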