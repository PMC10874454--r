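#' Optimal (Bayesian) threshold classifier on one signaling feature
#'
#' With a monotonic feature-fate relationship, the most-probable-fate rule
#' reduces to a threshold: cells above it are called amnion. The threshold
#' maximizing accuracy (true positives + true negatives) is found by an exact
#' scan over all inter-value intervals; on ties the midpoint of the widest
#' optimal interval is returned.
#'
#' @param values numeric feature values.
#' @param labels two-class labels; "amnion" (or `TRUE`) is the positive class
#'   predicted above the threshold.
#' @return list of class `threshold_classifier`: `threshold`, `accuracy`,
#'   `confusion` (2x2 percent: rows predicted, cols true), `orientation`.
#' @export
bayes_threshold <- function(values, labels) {
  pos <- as_amnion(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  n <- length(values)
  u <- sort(unique(values))
  # accuracy for a cut in each interval: predict amnion iff value > cut
  # interval i = (u[i], u[i+1]); i = 0 is (-Inf, u[1]), i = k is (u[k], Inf)
  ord <- order(values)
  poso <- pos[ord]
  vo <- values[ord]
  k <- length(u)
  # counts of (pluripotent, amnion) with value <= u[i]
  cum_pos <- cumsum(poso)
  cum_all <- seq_len(n)
  idx <- findInterval(u, vo)           # number of values <= u[i]
  npos_le <- cum_pos[idx]
  nneg_le <- idx - npos_le
  total_pos <- sum(pos)
  # cut above u[i]: correct = pluripotent <= u[i] + amnion > u[i]
  acc <- c((n - total_pos - 0) * 0 + total_pos,          # i = 0: all amnion
           nneg_le + (total_pos - npos_le)) / n
  best <- max(acc)
  opt <- which(acc == best) - 1L                         # interval indices
  widths <- vapply(opt, function(i) {
    if (i == 0 || i == k) Inf else u[i + 1] - u[i]
  }, numeric(1))
  fin <- opt[is.finite(widths)]
  if (length(fin)) {
    # widest finite optimal interval (first on further ties)
    wi <- fin[which.max(widths[is.finite(widths)])]
    thr <- (u[wi] + u[wi + 1]) / 2
  } else if (all(opt == 0)) {
    thr <- u[1] - 1
  } else {
    thr <- u[k] + 1
  }
  pred <- values > thr
  conf <- 100 * table(factor(pred, c(TRUE, FALSE),
                             labels = c("amnion", "pluripotent")),
                      factor(pos, c(TRUE, FALSE),
                             labels = c("amnion", "pluripotent"))) / n
  structure(list(threshold = thr, accuracy = best,
                 confusion = unclass(conf), orientation = "above_amnion"),
            class = "threshold_classifier")
}

as_amnion <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- as.character(labels)
  if (all(l %in% c("amnion", "pluripotent"))) return(l == "amnion")
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must be two-class")
  f == levels(f)[1]
}

#' Cross-validated accuracy of the feature-threshold classifier
#'
#' Fits the optimal threshold on each training fold and scores the held-out
#' fold, using the same stratified k-fold protocol as [history_classifier()].
#' This is the accuracy to compare against cross-validated history
#' classifiers: the in-sample [bayes_threshold()] accuracy carries a small
#' optimism from choosing the threshold on the evaluation data.
#'
#' @inheritParams bayes_threshold
#' @param folds number of CV folds (default 5).
#' @param seed fold-assignment seed.
#' @return list: `cv_accuracy`, `folds`, `seed`.
#' @export
bayes_threshold_cv <- function(values, labels, folds = 5, seed = 1L) {
  pos <- as_amnion(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  set.seed(substream_seed(seed, "bayes_cv_folds"))
  fold <- integer(length(values))
  for (cl in c(TRUE, FALSE)) {
    idx <- which(pos == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  ok <- logical(length(values))
  for (f in seq_len(folds)) {
    bt <- bayes_threshold(values[fold != f], pos[fold != f])
    ok[fold == f] <- (values[fold == f] > bt$threshold) == pos[fold == f]
  }
  list(cv_accuracy = mean(ok), folds = folds, seed = seed)
}

#' Quadrant percentages of the fate-score / signaling-feature plane
#'
#' The four quadrants formed by the fate-score threshold (default 0) and the
#' signaling-feature threshold give the confusion matrix of the threshold
#' classifier: correct assignments sit in the top-right (amnion, high feature)
#' and bottom-left (pluripotent, low feature).
#'
#' @param fate_scores,feature_values per-cell values.
#' @param score_threshold,feature_threshold finite thresholds.
#' @return 2x2 matrix of percentages (rows: score high/low, cols: feature
#'   high/low) with attribute `correct` = top-right + bottom-left.
#' @export
quadrant_confusion <- function(fate_scores, feature_values,
                               score_threshold = 0, feature_threshold) {
  stopifnot(is.finite(score_threshold), is.finite(feature_threshold))
  hi_s <- fate_scores > score_threshold
  hi_f <- feature_values > feature_threshold
  n <- length(fate_scores)
  q <- matrix(c(sum(hi_s & hi_f), sum(hi_s & !hi_f),
                sum(!hi_s & hi_f), sum(!hi_s & !hi_f)) / n * 100,
              2, 2, byrow = TRUE,
              dimnames = list(score = c("high", "low"),
                              feature = c("high", "low")))
  attr(q, "correct") <- q["high", "high"] + q["low", "low"]
  q
}

#' Cross-validated fate classification from full signaling histories
#'
#' Stratified k-fold cross-validation of a generic classifier on the raw
#' history vectors. `"linear_sigmoid"` is a no-hidden-layer sigmoid model ---
#' logistic regression, here ridge-penalized (small fixed penalty) so it stays
#' well-posed with hundreds of timepoints; `"svm_quadratic"` is an SVM with a
#' quadratic polynomial kernel.
#'
#' @param histories cells x timepoints matrix.
#' @param labels two-class fate labels.
#' @param model `"linear_sigmoid"` or `"svm_quadratic"`.
#' Both models tune their regularization (ridge penalty / SVM cost) by inner
#' cross-validation on each training fold, so reported accuracies reflect the
#' information in the histories rather than an arbitrary penalty choice.
#'
#' @param folds number of CV folds (default 5).
#' @param seed fold-assignment seed.
#' @param lambda optional fixed ridge penalty for the linear model; `NULL`
#'   (default) selects it by inner CV.
#' @param costs SVM cost grid searched by inner CV.
#' @return list: `cv_accuracy`, `confusion` (counts: rows predicted, cols
#'   true), `model`, `folds`, `seed`.
#' @export
history_classifier <- function(histories, labels,
                               model = c("linear_sigmoid", "svm_quadratic"),
                               folds = 5, seed = 1L, lambda = NULL,
                               costs = c(0.1, 0.3, 1, 3)) {
  model <- match.arg(model)
  pos <- as_amnion(labels)
  if (min(table(pos)) < 2 * folds)
    stop("need at least folds x 2 cells per class")
  X <- as.matrix(histories)
  n <- nrow(X)

  make_folds <- function(s) {
    set.seed(substream_seed(s, "history_classifier_folds"))
    fold <- integer(n)
    for (cl in c(TRUE, FALSE)) {
      idx <- which(pos == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  }
  fold <- make_folds(seed)
  tries <- 0
  while (any(vapply(seq_len(folds), function(f)
    length(unique(pos[fold != f])) < 2, logical(1))) && tries < 10) {
    tries <- tries + 1
    message("degenerate fold; refolding with a new seed")
    fold <- make_folds(seed + tries)
  }

  pred <- logical(n)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    if (model == "linear_sigmoid") {
      if (is.null(lambda)) {
        set.seed(substream_seed(seed, paste0("inner_cv_", f)))
        cvfit <- glmnet::cv.glmnet(X[tr, ], factor(pos[tr]),
                                   family = "binomial", alpha = 0,
                                   nfolds = 5, standardize = TRUE)
        lam <- cvfit$lambda.min
      } else lam <- lambda
      fit <- glmnet::glmnet(X[tr, ], factor(pos[tr]), family = "binomial",
                            alpha = 0, lambda = lam, standardize = TRUE)
      p <- stats::predict(fit, X[te, ], type = "response")[, 1]
      pred[te] <- p > 0.5
    } else {
      cost <- if (length(costs) > 1) {
        set.seed(substream_seed(seed, paste0("inner_svm_", f)))
        inner <- sample(rep_len(seq_len(5), sum(tr)))
        acc <- vapply(costs, function(cc) {
          ok <- logical(sum(tr))
          Xtr <- X[tr, ]; ptr <- pos[tr]
          for (g in 1:5) {
            fit <- e1071::svm(Xtr[inner != g, ], factor(ptr[inner != g]),
                              kernel = "polynomial", degree = 2, coef0 = 1,
                              cost = cc, scale = TRUE)
            ok[inner == g] <-
              as.logical(stats::predict(fit, Xtr[inner == g, ])) ==
              ptr[inner == g]
          }
          mean(ok)
        }, numeric(1))
        costs[which.max(acc)]
      } else costs
      fit <- e1071::svm(X[tr, ], factor(pos[tr]), kernel = "polynomial",
                        degree = 2, coef0 = 1, cost = cost, scale = TRUE)
      pred[te] <- as.logical(stats::predict(fit, X[te, ]))
    }
  }
  conf <- table(predicted = factor(pred, c(TRUE, FALSE),
                                   c("amnion", "pluripotent")),
                true = factor(pos, c(TRUE, FALSE),
                              c("amnion", "pluripotent")))
  list(cv_accuracy = mean(pred == pos), confusion = unclass(conf),
       model = model, folds = folds, seed = seed)
}

#' Decoder-based mutual information of a binary confusion matrix
#'
#' `I = H(fate) - H(fate | prediction)` computed from the confusion
#' frequencies, in bits; 0 for chance-level prediction, 1 bit for a perfect
#' balanced classifier. Empty cells contribute `0 log 0 = 0`.
#'
#' @param confusion 2x2 matrix of counts or percentages (rows predicted,
#'   cols true).
#' @return Mutual information in bits.
#' @export
decoder_mutual_information <- function(confusion) {
  p <- confusion / sum(confusion)
  if (any(p < 0) || !all(dim(p) == c(2, 2))) stop("invalid confusion matrix")
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  pr <- rowSums(p); pc <- colSums(p)
  sum(xlx(p)) - sum(xlx(pr)) - sum(xlx(pc))
}
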