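# Discrete AdaBoost with depth-limited Gini decision trees, weighted-error
# coefficients, per-round bagging, out-of-bag evaluation and impurity-based
# variable importance.

# ---- weighted decision tree base learner -----------------------------------

# Best weighted Gini split of one node. Candidate thresholds are midpoints of
# consecutive distinct values; ties in gain break to the lowest variable index
# then the lowest threshold. Returns NULL when no split improves.
.best_split <- function(X, y, w) {
  Wp <- sum(w[y > 0]); Wn <- sum(w[y < 0]); W <- Wp + Wn
  gini <- function(wp, wn) {
    tot <- wp + wn
    ifelse(tot > 0, tot * (1 - (wp / tot)^2 - (wn / tot)^2), 0)
  }
  parent <- gini(Wp, Wn)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xv <- X[ord, j]
    dup <- duplicated(xv)
    if (all(dup[-1])) next                    # constant column
    wp <- cumsum((w * (y > 0))[ord])
    wn <- cumsum((w * (y < 0))[ord])
    # split after position i (strictly below the midpoint goes left)
    cut_ok <- which(diff(xv) > 0)
    if (!length(cut_ok)) next
    gainv <- parent - (gini(wp[cut_ok], wn[cut_ok]) +
                       gini(Wp - wp[cut_ok], Wn - wn[cut_ok]))
    k <- which.max(gainv)                     # first max: lowest threshold
    if (gainv[k] > 1e-12 && (is.null(best) || gainv[k] > best$gain + 1e-12)) {
      i <- cut_ok[k]
      best <- list(var = j, threshold = (xv[i] + xv[i + 1]) / 2,
                   gain = gainv[k])
    }
  }
  best
}

.leaf <- function(y, w) {
  s <- sum(w * y)
  # tie in the weighted vote goes to the benign class (-1)
  list(leaf = TRUE, pred = if (s > 0) 1 else -1)
}

.fit_tree <- function(X, y, w, depth) {
  if (depth == 0L || length(unique(y)) == 1L) return(.leaf(y, w))
  sp <- .best_split(X, y, w)
  if (is.null(sp)) return(.leaf(y, w))
  left <- X[, sp$var] < sp$threshold
  list(leaf = FALSE, var = sp$var, threshold = sp$threshold, gain = sp$gain,
       left = .fit_tree(X[left, , drop = FALSE], y[left], w[left], depth - 1L),
       right = .fit_tree(X[!left, , drop = FALSE], y[!left], w[!left],
                         depth - 1L))
}

.predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$pred; return() }
    left <- X[idx, node$var] < node$threshold
    rec(node$left, idx[left])
    rec(node$right, idx[!left])
  }
  rec(tree, seq_len(nrow(X)))
  out
}

.tree_gains <- function(tree, p) {
  g <- numeric(p)
  rec <- function(node) {
    if (node$leaf) return()
    g[node$var] <<- g[node$var] + node$gain
    rec(node$left); rec(node$right)
  }
  rec(tree)
  g
}

# ---- boosting --------------------------------------------------------------

#' Train a Discrete AdaBoost ensemble
#'
#' Boosting with two-class tree base learners: starting from uniform weights
#' `w_i = 1/N`, each round fits a classifier `f_m(x) in {-1, +1}`, computes
#' the weighted error `err_m = sum(w_i 1(y_i != f_m(x_i)))`, sets
#' `c_m = log((1 - err_m) / err_m)`, multiplies the weights of misclassified
#' points by `exp(c_m)` and renormalizes. The ensemble predicts
#' `sign(sum_m c_m f_m(x))`.
#'
#' With `bagging = TRUE` (default) each round's learner is fitted on a sample
#' of size N drawn with replacement with probabilities proportional to the
#' current weights, decoupling the learner from the full reference sample;
#' the weighted error is always evaluated on the full sample. Degenerate
#' rounds are handled explicitly: `err_m = 0` caps `c_m` at a large finite
#' constant and the loop continues; `err_m >= 0.5` discards the round and
#' resamples (without bagging, training stops early at that round).
#'
#' @param X Numeric matrix or data frame of features (factors not supported;
#'   binary covariates should be 0/1 numeric).
#' @param y Labels in `{-1, +1}` (+1 = malignant) or a factor whose second
#'   level is taken as +1.
#' @param M Boosting iterations (default 50, the customary tree-boosting
#'   default used by the analysis protocol).
#' @param base_depth Maximum tree depth (default 2).
#' @param bagging Weighted resampling per round (default TRUE).
#' @param seed Integer seed; training is reproducible when given.
#' @param max_resample Attempts to redraw a round with `err_m >= 0.5`.
#' @param keep_weights Store the post-update weight vector of every round
#'   (`weight_history`, M x N), for diagnostics.
#' @return Object of class `boost_model`: `trees`, `coefficients` (`c_m`),
#'   `errors` (`err_m`), `M`, `features`, `bags` (per-round in-bag index
#'   lists, `NULL` without bagging), `y_levels`.
#' @export
train_discrete_adaboost <- function(X, y, M = 50, base_depth = 2,
                                    bagging = TRUE, seed = NULL,
                                    max_resample = 25, keep_weights = FALSE) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric")
  y_levels <- NULL
  if (is.factor(y)) {
    y_levels <- levels(y)
    y <- ifelse(y == y_levels[2], 1, -1)
  }
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1 or a two-level factor")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (M < 1) stop("M must be >= 1")
  N <- nrow(X)
  .with_seed(seed, {
    w <- rep(1 / N, N)
    trees <- vector("list", M)
    cm <- numeric(M)
    errs <- numeric(M)
    bags <- if (bagging) vector("list", M) else NULL
    wh <- if (keep_weights) matrix(NA_real_, M, N) else NULL
    m <- 1L
    while (m <= M) {
      fitted <- FALSE
      for (try in seq_len(if (bagging) max_resample else 1L)) {
        if (bagging) {
          bag <- sample.int(N, N, replace = TRUE, prob = w)
          tree <- .fit_tree(X[bag, , drop = FALSE], y[bag],
                            rep(1 / N, N), base_depth)
        } else {
          bag <- NULL
          tree <- .fit_tree(X, y, w, base_depth)
        }
        pred <- .predict_tree(tree, X)
        err <- sum(w[pred != y])
        if (err < 0.5) { fitted <- TRUE; break }
      }
      if (!fitted) {
        # no useful learner found: truncate the ensemble here
        warning(sprintf("round %d: weighted error >= 0.5 persisted; stopping at %d rounds",
                        m, m - 1L))
        trees <- trees[seq_len(m - 1L)]
        cm <- cm[seq_len(m - 1L)]
        errs <- errs[seq_len(m - 1L)]
        if (bagging) bags <- bags[seq_len(m - 1L)]
        if (keep_weights) wh <- wh[seq_len(m - 1L), , drop = FALSE]
        break
      }
      c_m <- if (err <= 0) log((1 - 1e-10) / 1e-10) else log((1 - err) / err)
      mis <- pred != y
      w[mis] <- w[mis] * exp(c_m)
      w <- w / sum(w)
      trees[[m]] <- tree
      cm[m] <- c_m
      errs[m] <- err
      if (bagging) bags[[m]] <- bag
      if (keep_weights) wh[m, ] <- w
      m <- m + 1L
    }
    structure(list(trees = trees, coefficients = cm, errors = errs,
                   M = length(trees), features = colnames(X),
                   base_depth = base_depth, bags = bags, y_levels = y_levels,
                   weight_history = wh, n_train = N),
              class = "boost_model")
  })
}

#' @export
print.boost_model <- function(x, ...) {
  cat(sprintf("Discrete AdaBoost: %d rounds, depth-%d trees, %d features\n",
              x$M, x$base_depth, length(x$features)))
  invisible(x)
}

#' Predict from a Discrete AdaBoost model
#'
#' @param object A `boost_model`.
#' @param newdata Feature matrix/data frame with the training columns.
#' @param type `"class"` (default) for -1/+1 labels, `"score"` for the raw
#'   additive score `F(x) = sum_m c_m f_m(x)`.
#' @param ... Unused.
#' @return Numeric vector. Ties (`F(x) = 0`) are broken to -1 (benign) and
#'   flagged via the `"ties"` attribute.
#' @export
predict.boost_model <- function(object, newdata, type = c("class", "score"),
                                ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  F <- numeric(nrow(X))
  for (m in seq_len(object$M))
    F <- F + object$coefficients[m] * .predict_tree(object$trees[[m]], X)
  if (type == "score") return(F)
  out <- ifelse(F > 0, 1, -1)
  ties <- which(F == 0)
  if (length(ties)) attr(out, "ties") <- ties
  out
}

#' Impurity-based variable importance
#'
#' Importance of a variable: the sum over ensemble trees of the weighted Gini
#' impurity decrease at every split on that variable, each tree weighted by
#' its boosting coefficient `c_m`, normalized to sum to one.
#'
#' @param model A `boost_model`.
#' @return Named numeric vector (sums to 1), sorted as the training columns.
#' @export
variable_importance <- function(model) {
  p <- length(model$features)
  if (p == 0) p <- max(vapply(model$trees, function(t) {
    mx <- 0
    rec <- function(n) if (!n$leaf) { mx <<- max(mx, n$var); rec(n$left); rec(n$right) }
    rec(t); mx
  }, numeric(1)))
  g <- numeric(p)
  for (m in seq_len(model$M))
    g <- g + model$coefficients[m] * .tree_gains(model$trees[[m]], p)
  tot <- sum(g)
  imp <- if (tot > 0) g / tot else g
  names(imp) <- model$features %||% paste0("V", seq_len(p))
  imp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under the ROC curve by threshold sweep
#'
#' Sweeps the score threshold to trace the ROC curve and integrates it by the
#' trapezoidal rule (equivalent to pairwise concordance with 0.5 for ties).
#'
#' @param scores Numeric classifier scores (larger = more malignant).
#' @param y Labels in `{-1, +1}`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, y) {
  stopifnot(length(scores) == length(y), all(y %in% c(-1, 1)))
  thr <- c(-Inf, sort(unique(scores)), Inf)
  pos <- y > 0
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
}

#' Repeated-run evaluation of the Discrete AdaBoost classifier
#'
#' Trains the ensemble `runs` times with different random streams and
#' summarizes out-of-bag (or held-out) performance as mean +/- SD
#' misclassification rate, sensitivity and specificity (malignant = positive
#' class), pooled-score AUC, and the average variable-importance ranking.
#'
#' With `method = "holdout"` (default) a random third of the cohort is held
#' out per run and scored by the full ensemble trained on the rest. With
#' `method = "oob"` each point is scored by the rounds whose bag did not
#' contain it; note that under weight-proportional bagging the out-of-bag
#' rounds of a frequently misclassified point systematically exclude the
#' rounds that adapted to it, so this estimator is pessimistically biased
#' and is provided for diagnostics rather than as the headline metric.
#'
#' @param X,y,M,base_depth,seed As in [train_discrete_adaboost()].
#' @param runs Number of repeats (default 20, the evaluation protocol).
#' @param method `"holdout"` (default) or `"oob"`.
#' @return Object of class `boost_evaluation`: `per_run` data frame,
#'   `summary` (mean and sd of the three rates, percent), `auc`,
#'   `importance` (mean over runs), `importance_rank`.
#' @export
evaluate_repeated <- function(X, y, runs = 20, M = 50, base_depth = 2,
                              seed = 1L, method = c("holdout", "oob")) {
  method <- match.arg(method)
  if (runs < 2) stop("runs must be >= 2")
  X <- as.matrix(X)
  if (is.factor(y)) y <- ifelse(y == levels(y)[2], 1, -1)
  N <- nrow(X)
  per_run <- data.frame(run = seq_len(runs), misclassification = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_)
  imp <- matrix(0, runs, ncol(X),
                dimnames = list(NULL, colnames(X)))
  pooled_scores <- numeric(0)
  pooled_y <- numeric(0)
  for (r in seq_len(runs)) {
    run_seed <- as.integer(seed) + r - 1L
    if (method == "oob") {
      model <- train_discrete_adaboost(X, y, M = M, base_depth = base_depth,
                                       bagging = TRUE, seed = run_seed)
      score <- numeric(N)
      covered <- logical(N)
      for (m in seq_len(model$M)) {
        oob <- setdiff(seq_len(N), model$bags[[m]])
        if (!length(oob)) next
        covered[oob] <- TRUE
        score[oob] <- score[oob] + model$coefficients[m] *
          .predict_tree(model$trees[[m]], X[oob, , drop = FALSE])
      }
      eval_idx <- which(covered)
      if (length(eval_idx) < N)
        message(sprintf("run %d: %d points never out-of-bag were excluded",
                        r, N - length(eval_idx)))
      sc <- score[eval_idx]; yy <- y[eval_idx]
    } else {
      test <- .with_seed(run_seed * 1000L + 7L,
                         sample.int(N, max(2, round(N / 3))))
      if (length(unique(y[test])) < 2 || length(unique(y[-test])) < 2) {
        message(sprintf("run %d: degenerate single-class split, skipped", r))
        next
      }
      model <- train_discrete_adaboost(X[-test, , drop = FALSE], y[-test],
                                       M = M, base_depth = base_depth,
                                       bagging = TRUE, seed = run_seed)
      sc <- predict(model, X[test, , drop = FALSE], type = "score")
      yy <- y[test]
    }
    pred <- ifelse(sc > 0, 1, -1)
    per_run$misclassification[r] <- 100 * mean(pred != yy)
    per_run$sensitivity[r] <- 100 * mean(pred[yy == 1] == 1)
    per_run$specificity[r] <- 100 * mean(pred[yy == -1] == -1)
    imp[r, ] <- variable_importance(model)
    pooled_scores <- c(pooled_scores, sc)
    pooled_y <- c(pooled_y, yy)
  }
  ok <- !is.na(per_run$misclassification)
  summ <- data.frame(
    metric = c("misclassification", "sensitivity", "specificity"),
    mean = c(mean(per_run$misclassification[ok]), mean(per_run$sensitivity[ok]),
             mean(per_run$specificity[ok])),
    sd = c(sd(per_run$misclassification[ok]), sd(per_run$sensitivity[ok]),
           sd(per_run$specificity[ok])))
  mean_imp <- colMeans(imp[ok, , drop = FALSE])
  structure(list(per_run = per_run, summary = summ,
                 auc = roc_auc(pooled_scores, pooled_y),
                 importance = mean_imp,
                 importance_rank = names(sort(mean_imp, decreasing = TRUE)),
                 runs = runs, M = M, method = method),
            class = "boost_evaluation")
}

#' @export
print.boost_evaluation <- function(x, ...) {
  cat(sprintf("Discrete AdaBoost evaluation (%d runs of %d rounds, %s):\n",
              x$runs, x$M, x$method))
  with(x$summary, cat(sprintf("  %-18s %5.1f +/- %.1f %%\n", metric, mean, sd),
                      sep = ""))
  cat(sprintf("  AUC = %.3f\n", x$auc))
  cat("  importance rank:", paste(x$importance_rank, collapse = " > "), "\n")
  invisible(x)
}
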