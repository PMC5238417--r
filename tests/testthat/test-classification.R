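test_that("boosting trace matches the independent round-by-round oracle", {
  # 8-point one-dimensional set, stumps, bagging off; expected weighted
  # errors, coefficients and weight vectors computed with a brute-force
  # minimum-error stump trainer run outside the package
  X <- matrix(1:8, ncol = 1)
  y <- c(1, 1, -1, 1, -1, -1, 1, -1)
  model <- train_discrete_adaboost(X, y, M = 3, base_depth = 1,
                                   bagging = FALSE, keep_weights = TRUE)
  expect_equal(model$errors, c(0.25, 0.25, 1 / 3), tolerance = 1e-12)
  expect_equal(model$coefficients, c(log(3), log(3), log(2)),
               tolerance = 1e-12)
  expect_equal(model$weight_history[1, ],
               c(1, 1, 1, 3, 1, 1, 3, 1) / 12, tolerance = 1e-12)
  expect_equal(model$weight_history[2, ],
               c(1, 1, 3, 3, 3, 3, 3, 1) / 18, tolerance = 1e-12)
  expect_equal(model$weight_history[3, ],
               c(1, 1, 3, 6, 3, 3, 6, 1) / 24, tolerance = 1e-12)
})

test_that("a single stump with weighted error 1/4 earns coefficient ln 3", {
  X <- matrix(1:4, ncol = 1)
  y <- c(-1, -1, 1, -1)
  model <- train_discrete_adaboost(X, y, M = 1, base_depth = 1,
                                   bagging = FALSE)
  expect_equal(model$errors[1], 0.25)
  expect_equal(model$coefficients[1], log(3), tolerance = 1e-12)
})

test_that("separable data is fit perfectly in one round", {
  set.seed(3)
  x <- c(runif(20, -2, -0.1), runif(20, 0.1, 2))
  y <- ifelse(x < 0, -1, 1)
  model <- train_discrete_adaboost(matrix(x, ncol = 1), y, M = 1,
                                   base_depth = 1, bagging = FALSE)
  expect_equal(predict(model, matrix(x, ncol = 1)), y)
  # a perfect round gets the capped, finite coefficient
  expect_true(is.finite(model$coefficients[1]))
  expect_equal(model$errors[1], 0)
})

test_that("weights stay a probability vector and the exponential bound holds", {
  co <- generate_cohort(cohort_spec(), seed = 33)
  f <- cohort_features(co, "composition+anamnesis")
  y <- ifelse(f$y == "malignant", 1, -1)
  model <- train_discrete_adaboost(f$X, y, M = 20, seed = 34,
                                   keep_weights = TRUE)
  expect_true(all(abs(rowSums(model$weight_history) - 1) < 1e-12))
  expect_true(all(model$weight_history >= 0))
  # training error of the partial ensemble vs Pi_m 2 sqrt(err (1 - err))
  scores <- numeric(nrow(f$X))
  for (m in seq_len(model$M)) {
    scores <- scores + model$coefficients[m] *
      optimammo:::.predict_tree(model$trees[[m]], f$X)
    train_err <- mean(ifelse(scores > 0, 1, -1) != y)
    bound <- prod(2 * sqrt(model$errors[1:m] * (1 - model$errors[1:m])))
    expect_lte(train_err, bound + 1e-12)
  }
})

test_that("prediction is the sign of the additive score with benign ties", {
  set.seed(41)
  X <- matrix(rnorm(40 * 3), 40)
  y <- ifelse(X[, 1] + 0.5 * rnorm(40) > 0, 1, -1)
  model <- train_discrete_adaboost(X, y, M = 7, seed = 42)
  sc <- predict(model, X, type = "score")
  cl <- predict(model, X)
  expect_equal(as.numeric(cl), ifelse(sc > 0, 1, -1))
  # single learner predicts exactly as its tree
  m1 <- train_discrete_adaboost(X, y, M = 1, seed = 43)
  expect_equal(as.numeric(predict(m1, X)),
               optimammo:::.predict_tree(m1$trees[[1]], X))
  # negating all coefficients flips every non-tied prediction
  m2 <- m1
  m2$coefficients <- -m2$coefficients
  expect_equal(as.numeric(predict(m2, X)), -as.numeric(predict(m1, X)))
})

test_that("ROC sweep AUC equals the pairwise concordance estimator", {
  set.seed(51)
  for (i in 1:5) {
    y <- sample(c(-1, 1), 60, replace = TRUE)
    sc <- rnorm(60) + y * runif(1, 0, 1.5)
    sc[sample(60, 10)] <- round(sc[sample(60, 10)], 1)   # some ties
    conc <- mean(outer(sc[y > 0], sc[y < 0],
                       function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(sc, y), conc, tolerance = 1e-12)
  }
})

test_that("variable importance is normalized and finds the informative axis", {
  set.seed(61)
  runs <- 60
  hits <- 0
  for (r in seq_len(runs)) {
    X <- matrix(rnorm(80 * 6), 80)
    y <- ifelse(X[, 1] + 0.3 * rnorm(80) > 0, 1, -1)
    model <- train_discrete_adaboost(X, y, M = 10, seed = 1000 + r)
    imp <- variable_importance(model)
    expect_equal(sum(imp), 1, tolerance = 1e-12)
    expect_true(all(imp >= 0))
    if (which.max(imp) == 1) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.95)
})

test_that("a variable never split on carries zero importance", {
  X <- cbind(x1 = c(-(1:10), 1:10), dead = rep(0, 20))
  y <- rep(c(-1, 1), each = 10)
  model <- train_discrete_adaboost(X, y, M = 3, base_depth = 2,
                                   bagging = FALSE)
  expect_equal(unname(variable_importance(model)["dead"]), 0)
})

test_that("repeated evaluation is perfect on a noiseless separable cohort", {
  set.seed(71)
  X <- matrix(rnorm(120 * 4), 120,
              dimnames = list(NULL, paste0("V", 1:4)))
  y <- ifelse(X[, 1] > 0, 1, -1)
  ev <- evaluate_repeated(X, y, runs = 3, M = 10, seed = 72)
  expect_equal(ev$summary$mean, c(0, 100, 100), tolerance = 1e-9)
  expect_equal(ev$auc, 1)
  expect_equal(ev$importance_rank[1], "V1")
})

test_that("training, prediction and importance are seed-reproducible", {
  co <- generate_cohort(cohort_spec(), seed = 81)
  f <- cohort_features(co, "composition+anamnesis")
  m1 <- train_discrete_adaboost(f$X, f$y, M = 15, seed = 82)
  m2 <- train_discrete_adaboost(f$X, f$y, M = 15, seed = 82)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(predict(m1, f$X, type = "score"),
                   predict(m2, f$X, type = "score"))
  expect_identical(variable_importance(m1), variable_importance(m2))
  ev1 <- evaluate_repeated(f$X, f$y, runs = 3, M = 10, seed = 83)
  ev2 <- evaluate_repeated(f$X, f$y, runs = 3, M = 10, seed = 83)
  expect_identical(ev1$summary, ev2$summary)
})

test_that("JSON serialization round-trips a trained model", {
  set.seed(91)
  X <- matrix(rnorm(50 * 3), 50)
  colnames(X) <- c("a", "b", "c")
  y <- ifelse(X[, 2] > 0.2, 1, -1)
  model <- train_discrete_adaboost(X, y, M = 6, seed = 92)
  path <- tempfile(fileext = ".json")
  write_boost_model(model, path)
  back <- read_boost_model(path)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(predict(back, X, type = "score"),
               predict(model, X, type = "score"))
})
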