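make_feature_data <- function(n_per_class, classes = 1:5, sep = 3, seed = 1) {
  set.seed(seed)
  labels <- rep(classes, each = n_per_class)
  x <- cbind(labels * sep + rnorm(length(labels)),
             rnorm(length(labels)))
  list(x = x, labels = labels)
}

test_that("OVO task construction covers all pairs in the canonical order", {
  d <- make_feature_data(6)
  tasks <- make_ovo_tasks(d$x, d$labels)
  expect_length(tasks, 10)
  expect_equal(names(tasks), c("1-5", "2-5", "1-4", "3-5", "2-4",
                               "1-3", "4-5", "3-4", "2-3", "1-2"))
  t34 <- tasks[["3-4"]]
  expect_equal(nrow(t34$x), 12)
  expect_setequal(unique(t34$y), c(0L, 1L))

  two <- make_ovo_tasks(d$x[d$labels %in% 1:2, ], d$labels[d$labels %in% 1:2])
  expect_length(two, 1)
  expect_error(make_ovo_tasks(d$x[d$labels == 1, ], d$labels[d$labels == 1]),
               "two classes")
})

test_that("stratified folds partition every sample and balance classes", {
  y <- rep(1:2, c(40, 20))
  f <- stratified_folds(y, 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_equal(length(f), 60)
  expect_true(all(table(f, y)[, "1"] == 4))
  expect_true(all(table(f, y)[, "2"] == 2))
})

test_that("split protocol fractions are validated and applied", {
  expect_error(split_protocol(0.8, 0.1, 0.2), "sum to 1")
  sp <- split_protocol(seed = 2)
  task <- make_ovo_tasks(make_feature_data(40)$x[1:80, ],
                         rep(1:2, each = 40))[["1-2"]]
  s <- thermofoot:::make_split(80, task$y, sp)
  expect_equal(sort(c(s$train, s$val, s$test)), 1:80)
  expect_equal(length(s$test), 8)   # 10% of 80, stratified
  expect_equal(length(s$val), 4)
})

test_that("SVM separates linearly separable features perfectly", {
  d <- make_feature_data(30, classes = c(1, 5), sep = 5)
  task <- make_ovo_tasks(d$x, d$labels)[["1-5"]]
  fit <- fit_svm(task, split_protocol(seed = 4))
  expect_equal(fit$test_accuracy, 1)
  # duplicating every sample leaves the margin (and predictions) unchanged
  task2 <- task
  task2$x <- rbind(task$x, task$x); task2$y <- c(task$y, task$y)
  fit2 <- fit_svm(task2, split_protocol(seed = 4))
  expect_equal(fit2$test_accuracy, 1)
})

test_that("MLP reaches perfect accuracy on separable pairs and is seeded", {
  d <- make_feature_data(30, classes = c(2, 4), sep = 6)
  task <- make_ovo_tasks(d$x, d$labels)[["2-4"]]
  f1 <- fit_mlp(task, split_protocol(seed = 7))
  f2 <- fit_mlp(task, split_protocol(seed = 7))
  expect_equal(f1$test_accuracy, 1)
  expect_identical(f1$val_accuracy, f2$val_accuracy)
})

test_that("indistinguishable classes score near chance under cross-validation", {
  set.seed(30)
  x <- matrix(rnorm(200 * 2), 200, 2)     # features carry no class signal
  labels <- rep(1:2, each = 100)
  tab <- evaluate_baseline(x, labels, model = "svm",
                           protocol = split_protocol(seed = 5))
  expect_lt(abs(tab["1-2", "accuracy"] - 0.5), 0.15)
})

test_that("cross-validated evaluation yields a full metrics table", {
  d <- make_feature_data(24, classes = 1:3, sep = 4, seed = 9)
  tab <- evaluate_baseline(d$x, d$labels, model = "svm",
                           protocol = split_protocol(seed = 1, cv_folds = 4))
  expect_equal(rownames(tab), c("1-3", "2-3", "1-2", "Average"))
  metric_cols <- c("sensitivity", "specificity", "precision", "accuracy",
                   "f_measure", "auc")
  expect_true(all(tab[, metric_cols] >= 0 & tab[, metric_cols] <= 1))
  # well-separated pair is classified perfectly
  expect_equal(tab["1-3", "accuracy"], 1)
})
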