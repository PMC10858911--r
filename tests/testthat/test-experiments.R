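fold_fixture <- function() {
  tibble::tibble(
    species = rep(c("A", "B"), c(150, 50)),
    bits = "10011"
  )
}

test_that("stratified folds keep train/val/test disjoint with equalized classes", {
  ds <- fold_fixture()
  folds <- stratified_folds(ds, k = 12, seed = 3)
  expect_equal(nrow(folds), 12L)
  for (f in seq_len(12)) {
    train <- folds$train[[f]]; val <- folds$val[[f]]; test <- folds$test[[f]]
    expect_length(intersect(train, test), 0)
    expect_length(intersect(val, test), 0)
    expect_length(intersect(train, val), 0)
    # equalized class counts in train and in val
    expect_equal(length(unique(table(ds$species[train]))), 1L)
    expect_equal(length(unique(table(ds$species[val]))), 1L)
    # raw 10% split preserves class ratios within one sequence
    raw <- folds$raw_test[[f]]
    expect_equal(sum(ds$species[raw] == "A"), 15, tolerance = 1)
    expect_equal(sum(ds$species[raw] == "B"), 5, tolerance = 1)
    # everything is somewhere
    expect_equal(sort(c(train, val, test)), seq_len(nrow(ds)))
  }
  # across folds, every sequence is tested at least once
  expect_equal(sort(unique(unlist(folds$raw_test))), seq_len(nrow(ds)))
  expect_error(stratified_folds(ds, k = 60), ">= 60")
})

test_that("undersampling equalizes class counts without replacement", {
  ds <- fold_fixture()
  eq <- undersample_equalize(ds, seed = 9)
  expect_equal(as.integer(table(eq$species)), c(50L, 50L))
  expect_equal(undersample_equalize(ds, seed = 9), eq)
})

test_that("weighted metrics match hand computations", {
  m <- weighted_metrics(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
  expect_equal(m$precision, 5 / 6, tolerance = 1e-9)
  expect_equal(m$recall, 0.75)
  expect_equal(m$accuracy, 0.75)
  perfect <- weighted_metrics(c("A", "B"), c("A", "B"))
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, accuracy = 1))
  onesided <- weighted_metrics(rep("A", 4), c("A", "A", "B", "B"))
  expect_equal(onesided$recall, 0.5)
})

test_that("weighted metrics agree with a tally oracle on random instances", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    classes <- LETTERS[1:sample(2:4, 1)]
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    got <- weighted_metrics(pred, truth)
    want <- oracle_weighted_metrics(pred, truth)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$accuracy, want$accuracy)
  }
})

test_that("confusion matrices are row-normalized with recall on the diagonal", {
  perfect <- confusion_matrix(c("A", "B"), c("A", "B"))
  expect_equal(unname(diag(perfect)), c(1, 1))
  m <- confusion_matrix(c("B", "A", "B"), c("A", "A", "B"))
  expect_equal(unname(m["A", ]), c(0.5, 0.5))
  expect_equal(unname(m["B", ]), c(0, 1))
  expect_equal(unname(rowSums(m)), c(1, 1))
})

test_that("one-vs-rest ROC curves behave at the extremes", {
  mk_preds <- function(scores_a) {
    tibble::tibble(probs = lapply(scores_a, function(p) c(A = p, B = 1 - p)))
  }
  truth <- rep(c("A", "B"), each = 10)
  perfect <- roc_curves(mk_preds(c(runif(10, 0.6, 1), runif(10, 0, 0.4))), truth)
  expect_equal(perfect$auc, c(1, 1))
  curve <- perfect$curve[[1]]
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))

  set.seed(33)
  n <- 600
  truth2 <- sample(c("A", "B"), n, replace = TRUE)
  rand <- roc_curves(mk_preds(runif(n)), truth2)
  expect_equal(rand$auc[1], 0.5, tolerance = 0.07)

  missing <- roc_curves(mk_preds(runif(5)), rep("A", 5))
  expect_true(is.na(missing$auc[missing$species == "B"]))
})
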