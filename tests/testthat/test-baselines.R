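test_that("the Jaccard score uses summed-mass union (identical inputs score 0.5)", {
  expect_equal(jaccard_score(c(1, 1, 0), c(1, 1, 0)), 0.5)
  expect_equal(jaccard_score(c(1, 0), c(0, 1)), 0)
  expect_equal(jaccard_score(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.25)
  expect_equal(jaccard_score(c(0, 0), c(0, 0, 0)), 0)
  # bounded by 0.5 for binary inputs
  set.seed(9)
  for (i in 1:30) {
    a <- as.numeric(runif(sample(2:20, 1)) < 0.5)
    b <- as.numeric(runif(sample(2:20, 1)) < 0.5)
    expect_lte(jaccard_score(a, b), 0.5)
  }
})

test_that("the dot score sums products over the overlapping prefix", {
  expect_equal(dot_score(c(1, 0, 1), c(1, 1, 1)), 2)
  expect_equal(dot_score(c(1, 1, 0, 1), rep(0, 4)), 0)
  a <- c(1, 0, 1, 1, 0, 1)
  expect_equal(dot_score(a, a), sum(a))
})

test_that("DTW matches hand-computed tables and basic identities", {
  expect_equal(dtw_distance(c(1, 0), c(0, 1)), 2)
  expect_equal(dtw_distance(c(1, 1, 0), c(1, 0)), 0)
  set.seed(21)
  for (i in 1:15) {
    a <- as.numeric(runif(sample(1:12, 1)) < 0.5)
    b <- as.numeric(runif(sample(1:12, 1)) < 0.5)
    expect_equal(dtw_distance(a, a), 0)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
  }
})

test_that("DTW agrees with exhaustive warping-path enumeration (lengths <= 4)", {
  for (M in 1:4) {
    for (N in 1:4) {
      A <- all_binary_rows(M)
      B <- all_binary_rows(N)
      oracle <- oracle_dtw_all_pairs(A, B)
      for (i in seq_len(nrow(A))) {
        for (j in seq_len(nrow(B))) {
          expect_equal(dtw_distance(A[i, ], B[j, ]), oracle[i, j])
        }
      }
    }
  }
})

test_that("softmax is stable, shift-invariant, and sums to 1", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  s <- c(1.3, -0.2, 4)
  expect_equal(softmax(s), softmax(s + 100))
  expect_equal(sum(softmax(s * 50)), 1)
  expect_equal(softmax(-c(0, 2)), c(0.8808, 0.1192), tolerance = 1e-4)
  expect_equal(softmax(-c(0, 2, 4)), c(0.8668, 0.1173, 0.0159),
               tolerance = 1e-3)
  expect_error(softmax(c(1, NA)), "finite")
})

test_that("reference classification predicts the matching species", {
  refs <- tibble::tibble(
    species = c("A", "B", "C"),
    values = list(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0), c(0, 0, 0, 0, 1, 1))
  )
  # noiseless encodings of the references themselves (trimmed to end on 1)
  out <- classify_by_reference(c("11", "110011"), refs, metric = "jaccard")
  expect_equal(out$predicted[1], "A")
  for (p in out$probs) expect_equal(sum(p), 1)

  # all scores equal -> uniform probabilities, first label wins
  same <- tibble::tibble(species = c("B", "A"), values = list(c(1, 1), c(1, 1)))
  tie <- classify_by_reference("11", same, metric = "dot")
  expect_equal(tie$predicted, "A")
  expect_equal(unname(tie$probs[[1]]), c(0.5, 0.5))

  expect_error(classify_by_reference("11", refs, metric = "cosine"))
})

test_that("DTW-based classification favors the nearest reference", {
  refs <- tibble::tibble(species = c("long", "short"),
                         values = list(rep(c(1, 0), 10), c(1, 0, 1)))
  out <- classify_by_reference("101", refs, metric = "dtw")
  expect_equal(out$predicted, "short")
  expect_true(all(out$confidence > 0.5))
})

test_that("SVM features are (count, mean duration, mean gap)", {
  f <- svm_features(paste0("111", "000", "111"))
  expect_equal(unlist(f), c(n_flashes = 2, mean_duration_s = 0.1,
                            mean_gap_s = 0.1))
  bits <- paste(rep(strrep("1", 4), 10), collapse = strrep("0", 26))
  f2 <- svm_features(bits)
  expect_equal(f2$n_flashes, 10L)
  expect_equal(f2$mean_duration_s, 4 / 30, tolerance = 1e-9)
  expect_equal(f2$mean_gap_s, 26 / 30, tolerance = 1e-9)
  expect_error(svm_features("111"), "at least 2 flashes")
})

test_that("a radial SVM separates disjoint-parameter species", {
  train <- two_species_dataset(40, seed = 31)
  fit <- train_svm(train, seed = 1)
  pr <- predict(fit, train)
  expect_equal(mean(pr$predicted == train$species), 1)
  for (p in pr$probs) expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_equal(glance(fit)$n_species, 2L)
  one <- train[train$species == "A", ]
  expect_error(train_svm(one), "at least 2 species")
})
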