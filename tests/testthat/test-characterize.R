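test_that("the confidence filter keeps the top correctly classified sequences", {
  ds <- tibble::tibble(species = c("A", "A", "B"), bits = c("101", "101", "11"))
  preds <- tibble::tibble(predicted = c("A", "A", "A"),
                          confidence = c(0.5, 0.9, 0.99))
  top <- top_confident_subset(ds, preds, n = 2)
  expect_equal(nrow(top), 2L)
  expect_equal(top$confidence, c(0.9, 0.5))

  # fewer correct than n: all of them
  top_all <- top_confident_subset(ds, preds, n = 100)
  expect_equal(nrow(top_all), 2L)

  none <- tibble::tibble(predicted = c("B", "B", "A"),
                         confidence = c(0.9, 0.9, 0.9))
  expect_warning(out <- top_confident_subset(ds, none), "no correct")
  expect_equal(nrow(out), 0L)
})

test_that("the confidence filter matches a direct sort of the prediction table", {
  set.seed(23)
  n <- 200
  ds <- tibble::tibble(species = sample(c("A", "B", "C"), n, replace = TRUE),
                       bits = replicate(n, random_bits(7)))
  preds <- tibble::tibble(
    predicted = sample(c("A", "B", "C"), n, replace = TRUE),
    confidence = round(runif(n), 2)  # rounded to force ties
  )
  got <- top_confident_subset(ds, preds, n = 50)
  # oracle: explicit (p, index) list, filter, order, index
  c_list <- data.frame(p = preds$confidence, idx = seq_len(n))
  c_list <- c_list[preds$predicted == ds$species, ]
  c_list <- c_list[order(-c_list$p, c_list$idx), ]
  want_idx <- head(c_list$idx, 50)
  expect_equal(got$bits, ds$bits[want_idx])
  expect_equal(got$confidence, preds$confidence[want_idx])
})

test_that("characterization of deterministic sequences is exact", {
  bits <- sample_sequence(species_params("X", 3, 0, 0.3, 0, 0.1, 0), seed = 1)
  expect_equal(nchar(bits), 27L)
  ds <- tibble::tibble(bits = rep(bits, 10))
  ch <- characterize_population(ds, population = "X")
  g <- glance(ch)
  expect_equal(g$n_flashes_mean, 3)
  expect_equal(g$gap_s_mean, 0.3)
  expect_equal(g$duration_s_mean, 0.1)
  expect_equal(c(g$n_flashes_sd, g$gap_s_sd, g$duration_s_sd), c(0, 0, 0))
  h <- tidy(ch)
  for (s in unique(h$statistic)) {
    expect_equal(sum(h$mass[h$statistic == s]), 1)
  }
  expect_error(characterize_population(ds[0, ]), "at least one")
})

test_that("synthetic populations recover their generative means", {
  pc <- preset_table2()
  pop <- generate_population(pc[pc$name == "P. carolinus, TN, Jun. 2020", ],
                             10000, seed = 101)
  g <- glance(characterize_population(pop))
  expect_equal(g$n_flashes_mean, 7.2, tolerance = 0.1 / 7.2)
  expect_equal(g$gap_s_mean, 0.42, tolerance = 0.02 / 0.42)
  expect_equal(g$duration_s_mean, 0.14, tolerance = 0.02 / 0.14)
})

test_that("literature comparison reports deltas and n/a where unpublished", {
  bits <- sample_sequence(species_params("X", 9, 0, 0.37, 0, 0.2333333, 0),
                          seed = 1)
  ch <- characterize_population(tibble::tibble(bits = bits))
  cmp <- compare_to_literature(ch, "P. carolinus")
  expect_equal(cmp$delta[cmp$statistic == "n_flashes"], 0)
  expect_equal(cmp$delta[cmp$statistic == "gap_s"], 0, tolerance = 1 / 60)

  cmp_bw <- compare_to_literature(ch, "B. wickershamorum")
  expect_true(all(is.na(cmp_bw$literature)))
  expect_true(all(is.na(cmp_bw$delta)))
})

test_that("characterization CSV output round-trips", {
  ds <- tibble::tibble(bits = c("1100011", "101011"))
  ch <- characterize_population(clean_short_gaps(ds), population = "pop")
  h <- withr::local_tempfile(fileext = ".csv")
  s <- withr::local_tempfile(fileext = ".csv")
  write_characterization(ch, h, s)
  back <- readr::read_csv(h, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tidy(ch)))
  expect_equal(readr::read_csv(s, show_col_types = FALSE)$n_sequences, 2)
})
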