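test_that("frame counts convert to seconds at 30 fps", {
  expect_equal(frames_to_seconds(30, 30), 1.0)
  expect_equal(frames_to_seconds(6, 30), 0.2)
  expect_equal(frames_to_seconds(1366, 30), 45.53, tolerance = 1e-3)
  expect_equal(round(frames_to_seconds(1366, 30), 1), 45.5)
  expect_equal(frames_to_seconds(0), 0)
  expect_error(frames_to_seconds(10, 0), "positive")
  expect_error(frames_to_seconds(-1), "non-negative")
})

make_events <- function(frame, x, y = 0, z = 0, rec = "r1") {
  tibble::tibble(recording_id = rec, frame = frame, x = x, y = y, z = z)
}

test_that("consecutive nearby detections join one streak, others split", {
  one <- link_streaks(make_events(c(0, 1), c(0, 0.05)), radius_m = 0.2)
  expect_equal(length(unique(one$streak)), 1L)

  far <- link_streaks(make_events(c(0, 1), c(0, 1.0)), radius_m = 0.2)
  expect_equal(length(unique(far$streak)), 2L)

  gap <- link_streaks(make_events(c(0, 5), c(0, 0)), radius_m = 10)
  expect_equal(length(unique(gap$streak)), 2L)

  expect_error(link_streaks(make_events(0, 0), radius_m = -1), "positive")
})

test_that("streaks link into trajectories under the 1 s / 1 m rule", {
  # A ends frame 10 at x=0; B starts frame 25 at x=0.5 (0.5 s, 0.5 m)
  ab <- make_events(c(8:10, 25:26), c(0, 0, 0, 0.5, 0.5))
  tr <- link_trajectories(link_streaks(ab))
  expect_equal(length(unique(tr$trajectory)), 1L)

  # same but B starts frame 56: 46 frames = 1.53 s gap
  ab2 <- make_events(c(8:10, 56:57), c(0, 0, 0, 0.5, 0.5))
  tr2 <- link_trajectories(link_streaks(ab2))
  expect_equal(length(unique(tr2$trajectory)), 2L)

  # transitivity: A~B and B~C but A-C distant
  abc <- make_events(c(0, 20, 40), c(0, 0.9, 1.8))
  tr3 <- link_trajectories(link_streaks(abc))
  expect_equal(length(unique(tr3$trajectory)), 1L)
})

test_that("trajectory linkage partitions the streaks", {
  set.seed(7)
  ev <- make_events(sort(sample(0:80, 40, replace = TRUE)),
                    runif(40, 0, 5), runif(40, 0, 5), runif(40, 0, 2))
  st <- link_streaks(ev)
  tr <- link_trajectories(st)
  expect_equal(nrow(tr), nrow(ev))
  expect_false(any(is.na(tr$trajectory)))
  # each streak belongs to exactly one trajectory
  map <- unique(tr[, c("streak", "trajectory")])
  expect_equal(nrow(map), length(unique(st$streak)))
})

test_that("binary sequences span first to last flash", {
  ev <- make_events(c(100:102, 110:111), rep(0, 5))
  sq <- trajectories_to_sequences(link_trajectories(link_streaks(ev)))
  expect_equal(nrow(sq), 1L)
  expect_equal(sq$bits, "111000000011")
  expect_equal(sq$start_frame, 100L)

  single <- trajectories_to_sequences(
    link_trajectories(link_streaks(make_events(0:3, rep(0, 4)))))
  expect_equal(single$bits, "1111")

  # length equals frame span + 1, start/end with 1
  set.seed(3)
  ev2 <- make_events(sort(sample(0:50, 12)), rep(0, 12))
  sq2 <- trajectories_to_sequences(link_trajectories(link_streaks(ev2)))
  for (b in sq2$bits) {
    expect_match(b, "^1")
    expect_match(b, "1$")
  }
})

test_that("short-gap cleaning fills 1-2 bit gaps, keeps longer ones, idempotent", {
  expect_equal(clean_short_gaps("101"), "111")
  expect_equal(clean_short_gaps("1001"), "1111")
  expect_equal(clean_short_gaps("10001"), "10001")
  set.seed(11)
  for (i in 1:25) {
    b <- random_bits(sample(3:40, 1))
    cl <- clean_short_gaps(b)
    expect_equal(clean_short_gaps(cl), cl)   # idempotent
    ones <- function(s) sum(fireflash:::bits_to_vec(s))
    expect_gte(ones(cl), ones(b))            # never removes light
  }
})

test_that("single-flash thresholding keeps only multi-flash sequences", {
  ds <- tibble::tibble(bits = c("11011", "111", "101", "1111111"))
  cleaned <- clean_short_gaps(ds)
  kept <- filter_single_flash(cleaned)
  expect_equal(nrow(kept), 0L)  # all gaps here are 1-bit, so all merge to one flash
  ds2 <- tibble::tibble(bits = c("110001", "111", "10001"))
  expect_equal(filter_single_flash(ds2)$bits, c("110001", "10001"))
})

test_that("rare species are removed and label map rebuilt", {
  ds <- tibble::tibble(species = rep(c("A", "B"), c(150, 99)),
                       bits = "101")
  out <- filter_rare_species(ds, min_count = 100)
  expect_equal(unique(out$species), "A")
  expect_equal(nrow(out), 150L)
  expect_equal(nrow(filter_rare_species(ds, min_count = 1)), 249L)
  lm <- make_label_map(out)
  expect_equal(lm$species, "A")
})

test_that("sequence statistics count flashes, durations and gaps", {
  bits <- paste0("111", strrep("0", 9), strrep("1", 6))
  st <- sequence_stats(bits)
  expect_equal(st$n_flashes, 2L)
  expect_equal(st$flash_durations_s[[1]], c(0.1, 0.2))
  expect_equal(st$gaps_s[[1]], 0.3)

  st2 <- sequence_stats("11111")
  expect_equal(st2$n_flashes, 1L)
  expect_equal(st2$mean_duration_s, 5 / 30)
  expect_equal(length(st2$gaps_s[[1]]), 0L)
  expect_true(is.na(st2$mean_gap_s))

  # invariants on random sequences: |gaps| = n - 1, on-mass preserved
  set.seed(5)
  for (i in 1:20) {
    b <- clean_short_gaps(random_bits(sample(5:60, 1)))
    s <- sequence_stats(b)
    expect_equal(length(s$gaps_s[[1]]), s$n_flashes - 1L)
    expect_equal(sum(s$flash_durations_s[[1]]) * 30,
                 sum(fireflash:::bits_to_vec(b)))
  }
})
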