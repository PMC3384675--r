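test_that("the phase-only filter has unit magnitude on the object's spectral support", {
  set.seed(5)
  obj <- encode_object(rand_seq(300), width = 20)
  filt <- pof(obj, frame_width = 20, frame_height = 20)
  mag <- Mod(filt)
  on_support <- mag > 0
  expect_true(all(abs(mag[on_support] - 1) < 1e-12))
  ## deterministic: same object, same filter bit-for-bit
  expect_identical(filt, pof(obj, 20, 20))
})

test_that("POF of an origin impulse is the constant unit zero-phase filter", {
  impulse <- matrix(0, 8, 8); impulse[1, 1] <- 1
  filt <- pof(impulse, 8, 8)
  expect_equal(unclass(filt), matrix(1 + 0i, 8, 8), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("degenerate all-zero object yields a flagged all-zero filter, never NaN", {
  expect_warning(filt <- pof(matrix(0, 4, 4), 4, 4), "all-zero")
  expect_equal(unclass(filt), matrix(0i, 4, 4), ignore_attr = TRUE)
  expect_false(anyNA(filt))
  expect_equal(attr(filt, "zero_frequencies"), 16)
})

test_that("objects larger than the frame are rejected", {
  expect_error(pof(matrix(1, 5, 5), 4, 4), "does not fit")
  expect_error(correlate(matrix(1, 4, 4), matrix(1 + 0i, 5, 5)), "filter is")
})

test_that("frequency-domain matched-filter correlation equals the brute-force spatial oracle", {
  set.seed(11)
  for (trial in 1:5) {
    s <- matrix(sample(c(0, 85, 170, 255), 64, TRUE), 8, 8)
    o <- matrix(sample(c(0, 85, 170, 255), 64, TRUE), 8, 8)
    plane <- correlate(s, cmf(o, 8, 8))
    ## the normalized inverse transform of S * conj(O) IS the plain
    ## circular cross-correlation sum, so no extra scaling appears here
    oracle <- brute_circular_xcorr(s, o)
    expect_equal(plane$values, abs(oracle), tolerance = 1e-9)
  }
})

test_that("a zero filter gives a zero plane", {
  s <- matrix(runif(64), 8, 8)
  expect_equal(correlate(s, matrix(0i, 8, 8))$values, matrix(0, 8, 8))
})

test_that("find_peak matches an exhaustive scan and breaks ties row-first", {
  single <- matrix(0, 5, 5); single[3, 4] <- 2
  pk <- find_peak(single)
  expect_equal(c(pk$row, pk$col, pk$intensity), c(2, 3, 2))
  flat <- matrix(1, 4, 6)
  expect_equal(unlist(find_peak(flat)[c("row", "col")]), c(row = 0, col = 0))
  set.seed(3)
  for (trial in 1:20) {
    ## integer-valued planes force ties
    v <- matrix(sample(0:5, 100 * 100, TRUE), 100, 100)
    got <- find_peak(v); want <- brute_peak(v)
    expect_equal(got$intensity, want$intensity)
    expect_equal(c(got$row, got$col), c(want$row, want$col))
  }
})

test_that("an embedded object's peak recovers its raster position (first-half columns)", {
  set.seed(21)
  for (trial in 1:60) {
    L <- sample(100:500, 1)
    r <- sample(0:40, 1)
    c <- sample(0:40, 1)         # start column clearly in the first half
    q <- rand_seq(L)
    scene <- scene_with_embedding(q, at = r * 100 + c)
    pk <- find_peak(correlate(scene, pof(encode_object(q, 100), 100, 100)))
    expect_equal(c(pk$row, pk$col), c(r, c),
                 label = sprintf("L=%d r=%d c=%d", L, r, c))
  }
})

test_that("second-half-column embeddings err by zero or exactly one row of bases", {
  set.seed(22)
  shifts <- integer(0)
  for (trial in 1:60) {
    L <- sample(300:3000, 1)
    r <- sample(0:((10000 - L) %/% 100 - 1), 1)
    c <- sample(c(0:39, 60:99), 1)   # keep clear of the 50/50 wrap tie
    at <- r * 100 + c
    q <- rand_seq(L)
    scene <- scene_with_embedding(q, at = at)
    d <- detect(scene, encode_object(q, 100), threshold = 0)
    err <- d$est_start_base - at
    expect_true(err %in% c(0, 100),
                label = sprintf("error %d at L=%d col=%d", err, L, at %% 100))
    ## the flag predicts the error direction; correction undoes it
    expect_equal(d$shift_flag, err == 100)
    d2 <- detect(scene, encode_object(q, 100), threshold = 0,
                 shift_correct = TRUE)
    expect_equal(d2$est_start_base, at)
    shifts <- c(shifts, err)
  }
  ## both regimes occur under random placement
  expect_gt(sum(shifts == 100), 5)
  expect_gt(sum(shifts == 0), 5)
})

test_that("detection decisions respect the threshold contract", {
  set.seed(23)
  q <- rand_seq(400)
  scene <- scene_with_embedding(q, at = 1210)
  obj <- encode_object(q, 100)
  expect_false(detect(scene, obj, threshold = Inf)$present)
  expect_error(detect(scene, obj, threshold = -1), ">= 0")
  pk <- find_peak(correlate(scene, pof(obj, 100, 100)))
  expect_true(detect(scene, obj, threshold = pk$intensity * 0.9)$present)
})

test_that("an absent object is rejected at a calibrated threshold in almost all trials", {
  set.seed(24)
  ## calibrate on a small labelled benchmark, then test on fresh scenes
  bench <- run_correlation_benchmark(db_size = 1e5, n_queries = 30,
                                     noise_levels = 0, seed = 99)
  thr <- as.numeric(bench$threshold)
  fp <- 0; trials <- 300
  obj <- encode_object(rand_seq(800), 100)
  filt <- pof(obj, 100, 100)
  for (i in seq_len(trials)) {
    scene <- tile_database(rand_seq(10000), 100, 100)[[1]]
    if (max(correlate(scene, filt)$values) > thr) fp <- fp + 1
  }
  expect_lte(fp / trials, 0.01)
})

test_that("search deduplicates overlap hits and enforces the span guard", {
  expect_identical(search_scenes(list(), encode_object("ACGT", 4), 1), list())
  set.seed(25)
  db <- rand_seq(30000)
  q <- substr(db, 12011, 12410)  # 400 bp at 0-based start 12010 (col 10)
  obj <- encode_object(q, 100)
  scenes <- tile_database(db, 100, 100, overlap = 400)
  expect_error(search_scenes(scenes, encode_object(rand_seq(500), 100), 1),
               "overlap")
  pk_true <- max(correlate(scenes[[2]], pof(obj, 100, 100))$values)
  hits <- search_scenes(scenes, obj, threshold = pk_true * 0.8)
  expect_length(hits, length(scenes))
  found <- hits_table(hits)
  expect_equal(sum(found$present), 1)
  expect_equal(found$est_start_base[found$present], 12010)
})
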