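test_that("moving average reproduces the printed filtered cells", {
  expect_lt(abs(moving_average(c(73.46, 74.21, 75.25, 79.82, 79.67), 5) -
                  76.48), 0.005)
  expect_lt(abs(moving_average(c(77.6, 89.65, 126.0, 97.8, 111.68), 5) -
                  100.55), 0.005)
})

test_that("moving average basics: constants, bounds, edges", {
  expect_equal(moving_average(rep(3.7, 12), 5), rep(3.7, 8))
  expect_equal(moving_average(rep(3.7, 12), 5, edge_policy = "reflect"),
               rep(3.7, 12))

  set.seed(11)
  x <- rnorm(40)
  out <- moving_average(x, 5)
  expect_length(out, 36)
  for (j in seq_along(out)) {
    expect_gte(out[j], min(x[j:(j + 4)]))
    expect_lte(out[j], max(x[j:(j + 4)]))
    expect_equal(out[j], mean(x[j:(j + 4)]))
  }

  expect_error(moving_average(rnorm(3), 5), "shorter")
  expect_error(moving_average(rnorm(10), 4), "window")
  expect_equal(moving_average(x, 1), x)
})

test_that("gaussian kernel is normalised and smoothing preserves constants", {
  for (sg in c(0.5, 1, 2, 3)) {
    k <- gaussian_kernel(sg, truncate = 4)
    expect_equal(sum(k), 1)
    expect_length(k, 2 * ceiling(4 * sg) + 1)
    expect_equal(k, rev(k))  # symmetric
  }
  expect_equal(gaussian_smooth(rep(5.5, 30), sigma = 2), rep(5.5, 30))
  # unit impulse under reflect padding: mass conserved away from edges
  imp <- c(rep(0, 20), 1, rep(0, 20))
  expect_equal(sum(gaussian_smooth(imp, sigma = 2)), 1, tolerance = 1e-12)
  expect_error(gaussian_smooth(1:10, sigma = 0), "sigma")
})

test_that("gaussian smoothing equals the direct convolution oracle", {
  set.seed(22)
  for (sg in c(1, 2)) {
    x <- rnorm(60)
    w <- gaussian_kernel(sg, truncate = 4)
    expect_equal(gaussian_smooth(x, sigma = sg, edge_policy = "reflect"),
                 conv_loop_oracle(x, w), tolerance = 1e-12)
    h <- (length(w) - 1L) %/% 2L
    full <- conv_loop_oracle(x, w)[(h + 1):(60 - h)]
    expect_equal(gaussian_smooth(x, sigma = sg, edge_policy = "complete_only"),
                 full, tolerance = 1e-12)
  }
})

test_that("alignment oracle places filtered tables at offset +1 of raw block means", {
  pairs <- list(c("raw_resting", "ma_resting"),
                c("raw_walking", "ma_walking"),
                c("raw_running", "ma_running"))
  for (p in pairs) {
    raw <- load_fixture(p[1])
    filt <- load_fixture(p[2])
    for (ch in session_channels) {
      fit <- best_offset(raw[[ch]], filt[[ch]][1:25], w = 5L)
      expect_equal(fit$offset, 1)
      expect_lte(fit$max_dev, 0.005)
      # the winning offset is decisive, not a near-tie artefact
      expect_gt(sort(fit$all)[2], 0.005)
    }
  }
})

test_that("printed filtered rows equal block means of raw rows i+1..i+5", {
  pairs <- list(c("raw_resting", "ma_resting"),
                c("raw_walking", "ma_walking"),
                c("raw_running", "ma_running"))
  for (p in pairs) {
    raw <- load_fixture(p[1])
    filt <- load_fixture(p[2])
    for (ch in session_channels) {
      block <- block_mean_oracle(raw[[ch]], 5L)  # block[j] = mean raw[j..j+4]
      expect_lte(max(abs(filt[[ch]][1:25] - block[2:26])), 0.005)
    }
  }
})

test_that("smooth_session smooths channels but never the alert column", {
  ma <- filter_spec("moving_average", window = 5)
  sm_rest <- smooth_session(load_fixture("raw_resting"), ma)
  expect_lt(abs(sm_rest$hr_bpm[2] - 76.48), 0.005)
  sm_walk <- smooth_session(load_fixture("raw_walking"), ma)
  expect_lt(abs(sm_walk$hr_bpm[2] - 83.18), 0.005)
  expect_equal(nrow(sm_rest), 26)

  run <- load_fixture("raw_running")
  sm_run <- smooth_session(run, filter_spec("moving_average",
                                            edge_policy = "reflect"))
  expect_equal(sm_run$alert, run$alert)  # carried, not smoothed
  expect_equal(session_phase(sm_run), "running")

  ident <- smooth_session(run, filter_spec("moving_average", window = 1))
  expect_equal(tibble::as_tibble(ident), tibble::as_tibble(run),
               ignore_attr = TRUE)
})

test_that("both filters reduce heart-rate variance on the running fixture", {
  run <- load_fixture("raw_running")
  for (spec in list(filter_spec("moving_average", edge_policy = "reflect"),
                    filter_spec("gaussian", edge_policy = "reflect"))) {
    expect_lt(var(smooth_session(run, spec)$hr_bpm), var(run$hr_bpm))
  }
})
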