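test_that("artifact filtering applies strict validity limits", {
  s <- physio_series(t = 1:6, v = c(12, 85, 80, 0.0, 79.9, -3), agg = 1)
  out <- filter_artifacts(s, "ICP")
  expect_equal(is.na(out$v), c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(attr(out, "n_removed"), 4L)
  expect_equal(attr(out, "removed_t"), c(2, 3, 4, 6))

  m <- physio_series(t = 1:3, v = c(399.9, 400, 70), agg = 1)
  expect_equal(is.na(filter_artifacts(m, "MAP")$v), c(FALSE, TRUE, FALSE))

  clean <- physio_series(t = 1:5, v = seq(10, 14), agg = 1)
  expect_equal(filter_artifacts(clean, "ICP")$v, clean$v)
  expect_error(filter_artifacts(clean, "CPP"), "unknown signal_kind")
})

test_that("drainage removal uses half-open intervals and merges overlaps", {
  s <- physio_series(t = c(9.5, 10, 19.9, 20), v = c(10, 11, 12, 13), agg = 1)
  out <- remove_drainage(s, cbind(10, 20))
  expect_equal(is.na(out$v), c(FALSE, TRUE, TRUE, FALSE))

  expect_equal(remove_drainage(s, NULL)$v, s$v)
  expect_true(all(is.na(remove_drainage(s, cbind(0, 100))$v)))

  # overlapping intervals merge rather than error
  out2 <- remove_drainage(s, rbind(c(10, 15), c(12, 20)))
  expect_equal(is.na(out2$v), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("artifact filtering and drainage removal commute", {
  rec <- small_record(rho = 0.4, days = 1, seed = 31, monitor = "EVD",
                      drain = rbind(c(100, 160), c(700, 730)))
  icp <- inject_artifacts(rec$icp, rate = 30, seed = 99, signal_kind = "ICP")
  ab <- remove_drainage(filter_artifacts(icp, "ICP"), rec$drainage_intervals)
  ba <- filter_artifacts(remove_drainage(icp, rec$drainage_intervals), "ICP")
  expect_identical(is.na(ab$v), is.na(ba$v))
  expect_identical(ab$v, ba$v)
})

test_that("regularize interpolates short gaps and is identity on-grid", {
  s <- physio_series(t = c(0, 2), v = c(10, 12), agg = 1)
  out <- regularize(s)
  expect_equal(out$v[out$t == 1], 11)

  reg <- physio_series(t = 1:60, v = sin(1:60) + 80, agg = 1)
  expect_equal(regularize(reg)$v, reg$v, tolerance = 1e-15)
  expect_equal(regularize(reg)$t, reg$t)

  # a 30-min gap with max_gap 5 stays missing inside
  g <- physio_series(t = c(1, 2, 32, 33), v = c(1, 2, 3, 4), agg = 1)
  out <- regularize(g, max_gap_minutes = 5)
  expect_true(all(is.na(out$v[out$t %in% 3:31])))
  expect_equal(out$v[out$t %in% c(1, 2, 32, 33)], c(1, 2, 3, 4))

  expect_equal(nrow(regularize(physio_series())), 0L)
})

test_that("moving_pearson handles exact relations, constants and missingness", {
  x <- c(5, 1, 4, 2, 8, 3, 7, 2, 6, 4, 9, 1)
  expect_equal(moving_pearson(x, 2 * x + 3, 10)[10:12], rep(1, 3),
               tolerance = 1e-12)
  expect_equal(moving_pearson(x, -x + 100, 10)[10:12], rep(-1, 3),
               tolerance = 1e-12)

  # constant window emits missing, not zero
  xc <- c(rep(2, 15), x)
  r <- moving_pearson(xc, seq_along(xc), 10)
  expect_true(all(is.na(r[10:15])))
  expect_false(is.na(r[length(xc)]))

  expect_error(moving_pearson(x, x, 2), "at least 3")

  # nothing before minute = window length
  expect_true(all(is.na(moving_pearson(x, x + rnorm(12), 10)[1:9])))

  # with a 0.8 floor, n = 10 tolerates 2 missing pairs (k = 8) but not 3
  set.seed(42)
  a <- rnorm(30); b <- rnorm(30)
  a2 <- a; a2[c(12, 15)] <- NA
  expect_false(is.na(moving_pearson(a2, b, 10, min_valid_fraction = 0.8)[20]))
  a3 <- a; a3[c(12, 14, 15)] <- NA
  expect_true(is.na(moving_pearson(a3, b, 10, min_valid_fraction = 0.8)[20]))
  # the default floor requires a majority of pairs
  a4 <- a; a4[11:16] <- NA
  expect_true(is.na(moving_pearson(a4, b, 10)[20]))
})

test_that("moving_pearson matches the textbook oracle on random windows", {
  set.seed(7)
  x <- rnorm(1500, mean = 80, sd = 4)
  y <- 0.4 * x + rnorm(1500, sd = 3) + 12
  x[sample(1500, 80)] <- NA
  y[sample(1500, 80)] <- NA
  for (n in c(10L, 30L, 90L)) {
    r <- moving_pearson(x, y, n)
    idx <- which(!is.na(r))
    pick <- sample(idx, min(80, length(idx)))
    for (i in pick)
      expect_lt(abs(r[i] - naive_pearson(x[(i - n + 1):i], y[(i - n + 1):i])),
                1e-12)
  }
})

test_that("moving_pearson is invariant to positive affine maps", {
  set.seed(11)
  x <- rnorm(400, 80, 4); y <- 0.3 * x + rnorm(400, sd = 2)
  r1 <- moving_pearson(x, y, 15)
  r2 <- moving_pearson(2.5 * x + 7, 0.3 * y + 1, 15)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("compute_lprx pipeline behaves on canonical inputs", {
  # perfect coupling, no independent noise (white or baseline wander):
  # every window correlation is +1
  p <- sim_params(noise_sd_icp = 0,
                  icp_wander = list(amplitude = 0, period_range = c(120, 480)),
                  sampling_interval_range = c(1, 1))
  rec <- small_record(rho = 1, days = 0.5, seed = 3, params = p)
  idx <- compute_lprx(rec, 10L)
  vals <- idx$lprx[!is.na(idx$lprx)]
  expect_gt(length(vals), 500)
  expect_true(all(vals > 1 - 1e-9))
  expect_true(all(idx$lprx >= -1 & idx$lprx <= 1, na.rm = TRUE))
  expect_true(all(is.na(idx$lprx[idx$t < 10])))

  # imputation is the identity on regularly sampled data
  idx_imp <- compute_lprx(rec, 10L, use_imputation = TRUE)
  expect_equal(idx$lprx, idx_imp$lprx, tolerance = 1e-12)

  # span shorter than the window: empty result with a warning
  set.seed(5)
  short <- list(icp = physio_series(t = 1:60, v = rnorm(60, 12), agg = 1),
                map = physio_series(t = 1:60, v = rnorm(60, 80), agg = 1))
  expect_warning(out <- compute_lprx(short, 120L), "shorter")
  expect_equal(nrow(out), 0L)

  expect_error(compute_lprx(rec, 25), "window_minutes")
})

test_that("patient mean LPRx_10 tracks the latent coupling at default noise", {
  p <- sim_params()
  means <- vapply(1:4, function(s) {
    rec <- small_record(rho = 0.5, days = 4, seed = 400 + s, params = p)
    mean(compute_lprx(rec, 10L)$lprx, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.1)
})

test_that("index series round-trips through CSV", {
  idx <- index_series(t = 1:20, lprx = c(rep(NA, 9), runif(11, -1, 1)),
                      window_minutes = 10L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_index_csv(idx, path)
  back <- read_index_csv(path)
  expect_equal(back$lprx, idx$lprx, tolerance = 1e-12)
  expect_equal(attr(back, "window_minutes"), 10L)
})
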