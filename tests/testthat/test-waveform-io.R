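test_that("waveform CSV reads with validated sampling and round-trips", {
  path <- write_record_fixture(n = 10000, fs = 1000)
  rec <- read_waveform_csv(path, config = list(fs = 1000))
  expect_s3_class(rec, "waveform_record")
  expect_equal(nrow(rec), 10000)
  expect_equal(record_fs(rec), 1000)
  expect_equal(record_duration(rec), 10)

  out <- tempfile(fileext = ".csv")
  write_waveform_csv(rec, out)
  rec2 <- read_waveform_csv(out, config = list(fs = 1000))
  expect_equal(rec2$bp, rec$bp)
  expect_equal(rec2$ppg, rec$ppg)
  expect_equal(rec2$time, rec$time)
})

test_that("reader rejects structurally broken files", {
  path <- write_record_fixture(n = 500)
  df <- readr::read_csv(path, show_col_types = FALSE)

  # missing channel, named in the error
  p1 <- tempfile(fileext = ".csv")
  readr::write_csv(df[setdiff(names(df), "ppg")], p1, progress = FALSE)
  expect_error(read_waveform_csv(p1), "ppg", class = "artstiff_format_error")

  # duplicated timestamp
  p2 <- tempfile(fileext = ".csv")
  df2 <- df; df2$time[10] <- df2$time[9]
  readr::write_csv(df2, p2, progress = FALSE)
  expect_error(read_waveform_csv(p2), class = "artstiff_format_error")
})

test_that("short NaN gaps are interpolated, long gaps are a data error", {
  path <- write_record_fixture(n = 2000, fs = 1000)
  df <- readr::read_csv(path, show_col_types = FALSE)

  p1 <- tempfile(fileext = ".csv")
  df1 <- df; df1$bp[100:110] <- NA   # 11 ms gap, under the 20 ms default
  readr::write_csv(df1, p1, progress = FALSE, na = "NA")
  expect_warning(rec <- read_waveform_csv(p1), "interpolated")
  expect_true(all(is.finite(rec$bp)))
  # linear interpolation between the gap edges
  expect_equal(rec$bp[105], (df$bp[99] + df$bp[111]) / 2, tolerance = 1e-6)

  p2 <- tempfile(fileext = ".csv")
  df2 <- df; df2$ppg[100:200] <- NA  # 101 ms gap
  readr::write_csv(df2, p2, progress = FALSE, na = "NA")
  expect_error(read_waveform_csv(p2), class = "artstiff_data_error")
})

test_that("reader rejects randomized invariant violations", {
  set.seed(101)
  for (k in 1:10) {
    path <- write_record_fixture(n = 500)
    df <- readr::read_csv(path, show_col_types = FALSE)
    mode <- sample(c("nonuniform", "backwards", "inf_bp", "inf_ppg"), 1)
    i <- sample(5:400, 1)
    if (mode == "nonuniform") df$time[i:500] <- df$time[i:500] + 0.4e-3
    if (mode == "backwards") df$time[i] <- df$time[i] - 2e-3
    if (mode == "inf_bp") df$bp[i:(i + 49)] <- Inf     # 50 ms, over gap limit
    if (mode == "inf_ppg") df$ppg[i:(i + 49)] <- -Inf
    p <- tempfile(fileext = ".csv")
    readr::write_csv(df, p, progress = FALSE)
    cnd <- tryCatch(suppressWarnings(read_waveform_csv(p, config = list(fs = 1000))),
                    condition = function(c) c)
    expect_true(inherits(cnd, "artstiff_format_error") ||
                  inherits(cnd, "artstiff_data_error"),
                label = paste("rejects corruption:", mode))
  }
})

test_that("beat-estimate tables round-trip and reject empty input", {
  est <- tibble::tibble(
    beat = 1:3, start_sample = c(1L, 858L, 1715L),
    end_sample = c(858L, 1715L, 2572L), t0_sample = c(1L, 858L, 1715L),
    t0 = c(0, 0.857, 1.714), rr = rep(0.857, 3), mean_bp = c(88.1, 87.9, 88.3),
    mu = runif(3), eta = runif(3), beta_A = runif(3) * 100,
    beta = c(1.5, 1.52, 1.49), intercept = rep(4.09, 3),
    r2 = c(0.999, 0.95, 0.89), accepted = c(TRUE, TRUE, FALSE),
    n_masked = c(300L, 310L, 280L), ref_shifted = c(FALSE, FALSE, TRUE),
    note = NA_character_)
  path <- tempfile(fileext = ".csv")
  write_beat_estimates(est, path)
  expect_identical(length(readLines(path)), 4L)  # header + 3 rows
  back <- read_beat_estimates(path)
  for (col in c("mu", "eta", "beta_A", "beta", "r2"))
    expect_equal(signif(back[[col]], 12), signif(est[[col]], 12))
  expect_equal(back$accepted, est$accepted)
  expect_error(write_beat_estimates(est[0, ], tempfile()),
               class = "artstiff_io_error")
})
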