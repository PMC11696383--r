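test_that("recording validates monotone uniform time and finite values", {
  r <- recording(c(0, 1, 2), c(1, 1, 1), "potential_mV")
  expect_length(r, 3L)
  expect_equal(r$sampling_interval, 1)

  expect_error(recording(c(0, 1, 1), c(1, 2, 3), "potential_mV"),
               "row 3")
  expect_error(recording(c(0, 1, 2), c(1, NA, 3), "potential_mV"),
               "non-finite")
  expect_error(recording(c(0, 1, 2.5), c(1, 2, 3), "potential_mV"),
               "non-uniform")
  expect_error(recording(0:2, 1:2, "potential_mV"), "equal length")
})

test_that("read/write round trip is the identity on recordings", {
  set.seed(11)
  n <- 10000L
  rec <- recording(seq(0, n - 1) * 0.5, rnorm(n, 2, 3), "potential_mV",
                   label = "Q")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, "potential_mV")
  expect_identical(back$values, rec$values)
  expect_identical(back$times, rec$times)
  expect_identical(back$label, "Q")
  expect_equal(back$sampling_interval, 0.5)
})

test_that("recording CSV reader handles headers, metadata and bad input", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("time_s,potential_mV", "0,1.0", "1,1.0", "2,1.0"), path)
  r <- read_recording(path, "potential_mV")
  expect_length(r, 3L)
  expect_equal(r$sampling_interval, 1)
  expect_equal(r$values, rep(1, 3))

  writeLines(c("0,1.0", "1,2.0"), path)  # headerless dialect
  expect_equal(read_recording(path, "potential_mV")$values, c(1, 2))

  writeLines(c("time_s,potential_mV", "0,1", "1,x"), path)
  expect_error(read_recording(path, "potential_mV"),
               "non-numeric value at data row 2")

  writeLines(c("0,1", "1,2", "1,3"), path)
  expect_error(read_recording(path, "potential_mV"), "row 3")

  writeLines(character(0), path)
  expect_error(read_recording(path, "potential_mV"), "empty")

  # empty recording writes header only and reads back empty
  write_recording(recording(numeric(0), numeric(0), "temperature_C"), path)
  expect_identical(readLines(path), "time_s,temperature_C")
  expect_length(read_recording(path, "temperature_C"), 0L)
})

test_that("packaged profile table matches an independent transcription", {
  tab <- suppressWarnings(load_profile_table())
  expect_s3_class(tab, "profile_table")
  expect_identical(tab$label, LETTERS)

  # spot rows re-typed independently from the published tables
  expect_equal(unname(unlist(tab["D", -1])),
               c(13.23, 15.63, 20.65, 17.26, 42.73, 7.54, 6.75,
                 10296.75, 11064.00, 12970.00, 11755.72, 18677.00, 1646.00,
                 2764.74))
  expect_equal(unname(unlist(tab["O", -1])),
               c(2.58, 3.40, 4.20, 3.76, 10.77, 1.56, 1.85,
                 708.75, 800.00, 1036.25, 916.48, 2143.00, 430.00, 297.24))
  expect_equal(unname(unlist(tab["A", -1])),
               c(2.09, 2.49, 3.13, 2.65, 5.46, 1.81, 0.72,
                 677.75, 847.00, 1873.75, 2034.88, 14558.00, 667.00, 2613.48))
  expect_equal(tab["Z", "amp_sd"], 7.72)
  expect_equal(tab["B", "per_sd"], 3220.38)
  expect_equal(tab["H", "per_mean"], 11816.00)

  # column checksums across the second transcription of the mean columns
  amp_means <- c(2.65, 2.98, 3.97, 17.26, 8.71, 4.96, 9.48, 15.62, 7.67,
                 4.67, 5.22, 16.95, 5.52, 6.64, 3.76, 8.73, 7.88, 3.71,
                 13.25, 8.67, 11.86, 8.13, 9.71, 8.29, 3.30, 7.17)
  expect_equal(tab$amp_mean, amp_means)
})

test_that("profile table validation reports missing letters and bad rows", {
  tab <- load_profile_table(check = "none")

  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[tab$label != "Q", ], path, row.names = FALSE)
  expect_error(load_profile_table(path), "missing profile: Q")

  # the published 'H' period row has q2 > q3; default check warns, strict errors
  expect_warning(load_profile_table(), "row 'H'")
  expect_error(load_profile_table(check = "error"), "row 'H'")

  bad <- tab
  bad$amp_q1[bad$label == "C"] <- 99  # q1 above q2
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_profile_table(path, check = "error"), "row 'C'")
})

test_that("stats_summary and character_profile enforce their invariants", {
  s <- stats_summary(1, 2, 3, 2.2, 5, 0, 0.5, n = 10L)
  expect_s3_class(s, "stats_summary")
  expect_error(stats_summary(3, 2, 1, 2, 5, 0, 0.5), "ordering")
  expect_error(stats_summary(1, 2, 3, 9, 5, 0, 0.5), "outside")
  expect_error(stats_summary(1, 2, 3, 2, 5, 0, -1), "sd")
  expect_error(character_profile("AB", s, s), "A-Z")
})
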