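test_that("database has the full factorial of recordings with correct shape", {
  db <- tiny_db()
  expect_length(db, 2 * 3 * 3)
  expect_true(all(vapply(db, function(r) nrow(r$samples) == 500, logical(1))))
  expect_true(all(vapply(db, function(r) ncol(r$samples) == 2, logical(1))))
  expect_true(all(vapply(db, function(r) all(is.finite(r$samples)),
                         logical(1))))
  meta <- database_metadata(db)
  expect_equal(nrow(unique(meta[c("subject", "movement", "repetition")])),
               length(db))

  one <- generate_database(database_spec(n_subjects = 1, movements = "M",
                                         n_reps = 1, n_channels = 1,
                                         fs = 250, duration = 1.3,
                                         rest_lead = 0.1, rest_label = NA,
                                         seed = 1))
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]$samples), round(250 * 1.3))
})

test_that("generation is seed-deterministic and seed-sensitive", {
  a <- tiny_db(seed = 5)
  b <- tiny_db(seed = 5)
  c <- tiny_db(seed = 6)
  expect_identical(a[[1]]$samples, b[[1]]$samples)
  expect_identical(a[[10]]$samples, b[[10]]$samples)
  expect_false(identical(a[[1]]$samples, c[[1]]$samples))
})

test_that("invalid specs are rejected", {
  expect_error(database_spec(n_subjects = 0), "n_subjects")
  expect_error(database_spec(fs = -1), "fs")
  expect_error(database_spec(rest_lead = 8, duration = 7), "rest_lead")
  expect_error(database_spec(movements = c("A", "A")), "distinct")
  expect_error(generate_database(list()), "database_spec")
})

test_that("rest class is near baseline and movement classes activate their channels", {
  db <- tiny_db()
  fm <- extract_features(db, "MAV", trim_start = 0.2)
  mav_ch1 <- fm$values[, "ch1_MAV"]
  cls <- fm$meta$movement
  # class A maps to channel 1 at full gain; rest stays at baseline
  expect_true(min(mav_ch1[cls == "A"]) > max(mav_ch1[cls == "RR"]))
  mav_ch2 <- fm$values[, "ch2_MAV"]
  expect_true(min(mav_ch2[cls == "B"]) > max(mav_ch2[cls == "RR"]))
})

test_that("single-recording CSV round trip preserves samples and metadata", {
  db <- tiny_db()
  rec <- db[[4]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_lt(max(abs(back$samples - rec$samples)), 1e-9)
  expect_equal(as.character(back$movement), as.character(rec$movement))
  expect_equal(as.numeric(back$subject), as.numeric(rec$subject))
  expect_equal(back$repetition, rec$repetition)
  expect_equal(back$fs, rec$fs)
})

test_that("malformed recording files raise format errors naming the line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ch1,ch2", "0.1,0.2", "0.3"), path)
  expect_error(read_recording(path), "line 3")
  writeLines(character(0), path)
  expect_error(read_recording(path), "empty")
  writeLines(c("ch1,ch2", "0.1,abc", "0.2,0.3"), path)
  expect_error(read_recording(path), "non-numeric")
})

test_that("database directory round trip preserves everything", {
  db <- tiny_db()
  dir <- withr::local_tempdir()
  write_database(db, dir)
  back <- read_database(dir)
  expect_length(back, length(db))
  expect_lt(max(abs(back[[7]]$samples - db[[7]]$samples)), 1e-9)
  expect_identical(database_metadata(back)$movement,
                   database_metadata(db)$movement)
  expect_error(read_database(withr::local_tempdir()), "metadata.csv")
})
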