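test_that("packaged fixtures load with the printed values", {
  resting <- load_fixture("raw_resting")
  expect_s3_class(resting, "vital_session")
  expect_equal(nrow(resting), 30)
  expect_equal(resting$hr_bpm[1], 67.31)
  expect_equal(session_phase(resting), "resting")
  expect_equal(sample_period(resting), 1)

  running <- load_fixture("raw_running")
  expect_equal(running$hr_bpm[16], 160.32)
  expect_equal(running$alert[16], 1)
  expect_equal(sum(running$alert), 4)

  expect_error(load_fixture("gauss_running"), "unknown fixture")
  expect_error(load_fixture("nope"), "unknown fixture")
})

test_that("fixture registry lists exactly the eight shipped tables", {
  fx <- list_fixtures()
  expect_equal(nrow(fx), 8)
  expect_false("gauss_running" %in% fx$name)
  expect_setequal(unique(fx$filter), c("raw", "moving_average", "gaussian"))
  for (nm in fx$name) expect_s3_class(load_fixture(nm), "vital_session")
})

test_that("sessions round-trip through CSV cell-for-cell", {
  for (nm in list_fixtures()$name) {
    orig <- load_fixture(nm)
    tf <- withr::local_tempfile(fileext = ".csv")
    write_session(orig, tf)
    back <- read_session(tf, phase = session_phase(orig))
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(orig),
                 ignore_attr = TRUE)
  }
})

test_that("invalid session files are rejected with row-numbered errors", {
  expect_error(read_session(file.path(tempdir(), "does-not-exist.csv"),
                            phase = "resting"), "missing file")

  hdr <- "index,hr_bpm,spo2_pct,ambient_c,body_c,speed_cm_s,alert"
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(hdr, tf)
  expect_error(read_session(tf, phase = "resting"), "no samples")

  rows <- c(hdr, paste0(1:6, ",80,97,32,36,1,", c(0, 0, 0, 0, 2, 0)))
  writeLines(rows, tf)
  expect_error(read_session(tf, phase = "resting"), "alert.*row 5")

  writeLines(c("hr_bpm,spo2_pct,body_c,speed_cm_s,alert", "80,97,36,1,0"), tf)
  expect_error(read_session(tf, phase = "resting"), "missing column.*ambient_c")

  writeLines(c(hdr, "1,80,97,32,36,1,0", "2,abc,97,32,36,1,0"), tf)
  expect_error(read_session(tf, phase = "resting"), "row 2")

  writeLines(c("time_s,hr_bpm,spo2_pct,ambient_c,body_c,speed_cm_s,alert",
               "0,80,97,32,36,1,0", "2,80,97,32,36,1,0", "1,80,97,32,36,1,0"),
             tf)
  expect_error(read_session(tf, phase = "resting"), "strictly increasing")
})

test_that("session invariants reject out-of-range channels", {
  base <- tibble::tibble(hr_bpm = 80, spo2_pct = 97, ambient_c = 32,
                         body_c = 36, speed_cm_s = 1, alert = 0)
  expect_error(vital_session(dplyr::mutate(base, hr_bpm = 0)), "hr_bpm")
  expect_error(vital_session(dplyr::mutate(base, spo2_pct = 101)), "spo2_pct")
  expect_error(vital_session(dplyr::mutate(base, speed_cm_s = -1)), "speed_cm_s")
  expect_error(vital_session(base[0, ]), "no samples")
  expect_s3_class(vital_session(base), "vital_session")
})

test_that("node records carry every schema path once and round-trip", {
  resting <- load_fixture("raw_resting")
  rec <- as_node_record(resting[4, ])
  expect_equal(rec[["sensor/BPM"]], 75.25)
  expect_equal(rec[["sensor/SpO2"]], 97)
  expect_equal(rec[["sensor/alert"]], 0)
  expect_false(any(duplicated(names(rec))))

  running <- load_fixture("raw_running")
  expect_equal(as_node_record(running[16, ])[["sensor/alert"]], 1)

  imu <- tibble::tibble(gyro_x = 1.5, gyro_y = -2, gyro_z = 0.25,
                        acc_x = 0.1, acc_y = 0, acc_z = 1)
  rec2 <- as_node_record(resting[7, ], imu)
  back <- from_node_record(rec2, index = 7)
  expect_equal(back$sample, tibble::as_tibble(resting)[7, ],
               ignore_attr = TRUE)
  expect_equal(back$imu, imu)

  # serialisation bijection through JSON
  tf <- withr::local_tempfile(fileext = ".json")
  write_node_record(rec2, tf)
  expect_equal(read_node_record(tf), rec2)

  bad <- rec2
  bad[["sensor/alert"]] <- 2
  expect_error(validate_node_record(bad), "alert")
  expect_error(from_node_record(rec2[-1]), "missing path")
})
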