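test_that("CSV traces round-trip within 1e-9 uV", {
  tr <- trace(c(0, 1, -1, 123.456789123, -7e3), 250, label = "ch1")
  f <- withr::local_tempfile(fileext = ".csv")
  write_csv_trace(tr, f)
  back <- read_csv_trace(f, 250)
  expect_length(back$samples, length(tr$samples))
  expect_lt(max(abs(back$samples - tr$samples)), 1e-9)
})

test_that("CSV reader reports parse problems precisely", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("uv", "0", "1", "-1"), f)
  expect_length(read_csv_trace(f, 1000)$samples, 3)

  writeLines(character(), f)
  expect_error(read_csv_trace(f, 1000), "parse|data rows")

  writeLines(c("uv", "0", "oops", "2"), f)
  expect_error(read_csv_trace(f, 1000), "row 2")

  expect_error(read_csv_trace(file.path(tempdir(), "nope.csv"), 1000),
               "no such file")
})

test_that("WFDB records round-trip bit-exactly with channel order", {
  fs <- 500; gain <- 200
  # digital-exact values: multiples of 1000/gain microvolts
  set.seed(7)
  t1 <- trace(sample(-3000:3000, 400) * (1000 / gain), fs, label = "direct")
  t2 <- trace(sample(-3000:3000, 400) * (1000 / gain), fs, label = "abd 1")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rec01")
  write_wfdb_record(list(t1, t2), path, gain = gain)
  rs <- read_wfdb_record(path, direct_channel = 1L)
  expect_identical(rs$direct$samples, t1$samples)
  expect_identical(rs$abdominal[[1]]$samples, t2$samples)
  expect_equal(rs$metadata$fs, fs)
})

test_that("WFDB gain formula: digital 200 at gain 200 ADC/mV reads as 1000 uV", {
  # hand-crafted files: the oracle is the WFDB conversion (d - baseline)/gain mV
  dir <- withr::local_tempdir()
  writeLines(c("g 1 1000 4", "g.dat 16 200(0)/mV 16 0 200 0 0 sig"),
             file.path(dir, "g.hea"))
  writeBin(c(200L, 0L, -200L, 400L), file.path(dir, "g.dat"),
           size = 2L, endian = "little")
  rs <- read_wfdb_record(file.path(dir, "g"), direct_channel = NA)
  expect_equal(rs$abdominal[[1]]$samples, c(1000, 0, -1000, 2000))
})

test_that("annotations round-trip, including long (>1023 sample) gaps", {
  f <- withr::local_tempfile()
  idx <- c(10L, 500L, 1490L, 9000L)  # includes dt > 1023
  write_wfdb_annotation(idx, f)
  expect_equal(read_wfdb_annotation(f) + 1L, idx)
  expect_error(write_wfdb_annotation(c(10, 5), f), "strictly increasing")
})

test_that("a record with a non-increasing annotation series is rejected", {
  fs <- 250
  tr <- trace(sample(-100:100, 300, replace = TRUE) * 5, fs)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "r")
  write_wfdb_record(list(tr), path)
  # craft an annotation whose decoded indices are not increasing:
  # two zero increments give duplicated times
  bad <- as.raw(c(10, 4, 0, 4, 0, 0))  # NORMAL dt=10, NORMAL dt=0, end
  writeBin(bad, paste0(path, ".ann"))
  expect_error(read_wfdb_record(path, annotation_extension = "ann"),
               "strictly increasing")
  expect_error(read_wfdb_record(path, annotation_extension = "qrs"),
               "missing annotation")
})

test_that("decomposition writer emits conserved components + sidecar", {
  g <- periodic_ecg(duration_s = 10, fs = 250)
  noisy <- trace(g$tr$samples * 100 + rnorm(length(g$tr$samples), 0, 5),
                 g$tr$fs)
  dec <- extract_direct(noisy, g$rpeaks)
  out <- withr::local_tempdir()
  files <- write_decomposition(dec, out)
  side <- jsonlite::read_json(file.path(out, "decomposition.json"),
                              simplifyVector = TRUE)
  expect_true(side$conserved)
  expect_equal(side$n, length(dec$input$samples))
  expect_equal(unlist(side$components), rep(side$n, 3),
               ignore_attr = TRUE)
  dfecg <- read_csv_trace(file.path(out, "dfecg.csv"), side$fs)
  dn <- read_csv_trace(file.path(out, "dn.csv"), side$fs)
  input <- read_csv_trace(file.path(out, "input.csv"), side$fs)
  expect_lt(max(abs(dfecg$samples + dn$samples - input$samples)), 1e-6)
})
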