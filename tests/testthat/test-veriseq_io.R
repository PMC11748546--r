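test_that("run dates parse from YYMMDD prefixes with century pivot", {
  expect_equal(parse_run_date("201123_x.csv"), as.Date("2020-11-23"))
  expect_equal(parse_run_date("210115_runA.csv"), as.Date("2021-01-15"))
  expect_equal(parse_run_date("240229_x.csv"), as.Date("2024-02-29"))  # leap year
  expect_equal(parse_run_date("990101_x.csv"), as.Date("1999-01-01"))  # pivot
  expect_equal(parse_run_date("790101_x.csv"), as.Date("2079-01-01"))
  expect_error(parse_run_date("999999_x.csv"), class = "nipt_malformed_filename")
  expect_error(parse_run_date("210229_x.csv"), class = "nipt_malformed_filename")
  expect_error(parse_run_date("run_A.csv"), class = "nipt_malformed_filename")
  expect_error(parse_run_date("21011_x.csv"), class = "nipt_malformed_filename")
})

test_that("a written batch re-parses to an equal batch, FF as percent", {
  dir <- withr::local_tempdir()
  b <- make_batch(n = 16, run_qc = list(q30_pct = 96.5,
                                        cluster_density_k_mm2 = 180,
                                        library_conc_nM = c(20, 30)))
  b$samples[[1]]$ff <- 0.023
  path <- file.path(dir, b$source_filename)
  write_run_csv(b, path)
  reparsed <- parse_run_csv(path)
  expect_true(run_batch_equal(b, reparsed))
  expect_equal(reparsed$run_date, as.Date("2021-01-15"))
  expect_length(reparsed$samples, 16)

  # FF is serialized as percent: fraction 0.023 -> cell "2.3"
  raw <- read.csv(path, colClasses = "character")
  expect_equal(raw$FF[1], "2.3")

  # minimum capacity: a 1-sample batch round-trips too
  b1 <- make_batch(n = 1)
  p1 <- file.path(dir, b1$source_filename)
  write_run_csv(b1, p1)
  expect_true(run_batch_equal(b1, parse_run_csv(p1)))
})

test_that("round-trip holds over randomized batches (property)", {
  dir <- withr::local_tempdir()
  set.seed(4711)
  for (i in 1:10) {
    b <- random_batch(runid = sprintf("fz%02d", i))
    path <- file.path(dir, sprintf("210301_fz%02d.csv", i))
    write_run_csv(b, path)
    b2 <- parse_run_csv(path)
    # reparse under the actual filename identity
    b$run_id <- b2$run_id; b$source_filename <- b2$source_filename
    expect_true(run_batch_equal(b, b2))
  }
})

test_that("column order does not matter", {
  dir <- withr::local_tempdir()
  set.seed(11)
  b <- random_batch(n = 4)
  path <- file.path(dir, b$source_filename)
  write_run_csv(b, path)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  shuffled <- file.path(dir, "210301_shuffled.csv")
  set.seed(12)
  write.csv(df[, sample(names(df))], shuffled, row.names = FALSE)
  b2 <- parse_run_csv(shuffled)
  b$run_id <- "210301_shuffled"; b$source_filename <- "210301_shuffled.csv"
  expect_true(run_batch_equal(b, b2))
})

test_that("malformed files raise typed errors, never a partial batch", {
  dir <- withr::local_tempdir()
  b <- make_batch(n = 3)
  good <- file.path(dir, b$source_filename)
  write_run_csv(b, good)
  df <- read.csv(good, colClasses = "character", check.names = FALSE)
  rewrite <- function(d, name) {
    p <- file.path(dir, name)
    write.csv(d, p, row.names = FALSE)
    p
  }

  # no YYMMDD prefix
  file.copy(good, file.path(dir, "run_A.csv"))
  expect_error(parse_run_csv(file.path(dir, "run_A.csv")),
               class = "nipt_malformed_filename")

  # missing required column, named in the message
  err <- expect_error(
    parse_run_csv(rewrite(df[, setdiff(names(df), "NCV_21")], "210115_m1.csv")),
    class = "nipt_schema_error")
  expect_match(conditionMessage(err), "NCV_21")

  # no NCD columns at all
  expect_error(
    parse_run_csv(rewrite(df[, !grepl("^NCD_", names(df))], "210115_m2.csv")),
    class = "nipt_schema_error")

  # non-numeric cell, located by row and column
  bad <- df; bad$NCV_18[2] <- "oops"
  err <- expect_error(parse_run_csv(rewrite(bad, "210115_m3.csv")),
                      class = "nipt_value_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "NCV_18")

  # FF outside [0, 100] percent
  bad <- df; bad$FF[1] <- "150"
  expect_error(parse_run_csv(rewrite(bad, "210115_m4.csv")),
               class = "nipt_value_error")

  # duplicate sample ids
  bad <- df; bad$SampleID[2] <- bad$SampleID[1]
  expect_error(parse_run_csv(rewrite(bad, "210115_m5.csv")),
               class = "nipt_duplicate_sample")

  # zero sample rows
  expect_error(parse_run_csv(rewrite(df[0, ], "210115_m6.csv")),
               class = "nipt_empty_run")

  # capacity exceeded: 17 rows
  over <- df[rep(1, 17), ]
  over$SampleID <- sprintf("S%02d", 1:17)
  expect_error(parse_run_csv(rewrite(over, "210115_m7.csv")),
               class = "nipt_schema_error")

  # empty / non-CSV file
  writeLines(character(0), file.path(dir, "210115_empty.csv"))
  expect_error(parse_run_csv(file.path(dir, "210115_empty.csv")),
               class = "nipt_error")
  expect_error(parse_run_csv(file.path(dir, "210115_absent.csv")),
               class = "nipt_io_error")
})

test_that("unknown columns are preserved in vendor_qc", {
  dir <- withr::local_tempdir()
  b <- make_batch(n = 2)
  path <- file.path(dir, b$source_filename)
  write_run_csv(b, path)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  df$VendorFlag <- c("WARN", "")
  p2 <- file.path(dir, "210115_vendor.csv")
  write.csv(df, p2, row.names = FALSE)
  b2 <- parse_run_csv(p2)
  expect_equal(unname(b2$samples[[1]]$vendor_qc["VendorFlag"]), "WARN")
  # and round-trips through write
  p3 <- file.path(dir, "210115_vendor2.csv")
  write_run_csv(b2, p3)
  b3 <- parse_run_csv(p3)
  b2$run_id <- b3$run_id; b2$source_filename <- b3$source_filename
  expect_true(run_batch_equal(b2, b3))
})

test_that("record invariants are enforced", {
  expect_error(make_sample(id = ""), class = "nipt_validation_error")
  expect_error(make_sample(ncv = c("13" = 0, "18" = 0, "21" = 0, "X" = 0)),
               class = "nipt_validation_error")
  expect_error(make_sample(ff = 1.2), class = "nipt_validation_error")
  expect_error(make_sample(coverage = stats::setNames(rep(-1, 24),
                                                      c(as.character(1:22), "X", "Y"))),
               class = "nipt_validation_error")
  expect_error(make_batch(n = 0), class = "nipt_validation_error")
  expect_error(make_batch(n = 2, ids = c("A", "A")),
               class = "nipt_duplicate_sample")
  # run_date must agree with the filename prefix
  expect_error(run_batch("x", as.Date("2021-01-16"),
                         list(make_sample()), list(), "210115_x.csv"),
               class = "nipt_validation_error")
})
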