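test_that("CSV tables read, convert units at the boundary, and round trip", {
  df <- data.frame(id = c("a", "b", "c"),
                   icv = c(1500.25, 1600.5, 1700.75),
                   caudate = c(3.125, 3.25, 3.5))
  p <- write_tmp_csv(df)
  vt <- read_volumes_table(p)
  expect_s3_class(vt, "volume_table")
  expect_equal(nrow(vt), 3)
  expect_equal(region_names(vt), "caudate")
  expect_equal(vt$icv, df$icv)

  # the same data expressed in mm^3 read with the mm3 flag is identical
  df_mm <- data.frame(id = df$id, icv = df$icv * 1000,
                      caudate = df$caudate * 1000)
  vt_mm <- read_volumes_table(write_tmp_csv(df_mm), unit = "mm3")
  expect_identical(vt_mm$icv, vt$icv)
  expect_identical(vt_mm$caudate, vt$caudate)

  # write -> read preserves full double precision
  set.seed(42)
  df2 <- data.frame(id = sprintf("s%d", 1:5),
                    icv = runif(5, 1400, 1800),
                    caudate = runif(5, 3, 4), putamen = runif(5, 3.5, 4.5))
  vt2 <- read_volumes_table(write_tmp_csv(df2))
  p2 <- tempfile(fileext = ".csv")
  write_volumes_table(vt2, p2)
  vt3 <- read_volumes_table(p2)
  expect_identical(vt3$icv, vt2$icv)
  expect_identical(vt3$caudate, vt2$caudate)
  expect_identical(vt3$putamen, vt2$putamen)

  # TSV by extension
  pt <- tempfile(fileext = ".tsv")
  utils::write.table(df, pt, sep = "\t", row.names = FALSE)
  expect_equal(read_volumes_table(pt)$icv, df$icv)
})

test_that("invalid rows are rejected per contract and structure errors raised", {
  # a bad ICV row is dropped with a report, the rest retained
  df <- data.frame(id = c("a", "b", "c", "d"),
                   icv = c(1500, -1, 1600, 1700),
                   caudate = c(3.1, 3.2, 3.3, 3.4))
  expect_message(vt <- read_volumes_table(write_tmp_csv(df)),
                 "dropped for missing/nonpositive ICV")
  expect_equal(nrow(vt), 3)
  expect_false("b" %in% vt$subject_id)

  # nonpositive region values become NA per region, subject retained
  df$icv <- abs(df$icv) * 1000 / 1000 + 1500  # all valid
  df$caudate[2] <- -5
  expect_message(vt2 <- read_volumes_table(write_tmp_csv(df)),
                 "nonpositive region value")
  expect_equal(nrow(vt2), 4)
  expect_true(is.na(vt2$caudate[2]))

  # dropping below 3 usable rows is an error
  df3 <- data.frame(id = c("a", "b", "c"), icv = c(1500, -1, 1600),
                    caudate = c(3.1, 3.2, 3.3))
  expect_error(suppressMessages(read_volumes_table(write_tmp_csv(df3))),
               "at least 3 subjects")

  # structural errors
  expect_error(read_volumes_table(
    write_tmp_csv(data.frame(id = letters[1:3], caudate = 1:3))), "ICV")
  expect_error(read_volumes_table(
    write_tmp_csv(data.frame(id = c("a", "a", "b"), icv = c(1, 2, 3) + 1500,
                             caudate = c(3, 3, 3)))), "[Dd]uplicate")
  expect_error(read_volumes_table(
    write_tmp_csv(data.frame(id = letters[1:3], icv = 1500:1502))),
    "no region columns")
})

test_that("FreeSurfer stats files parse with unit conversion and hemisphere handling", {
  aseg <- system.file("extdata", "synthetic_aseg.stats", package = "powerprop")
  vt <- read_freesurfer_stats(aseg, subject_id = "s1")
  expect_equal(vt$icv, 1600)                   # 1.6e6 mm^3 -> cc
  expect_equal(vt$caudate, 3.5)                # 1750 + 1750 mm^3 summed
  expect_equal(vt$putamen, 4.0)
  expect_equal(vt$hippocampus, 3.5)
  expect_equal(vt$csf, 0.95)

  # hemispheres kept separate on request
  vt2 <- read_freesurfer_stats(aseg, subject_id = "s1", hemi_sum = FALSE)
  expect_true(all(c("left_caudate", "right_caudate") %in% region_names(vt2)))
  expect_equal(vt2$left_caudate, 1.75)

  # aparc file has no ICV measure line: merged into an existing table,
  # the table's ICV is kept
  aparc <- system.file("extdata", "synthetic_aparc.stats",
                       package = "powerprop")
  vt3 <- read_freesurfer_stats(aparc, table = vt, subject_id = "s1")
  i <- match("s1", vt3$subject_id)
  expect_equal(vt3$icv[i], 1600)
  expect_equal(vt3$precuneus[i], 9.5)          # GrayVol 9500 mm^3
  expect_equal(vt3$caudate[i], 3.5)            # earlier regions preserved

  # errors: missing ColHeaders, missing measure column
  bad <- tempfile(fileext = ".stats")
  writeLines(c("# Title x", "1 2 3"), bad)
  expect_error(read_freesurfer_stats(bad, subject_id = "s1"), "ColHeaders")
  expect_error(read_freesurfer_stats(aseg, subject_id = "s1",
                                     measure = "GrayVol"),
               "measure column")
})

test_that("fit tables are written rounded for display with full precision kept", {
  d <- make_powerlaw_data(60, alpha = 0.002, beta = 0.8, sigma = 0.2,
                          seed = 11)
  vt <- volume_table(sprintf("s%d", 1:60), d$icv,
                     data.frame(putamen = d$voi))
  fits <- fit_all_regions(vt)
  p <- tempfile(fileext = ".csv")
  write_fit_table(fits, p)
  got <- utils::read.csv(p)
  expect_equal(names(got)[1:9],
               c("region", "n", "beta", "se", "ci_lower", "ci_upper",
                 "nonproportional_flag", "alpha", "sigma2"))
  expect_equal(got$beta, round(got$beta_full, 2))
  expect_equal(got$se, round(got$se_full, 2))
  expect_equal(got$beta_full, fits[["putamen"]]$beta_hat, tolerance = 1e-12)

  # an unconverged fit keeps its row, flagged
  broken <- fake_fit(c(0.5, 1.1), converged = FALSE)
  broken$region <- "broken"
  fl <- structure(list(putamen = fits[["putamen"]], broken = broken),
                  class = "power_law_fits")
  write_fit_table(fl, p)
  got2 <- utils::read.csv(p)
  expect_equal(nrow(got2), 2)
  expect_false(got2$converged[got2$region == "broken"])
  expect_true(is.na(got2$nonproportional_flag[got2$region == "broken"]))
})
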