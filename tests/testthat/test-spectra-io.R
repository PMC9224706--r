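test_that("CSV round trips are identities and orientation is normalized", {
  set.seed(42)
  wn <- seq(650, 700, by = 2)
  d <- ev_dataset(wn, matrix(runif(3 * length(wn)), 3), c("A", "B", "C"),
                  c("control", "control", "case"))

  for (fmt in c("csv_wide", "csv_long")) {
    path <- file.path(withr_tempdir <- tempdir(), paste0("rt_", fmt, ".csv"))
    write_spectra(d, path, fmt)
    back <- read_spectra(path, fmt)
    expect_equal(back$wavenumber, d$wavenumber, tolerance = 1e-12)
    expect_equal(back$absorbance, d$absorbance, tolerance = 1e-12)
    expect_equal(back$subject_id, d$subject_id)
    expect_equal(as.character(back$group), as.character(d$group))
  }

  # descending storage ingests to the identical ascending dataset
  desc <- data.frame(wavenumber = rev(wn), t(d$absorbance[, rev(seq_along(wn))]))
  names(desc) <- c("wavenumber", d$subject_id)
  p2 <- file.path(tempdir(), "desc.csv")
  utils::write.csv(desc, p2, row.names = FALSE, quote = FALSE)
  back2 <- read_spectra(p2, "csv_wide")
  expect_equal(back2$wavenumber, d$wavenumber)
  expect_equal(unname(back2$absorbance), unname(d$absorbance), tolerance = 1e-12)

  # long -> wide -> long preserves values
  pl <- file.path(tempdir(), "conv.csv")
  pw <- file.path(tempdir(), "conv_wide.csv")
  write_spectra(d, pl, "csv_long")
  write_spectra(read_spectra(pl, "csv_long"), pw, "csv_wide")
  expect_equal(read_spectra(pw, "csv_wide")$absorbance, d$absorbance,
               tolerance = 1e-12)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(ev_spectrum(c(1000, 1002, 1002, 1004), rep(1, 4)),
               "duplicated wavenumber value: 1002")
  expect_error(ev_spectrum(1:3, c(1, NA, 2)), "non-finite")
  expect_error(ev_spectrum(1:3, 1:2), "lengths differ")
  empty <- structure(
    list(wavenumber = seq(650, 654, 2),
         absorbance = matrix(numeric(0), 0, 3),
         subject_id = character(0),
         group = factor(character(0), levels = c("control", "case"))),
    class = "ev_dataset")
  expect_error(write_spectra(empty, tempfile(fileext = ".csv")), "empty")
  # missing labels: dataset is built, but group-wise operations refuse it
  wn <- seq(650, 700, 2)
  unl <- ev_dataset(wn, matrix(1 + runif(2 * length(wn)), 2), c("A", "B"))
  expect_true(all(is.na(unl$group)))
  expect_error(group_mean_spectrum(unl, "control"), "")
  expect_error(pca_lda_scores(unl, band("w", 660, 690)), "unknown group")
})

test_that("common_grid interpolates linearly and refuses disjoint ranges", {
  s1 <- ev_spectrum(seq(1000, 1100, 2), seq(1000, 1100, 2) * 0.01, "A", "control")
  s2 <- ev_spectrum(seq(1001, 1101, 2), seq(1001, 1101, 2) * 0.01, "B", "case")
  # identical grids pass through unchanged
  s1b <- ev_spectrum(seq(1000, 1100, 2), runif(51), "B2", "case")
  same <- common_grid(list(s1, s1b), step = 2)
  expect_equal(same$wavenumber, s1$wavenumber)
  expect_equal(unname(same$absorbance[1, ]), s1$absorbance)
  # linear interpolation is exact for linear spectra on offset grids
  mixed <- common_grid(list(s1, s2), step = 2)
  expect_equal(unname(mixed$absorbance[2, ]), mixed$wavenumber * 0.01,
               tolerance = 1e-12)
  s3 <- ev_spectrum(seq(2000, 2100, 2), rep(1, 51), "C", "case")
  expect_error(common_grid(list(s1, s3)), "overlap")
})

test_that("minimal JCAMP-DX tables are parsed with X/Y factors", {
  path <- file.path(tempdir(), "spec.jdx")
  writeLines(c(
    "##TITLE=S01",
    "##JCAMP-DX=4.24",
    "##XUNITS=1/CM",
    "##XFACTOR=1",
    "##YFACTOR=0.5",
    "##DELTAX=2",
    "##XYDATA=(X++(Y..Y))",
    "1000 2 4 6",
    "1006 8 10",
    "##END="
  ), path)
  d <- read_spectra(path, "jcampdx")
  expect_equal(d$wavenumber, seq(1000, 1008, 2))
  expect_equal(unname(d$absorbance[1, ]), c(1, 2, 3, 4, 5))
  expect_equal(d$subject_id, "S01")
})

test_that("replicate spectra average to one row per subject", {
  wn <- seq(1000, 1010, 2)
  reps <- list(
    ev_spectrum(wn, rep(0, 6), "A", "control"),
    ev_spectrum(wn, rep(2, 6), "A", "control"),
    ev_spectrum(wn, rep(1, 6), "B", "case")
  )
  d <- replicate_mean(reps)
  expect_equal(n_subjects(d), 2L)
  expect_equal(unname(d$absorbance["A", ]), rep(1, 6))
})
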