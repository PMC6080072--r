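test_that("wide and long layouts parse to the same dataset", {
  wide <- c("wavelength_nm,a,b",
            "500,1,4",
            "501,2,5",
            "502,3,6")
  long <- c("sample_id,wavelength,intensity",
            "a,500,1", "a,501,2", "a,502,3",
            "b,500,4", "b,501,5", "b,502,6")
  dw <- read_spectra_table(wide, "wide")
  dl <- read_spectra_table(long, "long")
  expect_equal(dim(dw), c(2L, 3L))
  expect_equal(dw$intensities, matrix(1:6, 2, 3, byrow = TRUE,
                                      dimnames = list(c("a", "b"), NULL)),
               ignore_attr = TRUE)
  expect_equal(dw$wavelengths, dl$wavelengths)
  expect_equal(unname(dw$intensities), unname(dl$intensities))
  expect_equal(dw$sample_ids, dl$sample_ids)
})

test_that("parse errors name the offending content", {
  expect_error(read_spectra_table(
    c("wavelength_nm,a", "500,1", "500,2"), "wide"),
    "duplicated wavelength.*500")
  expect_error(read_spectra_table(
    c("wavelength_nm,a", "500,1,9", "501,2"), "wide"), "ragged")
  expect_error(read_spectra_table(
    c("wavelength_nm,a", "500,x"), "wide"), "non-numeric")
  expect_error(read_spectra_table(
    c("sample_id,wavelength,intensity", "a,500,1", "a,500,2"), "long"),
    "duplicate.*500")
})

test_that("write/read round-trips at full double precision", {
  ds <- tiny_dataset(n = 5, k = 9, seed = 7)
  for (layout in c("wide", "long")) {
    txt <- write_spectra_table(ds, layout = layout)
    back <- read_spectra_table(
      txt, layout,
      concentrations = stats::setNames(ds$concentrations, ds$sample_ids))
    expect_identical(back$wavelengths, ds$wavelengths)
    expect_identical(unname(back$intensities), unname(ds$intensities))
    expect_identical(back$concentrations, ds$concentrations)
  }
  ## degenerate: no samples -> header-only wide table
  empty <- spectra_dataset(1:3, matrix(0, 0, 3))
  expect_length(write_spectra_table(empty, layout = "wide"), 4L)
  expect_equal(write_spectra_table(empty, layout = "wide")[1L],
               "wavelength_nm")
})

test_that("concentration table round-trips and validates", {
  cc <- c(a = 0.5, b = 0.62)
  txt <- write_concentration_table(cc)
  expect_equal(read_concentration_table(txt), cc)
  expect_error(read_spectra_table(
    c("wavelength_nm,a,b", "1,1,1", "2,2,2"), "wide",
    concentrations = c(a = 1)), "no concentration.*b")
})

test_that("extract_region keeps the closed interval", {
  cfg <- easy_config()
  ds <- simulate_dataset(2, cfg, seed = 1)
  expect_equal(ncol(extract_region(ds, 751.90, 774.86)$intensities), 512L)
  expect_error(extract_region(ds, 100, 200), "no wavelengths")
  expect_error(extract_region(ds, 760, 755), "lo must be")
  ## brute-force mask oracle around the first analyte line
  lo <- 766.57 - 0.5; hi <- 766.57 + 0.5
  sub <- extract_region(ds, lo, hi)
  mask <- sapply(ds$wavelengths, function(w) w >= lo && w <= hi)
  expect_identical(sub$wavelengths, ds$wavelengths[mask])
  expect_identical(sub$intensities, ds$intensities[, mask])
  expect_identical(sub$concentrations, ds$concentrations)
  ## nested windows: outer then inner equals inner alone
  inner <- extract_region(ds, 760, 770)
  expect_identical(extract_region(extract_region(ds, 755, 772), 760, 770),
                   inner)
})

test_that("split_dataset partitions deterministically", {
  ds <- tiny_dataset(n = 90, k = 5, seed = 3)
  sp <- split_dataset(ds, 65, seed = 11)
  expect_equal(nrow(sp$first$intensities), 65L)
  expect_equal(nrow(sp$second$intensities), 25L)
  expect_length(intersect(sp$first$sample_ids, sp$second$sample_ids), 0L)
  expect_setequal(c(sp$first$sample_ids, sp$second$sample_ids),
                  ds$sample_ids)
  sp2 <- split_dataset(ds, 65, seed = 11)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(ds, 65, seed = 12)
  expect_false(identical(sp$first$sample_ids, sp3$first$sample_ids))
  ## edge: second set of exactly one sample; out-of-range guard
  expect_equal(nrow(split_dataset(ds, 89, seed = 1)$second$intensities), 1L)
  expect_error(split_dataset(ds, 90, seed = 1), "n_first")
})

test_that("dataset validation catches malformed input", {
  expect_error(spectra_dataset(c(1, 2, 2), matrix(0, 1, 3)),
               "strictly increasing")
  expect_error(spectra_dataset(1:3, matrix(0, 1, 2)), "columns")
  expect_error(spectra_dataset(1:3, matrix(0, 2, 3),
                               concentrations = c(-1, 1)), "non-negative")
  expect_error(spectra_dataset(1:3, matrix(0, 2, 3),
                               sample_ids = c("a", "a")), "duplicate")
})
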