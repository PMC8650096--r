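test_that("full-factorial enumeration has the product cardinality", {
  one <- factor_table(q1 = 0.01, q2 = 0.01, wl = 20, wr = 20, hl = 20,
                      hr = 20, radius = 80, phi = 0.5)
  expect_equal(nrow(enumerate_designs(one)), 1L)

  tab <- default_factor_table()
  designs <- enumerate_designs(tab)
  expect_equal(nrow(designs), 2 * 2 * 5 * 4 * 5 * 4 * 3 * 4)
  expect_equal(nrow(designs), 19200L)
  expect_gte(nrow(designs), 15000L)
  ## no duplicated (name, scenario) keys
  expect_false(anyDuplicated(paste(designs$name, designs$q1_ml_h,
                                   designs$q2_ml_h)) > 0)
})

test_that("enumeration is deterministic and matches a nested-loop oracle", {
  tab <- default_factor_table()
  expect_identical(enumerate_designs(tab), enumerate_designs(tab))

  set.seed(7)
  for (rep in 1:5) {
    lev <- lapply(1:7, function(i) sort(sample(seq(10, 90, by = 10),
                                               sample(1:3, 1))))
    ft <- factor_table(q1 = lev[[1]], q2 = lev[[2]], wl = lev[[3]],
                       wr = lev[[4]], hl = lev[[5]], hr = lev[[6]],
                       radius = lev[[7]],
                       phi = sort(sample(1:9, sample(1:3, 1))) / 10)
    ## oracle: count combinations by explicit nested looping
    cnt <- 0L
    for (a in ft$q1) for (b in ft$q2) for (c in ft$wl) for (d in ft$wr)
      for (e in ft$hl) for (f in ft$hr) for (g in ft$radius)
        for (h in ft$phi) cnt <- cnt + 1L
    expect_equal(nrow(enumerate_designs(ft)), cnt)
  }
})

test_that("invalid factor tables are rejected", {
  expect_error(factor_table(q1 = numeric(0), q2 = 0.01, wl = 20, wr = 20,
                            hl = 20, hr = 20, radius = 80, phi = 0.5),
               "empty")
  expect_error(factor_table(q1 = 0.01, q2 = 0.01, wl = c(30, 20), wr = 20,
                            hl = 20, hr = 20, radius = 80, phi = 0.5),
               "increasing")
  expect_error(factor_table(q1 = 0.01, q2 = 0.01, wl = 20, wr = 20,
                            hl = 20, hr = 20, radius = 80, phi = 1.2),
               "porosity")
})

test_that("design names follow the concatenated naming convention", {
  expect_equal(design_name(0.9, wr = 60, radius = 80, hr = 60, wl = 60,
                           hl = 20),
               "P9.Wr6.R8.Hr6.Wl6.Hl2")
  expect_equal(design_name(0.3, wr = 60, radius = 80, hr = 60, wl = 60,
                           hl = 60),
               "P3.Wr6.R8.Hr6.Wl6.Hl6")
  ## closed sentinel encodes as digit 0; radii may need two digits
  expect_equal(design_name(0.5, wr = 20, radius = 120, hr = 20, wl = 0.1,
                           hl = 0.1),
               "P5.Wr2.R12.Hr2.Wl0.Hl0")
  expect_error(design_name(0.55, 60, 80, 60, 60, 60), "porosity")
  expect_error(design_name(0.5, 65, 80, 60, 60, 60), "multiple of 10")
})

test_that("decoding inverts encoding and flags malformed names", {
  d <- decode_design_name("P9.Wr6.R8.Hr6.Wl6.Hl2")
  expect_equal(d$phi, 0.9)
  expect_equal(d$wr_um, 60); expect_equal(d$radius_um, 80)
  expect_equal(d$hr_um, 60); expect_equal(d$wl_um, 60)
  expect_equal(d$hl_um, 20)
  expect_equal(d$topology, "DSC")

  expect_equal(decode_design_name("P5.Wr2.R12.Hr2.Wl0.Hl0")$topology, "SSC")

  expect_error(decode_design_name("Px.Wr6"), "malformed")
  expect_error(decode_design_name("P9.Wr6.R8.Hr6.Wl6"), "6 dot-separated")
  expect_error(decode_design_name("P9.Wr6.R8.Hq6.Wl6.Hl2"), "Hr")
})

test_that("the codec round-trips every geometry of the reference table", {
  designs <- enumerate_designs(default_factor_table())
  geo <- unique(designs[, c("name", "phi", "radius_um", "wl_um", "wr_um",
                            "hl_um", "hr_um", "topology")])
  expect_equal(nrow(geo), 5 * 4 * 5 * 4 * 3 * 4)
  for (i in seq_len(nrow(geo))) {
    d <- decode_design_name(geo$name[i])
    expect_identical(d$name, geo$name[i])
    expect_equal(unlist(d[1, c("phi", "radius_um", "wl_um", "wr_um",
                               "hl_um", "hr_um")]),
                 unlist(geo[i, c("phi", "radius_um", "wl_um", "wr_um",
                                 "hl_um", "hr_um")]),
                 ignore_attr = TRUE)
    expect_identical(d$topology, geo$topology[i])
  }
})

test_that("factor tables load from YAML and manifests round-trip", {
  path <- system.file("extdata", "factors_table.yaml",
                      package = "spherochip")
  tab <- read_factor_table(path)
  expect_identical(unclass(tab), unclass(default_factor_table()),
                   ignore_attr = TRUE)

  designs <- enumerate_designs(tiny_factors())
  csv <- tempfile(fileext = ".csv")
  write_design_manifest(designs, csv)
  back <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(back$name, designs$name)
  expect_equal(back$topology, designs$topology)
  expect_equal(back$phi, designs$phi)
})
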