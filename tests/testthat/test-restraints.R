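test_that("intensity-to-distance implements the isolated spin-pair relation", {
  cal <- roesy_calibration(i_ref = 1000)

  # reference-intensity peak returns the reference distance
  peak <- tibble::tibble(atom1 = "H8", atom2 = "H1'", intensity = 1000)
  expect_equal(intensity_to_distance(peak, cal)$distance, 2.90)

  # sixth root of an intensity ratio of 64 halves the distance
  peak$intensity <- 64 * 1000
  expect_equal(intensity_to_distance(peak, cal)$distance, 1.45)

  # noise-free synthetic intensity built from the packaged methyl-Hbeta
  # distance recovers it (to the table's two-decimal precision)
  tab <- sam_restraints()
  r_true <- tab$distance[tab$atom1 == "MET-CH3" & tab$atom2 == "Hbeta"]
  peak <- tibble::tibble(
    atom1 = "MET-CH3", atom2 = "Hbeta",
    intensity = 1000 * (2.90 / r_true)^6
  )
  expect_equal(round(intensity_to_distance(peak, cal)$distance, 2), 2.91)
})

test_that("distance conversion inverts the intensity oracle across the range", {
  cal <- roesy_calibration(i_ref = 123.4, r_ref = 2.90)
  r <- c(0.5, 1, 1.45, 2.9, 3.7, 5.2, 8, 20)
  peaks <- tibble::tibble(
    atom1 = "H8", atom2 = "H2",
    intensity = cal$i_ref * (cal$r_ref / r)^6
  )
  expect_equal(intensity_to_distance(peaks[1, ], cal)$distance, r[1],
               tolerance = 1e-9)
  got <- vapply(seq_along(r), function(i) {
    intensity_to_distance(peaks[i, ], cal)$distance
  }, numeric(1))
  expect_equal(got, r, tolerance = 1e-9)
})

test_that("invalid cross peaks are rejected with the offending pair named", {
  cal <- roesy_calibration(i_ref = 10)
  bad <- tibble::tibble(atom1 = "H8", atom2 = "H3'", intensity = -1)
  expect_error(intensity_to_distance(bad, cal), "H8-H3'")
  expect_error(intensity_to_distance(
    tibble::tibble(atom1 = "H8", atom2 = "H8", intensity = 1), cal
  ), "identical")
  expect_error(roesy_calibration(i_ref = 0), "positive")
})

test_that("error propagation matches the analytic and finite-difference forms", {
  # all sources zero -> zero
  cal0 <- roesy_calibration(i_ref = 50, di_ref = 0, dr_ref = 0)
  expect_equal(propagate_distance_error(10, 0, cal0), 0)

  # intensity errors zero: dr = (r / r_ref) * dr_ref, and the packaged
  # methyl-Hbeta row reproduces its printed 0.20 A error
  cal <- roesy_calibration(i_ref = 1000, di_ref = 0, dr_ref = 0.2)
  tab <- sam_restraints()
  r_true <- tab$distance[tab$atom1 == "MET-CH3" & tab$atom2 == "Hbeta"]
  I <- cal$i_ref * (cal$r_ref / r_true)^6
  expect_equal(propagate_distance_error(I, 0, cal), (r_true / 2.90) * 0.2)
  expect_equal(round(propagate_distance_error(I, 0, cal), 2), 0.20)

  # random positive parameter sets agree with central finite differences
  set.seed(42)
  for (i in 1:25) {
    I <- runif(1, 0.1, 2000); dI <- runif(1, 0, 50)
    i_ref <- runif(1, 0.1, 2000); di_ref <- runif(1, 0, 50)
    r_ref <- runif(1, 1, 5); dr_ref <- runif(1, 0, 0.5)
    cal_i <- roesy_calibration(i_ref, di_ref, r_ref, dr_ref)
    expect_equal(
      propagate_distance_error(I, dI, cal_i),
      oracle_propagation(I, dI, i_ref, di_ref, r_ref, dr_ref),
      tolerance = 1e-6
    )
  }
})

test_that("propagated uncertainty is monotone in each error source", {
  grid <- seq(0, 1, by = 0.25)
  base <- list(I = 40, i_ref = 100, r_ref = 2.9)
  dr <- vapply(grid, function(g) {
    propagate_distance_error(base$I, 0, roesy_calibration(base$i_ref, 0, base$r_ref, g))
  }, numeric(1))
  expect_true(all(diff(dr) >= 0))
  dr <- vapply(grid * 20, function(g) {
    propagate_distance_error(base$I, 0, roesy_calibration(base$i_ref, g, base$r_ref, 0.1))
  }, numeric(1))
  expect_true(all(diff(dr) >= 0))
  dr <- vapply(grid * 10, function(g) {
    propagate_distance_error(base$I, g, roesy_calibration(base$i_ref, 5, base$r_ref, 0.1))
  }, numeric(1))
  expect_true(all(diff(dr) >= 0))
  expect_error(propagate_distance_error(10, -1, roesy_calibration(10)), ">= 0")
})

test_that("the packaged restraint table reads as 39 canonical rows", {
  tab <- sam_restraints()
  expect_equal(nrow(tab), 39)
  expect_true(all(tab$atom1 %in% sam_proton_vocabulary$label))
  expect_true(all(tab$atom2 %in% sam_proton_vocabulary$label))
  expect_true(all(tab$distance > 0 & tab$error > 0))
  # row order preserved: first and last rows as printed
  expect_equal(tab$distance[1], 2.10)
  expect_equal(tab$distance[39], 5.82)
})

test_that("restraint table parsing enforces the format contract", {
  # header-only file -> empty table
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Atom1\tAtom2\tDistance_A\tError_A", f)
  expect_equal(nrow(read_restraint_table(f)), 0)

  # duplicated unordered pair -> error
  writeLines(c(
    "Atom1\tAtom2\tDistance_A\tError_A",
    "H3'\tH5'\t2.10\t0.14",
    "H5'\tH3'\t2.20\t0.15"
  ), f)
  expect_error(read_restraint_table(f), "Duplicated")

  # unknown proton label -> error naming the token
  writeLines(c(
    "Atom1\tAtom2\tDistance_A\tError_A",
    "H3'\tHQQ\t2.10\t0.14"
  ), f)
  expect_error(read_restraint_table(f), "HQQ")
})

test_that("restraint serialization round trip is lossless", {
  f <- withr::local_tempfile(fileext = ".tsv")

  tab <- sam_restraints()
  write_restraint_table(tab, f)
  expect_equal(read_restraint_table(f), tab)

  one <- tab[1, ]
  write_restraint_table(one, f)
  expect_equal(read_restraint_table(f), one)
  expect_equal(length(readLines(f)), 2) # header + one row

  rnd <- random_restraint_table(50, seed = 99)
  rnd$distance <- rnd$distance * pi # full-precision doubles
  write_restraint_table(rnd, f)
  expect_equal(read_restraint_table(f), rnd)
})

test_that("proton labels normalize across dialects and flag pseudo-atoms", {
  expect_equal(
    normalize_proton_label(c("H5\"", "H5'2", "methyl group", "HB", "Hgamma'", "h-1'")),
    c("H5''", "H5''", "MET-CH3", "Hbeta", "Hgamma'", "H1'")
  )
  expect_error(normalize_proton_label("H99"), "H99")
  expect_true(is_pseudo_proton("MET-CH3"))
  expect_false(any(is_pseudo_proton(c("H8", "Hbeta"))))
})

test_that("cross-peak tables read and convert end to end", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# synthetic peaks",
    "Atom1\tAtom2\tIntensity\tIntensityError",
    "H8\tH1'\t1000\t10",
    "methyl group\tHbeta\t500\t5"
  ), f)
  peaks <- read_cross_peaks(f)
  expect_equal(peaks$atom1, c("H8", "MET-CH3"))
  expect_equal(peaks$atom2, c("H1'", "Hbeta"))
  restr <- intensity_to_distance(peaks, roesy_calibration(i_ref = 1000))
  expect_equal(restr$distance[1], 2.90)
  expect_true(all(restr$error > 0))
})
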