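test_that("ligand extraction finds every SAM instance with provenance", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_survey_fixture(f, list(sam_template(id = "x"), sam_template(chi = 40, id = "y")))

  ens <- extract_ligands(f)
  expect_equal(length(conformer_ids(ens)), 2)
  expect_setequal(unique(ens$chain), c("A", "B"))
  expect_true(all(c("source", "model", "resno") %in% names(ens)))
  # coordinates survive the round trip at PDB precision
  d <- describe_conformers(dplyr::filter(ens, chain == "B"))
  expect_equal(d$chi_deg, 40, tolerance = 1e-2)

  # SAH-only file with SAM requested -> empty with a warning
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_survey_fixture(f2, list(sam_template(id = "x")), resid = "SAH")
  expect_warning(out <- extract_ligands(f2, het_codes = "SAM"), "No HET")
  expect_equal(nrow(out), 0)
  # ...and SAH is picked up under the default HET codes
  expect_equal(length(conformer_ids(extract_ligands(f2))), 1)
})

test_that("multi-model files yield one conformer per model when asked", {
  spec <- synthetic_spec(sam_default_components(chi_sd = 5), 5, seed = 61)
  b <- sample_ensemble(spec)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  f <- file.path(dir, "ensemble.pdb")

  expect_equal(length(conformer_ids(extract_ligands(f))), 1)
  ens <- extract_ligands(f, all_models = TRUE)
  expect_equal(length(conformer_ids(ens)), 5)
  expect_equal(sort(unique(ens$model)), 1:5)
})

test_that("contact listing applies the 5 A cutoff exactly", {
  lig <- sam_template(id = "l")
  xyz <- cbind(lig$x, lig$y, lig$z)
  rownames(xyz) <- lig$atom
  o2 <- xyz["O2'", ]
  # direction pointing away from every other ligand atom
  away <- (o2 - colMeans(xyz[lig$element != "H", ]))
  away <- away / sqrt(sum(away^2))
  probes <- tibble::tibble(
    type = "ATOM",
    atom = c("CA", "CA", "O"),
    resid = c("ALA", "ALA", "GLY"),
    chain = "P",
    resno = c(1L, 2L, 3L),
    x = c(o2[1] + 4.9 * away[1], o2[1] + 5.1 * away[1], o2[1] + 3.0 * away[1]),
    y = c(o2[2] + 4.9 * away[2], o2[2] + 5.1 * away[2], o2[2] + 3.0 * away[2]),
    z = c(o2[3] + 4.9 * away[3], o2[3] + 5.1 * away[3], o2[3] + 3.0 * away[3])
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  write_survey_fixture(f, list(lig), probes = probes)

  contacts <- binding_site_contacts(f, cutoff = 5)
  # residue at 4.9 A from a ribose atom included, at 5.1 A excluded
  expect_true(1 %in% contacts$resno)
  expect_false(2 %in% contacts$resno)
  r1 <- contacts[contacts$resno == 1, ]
  expect_equal(r1$contacted_moiety, "ribose")
  expect_equal(r1$min_distance, 4.9, tolerance = 1e-2)
  # glycine backbone O at 3.0 A from O2' flags a main-chain contact
  r3 <- contacts[contacts$resno == 3, ]
  expect_true(r3$via_backbone)
  expect_equal(r3$min_distance, 3.0, tolerance = 1e-2)

  expect_error(binding_site_contacts(f, ligand = list(chain = "Z", resno = 1)),
               "not found")
})

test_that("production contacts equal the brute-force all-pairs oracle", {
  f <- withr::local_tempfile(fileext = ".pdb")
  build_synthetic_complex("compact", f, seed = 62)
  got <- binding_site_contacts(f, cutoff = 5)
  ref <- oracle_contacts(f, cutoff = 5)
  expect_equal(nrow(got), nrow(ref))
  expect_equal(got$resno, ref$resno)
  expect_equal(got$min_distance, ref$min_distance, tolerance = 1e-9)
  expect_equal(got$contacted_moiety, ref$contacted_moiety)
  expect_equal(got$via_backbone, ref$via_backbone)
})

test_that("moiety partition is total over the SAM and SAH vocabularies", {
  m <- sam_moieties()
  expect_setequal(m$atom, sam_heavy_atoms)
  expect_equal(anyDuplicated(m$atom), 0)
  expect_setequal(unique(m$moiety), c("adenine", "ribose", "methionine"))
  sah_atoms <- setdiff(sam_heavy_atoms, "CE") # SAH lacks the methyl carbon
  expect_true(all(sah_atoms %in% m$atom))
})

test_that("group profiles tabulate descriptor distributions faithfully", {
  # all conformers identical at chi = 0 -> anti1 fraction 1, one occupied bin
  ens <- dplyr::bind_rows(lapply(1:6, function(i) {
    sam_template(chi = 0, id = sprintf("c%d", i))
  }))
  d <- describe_conformers(ens)
  labels <- tibble::tibble(conformer_id = d$conformer_id, group = "g1")
  prof <- build_group_profile(d, labels)
  cf <- prof$class_fractions
  expect_equal(cf$fraction[cf$class == "anti1"], 1)
  expect_equal(sum(prof$chi_hist$count > 0), 1)
  # histogram mass conservation
  expect_equal(sum(prof$chi_hist$count), 6)
  expect_equal(sum(prof$theta_hist$count), 6)
  expect_equal(sum(prof$occupancy$count), 6)

  # deterministic 80/20 syn/anti1 mixture -> exact class fractions
  spec <- synthetic_spec(
    list(
      mixture_component("syn", -120, 0, weight = 0.8),
      mixture_component("anti", 0, 0, weight = 0.2)
    ),
    n_conformers = 40, seed = 63
  )
  b <- sample_ensemble(spec)
  d <- describe_conformers(b$ensemble)
  labels <- tibble::tibble(conformer_id = d$conformer_id, group = "water")
  prof <- build_group_profile(d, labels)
  cf <- prof$class_fractions
  n_syn <- sum(b$labels$component == "syn")
  expect_equal(cf$fraction[cf$class == "syn"], n_syn / 40)
  expect_equal(cf$fraction[cf$class == "anti1"], 1 - n_syn / 40)

  expect_error(build_group_profile(d, labels[-1, ]), "Unlabelled")
})

test_that("group comparison separates bent and extended generators", {
  bent <- synthetic_spec(
    list(mixture_component("b", 20, 5, c(met1 = -60, met2 = -80, met3 = -60,
                                         met4 = 180, met5 = 180), 1)),
    30, seed = 64
  )
  ext <- synthetic_spec(
    list(mixture_component("e", -120, 5, weight = 1)),
    30, seed = 65
  )
  db <- describe_conformers(sample_ensemble(bent)$ensemble)
  de <- describe_conformers(sample_ensemble(ext)$ensemble)
  db$conformer_id <- paste0("bent_", db$conformer_id)
  prof <- build_group_profile(
    dplyr::bind_rows(db, de),
    tibble::tibble(
      conformer_id = c(db$conformer_id, de$conformer_id),
      group = rep(c("knotted_like", "unknotted_like"), each = 30)
    )
  )
  cmp <- compare_groups(prof)
  expect_equal(nrow(cmp), 2)
  expect_gt(cmp$bent[cmp$group == "knotted_like"], 0.9)
  expect_lt(cmp$bent[cmp$group == "unknotted_like"], 0.1)
  # the knotted-MT 2-D window is populated only by the bent/anti group
  expect_gt(cmp$knotted_mt_like[cmp$group == "knotted_like"],
            cmp$knotted_mt_like[cmp$group == "unknotted_like"])

  # identical profiles produce identical rows
  cmp2 <- compare_groups(prof, prof)
  expect_equal(cmp2$n, cmp$n * 2)
  expect_equal(cmp2$bent, cmp$bent)

  # a label group with no conformers shows up as an empty, flagged row
  labels_extra <- tibble::tibble(
    conformer_id = c(de$conformer_id, "absent_conf"),
    group = c(rep("unknotted_like", 30), "vacant")
  )
  prof_with_empty <- build_group_profile(de, labels_extra)
  cmp_e <- compare_groups(prof_with_empty)
  expect_true("vacant" %in% cmp_e$group)
  expect_true(cmp_e$empty[cmp_e$group == "vacant"])
  expect_equal(cmp_e$n[cmp_e$group == "vacant"], 0L)

  # mismatched binning rejected
  labels_plain <- tibble::tibble(conformer_id = de$conformer_id,
                                 group = "unknotted_like")
  expect_error(
    compare_groups(prof, build_group_profile(de, labels_plain, bin_width = 20)),
    "binning"
  )
})
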