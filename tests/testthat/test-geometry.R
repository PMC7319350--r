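test_that("dihedral angle follows the signed IUPAC convention", {
  # planar cis -> 0, planar trans -> 180
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)

  set.seed(7)
  for (i in 1:50) {
    p <- matrix(rnorm(12, sd = 2), 4)
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "Degenerate")
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("bend angle matches the arccos oracle and handles degeneracies", {
  expect_equal(bend_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_equal(bend_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  set.seed(8)
  for (i in 1:50) {
    p <- matrix(rnorm(9, sd = 2), 3)
    expect_equal(bend_angle(p[1, ], p[2, ], p[3, ]),
                 oracle_bend(p[1, ], p[2, ], p[3, ]), tolerance = 1e-9)
  }
  expect_error(bend_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "Degenerate")
})

test_that("angles are rigid-motion invariant; reversal and mirroring behave", {
  set.seed(9)
  for (i in 1:20) {
    p <- matrix(rnorm(12, sd = 2), 4)
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    q <- sweep(p %*% t(R), 2, t, "+")
    d0 <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]), d0, tolerance = 1e-9)
    expect_equal(bend_angle(q[1, ], q[2, ], q[3, ]),
                 bend_angle(p[1, ], p[2, ], p[3, ]), tolerance = 1e-9)
    # reversing the four points preserves the signed dihedral
    expect_equal(dihedral_angle(p[4, ], p[3, ], p[2, ], p[1, ]), d0, tolerance = 1e-9)
    # mirroring negates it (180 stays 180 in the (-180, 180] convention)
    m <- p
    m[, 1] <- -m[, 1]
    dm <- dihedral_angle(m[1, ], m[2, ], m[3, ], m[4, ])
    if (abs(abs(d0) - 180) > 1e-9) {
      expect_equal(dm, -d0, tolerance = 1e-9)
    }
  }
})

test_that("superposition is the least-squares optimum", {
  a <- make_conformer(toy_xyz(), "a")

  fit <- superpose(a, a, atoms = rownames(toy_xyz()))
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)

  set.seed(10)
  b <- apply_rigid(a)
  b$conformer_id <- "b"
  fit <- superpose(b, a, atoms = rownames(toy_xyz()))
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  # the transformed coordinates land on the target
  expect_equal(fit$conformer$x, a$x, tolerance = 1e-9)

  # optimality: no random rigid placement of the mobile beats the fit
  a2 <- make_conformer(toy_xyz(jitter = 0.4, seed = 3), "a2")
  atoms <- rownames(toy_xyz())
  best <- superpose(a2, a, atoms = atoms)$rmsd
  A <- cbind(a$x, a$y, a$z)
  for (i in 1:1000) {
    moved <- apply_rigid(a2)
    M <- cbind(moved$x, moved$y, moved$z)
    expect_gte(sqrt(mean(rowSums((M - A)^2))), best - 1e-12)
  }
})

test_that("superposition RMSD agrees with the bio3d reference", {
  set.seed(11)
  for (i in 1:10) {
    a <- make_conformer(toy_xyz(jitter = 0.5, seed = i), "a")
    b <- make_conformer(toy_xyz(jitter = 0.5, seed = i + 100), "b")
    atoms <- rownames(toy_xyz())
    mine <- superpose(a, b, atoms = atoms)$rmsd
    ref <- bio3d::rmsd(
      as.numeric(t(cbind(a$x, a$y, a$z))),
      as.numeric(t(cbind(b$x, b$y, b$z))),
      fit = TRUE
    )
    expect_equal(round(mine, 3), ref) # bio3d rounds to three decimals
  }
})

test_that("heavy-atom RMSD is a pseudo-metric matching the brute-force oracle", {
  spec <- synthetic_spec(sam_default_components(chi_sd = 15), 6, seed = 5)
  ens <- sample_ensemble(spec)$ensemble
  ids <- conformer_ids(ens)
  confs <- lapply(ids, function(i) dplyr::filter(ens, conformer_id == i))

  expect_equal(heavy_atom_rmsd(confs[[1]], confs[[1]]), 0, tolerance = 1e-12)

  # symmetry + triangle inequality + bio3d agreement on all pairs
  n <- length(confs)
  m <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) m[i, j] <- heavy_atom_rmsd(confs[[i]], confs[[j]])
  expect_equal(m, t(m), tolerance = 1e-9)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-9)
  }
  xyz <- function(cf) {
    cc <- cf[match(sam_heavy_atoms, cf$atom), ]
    as.numeric(t(cbind(cc$x, cc$y, cc$z)))
  }
  expect_equal(m[1, 2], bio3d::rmsd(xyz(confs[[1]]), xyz(confs[[2]]), fit = TRUE),
               tolerance = 1e-3)

  # single displaced atom: optimal refit can only reduce the naive bound
  a <- confs[[1]]
  b <- a
  delta <- 0.9
  b$z[b$atom == "N6"] <- b$z[b$atom == "N6"] + delta
  r <- heavy_atom_rmsd(a, b)
  expect_lte(r, delta / sqrt(27) + 1e-12)
  expect_gt(r, 0)
  expect_error(heavy_atom_rmsd(a, b[b$atom != "SD", ]), "SD")
})

test_that("interproton distances honour the methyl pseudo-atom physics", {
  xyz <- rbind(
    "H8" = c(0, 0, 0), "H2" = c(2.5, 0, 0),
    "HE1" = c(2, 0, 0), "HE2" = c(0, 3, 0), "HE3" = c(0, 0, 4)
  )
  cf <- make_conformer(xyz)
  pairs <- tibble::tibble(atom1 = "H8", atom2 = "H2")
  expect_equal(interproton_distance(cf, pairs), 2.5)

  # equidistant methyl protons collapse to the common distance
  xyz_eq <- rbind(
    "H8" = c(0, 0, 0),
    "HE1" = c(3, 0, 0), "HE2" = c(0, 3, 0), "HE3" = c(0, 0, 3)
  )
  pairs <- tibble::tibble(atom1 = "MET-CH3", atom2 = "H8")
  expect_equal(interproton_distance(make_conformer(xyz_eq), pairs), 3)

  # 2/3/4 A methyl protons -> r^-6-effective closed form
  d_eff <- ((2^-6 + 3^-6 + 4^-6) / 3)^(-1 / 6)
  expect_equal(interproton_distance(cf, pairs), d_eff)
  # centroid alternative differs
  expect_false(isTRUE(all.equal(
    interproton_distance(cf, pairs, method = "centroid"), d_eff
  )))
  expect_error(
    interproton_distance(make_conformer(xyz_eq[1:2, , drop = FALSE]), pairs),
    "HE2"
  )
})

test_that("RMSF reports per-atom spread after superposition", {
  a <- make_conformer(toy_xyz(), "m1")
  atoms <- rownames(toy_xyz())

  # identical copies -> all zero
  ens <- dplyr::bind_rows(a, dplyr::mutate(a, conformer_id = "m2"))
  expect_equal(conformer_rmsf(ens, atoms = atoms)$rmsf, rep(0, 5), tolerance = 1e-12)

  # two conformers, one atom apart by 2*delta -> that atom's rmsf = delta
  b <- dplyr::mutate(a, conformer_id = "m2")
  b$z[b$atom == "A5"] <- b$z[b$atom == "A5"] + 1.6
  ens <- dplyr::bind_rows(a, b)
  out <- conformer_rmsf(ens, atoms = atoms, fit_atoms = c("A1", "A2", "A3", "A4"))
  expect_equal(out$rmsf[out$atom == "A5"], 0.8, tolerance = 1e-9)

  # isotropic jitter of one atom converges to sigma * sqrt(3)
  set.seed(12)
  sigma <- 0.3
  n <- 8000
  jit <- purrr::map_dfr(seq_len(n), function(i) {
    cf <- dplyr::mutate(a, conformer_id = sprintf("j%05d", i))
    cf[cf$atom == "A5", c("x", "y", "z")] <-
      cf[cf$atom == "A5", c("x", "y", "z")] + rnorm(3, 0, sigma)
    cf
  })
  out <- conformer_rmsf(jit, atoms = "A5", fit_atoms = c("A1", "A2", "A3", "A4"))
  expect_equal(out$rmsf, sigma * sqrt(3), tolerance = 0.05)

  expect_error(conformer_rmsf(a[0, ]), "Empty")
})
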