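# Idealised SAM template: 27 heavy atoms plus the non-exchangeable
# protons, built from internal coordinates. Bond lengths and angles are
# textbook ideal values; the two rings are constructed as planar regular
# polygons (side 1.43 A for the ribose, 1.39 A for the purine), which
# keeps every ring bond inside chemically plausible bounds while making
# the construction exactly reproducible. Exchangeable protons (N-H, O-H)
# are omitted: they are invisible in the D2O ROESY bookkeeping and no
# restraint involves them.

unit3 <- function(v) v / sqrt(sum(v^2))

# NeRF placement: position of atom D bonded to C, with |CD| = bond,
# angle(B,C,D) = ang (degrees) and dihedral(A,B,C,D) = tor (degrees).
nerf_place <- function(a, b, c, bond, ang, tor) {
  ang <- ang * pi / 180
  tor <- tor * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix (column convention, R %*% v) about unit axis `ax`.
axis_rotation <- function(ax, angle_deg) {
  th <- angle_deg * pi / 180
  ax <- unit3(ax)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation taking unit vector u onto unit vector v.
align_rotation <- function(u, v) {
  u <- unit3(u); v <- unit3(v)
  ax <- cross3(u, v)
  s <- sqrt(sum(ax^2))
  d <- sum(u * v)
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(axis_rotation(cross3(u, p), 180))
  }
  axis_rotation(ax, atan2(s, d) * 180 / pi)
}

# Regular planar pentagon/hexagon vertices (rows), centred at the origin.
ring_vertices <- function(n, side) {
  R <- side / (2 * sin(pi / n))
  th <- pi / 2 + 2 * pi * (seq_len(n) - 1) / n
  cbind(R * cos(th), R * sin(th), 0)
}

#' Covalent bond list of the SAM template
#'
#' @return A two-column tibble (`atom1`, `atom2`), one row per covalent
#'   bond of the template returned by [sam_template()].
#' @export
sam_bonds <- function() {
  b <- rbind(
    # methionine moiety
    c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"), c("CA", "HA"),
    c("CA", "CB"), c("CB", "HB"), c("CB", "HB'"), c("CB", "CG"),
    c("CG", "HG"), c("CG", "HG'"), c("CG", "SD"),
    c("SD", "CE"), c("CE", "HE1"), c("CE", "HE2"), c("CE", "HE3"),
    c("SD", "C5'"),
    # ribose
    c("C5'", "H5'"), c("C5'", "H5''"), c("C5'", "C4'"),
    c("C4'", "H4'"), c("C4'", "O4'"), c("C4'", "C3'"),
    c("C3'", "H3'"), c("C3'", "O3'"), c("C3'", "C2'"),
    c("C2'", "H2'"), c("C2'", "O2'"), c("C2'", "C1'"),
    c("C1'", "H1'"), c("C1'", "O4'"), c("C1'", "N9"),
    # adenine
    c("N9", "C8"), c("C8", "H8"), c("C8", "N7"), c("N7", "C5"),
    c("C5", "C4"), c("C4", "N9"), c("C4", "N3"), c("N3", "C2"),
    c("C2", "H2"), c("C2", "N1"), c("N1", "C6"), c("C6", "C5"),
    c("C6", "N6")
  )
  tibble::tibble(atom1 = b[, 1], atom2 = b[, 2])
}

# The driven torsions: the glycosidic dihedral plus the five rotatable
# bonds of the methionine chain. Each row names the a-b-c-d quadruple;
# rotation moves the atoms on the d side of the b-c bond.
sam_torsions <- function() {
  list(
    chi = c("O4'", "C1'", "N9", "C8"),
    met1 = c("C3'", "C4'", "C5'", "SD"),
    met2 = c("C4'", "C5'", "SD", "CG"),
    met3 = c("C5'", "SD", "CG", "CB"),
    met4 = c("SD", "CG", "CB", "CA"),
    met5 = c("CG", "CB", "CA", "C")
  )
}

# Default chain torsions of the all-anti (extended) template.
.extended_torsions <- c(met1 = 180, met2 = 180, met3 = 180, met4 = 180, met5 = 180)

build_template_xyz <- function() {
  pos <- list()
  pos$N <- c(0, 0, 0)
  pos$CA <- c(1.47, 0, 0)
  pos$C <- pos$CA + 1.52 * c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
  pos$O <- nerf_place(pos$N, pos$CA, pos$C, 1.23, 120, 0)
  pos$OXT <- nerf_place(pos$N, pos$CA, pos$C, 1.25, 120, 180)
  pos$CB <- nerf_place(pos$C, pos$N, pos$CA, 1.53, 110, 122)
  pos$HA <- nerf_place(pos$C, pos$N, pos$CA, 1.09, 108, -119)
  pos$CG <- nerf_place(pos$N, pos$CA, pos$CB, 1.53, 112, 180)
  pos$HB <- nerf_place(pos$N, pos$CA, pos$CB, 1.09, 108, 60)
  pos$"HB'" <- nerf_place(pos$N, pos$CA, pos$CB, 1.09, 108, -60)
  pos$SD <- nerf_place(pos$CA, pos$CB, pos$CG, 1.81, 112, 180)
  pos$HG <- nerf_place(pos$CA, pos$CB, pos$CG, 1.09, 108, 60)
  pos$"HG'" <- nerf_place(pos$CA, pos$CB, pos$CG, 1.09, 108, -60)
  pos$CE <- nerf_place(pos$CB, pos$CG, pos$SD, 1.79, 100, 70)
  pos$"C5'" <- nerf_place(pos$CB, pos$CG, pos$SD, 1.82, 100, 180)
  pos$HE1 <- nerf_place(pos$CG, pos$SD, pos$CE, 1.09, 109.5, 60)
  pos$HE2 <- nerf_place(pos$CG, pos$SD, pos$CE, 1.09, 109.5, 180)
  pos$HE3 <- nerf_place(pos$CG, pos$SD, pos$CE, 1.09, 109.5, -60)
  c4_anchor <- nerf_place(pos$CG, pos$SD, pos$"C5'", 1.52, 112, 180)
  pos$"H5'" <- nerf_place(pos$CG, pos$SD, pos$"C5'", 1.09, 109, 62)
  pos$"H5''" <- nerf_place(pos$CG, pos$SD, pos$"C5'", 1.09, 109, -62)

  # ribose: planar pentagon O4', C1', C2', C3', C4' in a local frame
  ring <- ring_vertices(5, 1.43)
  rnames <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  centre_dir <- function(v) unit3(c(v[1], v[2], 0))
  elev <- function(u, s, phi) {
    phi <- phi * pi / 180
    unit3(cos(phi) * u + s * sin(phi) * c(0, 0, 1))
  }
  loc <- setNames(lapply(seq_len(5), function(i) ring[i, ]), rnames)
  u <- lapply(loc, centre_dir)
  loc$"C5'" <- loc$"C4'" + 1.52 * elev(u$"C4'", +1, 40)
  loc$"H4'" <- loc$"C4'" + 1.09 * elev(u$"C4'", -1, 55)
  # beta-face (same side as C5'): the base at C1'; alpha face: the 2'/3'
  # hydroxyls, as in beta-D-ribofuranose
  loc$"O3'" <- loc$"C3'" + 1.41 * elev(u$"C3'", -1, 50)
  loc$"H3'" <- loc$"C3'" + 1.09 * elev(u$"C3'", +1, 55)
  loc$"O2'" <- loc$"C2'" + 1.41 * elev(u$"C2'", -1, 50)
  loc$"H2'" <- loc$"C2'" + 1.09 * elev(u$"C2'", +1, 55)
  loc$N9 <- loc$"C1'" + 1.47 * elev(u$"C1'", +1, 40)
  loc$"H1'" <- loc$"C1'" + 1.09 * elev(u$"C1'", -1, 55)

  # attach the ribose frame onto the chain's C5'-C4' anchor
  Rr <- align_rotation(loc$"C4'" - loc$"C5'", c4_anchor - pos$"C5'")
  shift <- pos$"C5'"
  origin <- loc$"C5'"
  for (nm in setdiff(names(loc), "C5'")) {
    pos[[nm]] <- drop(Rr %*% (loc[[nm]] - origin)) + shift
  }

  # adenine: planar purine in a local frame (hexagon + fused pentagon)
  hexv <- ring_vertices(6, 1.39)
  hnames <- c("N1", "C2", "N3", "C4", "C5", "C6")
  aloc <- setNames(lapply(seq_len(6), function(i) hexv[i, ]), hnames)
  M <- (aloc$C4 + aloc$C5) / 2
  uo <- unit3(M) # outward from hexagon centre
  a5 <- 1.39 / (2 * tan(pi / 5))
  P <- M + a5 * uo # pentagon centre
  phi4 <- atan2(aloc$C4[2] - P[2], aloc$C4[1] - P[1])
  phi5 <- atan2(aloc$C5[2] - P[2], aloc$C5[1] - P[1])
  R5 <- sqrt(sum((aloc$C4 - P)^2))
  step <- 2 * pi / 5
  # direction of traversal C4 -> N9 -> C8 -> N7 -> C5 around the pentagon
  dirsgn <- if (abs(sin(phi4 + 4 * step - phi5)) < 1e-8 &&
                cos(phi4 + 4 * step - phi5) > 0) 1 else -1
  pent <- function(k) P + R5 * c(cos(phi4 + dirsgn * k * step),
                                 sin(phi4 + dirsgn * k * step), 0)
  aloc$N9 <- pent(1)
  aloc$C8 <- pent(2)
  aloc$N7 <- pent(3)
  aloc$N6 <- aloc$C6 + 1.34 * unit3(aloc$C6)
  aloc$H2 <- aloc$C2 + 1.08 * unit3(aloc$C2)
  aloc$H8 <- aloc$C8 + 1.08 * unit3(aloc$C8 - P)
  c1_anchor <- aloc$N9 + 1.47 * unit3(aloc$N9 - P)

  Ra <- align_rotation(c1_anchor - aloc$N9, pos$"C1'" - pos$N9)
  shift <- pos$N9
  origin <- aloc$N9
  for (nm in setdiff(names(aloc), "N9")) {
    pos[[nm]] <- drop(Ra %*% (aloc[[nm]] - origin)) + shift
  }

  do.call(rbind, pos)
}

# Atom indices on the rotating (d) side of each driven torsion, computed
# once from the bond graph by breadth-first search with the b-c edge cut.
torsion_sides <- function(atoms, bonds = sam_bonds()) {
  n <- length(atoms)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(bonds))) {
    i <- match(bonds$atom1[r], atoms)
    j <- match(bonds$atom2[r], atoms)
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(sam_torsions(), function(tt) {
    b <- match(tt[2], atoms)
    cc <- match(tt[3], atoms)
    seen <- rep(FALSE, n)
    seen[c(b, cc)] <- TRUE
    queue <- cc
    side <- integer(0)
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (!seen[nb]) {
          seen[nb] <- TRUE
          side <- c(side, nb)
          queue <- c(queue, nb)
        }
      }
    }
    list(ref = match(tt, atoms), side = side, axis = c(b, cc))
  })
}

# Rotate `xyz` so that the named torsion equals `target` degrees. The
# atoms on the d side of the b-c bond move; c itself lies on the axis.
set_torsion_xyz <- function(xyz, side_info, target) {
  r <- side_info$ref
  cur <- dihedral_angle(xyz[r[1], ], xyz[r[2], ], xyz[r[3], ], xyz[r[4], ])
  delta <- target - cur
  ax_from <- xyz[side_info$axis[1], ]
  ax_dir <- xyz[side_info$axis[2], ] - ax_from
  R <- axis_rotation(ax_dir, delta)
  idx <- side_info$side
  xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, ax_from) %*% t(R), 2, ax_from, "+")
  xyz
}

.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)

# TRUE when any non-bonded, non-1-3 atom pair is closer than
# `tol` x (sum of covalent radii).
has_clashes <- function(xyz, elements, exclude, tol = 0.8) {
  d <- as.matrix(stats::dist(xyz))
  rad <- .covalent_radii[elements]
  lim <- tol * outer(rad, rad, "+")
  bad <- d < lim
  bad[exclude] <- FALSE
  diag(bad) <- FALSE
  any(bad)
}

# Logical mask of 1-2 and 1-3 pairs (excluded from clash checking).
bonded_mask <- function(atoms, bonds = sam_bonds()) {
  n <- length(atoms)
  m <- matrix(FALSE, n, n)
  i <- match(bonds$atom1, atoms)
  j <- match(bonds$atom2, atoms)
  m[cbind(i, j)] <- TRUE
  m[cbind(j, i)] <- TRUE
  one3 <- (m %*% m) > 0
  m | one3
}

#' Idealised SAM conformer template
#'
#' Builds a single SAM conformer from ideal internal coordinates: all 27
#' heavy atoms plus the non-exchangeable protons (42 atoms). The two rings
#' are planar regular polygons; bond lengths and angles are textbook
#' values. The glycosidic dihedral and the five methionine-chain torsions
#' are set to the requested values (defaults: syn glycosidic angle, fully
#' extended chain).
#'
#' @param chi Glycosidic dihedral (degrees, default -120, syn).
#' @param met_torsions Named numeric vector of the chain torsions `met1`
#'   (C3'-C4'-C5'-SD) through `met5` (CG-CB-CA-C) in degrees; defaults to
#'   the all-anti extended chain.
#' @param id Conformer id.
#' @return A conformer tibble (see [as_conformer()]).
#' @export
sam_template <- function(chi = -120, met_torsions = .extended_torsions, id = "template") {
  xyz <- template_cache$xyz
  atoms <- rownames(xyz)
  sides <- template_cache$sides
  full <- .extended_torsions
  full[names(met_torsions)] <- met_torsions
  for (nm in names(full)) xyz <- set_torsion_xyz(xyz, sides[[nm]], full[[nm]])
  xyz <- set_torsion_xyz(xyz, sides$chi, chi)
  as_conformer(tibble::tibble(
    conformer_id = id,
    atom = atoms,
    element = guess_element(atoms),
    x = unname(xyz[, 1]), y = unname(xyz[, 2]), z = unname(xyz[, 3])
  ))
}

# Built once at load time; sam_template() only drives torsions.
template_cache <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  xyz <- build_template_xyz()
  template_cache$xyz <- xyz
  template_cache$sides <- torsion_sides(rownames(xyz))
  template_cache$exclude <- bonded_mask(rownames(xyz))
  invisible()
}
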