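# Shared builders and independent oracles for the test suite.

# A named point cloud as a conformer tibble.
make_conformer <- function(xyz, id = "c1") {
  as_conformer(tibble::tibble(
    conformer_id = id,
    atom = rownames(xyz),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
}

random_rotation <- function() {
  M <- matrix(rnorm(9), 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply a random rigid motion to a conformer (or raw coordinates).
apply_rigid <- function(conformer, R = random_rotation(), t = rnorm(3, sd = 5)) {
  xyz <- cbind(conformer$x, conformer$y, conformer$z) %*% t(R)
  out <- conformer
  out$x <- xyz[, 1] + t[1]
  out$y <- xyz[, 2] + t[2]
  out$z <- xyz[, 3] + t[3]
  out
}

# Independent dihedral oracle: angle between the two bond-plane normals,
# signed by the triple product with the central bond (acos + sign, a
# different construction from the package's atan2 form).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(pmin(1, pmax(-1, cosphi))) * 180 / pi
  s <- sum(cr(n1, n2) * b2)
  if (s < 0) -phi else phi
}

oracle_bend <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}

# Central-finite-difference propagation of Eq-1 uncertainties.
oracle_propagation <- function(I, dI, i_ref, di_ref, r_ref, dr_ref, h = 1e-6) {
  f <- function(I, i_ref, r_ref) (i_ref / I)^(1/6) * r_ref
  d_dI <- (f(I * (1 + h), i_ref, r_ref) - f(I * (1 - h), i_ref, r_ref)) / (2 * h * I)
  d_diref <- (f(I, i_ref * (1 + h), r_ref) - f(I, i_ref * (1 - h), r_ref)) / (2 * h * i_ref)
  d_drref <- (f(I, i_ref, r_ref + h) - f(I, i_ref, r_ref - h)) / (2 * h)
  sqrt((d_dI * dI)^2 + (d_diref * di_ref)^2 + (d_drref * dr_ref)^2)
}

# A random valid restraint table over distinct proton pairs.
random_restraint_table <- function(n, seed = 1) {
  set.seed(seed)
  labels <- sam_proton_vocabulary$label
  pairs <- t(combn(labels, 2))
  pick <- sample(nrow(pairs), n)
  tibble::tibble(
    atom1 = pairs[pick, 1],
    atom2 = pairs[pick, 2],
    distance = runif(n, 1.8, 6),
    error = runif(n, 0.05, 0.5)
  )
}

# Small rigid tetrahedron-ish cloud used as a generic "conformer".
toy_xyz <- function(jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- rbind(
    A1 = c(0, 0, 0), A2 = c(1.5, 0, 0), A3 = c(0.7, 1.3, 0),
    A4 = c(0.5, 0.4, 1.2), A5 = c(-0.6, 0.9, -0.8)
  )
  base + matrix(rnorm(15, 0, jitter), 5, 3)
}

# Brute-force contact oracle: plain double loop over residues and atoms.
oracle_contacts <- function(path, cutoff = 5) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at$elety <- gsub("\\*", "'", at$elety)
  lig <- at[at$resid %in% c("SAM", "SAH"), ]
  lig <- lig[!grepl("^H", lig$elety), ]
  prot <- at[at$type == "ATOM" & !grepl("^H", at$elety), ]
  moieties <- sam_moieties()
  out <- list()
  for (key in unique(paste(prot$chain, prot$resno))) {
    rows <- prot[paste(prot$chain, prot$resno) == key, ]
    best <- Inf; best_moiety <- NA; best_atom <- NA
    for (i in seq_len(nrow(rows))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((rows$x[i] - lig$x[j])^2 + (rows$y[i] - lig$y[j])^2 + (rows$z[i] - lig$z[j])^2)
        if (d < best) {
          best <- d
          best_moiety <- moieties$moiety[moieties$atom == lig$elety[j]]
          best_atom <- rows$elety[i]
        }
      }
    }
    if (best <= cutoff) {
      out[[key]] <- tibble::tibble(
        chain = rows$chain[1], resno = rows$resno[1],
        min_distance = best, contacted_moiety = best_moiety,
        via_backbone = best_atom %in% c("N", "CA", "C", "O")
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), chain, resno)
}

# Write a small PDB holding the given conformers as SAM/SAH HETATM
# residues (one per chain), with optional probe atoms (a tibble with
# columns type, atom, resid, chain, resno, x, y, z).
write_survey_fixture <- function(path, ligands, resid = "SAM", probes = NULL) {
  rows <- list()
  for (i in seq_along(ligands)) {
    cf <- ligands[[i]]
    rows[[i]] <- tibble::tibble(
      type = "HETATM", atom = cf$atom, resid = resid,
      chain = LETTERS[i], resno = 400 + i,
      x = cf$x, y = cf$y, z = cf$z
    )
  }
  df <- dplyr::bind_rows(rows)
  if (!is.null(probes)) df <- dplyr::bind_rows(df, probes)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(df[, c("x", "y", "z")]))),
    type = df$type, resno = df$resno, resid = df$resid,
    eleno = seq_len(nrow(df)), elety = df$atom, chain = df$chain,
    o = rep(1, nrow(df)), b = rep(0, nrow(df)),
    elesy = substr(gsub("['0-9]", "", df$atom), 1, 1)
  )
  path
}
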