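#' Conformer coordinate tables
#'
#' Conformers are represented as plain tibbles in long form with one row
#' per atom and columns `conformer_id`, `atom`, `element`, `x`, `y`, `z`
#' (coordinates in Angstrom). An ensemble is the same tibble holding
#' several `conformer_id` values; conformer order is the order of first
#' appearance.
#'
#' @param df A data frame with at least columns `atom`, `x`, `y`, `z`;
#'   `conformer_id` defaults to `"conf1"` and `element` is derived from
#'   the atom name when absent.
#' @return A conformer tibble.
#' @export
as_conformer <- function(df) {
  df <- tibble::as_tibble(df)
  missing <- setdiff(c("atom", "x", "y", "z"), names(df))
  if (length(missing)) {
    abort(sprintf("Conformer table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"conformer_id" %in% names(df)) df$conformer_id <- "conf1"
  if (!"element" %in% names(df)) df$element <- guess_element(df$atom)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("Conformer coordinates must be finite.")
  }
  dup <- df |>
    dplyr::count(.data$conformer_id, .data$atom) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf(
      "Duplicated atom name(s) within conformer(s): %s",
      paste(unique(sprintf("%s:%s", dup$conformer_id, dup$atom)), collapse = ", ")
    ))
  }
  dplyr::select(
    df, "conformer_id", "atom", "element", "x", "y", "z",
    dplyr::any_of(c("source"))
  )
}

guess_element <- function(atom) {
  core <- sub("^[0-9]+", "", gsub("['\"*]", "", atom))
  dplyr::case_when(
    grepl("^SD", core) ~ "S",
    grepl("^H", core) ~ "H",
    grepl("^C", core) ~ "C",
    grepl("^N", core) ~ "N",
    grepl("^O", core) ~ "O",
    TRUE ~ substr(core, 1, 1)
  )
}

#' Conformer ids of an ensemble, in order of first appearance
#' @param ensemble An ensemble tibble.
#' @return Character vector of conformer ids.
#' @export
conformer_ids <- function(ensemble) {
  unique(ensemble$conformer_id)
}

# Coordinate matrix (atoms x 3) for one conformer, rows named by atom.
conformer_coords <- function(conformer, atoms = NULL) {
  id <- conformer$conformer_id[1]
  if (!is.null(atoms)) {
    idx <- match(atoms, conformer$atom)
    if (anyNA(idx)) {
      abort(sprintf(
        "Conformer %s is missing atom(s): %s",
        id %||% "?", paste(atoms[is.na(idx)], collapse = ", ")
      ))
    }
    conformer <- conformer[idx, , drop = FALSE]
  }
  m <- cbind(conformer$x, conformer$y, conformer$z)
  rownames(m) <- conformer$atom
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 3-D coordinate array (atoms x 3 x conformers) over a shared atom subset.
ensemble_coord_array <- function(ensemble, atoms) {
  ids <- conformer_ids(ensemble)
  parts <- split(ensemble, factor(ensemble$conformer_id, levels = ids))
  arr <- array(NA_real_, dim = c(length(atoms), 3L, length(ids)),
               dimnames = list(atoms, c("x", "y", "z"), ids))
  for (k in seq_along(ids)) {
    arr[, , k] <- conformer_coords(parts[[k]], atoms)
  }
  arr
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' Right-handed (IUPAC) torsion convention: looking down the p2->p3 bond,
#' the angle is positive when the far bond (p3->p4) is rotated clockwise
#' from the near bond (p2->p1). Returned in degrees in (-180, 180]; a
#' planar cis arrangement gives 0 and trans gives 180.
#'
#' @param p1,p2,p3,p4 Numeric length-3 Cartesian coordinates.
#' @return Dihedral angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0) {
    abort("Degenerate geometry: consecutive dihedral points coincide.")
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    abort("Degenerate geometry: three consecutive dihedral points are collinear.")
  }
  b2u <- b2 / sqrt(sum(b2^2))
  m1 <- cross3(b2u, n1)
  deg <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (deg <= -180) deg <- deg + 360
  deg
}

#' Planar angle at a vertex
#'
#' @param p1,p2,p3 Numeric length-3 coordinates; the angle is measured at
#'   `p2`.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
bend_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2
  v2 <- p3 - p2
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    abort("Degenerate geometry: angle points coincide.")
  }
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Kabsch least-squares rotation mapping rows of A (centred) onto rows of
# B (centred); row-vector convention, i.e. A_centred %*% rotation ~ B_centred.
kabsch <- function(A, B) {
  ca <- colMeans(A)
  cb <- colMeans(B)
  A1 <- sweep(A, 2, ca)
  B1 <- sweep(B, 2, cb)
  s <- svd(t(A1) %*% B1)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  moved <- A1 %*% R
  list(
    rotation = R, mobile_center = ca, target_center = cb,
    rmsd = sqrt(mean(rowSums((moved - B1)^2)))
  )
}

#' Least-squares rigid superposition of two conformers
#'
#' Optimally superposes `mobile` onto `target` over a named atom subset
#' (Kabsch algorithm) and reports the post-fit RMSD over that subset.
#'
#' @param mobile,target Conformer tibbles sharing the subset atoms.
#' @param atoms Atom names to fit on (>= 3); defaults to the five-atom
#'   glycosidic core C5', C4', O4', C1', N9.
#' @return A list with `rotation` (3x3, row-vector convention),
#'   `mobile_center`, `target_center`, `rmsd` (A over the subset) and
#'   `conformer`, the full mobile conformer after transformation.
#' @export
superpose <- function(mobile, target, atoms = sam_superposition_atoms) {
  if (length(atoms) < 3) abort("Superposition needs at least 3 atoms.")
  A <- conformer_coords(mobile, atoms)
  B <- conformer_coords(target, atoms)
  fit <- kabsch(A, B)
  xyz <- conformer_coords(mobile)
  moved <- sweep(xyz, 2, fit$mobile_center) %*% fit$rotation
  moved <- sweep(moved, 2, fit$target_center, "+")
  out <- mobile
  out$x <- moved[, 1]
  out$y <- moved[, 2]
  out$z <- moved[, 3]
  fit$conformer <- out
  fit
}

#' Heavy-atom RMSD between two conformers after optimal superposition
#'
#' @param a,b Conformer tibbles.
#' @param atoms Atom subset; defaults to the 27 heavy atoms of SAM.
#' @return RMSD in Angstrom over `atoms` after Kabsch superposition on
#'   the same subset.
#' @export
heavy_atom_rmsd <- function(a, b, atoms = sam_heavy_atoms) {
  kabsch(conformer_coords(a, atoms), conformer_coords(b, atoms))$rmsd
}

#' Interproton distances on a conformer, with pseudo-atom handling
#'
#' Euclidean distance between the two protons of each pair. For the
#' methyl pseudo-atom (`MET-CH3`) the default is the r^-6-effective
#' distance over its three protons,
#' `d_eff = (mean(d_k^-6))^(-1/6)`, which is the distance the NOE sees for
#' fast-rotating equivalent protons; `method = "centroid"` instead
#' measures to the geometric centre of the methyl protons.
#'
#' @param conformer A conformer tibble containing the required protons.
#' @param pairs A data frame with columns `atom1`, `atom2` (canonical or
#'   dialect proton labels), e.g. a restraint table.
#' @param method Pseudo-atom averaging: `"r6"` (default) or `"centroid"`.
#' @return Numeric vector of distances (A), one per pair row.
#' @export
interproton_distance <- function(conformer, pairs, method = c("r6", "centroid")) {
  method <- match.arg(method)
  a1 <- normalize_proton_label(pairs$atom1)
  a2 <- normalize_proton_label(pairs$atom2)
  xyz <- conformer_coords(conformer)
  get_protons <- function(label) {
    nm <- proton_atom_names(label)
    idx <- match(nm, rownames(xyz))
    if (anyNA(idx)) {
      abort(sprintf(
        "Conformer %s is missing proton atom(s) %s for label %s",
        conformer$conformer_id[1], paste(nm[is.na(idx)], collapse = ", "), label
      ))
    }
    xyz[idx, , drop = FALSE]
  }
  vapply(seq_along(a1), function(i) {
    P <- get_protons(a1[i])
    Q <- get_protons(a2[i])
    if (method == "centroid") {
      P <- matrix(colMeans(P), 1)
      Q <- matrix(colMeans(Q), 1)
    }
    d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
    d <- sqrt(pmax(d2, 0))
    if (method == "centroid") d[1, 1] else mean(d^-6)^(-1 / 6)
  }, numeric(1))
}

#' Per-atom root-mean-square fluctuation of an ensemble
#'
#' Superposes every conformer onto the first on `fit_atoms`, then reports
#' each atom's RMS deviation from its ensemble-mean position.
#'
#' @param ensemble An ensemble tibble.
#' @param atoms Atoms to report fluctuations for (default: the 27 SAM
#'   heavy atoms).
#' @param fit_atoms Atoms used for superposition (default: same as
#'   `atoms`).
#' @return A tibble with columns `atom` and `rmsf` (A).
#' @export
conformer_rmsf <- function(ensemble, atoms = sam_heavy_atoms, fit_atoms = atoms) {
  ids <- conformer_ids(ensemble)
  if (length(ids) == 0) abort("Empty ensemble.")
  parts <- split(ensemble, factor(ensemble$conformer_id, levels = ids))
  ref <- parts[[1]]
  coords <- lapply(parts, function(cf) {
    if (identical(cf$conformer_id[1], ref$conformer_id[1])) {
      conformer_coords(cf, atoms)
    } else {
      conformer_coords(superpose(cf, ref, fit_atoms)$conformer, atoms)
    }
  })
  arr <- simplify2array(coords) # atoms x 3 x n
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- apply(
    sweep(arr, c(1, 2), mean_pos)^2,
    3, rowSums
  ) # atoms x n
  tibble::tibble(atom = atoms, rmsf = sqrt(rowMeans(matrix(dev2, nrow = length(atoms)))))
}
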