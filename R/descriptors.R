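#' Classification windows for SAM conformational descriptors
#'
#' Degree windows over the glycosidic dihedral chi (O4'-C1'-N9-C8) and the
#' bend angle theta (SD-O4'-N9) that define the conformational classes:
#'
#' * `syn`: chi in `[-150, -100]`
#' * `anti1`: chi in `[-30, 30]`
#' * `anti2`: chi in `[50, 100]`
#' * `intermediate`: chi in `(-100, -50)` — the transient state between
#'   anti1 and syn
#' * anything else: `other`
#' * `bent`: theta in `[80, 125]`; everything outside is `extended`
#' * knotted-methyltransferase-like: theta in `[80, 125]` AND chi in
#'   `[-20, 60]` — the two-dimensional window occupied by SAM bound to
#'   knotted methyltransferases.
#'
#' All chi windows are closed intervals (inclusive at both bounds) except
#' the intermediate window, which is open so that it never overlaps the
#' syn window at -100.
#'
#' @param syn,anti1,anti2,intermediate Length-2 numeric chi windows
#'   (degrees).
#' @param bent Length-2 numeric theta window (degrees).
#' @param knotted_theta,knotted_chi The two-dimensional knotted-MT window.
#' @return An object of class `sam_rules`.
#' @export
glyco_rules <- function(syn = c(-150, -100),
                        anti1 = c(-30, 30),
                        anti2 = c(50, 100),
                        intermediate = c(-100, -50),
                        bent = c(80, 125),
                        knotted_theta = c(80, 125),
                        knotted_chi = c(-20, 60)) {
  chk <- function(w, nm, lo, hi) {
    if (length(w) != 2 || w[1] > w[2] || w[1] < lo || w[2] > hi) {
      abort(sprintf("Window `%s` must be an increasing pair within [%g, %g].", nm, lo, hi))
    }
  }
  chk(syn, "syn", -180, 180); chk(anti1, "anti1", -180, 180)
  chk(anti2, "anti2", -180, 180); chk(intermediate, "intermediate", -180, 180)
  chk(bent, "bent", 0, 180)
  chk(knotted_theta, "knotted_theta", 0, 180); chk(knotted_chi, "knotted_chi", -180, 180)
  overlaps <- function(a, b) max(a[1], b[1]) < min(a[2], b[2])
  wins <- list(syn = syn, anti1 = anti1, anti2 = anti2, intermediate = intermediate)
  pairs <- combn(names(wins), 2)
  for (j in seq_len(ncol(pairs))) {
    if (overlaps(wins[[pairs[1, j]]], wins[[pairs[2, j]]])) {
      abort(sprintf("Chi windows `%s` and `%s` overlap.", pairs[1, j], pairs[2, j]))
    }
  }
  structure(
    list(
      syn = syn, anti1 = anti1, anti2 = anti2, intermediate = intermediate,
      bent = bent, knotted_theta = knotted_theta, knotted_chi = knotted_chi
    ),
    class = "sam_rules"
  )
}

in_window <- function(x, w, closed = TRUE) {
  if (closed) x >= w[1] & x <= w[2] else x > w[1] & x < w[2]
}

#' Classify the glycosidic dihedral
#'
#' Total, single-valued classification of chi values into
#' `syn` / `anti1` / `anti2` / `intermediate` / `other` under the windows
#' in `rules`.
#'
#' @param chi Glycosidic dihedral values in degrees, in (-180, 180].
#' @param rules A [glyco_rules()] object.
#' @return Character vector of classes.
#' @examples
#' classify_glycosidic(c(-120, 0, 75, -60, 40))
#' @export
classify_glycosidic <- function(chi, rules = glyco_rules()) {
  stopifnot(inherits(rules, "sam_rules"))
  if (any(chi <= -180 | chi > 180, na.rm = TRUE)) {
    abort("`chi` must lie in (-180, 180].")
  }
  dplyr::case_when(
    in_window(chi, rules$syn) ~ "syn",
    in_window(chi, rules$anti1) ~ "anti1",
    in_window(chi, rules$anti2) ~ "anti2",
    in_window(chi, rules$intermediate, closed = FALSE) ~ "intermediate",
    TRUE ~ "other"
  )
}

#' Classify the overall bend of the molecule
#'
#' `bent` when the SD-O4'-N9 angle lies inside the bent window (default
#' `[80, 125]` degrees), `extended` otherwise.
#'
#' @param theta Bend angle values in degrees, in `[0, 180]`.
#' @param rules A [glyco_rules()] object.
#' @return Character vector, `"bent"` or `"extended"`.
#' @export
classify_shape <- function(theta, rules = glyco_rules()) {
  stopifnot(inherits(rules, "sam_rules"))
  if (any(theta < 0 | theta > 180, na.rm = TRUE)) {
    abort("`theta` must lie in [0, 180].")
  }
  ifelse(in_window(theta, rules$bent), "bent", "extended")
}

#' Is a conformation inside the knotted-methyltransferase window?
#'
#' SAM bound to knotted methyltransferases occupies a characteristic
#' two-dimensional window: theta in `[80, 125]` and chi in `[-20, 60]`
#' under the default rules.
#'
#' @param theta,chi Descriptor values in degrees.
#' @param rules A [glyco_rules()] object.
#' @return Logical vector.
#' @export
is_knotted_mt_like <- function(theta, chi, rules = glyco_rules()) {
  stopifnot(inherits(rules, "sam_rules"))
  in_window(theta, rules$knotted_theta) & in_window(chi, rules$knotted_chi)
}

#' Compute conformational descriptors for every conformer in an ensemble
#'
#' For each conformer, the glycosidic dihedral chi (atoms O4', C1', N9,
#' C8), the bend angle theta (atoms SD, O4', N9), and their classes.
#'
#' @param ensemble A conformer or ensemble tibble containing the
#'   descriptor atoms SD, O4', C1', N9, C8.
#' @param rules A [glyco_rules()] object.
#' @return A tibble with one row per conformer: `conformer_id`, `chi_deg`,
#'   `theta_deg`, `glyco_class`, `shape_class`, `knotted_mt_like`.
#' @export
describe_conformers <- function(ensemble, rules = glyco_rules()) {
  ids <- conformer_ids(ensemble)
  parts <- split(ensemble, factor(ensemble$conformer_id, levels = ids))
  rows <- purrr::map(parts, function(cf) {
    xyz <- conformer_coords(cf, sam_descriptor_atoms) # SD, O4', C1', N9, C8
    tibble::tibble(
      conformer_id = cf$conformer_id[1],
      chi_deg = dihedral_angle(xyz["O4'", ], xyz["C1'", ], xyz["N9", ], xyz["C8", ]),
      theta_deg = bend_angle(xyz["SD", ], xyz["O4'", ], xyz["N9", ])
    )
  })
  out <- dplyr::bind_rows(rows)
  out$glyco_class <- classify_glycosidic(out$chi_deg, rules)
  out$shape_class <- classify_shape(out$theta_deg, rules)
  out$knotted_mt_like <- is_knotted_mt_like(out$theta_deg, out$chi_deg, rules)
  out
}
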