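#' ROESY calibration against the H1'-H2' reference peak
#'
#' The isolated spin-pair approximation relates a ROESY cross-peak
#' intensity `I` to the interproton distance `r` through a reference peak
#' of known distance: `r = (I_ref / I)^(1/6) * r_ref`. For SAM the
#' H1'-H2' pair serves as the internal reference, with a literature
#' distance of 2.90 A and 0.2 A uncertainty.
#'
#' Intensities are in arbitrary units: only the ratio `I_ref / I` enters
#' the calculation, so no unit is stored. When the reference peak is
#' absent from a user's peak table, `i_ref` must be supplied explicitly —
#' the calibration is underdetermined without it.
#'
#' @param i_ref Intensity of the reference cross peak (arbitrary units,
#'   > 0).
#' @param di_ref Intensity error of the reference peak (same units, >= 0).
#' @param r_ref Reference interproton distance in Angstrom (default the
#'   H1'-H2' value 2.90).
#' @param dr_ref Uncertainty of `r_ref` in Angstrom (default 0.2).
#' @param reference_pair Canonical labels of the reference protons.
#' @return An object of class `sam_calibration`.
#' @examples
#' cal <- roesy_calibration(i_ref = 1000)
#' @export
roesy_calibration <- function(i_ref, di_ref = 0, r_ref = 2.90, dr_ref = 0.2,
                              reference_pair = c("H1'", "H2'")) {
  stopifnot(length(i_ref) == 1, length(r_ref) == 1)
  if (!is.finite(i_ref) || i_ref <= 0) {
    abort("Reference intensity `i_ref` must be a positive number.")
  }
  if (r_ref <= 0) abort("Reference distance `r_ref` must be positive.")
  if (di_ref < 0 || dr_ref < 0) {
    abort("Calibration uncertainties `di_ref` and `dr_ref` must be >= 0.")
  }
  structure(
    list(
      i_ref = i_ref, di_ref = di_ref,
      r_ref = r_ref, dr_ref = dr_ref,
      reference_pair = normalize_proton_label(reference_pair)
    ),
    class = "sam_calibration"
  )
}

#' @export
print.sam_calibration <- function(x, ...) {
  cat(sprintf(
    "ROESY calibration: %s-%s reference, r_ref = %.2f +/- %.2f A, I_ref = %g +/- %g\n",
    x$reference_pair[1], x$reference_pair[2],
    x$r_ref, x$dr_ref, x$i_ref, x$di_ref
  ))
  invisible(x)
}

#' Convert ROESY cross-peak intensities to distance restraints
#'
#' Applies the isolated spin-pair relation
#' `r = (I_ref / I)^(1/6) * r_ref` to every cross peak and fills the
#' propagated uncertainty from [propagate_distance_error()].
#'
#' @param peaks A data frame of cross peaks with columns `atom1`, `atom2`
#'   (proton labels in any accepted dialect), `intensity` (> 0) and
#'   optionally `intensity_error` (>= 0, defaults to 0).
#' @param cal A [roesy_calibration()].
#' @return A restraint tibble with columns `atom1`, `atom2`, `distance`
#'   (A) and `error` (A), in the input row order. Distances are kept at
#'   full precision; round only for presentation.
#' @examples
#' cal <- roesy_calibration(i_ref = 1000)
#' peaks <- tibble::tibble(atom1 = "H8", atom2 = "H1'", intensity = 1000)
#' intensity_to_distance(peaks, cal) # recovers r_ref exactly
#' @export
intensity_to_distance <- function(peaks, cal) {
  stopifnot(inherits(cal, "sam_calibration"))
  peaks <- tibble::as_tibble(peaks)
  required <- c("atom1", "atom2", "intensity")
  missing <- setdiff(required, names(peaks))
  if (length(missing)) {
    abort(sprintf("`peaks` is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"intensity_error" %in% names(peaks)) peaks$intensity_error <- 0
  a1 <- normalize_proton_label(peaks$atom1)
  a2 <- normalize_proton_label(peaks$atom2)
  same <- a1 == a2
  if (any(same)) {
    abort(sprintf("Cross peak with identical protons: %s", paste(unique(a1[same]), collapse = ", ")))
  }
  bad <- !is.finite(peaks$intensity) | peaks$intensity <= 0
  if (any(bad)) {
    abort(sprintf(
      "Non-positive intensity for pair(s): %s",
      paste(sprintf("%s-%s", a1[bad], a2[bad]), collapse = ", ")
    ))
  }
  tibble::tibble(
    atom1 = a1,
    atom2 = a2,
    distance = (cal$i_ref / peaks$intensity)^(1 / 6) * cal$r_ref,
    error = propagate_distance_error(peaks$intensity, peaks$intensity_error, cal)
  )
}

#' Propagate the ROESY distance uncertainty
#'
#' First-order error propagation of `r = (I_ref / I)^(1/6) * r_ref` under
#' independent errors: the quadrature sum of the three partial-derivative
#' terms
#' `(dr/dr_ref) * dr_ref`, `(dr/dI_ref) * dI_ref` and `(dr/dI) * dI`, with
#' `dr/dr_ref = (I_ref/I)^(1/6)`,
#' `dr/dI_ref = (1/6) I_ref^(-5/6) I^(-1/6) r_ref` and
#' `dr/dI = -(1/6) I_ref^(1/6) r_ref I^(-7/6)`.
#'
#' With both intensity errors zero the result reduces to
#' `dr = (r / r_ref) * dr_ref`.
#'
#' @param intensity Cross-peak intensities (> 0), arbitrary units.
#' @param intensity_error Per-peak intensity errors (>= 0), same units.
#' @param cal A [roesy_calibration()].
#' @return Numeric vector of distance uncertainties in Angstrom (>= 0).
#' @export
propagate_distance_error <- function(intensity, intensity_error, cal) {
  stopifnot(inherits(cal, "sam_calibration"))
  if (any(!is.finite(intensity) | intensity <= 0)) {
    abort("Intensities must be positive and finite.")
  }
  if (any(intensity_error < 0)) abort("Intensity errors must be >= 0.")
  term_rref <- (cal$i_ref / intensity)^(1 / 6) * cal$dr_ref
  term_iref <- (1 / 6) * cal$i_ref^(-5 / 6) * intensity^(-1 / 6) * cal$r_ref * cal$di_ref
  term_i <- (1 / 6) * cal$i_ref^(1 / 6) * cal$r_ref * intensity^(-7 / 6) * intensity_error
  sqrt(term_rref^2 + term_iref^2 + term_i^2)
}

pair_key <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "|")
}

#' Read and write interproton distance restraint tables
#'
#' Restraint tables are UTF-8 TSV files with header columns `Atom1`,
#' `Atom2`, `Distance_A`, `Error_A`; lines starting with `#` are comments.
#' Proton labels are normalized to the canonical vocabulary on read and
#' row order is preserved. Unordered proton pairs must be unique within a
#' table. `write_restraint_table()` writes at full precision so that a
#' read/write round trip is lossless.
#'
#' @param path File path.
#' @return `read_restraint_table()` returns a tibble with columns `atom1`,
#'   `atom2`, `distance`, `error`.
#' @seealso [sam_restraints()] for the packaged SAM table.
#' @export
read_restraint_table <- function(path) {
  raw <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      Atom1 = readr::col_character(),
      Atom2 = readr::col_character(),
      Distance_A = readr::col_double(),
      Error_A = readr::col_double()
    )
  )
  missing <- setdiff(c("Atom1", "Atom2", "Distance_A", "Error_A"), names(raw))
  if (length(missing)) {
    abort(sprintf("Restraint table %s lacks column(s): %s", path, paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    atom1 = normalize_proton_label(raw$Atom1),
    atom2 = normalize_proton_label(raw$Atom2),
    distance = raw$Distance_A,
    error = raw$Error_A
  )
  validate_restraints(out)
  out
}

validate_restraints <- function(table) {
  if (nrow(table) == 0) return(invisible(table))
  if (any(table$atom1 == table$atom2)) abort("Restraint with identical protons.")
  if (any(!is.finite(table$distance) | table$distance <= 0)) {
    abort("Restraint distances must be positive.")
  }
  if (any(!is.finite(table$error) | table$error < 0)) {
    abort("Restraint errors must be >= 0.")
  }
  keys <- pair_key(table$atom1, table$atom2)
  dup <- duplicated(keys)
  if (any(dup)) {
    abort(sprintf(
      "Duplicated restraint pair(s): %s",
      paste(unique(sprintf("%s-%s", table$atom1[dup], table$atom2[dup])), collapse = ", ")
    ))
  }
  invisible(table)
}

#' @param table A restraint tibble (columns `atom1`, `atom2`, `distance`,
#'   `error`).
#' @rdname read_restraint_table
#' @export
write_restraint_table <- function(table, path) {
  validate_restraints(tibble::as_tibble(table))
  out <- tibble::tibble(
    Atom1 = table$atom1, Atom2 = table$atom2,
    Distance_A = table$distance, Error_A = table$error
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a ROESY cross-peak table
#'
#' TSV with columns `Atom1`, `Atom2`, `Intensity` and optionally
#' `IntensityError`; `#` comment lines allowed.
#'
#' @param path File path.
#' @return A tibble with columns `atom1`, `atom2`, `intensity`,
#'   `intensity_error`.
#' @export
read_cross_peaks <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("Atom1", "Atom2", "Intensity"), names(raw))
  if (length(missing)) {
    abort(sprintf("Cross-peak table %s lacks column(s): %s", path, paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    atom1 = normalize_proton_label(raw$Atom1),
    atom2 = normalize_proton_label(raw$Atom2),
    intensity = raw$Intensity,
    intensity_error = if ("IntensityError" %in% names(raw)) raw$IntensityError else 0
  )
}

#' The packaged SAM interproton restraint table
#'
#' The 39 ROESY-derived interproton distances of SAM in water at 25 C,
#' with their uncertainties, shipped as a plain-text fixture.
#'
#' @return A restraint tibble (columns `atom1`, `atom2`, `distance`,
#'   `error`) with 39 rows.
#' @examples
#' sam_restraints()
#' @export
sam_restraints <- function() {
  read_restraint_table(
    system.file("extdata", "sam_roesy_distances_25C.tsv", package = "samconf", mustWork = TRUE)
  )
}
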