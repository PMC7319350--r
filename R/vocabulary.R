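#' Canonical atom vocabularies for SAM-like ligands
#'
#' Named constants describing the atoms of S-adenosylmethionine (SAM) and
#' S-adenosylhomocysteine (SAH) used throughout the package:
#'
#' * `sam_heavy_atoms`: the 27 heavy atoms of SAM (15 C, 6 N, 5 O, 1 S) —
#'   the default subset for ensemble clustering and RMSD.
#' * `sam_superposition_atoms`: the five-atom core (C5', C4', O4', C1', N9)
#'   used to superpose conformers about the glycosidic linkage.
#' * `sam_descriptor_atoms`: the atoms required to compute the two
#'   conformational descriptors (glycosidic dihedral O4'-C1'-N9-C8 and bend
#'   angle SD-O4'-N9).
#' * `sam_proton_vocabulary`: the canonical proton labels of the ROESY
#'   restraint bookkeeping, with `MET-CH3` flagged as the methyl
#'   pseudo-atom.
#'
#' @format `sam_heavy_atoms`, `sam_superposition_atoms` and
#'   `sam_descriptor_atoms` are character vectors; `sam_proton_vocabulary`
#'   is a tibble with columns `label` and `pseudo`.
#' @name sam_vocabulary
NULL

#' @rdname sam_vocabulary
#' @export
sam_heavy_atoms <- c(
  # methionine moiety
  "N", "CA", "C", "O", "OXT", "CB", "CG", "SD", "CE",
  # ribose
  "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'",
  # adenine
  "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"
)

#' @rdname sam_vocabulary
#' @export
sam_superposition_atoms <- c("C5'", "C4'", "O4'", "C1'", "N9")

#' @rdname sam_vocabulary
#' @export
sam_descriptor_atoms <- c("SD", "O4'", "C1'", "N9", "C8")

#' @rdname sam_vocabulary
#' @export
sam_proton_vocabulary <- tibble::tibble(
  label = c(
    "H1'", "H2'", "H3'", "H4'", "H5'", "H5''",
    "H8", "H2", "Halpha", "Hbeta", "Hgamma", "Hgamma'", "MET-CH3"
  ),
  pseudo = c(rep(FALSE, 12), TRUE)
)

# Accepted spelling dialects -> canonical label. Keys are matched after
# squeezing case and whitespace; primes are normalised separately.
.proton_aliases <- c(
  "h1'" = "H1'", "h-1'" = "H1'",
  "h2'" = "H2'", "h-2'" = "H2'",
  "h3'" = "H3'", "h-3'" = "H3'",
  "h4'" = "H4'", "h-4'" = "H4'",
  "h5'" = "H5'", "h-5'" = "H5'", "h5'1" = "H5'",
  "h5''" = "H5''", "h-5''" = "H5''", "h5'2" = "H5''",
  "h8" = "H8", "h-8" = "H8",
  "h2" = "H2", "h-2" = "H2",
  "halpha" = "Halpha", "ha" = "Halpha", "hα" = "Halpha",
  "hbeta" = "Hbeta", "hb" = "Hbeta", "hβ" = "Hbeta",
  "hgamma" = "Hgamma", "hg" = "Hgamma", "hγ" = "Hgamma",
  "hgamma'" = "Hgamma'", "hg'" = "Hgamma'", "hγ'" = "Hgamma'",
  "met-ch3" = "MET-CH3", "methyl group" = "MET-CH3",
  "methyl" = "MET-CH3", "ch3" = "MET-CH3", "me" = "MET-CH3"
)

#' Normalize proton labels to the canonical SAM vocabulary
#'
#' Accepts common spelling dialects (`H5"`, `H5'2`, `HB`, Greek `Hβ`,
#' `"methyl group"`, ...) and returns the canonical label. Unknown tokens
#' raise an error naming the offending input.
#'
#' @param x Character vector of proton labels.
#' @return Character vector of canonical labels (see
#'   [sam_proton_vocabulary]).
#' @examples
#' normalize_proton_label(c("H5\"", "methyl group", "HB"))
#' @export
normalize_proton_label <- function(x) {
  raw <- x
  x <- trimws(as.character(x))
  # prime dialects: typographic quotes and doubled apostrophes
  x <- gsub("’", "'", x)
  x <- gsub("”", "''", x)
  x <- gsub('"', "''", x)
  key <- tolower(gsub("[*]", "", x))
  key <- gsub("\\s+", " ", key)
  out <- unname(.proton_aliases[key])
  bad <- is.na(out) & !is.na(raw)
  if (any(bad)) {
    abort(sprintf(
      "Unknown proton label(s): %s",
      paste(unique(raw[bad]), collapse = ", ")
    ))
  }
  out
}

#' Is a canonical proton label a pseudo-atom?
#'
#' @param label Canonical proton labels (see [normalize_proton_label]).
#' @return Logical vector; `TRUE` for pseudo-atoms such as the methionine
#'   methyl group.
#' @export
is_pseudo_proton <- function(label) {
  label %in% sam_proton_vocabulary$label[sam_proton_vocabulary$pseudo]
}

# Canonical proton label -> structure atom name(s). The methyl pseudo-atom
# expands to its three protons.
.proton_atoms <- list(
  "H1'" = "H1'", "H2'" = "H2'", "H3'" = "H3'", "H4'" = "H4'",
  "H5'" = "H5'", "H5''" = "H5''",
  "H8" = "H8", "H2" = "H2",
  "Halpha" = "HA", "Hbeta" = "HB",
  "Hgamma" = "HG", "Hgamma'" = "HG'",
  "MET-CH3" = c("HE1", "HE2", "HE3")
)

proton_atom_names <- function(label) {
  out <- .proton_atoms[[label]]
  if (is.null(out)) abort(sprintf("No structure atoms mapped for proton label '%s'", label))
  out
}

#' Moiety partition of SAM/SAH heavy atoms
#'
#' Every heavy atom of SAM (and of SAH, whose atoms are a subset) is
#' assigned to exactly one of the three chemical moieties: the adenine base
#' (purine ring plus the exocyclic N6), the ribose sugar (ring plus O2',
#' O3' and C5'), and the methionine chain (from SD through the amino-acid
#' backbone; the homocysteine chain of SAH maps identically, minus the
#' methyl carbon).
#'
#' @return A tibble with columns `atom` and `moiety`
#'   (`"adenine"`, `"ribose"` or `"methionine"`).
#' @export
sam_moieties <- function() {
  tibble::tibble(
    atom = sam_heavy_atoms,
    moiety = dplyr::case_when(
      sam_heavy_atoms %in% c("N", "CA", "C", "O", "OXT", "CB", "CG", "SD", "CE") ~ "methionine",
      grepl("'", sam_heavy_atoms, fixed = TRUE) ~ "ribose",
      TRUE ~ "adenine"
    )
  )
}
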