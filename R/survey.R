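read_structure <- function(path, multi = FALSE) {
  if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path, multi = multi, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  }
}

#' Extract SAM/SAH ligand conformers from a protein-ligand structure file
#'
#' Reads a PDB or mmCIF file and returns one conformer per ligand
#' instance (chain + residue number) per selected model. By default only
#' the first model is used; `all_models = TRUE` returns every MODEL of an
#' NMR-style multi-model file. Alternate locations are resolved to the
#' highest occupancy (ties to the alphabetically first altloc). Atom
#' names are normalised to prime notation (`C5'`).
#'
#' @param path Structure file (PDB or mmCIF), or a `bio3d` pdb object.
#' @param het_codes HET residue names to extract (default SAM and SAH).
#' @param all_models Extract every model instead of only the first.
#' @return An ensemble tibble with provenance columns `source` (file),
#'   `model`, `chain`, `resno` and `resid`. Empty (with a warning) when
#'   no matching HET residue exists.
#' @export
extract_ligands <- function(path, het_codes = c("SAM", "SAH"), all_models = FALSE) {
  if (inherits(path, "pdb")) {
    pdb <- path
    src <- "pdb_object"
  } else {
    pdb <- read_structure(path, multi = all_models)
    src <- basename(path)
  }
  at <- pdb$atom
  at$elety <- gsub("\\*", "'", at$elety)
  sel <- which(at$resid %in% het_codes)
  empty <- tibble::tibble(
    conformer_id = character(), atom = character(), element = character(),
    x = numeric(), y = numeric(), z = numeric(),
    source = character(), model = integer(),
    chain = character(), resno = integer(), resid = character()
  )
  if (!length(sel)) {
    warn(sprintf("No HET residue among {%s} found in %s.",
                 paste(het_codes, collapse = ", "), src))
    return(empty)
  }
  lat <- at[sel, , drop = FALSE]
  lat$.row <- sel
  ins <- lat$insert
  ins[is.na(ins)] <- ""
  lat$.instance <- paste0(lat$chain, lat$resno, ins)

  # altloc: keep the highest-occupancy copy of each atom, ties -> first alt
  alt <- lat$alt
  alt[is.na(alt)] <- ""
  occ <- lat$o
  occ[is.na(occ)] <- 1
  lat <- lat[order(lat$.instance, lat$elety, -occ, alt), , drop = FALSE]
  lat <- lat[!duplicated(paste(lat$.instance, lat$elety)), , drop = FALSE]
  lat <- lat[order(lat$.row), , drop = FALSE]

  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_models <- if (all_models) nrow(xyz) else 1L
  base_id <- sub("\\.(pdb|cif)(\\.gz)?$", "", src, ignore.case = TRUE)

  out <- purrr::map_dfr(seq_len(n_models), function(m) {
    tibble::tibble(
      conformer_id = if (n_models > 1) {
        sprintf("%s_%s_m%d", base_id, lat$.instance, m)
      } else {
        sprintf("%s_%s", base_id, lat$.instance)
      },
      atom = lat$elety,
      element = ifelse(is.na(lat$elesy) | lat$elesy == "",
                       guess_element(lat$elety), lat$elesy),
      x = xyz[m, 3 * lat$.row - 2],
      y = xyz[m, 3 * lat$.row - 1],
      z = xyz[m, 3 * lat$.row],
      source = src,
      model = m,
      chain = lat$chain,
      resno = lat$resno,
      resid = lat$resid
    )
  })
  out
}

#' Binding-site residues in contact with a bound ligand
#'
#' Lists every protein residue with at least one atom within `cutoff` of
#' any ligand atom (heavy atoms only by default, since crystal structures
#' usually lack hydrogens). For each contacting residue the minimum
#' distance is reported together with the ligand moiety (adenine, ribose
#' or methionine) achieving it and whether the protein atom at the
#' minimum is a backbone atom (N, CA, C or O). Waters and other
#' heteroatoms are excluded.
#'
#' @param path Structure file (PDB/mmCIF) or `bio3d` pdb object.
#' @param ligand Optional instance selector `list(chain =, resno =)`;
#'   default: the first SAM/SAH instance in the file.
#' @param cutoff Contact cutoff in Angstrom (default 5.0).
#' @param het_codes Ligand residue names (default SAM, SAH).
#' @param heavy_only Ignore hydrogens on both sides (default `TRUE`).
#' @return A tibble with one row per contacting residue: `structure_id`,
#'   `ligand_chain`, `ligand_resno`, `chain`, `resno`, `residue`,
#'   `min_distance`, `contacted_moiety`, `via_backbone`.
#' @export
binding_site_contacts <- function(path, ligand = NULL, cutoff = 5.0,
                                  het_codes = c("SAM", "SAH"), heavy_only = TRUE) {
  if (inherits(path, "pdb")) {
    pdb <- path
    src <- "pdb_object"
  } else {
    pdb <- read_structure(path)
    src <- basename(path)
  }
  at <- pdb$atom
  at$elety <- gsub("\\*", "'", at$elety)
  at$element <- ifelse(is.na(at$elesy) | at$elesy == "", guess_element(at$elety), at$elesy)

  lig_rows <- at$resid %in% het_codes
  if (!is.null(ligand)) {
    lig_rows <- lig_rows & at$chain == ligand$chain & at$resno == ligand$resno
  }
  if (!any(lig_rows)) {
    abort(sprintf("Requested ligand instance not found in %s.", src))
  }
  # if several instances and none requested, take the first
  ins <- paste0(at$chain, at$resno)
  first_ins <- ins[which(lig_rows)[1]]
  lig_rows <- lig_rows & ins == first_ins

  prot_rows <- at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (heavy_only) {
    lig_rows <- lig_rows & at$element != "H"
    prot_rows <- prot_rows & at$element != "H"
  }
  if (!any(prot_rows)) {
    return(tibble::tibble(
      structure_id = character(), ligand_chain = character(),
      ligand_resno = integer(), chain = character(), resno = integer(),
      residue = character(), min_distance = numeric(),
      contacted_moiety = character(), via_backbone = logical()
    ))
  }

  L <- cbind(at$x[lig_rows], at$y[lig_rows], at$z[lig_rows])
  P <- cbind(at$x[prot_rows], at$y[prot_rows], at$z[prot_rows])
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  d <- sqrt(pmax(d2, 0)) # protein x ligand

  moieties <- sam_moieties()
  lig_moiety <- moieties$moiety[match(at$elety[lig_rows], moieties$atom)]
  pa <- at[prot_rows, , drop = FALSE]
  res_key <- paste(pa$chain, pa$resno, pa$resid)

  min_per_atom <- apply(d, 1, min)
  arg_per_atom <- apply(d, 1, which.min)

  keep <- min_per_atom <= cutoff
  if (!any(keep)) {
    return(tibble::tibble(
      structure_id = character(), ligand_chain = character(),
      ligand_resno = integer(), chain = character(), resno = integer(),
      residue = character(), min_distance = numeric(),
      contacted_moiety = character(), via_backbone = logical()
    ))
  }
  df <- tibble::tibble(
    key = res_key[keep],
    chain = pa$chain[keep],
    resno = pa$resno[keep],
    residue = pa$resid[keep],
    atom = pa$elety[keep],
    dist = min_per_atom[keep],
    moiety = lig_moiety[arg_per_atom[keep]]
  )
  base_id <- sub("\\.(pdb|cif)(\\.gz)?$", "", src, ignore.case = TRUE)
  df |>
    dplyr::group_by(.data$key, .data$chain, .data$resno, .data$residue) |>
    dplyr::slice_min(.data$dist, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      structure_id = base_id,
      ligand_chain = at$chain[which(lig_rows)[1]],
      ligand_resno = at$resno[which(lig_rows)[1]],
      chain = .data$chain,
      resno = .data$resno,
      residue = .data$residue,
      min_distance = .data$dist,
      contacted_moiety = .data$moiety,
      via_backbone = .data$atom %in% c("N", "CA", "C", "O")
    ) |>
    dplyr::arrange(.data$chain, .data$resno)
}

#' Descriptor distributions of labelled conformer groups
#'
#' Bins the two conformational descriptors per user-defined group
#' (e.g. knotted vs unknotted proteins): one-dimensional histograms of
#' chi and theta, the two-dimensional (theta, chi) occupancy table, and
#' the class fractions.
#'
#' @param descriptors A descriptor tibble from [describe_conformers()];
#'   if joined by `structure_id` the tibble must carry that column (as
#'   produced when the ensemble comes from [extract_ligands()]).
#' @param labels A tibble assigning groups, with column `group` plus
#'   either `conformer_id` or `structure_id`.
#' @param bin_width Histogram bin width in degrees (must divide 180).
#' @return An object of class `sam_profiles` holding per-group
#'   descriptors, histograms, the 2-D occupancy table and class
#'   fractions. Histogram masses equal the per-group conformer counts.
#' @export
build_group_profile <- function(descriptors, labels, bin_width = 10) {
  descriptors <- tibble::as_tibble(descriptors)
  labels <- tibble::as_tibble(labels)
  if (!"group" %in% names(labels)) abort("`labels` needs a `group` column.")
  if (180 %% bin_width != 0) abort("`bin_width` must divide 180.")
  if ("conformer_id" %in% names(labels)) {
    joined <- dplyr::left_join(descriptors, labels[, c("conformer_id", "group")],
                               by = "conformer_id")
  } else if ("structure_id" %in% names(labels) && "structure_id" %in% names(descriptors)) {
    joined <- dplyr::left_join(descriptors, labels[, c("structure_id", "group")],
                               by = "structure_id")
  } else {
    abort("`labels` needs `conformer_id` or `structure_id` matching the descriptors.")
  }
  if (any(is.na(joined$group))) {
    abort(sprintf(
      "Unlabelled conformer(s): %s",
      paste(head(joined$conformer_id[is.na(joined$group)], 5), collapse = ", ")
    ))
  }
  # keep label-file groups with zero conformers visible as empty groups
  joined$group <- factor(joined$group, levels = sort(unique(labels$group)))
  chi_breaks <- seq(-180, 180, by = bin_width)
  theta_breaks <- seq(0, 180, by = bin_width)
  joined$chi_bin <- cut(joined$chi_deg, chi_breaks, include.lowest = TRUE)
  joined$theta_bin <- cut(joined$theta_deg, theta_breaks, include.lowest = TRUE)
  mids <- function(breaks) (breaks[-1] + breaks[-length(breaks)]) / 2

  hist1d <- function(var, breaks) {
    joined |>
      dplyr::count(.data$group, bin = .data[[var]], .drop = FALSE) |>
      dplyr::mutate(mid = mids(breaks)[as.integer(.data$bin)]) |>
      dplyr::select("group", "mid", count = "n")
  }
  structure(
    list(
      descriptors = joined,
      groups = dplyr::count(joined, .data$group, name = "n", .drop = FALSE),
      chi_hist = hist1d("chi_bin", chi_breaks),
      theta_hist = hist1d("theta_bin", theta_breaks),
      occupancy = joined |>
        dplyr::count(.data$group, .data$theta_bin, .data$chi_bin, .drop = FALSE) |>
        dplyr::mutate(
          theta_mid = mids(theta_breaks)[as.integer(.data$theta_bin)],
          chi_mid = mids(chi_breaks)[as.integer(.data$chi_bin)]
        ) |>
        dplyr::select("group", "theta_mid", "chi_mid", count = "n"),
      class_fractions = joined |>
        dplyr::count(.data$group, class = .data$glyco_class) |>
        dplyr::group_by(.data$group) |>
        dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
        dplyr::ungroup(),
      bin_width = bin_width
    ),
    class = "sam_profiles"
  )
}

#' @export
print.sam_profiles <- function(x, ...) {
  cat(sprintf("Descriptor profiles for %d group(s), %d degree bins\n",
              nrow(x$groups), x$bin_width))
  print(x$groups, ...)
  invisible(x)
}

#' Side-by-side comparison of group descriptor profiles
#'
#' Tabulates, per group: conformer count, glycosidic class fractions,
#' bent fraction, the fraction inside the knotted-MT (theta, chi) window,
#' and descriptor medians with interquartile ranges. Accepts one
#' `sam_profiles` object or several (they are merged; binning must
#' match). Empty groups yield a zero row flagged in `empty`.
#'
#' @param ... One or more `sam_profiles` objects from
#'   [build_group_profile()].
#' @return A summary tibble with one row per group.
#' @export
compare_groups <- function(...) {
  profiles <- list(...)
  if (!length(profiles) || !all(vapply(profiles, inherits, logical(1), "sam_profiles"))) {
    abort("Arguments must be sam_profiles objects.")
  }
  bw <- unique(vapply(profiles, function(p) p$bin_width, numeric(1)))
  if (length(bw) != 1) abort("Profiles use different binning; rebuild with a common bin_width.")
  desc <- dplyr::bind_rows(lapply(profiles, function(p) p$descriptors))
  all_groups <- unique(unlist(lapply(profiles, function(p) levels(p$descriptors$group))))
  desc$group <- as.character(desc$group)
  frac <- function(x) if (length(x)) mean(x) else 0
  out <- desc |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      syn = frac(.data$glyco_class == "syn"),
      anti1 = frac(.data$glyco_class == "anti1"),
      anti2 = frac(.data$glyco_class == "anti2"),
      intermediate = frac(.data$glyco_class == "intermediate"),
      other = frac(.data$glyco_class == "other"),
      bent = frac(.data$shape_class == "bent"),
      knotted_mt_like = frac(.data$knotted_mt_like),
      chi_median = median(.data$chi_deg),
      chi_iqr = stats::IQR(.data$chi_deg),
      theta_median = median(.data$theta_deg),
      theta_iqr = stats::IQR(.data$theta_deg),
      .groups = "drop"
    )
  missing <- setdiff(all_groups, out$group)
  if (length(missing)) {
    out <- dplyr::bind_rows(out, tibble::tibble(group = missing, n = 0L))
  }
  out$empty <- out$n == 0
  dplyr::arrange(out, .data$group)
}

#' @rdname build_group_profile
#' @param object A `sam_profiles` object.
#' @param which Which distribution to draw: `"chi"`, `"theta"` or the 2-D
#'   `"map"`.
#' @param ... Unused.
#' @export
autoplot.sam_profiles <- function(object, which = c("chi", "theta", "map"), ...) {
  which <- match.arg(which)
  if (which == "map") {
    df <- dplyr::filter(object$occupancy, .data$count > 0)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$chi_mid, y = .data$theta_mid,
                                       fill = .data$count)) +
        ggplot2::geom_tile() +
        ggplot2::facet_wrap(~group) +
        ggplot2::labs(x = "glycosidic dihedral χ (°)", y = "bend angle θ (°)",
                      fill = "conformers") +
        ggplot2::theme_minimal()
    )
  }
  df <- if (which == "chi") object$chi_hist else object$theta_hist
  xlab <- if (which == "chi") "glycosidic dihedral χ (°)" else "bend angle θ (°)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count, fill = .data$group)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, width = object$bin_width) +
    ggplot2::labs(x = xlab, y = "conformers", fill = "group") +
    ggplot2::theme_minimal()
}
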