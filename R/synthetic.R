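#' Mixture components and specs for synthetic SAM ensembles
#'
#' A synthetic ensemble is a mixture over conformational states. Each
#' component fixes the methionine-chain torsions and draws the glycosidic
#' dihedral chi from a wrapped normal distribution; its weight is the
#' ground-truth population. The generator emulates what a solution MD
#' trajectory of free SAM samples — interchange between syn and anti
#' glycosidic states with a flexible methionine chain — without any
#' force-field energetics.
#'
#' @param name Component name.
#' @param chi_mean,chi_sd Wrapped-normal parameters of the glycosidic
#'   dihedral (degrees; `chi_sd >= 0`).
#' @param met_torsions Named numeric vector of chain torsion targets
#'   (`met1`..`met5`, degrees); see [sam_template()].
#' @param weight Mixture weight (fraction).
#' @return `mixture_component()` returns a `sam_component`;
#'   `synthetic_spec()` returns a `sam_spec`.
#' @export
mixture_component <- function(name, chi_mean, chi_sd = 0,
                              met_torsions = .extended_torsions, weight = 1) {
  if (chi_sd < 0) abort("`chi_sd` must be >= 0.")
  if (weight < 0) abort("`weight` must be >= 0.")
  structure(
    list(name = name, chi_mean = chi_mean, chi_sd = chi_sd,
         met_torsions = met_torsions, weight = weight),
    class = "sam_component"
  )
}

#' @param components List of [mixture_component()] objects; weights must
#'   sum to 1 (within 1e-9).
#' @param n_conformers Number of conformers to draw (>= 1).
#' @param noise_sigma Multiplicative lognormal sigma applied to simulated
#'   ROESY intensities (>= 0).
#' @param seed Integer seed; generation is bit-reproducible given
#'   `(spec, seed)`.
#' @rdname mixture_component
#' @export
synthetic_spec <- function(components, n_conformers, noise_sigma = 0, seed = 1) {
  if (!length(components) || !all(vapply(components, inherits, logical(1), "sam_component"))) {
    abort("`components` must be a list of mixture_component() objects.")
  }
  w <- vapply(components, function(cc) cc$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) abort("Component weights must sum to 1.")
  if (n_conformers < 1) abort("`n_conformers` must be >= 1.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  nm <- vapply(components, function(cc) cc$name, character(1))
  if (anyDuplicated(nm)) abort("Component names must be unique.")
  structure(
    list(components = components, n_conformers = as.integer(n_conformers),
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "sam_spec"
  )
}

#' Default four-component mixture of free SAM in water
#'
#' The reference study conditions of the synthetic generator: 50%
#' syn + extended, 20% syn + bent (carboxylate away from the ribose
#' hydroxyls), 10% syn + bent (the two groups facing each other, the
#' knotted-MT-like form) and 20% anti1 + extended — i.e. 80% syn / 20%
#' anti1 about the glycosidic angle and 70% extended / 30% bent overall,
#' realised with exactly four conformational states.
#'
#' @param chi_sd Within-component spread of the glycosidic dihedral
#'   (degrees; 0 makes every component a single rigid conformation).
#' @return A list of four [mixture_component()] objects.
#' @export
sam_default_components <- function(chi_sd = 10) {
  list(
    mixture_component("syn_extended", -120, chi_sd, .extended_torsions, 0.5),
    mixture_component("syn_bent_away", -120, chi_sd, .bent_away_torsions, 0.2),
    mixture_component("syn_bent_close", -120, chi_sd, .bent_close_torsions, 0.1),
    mixture_component("anti1_extended", 0, chi_sd, .extended_torsions, 0.2)
  )
}

# Chain torsion sets that bring the sulfur back over the ribose so that
# the SD-O4'-N9 bend angle falls inside the bent window [80, 125]; the
# two variants differ in which face of the ribose the carboxylate ends up
# on. Values chosen once during template construction.
.bent_away_torsions <- c(met1 = -60, met2 = 60, met3 = 90, met4 = 180, met5 = 180)
.bent_close_torsions <- c(met1 = -60, met2 = -80, met3 = -60, met4 = 180, met5 = 180)

wrap_angle <- function(x) {
  out <- (x + 180) %% 360 - 180
  ifelse(out == -180, 180, out)
}

#' Sample a synthetic conformer ensemble with known mixture structure
#'
#' Draws `n_conformers` conformers by assigning each to a mixture
#' component (multinomially, by component weight), drawing its glycosidic
#' dihedral from the component's wrapped normal, and driving the template
#' torsions to the sampled values. Conformers whose torsion targets
#' produce steric clashes (closer than 0.8 x the summed covalent radii on
#' non-bonded pairs) are resampled with a bounded number of retries.
#'
#' @param spec A [synthetic_spec()].
#' @param max_retries Retries per conformer before failing (default 25).
#' @return A `sam_bundle`: list with `ensemble` (conformer tibble),
#'   `labels` (tibble `conformer_id`, `component`, `chi_target`),
#'   `true_populations` (tibble `component`, `weight`), and `spec`.
#'   Deterministic given the spec's seed.
#' @export
sample_ensemble <- function(spec, max_retries = 25) {
  stopifnot(inherits(spec, "sam_spec"))
  set.seed(spec$seed)
  k <- length(spec$components)
  w <- vapply(spec$components, function(cc) cc$weight, numeric(1))
  nm <- vapply(spec$components, function(cc) cc$name, character(1))
  assignment <- sample.int(k, spec$n_conformers, replace = TRUE, prob = w)
  atoms <- rownames(template_cache$xyz)
  elements <- guess_element(atoms)
  exclude <- template_cache$exclude
  sides <- template_cache$sides

  confs <- vector("list", spec$n_conformers)
  chis <- numeric(spec$n_conformers)
  for (i in seq_len(spec$n_conformers)) {
    comp <- spec$components[[assignment[i]]]
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      chi <- wrap_angle(comp$chi_mean + rnorm(1, 0, comp$chi_sd))
      xyz <- template_cache$xyz
      full <- .extended_torsions
      full[names(comp$met_torsions)] <- comp$met_torsions
      for (tn in names(full)) xyz <- set_torsion_xyz(xyz, sides[[tn]], full[[tn]])
      xyz <- set_torsion_xyz(xyz, sides$chi, chi)
      if (!has_clashes(xyz, elements, exclude)) {
        ok <- TRUE
        break
      }
      if (comp$chi_sd == 0) break # nothing left to resample
    }
    if (!ok) {
      abort(sprintf(
        "Component '%s' produces steric clashes after %d retries.",
        comp$name, max_retries
      ))
    }
    chis[i] <- chi
    confs[[i]] <- tibble::tibble(
      conformer_id = sprintf("synth%05d", i),
      atom = atoms, element = elements,
      x = unname(xyz[, 1]), y = unname(xyz[, 2]), z = unname(xyz[, 3])
    )
  }
  structure(
    list(
      ensemble = dplyr::bind_rows(confs),
      labels = tibble::tibble(
        conformer_id = sprintf("synth%05d", seq_len(spec$n_conformers)),
        component = nm[assignment],
        chi_target = chis
      ),
      true_populations = tibble::tibble(component = nm, weight = w),
      spec = spec
    ),
    class = "sam_bundle"
  )
}

#' @export
print.sam_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic SAM bundle: %d conformers, %d components (seed %d)\n",
    length(conformer_ids(x$ensemble)), nrow(x$true_populations), x$spec$seed
  ))
  print(dplyr::count(x$labels, .data$component), ...)
  invisible(x)
}

# One representative conformer id per component: the member whose sampled
# glycosidic dihedral is closest (wrapped) to the component mean.
component_representatives <- function(bundle) {
  stopifnot(inherits(bundle, "sam_bundle"))
  means <- vapply(bundle$spec$components, function(cc) cc$chi_mean, numeric(1))
  names(means) <- vapply(bundle$spec$components, function(cc) cc$name, character(1))
  lab <- bundle$labels
  lab$dev <- abs(wrap_angle(lab$chi_target - means[lab$component]))
  lab |>
    dplyr::group_by(.data$component) |>
    dplyr::slice_min(.data$dev, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("component", "conformer_id")
}

# Ground-truth effective distances of a bundle: r^-6 average of the
# per-component representative distances at the true populations.
bundle_distance_matrix <- function(bundle, pairs) {
  reps <- component_representatives(bundle)
  reps <- reps[match(bundle$true_populations$component, reps$component), ]
  X <- t(vapply(reps$conformer_id, function(id) {
    cf <- dplyr::filter(bundle$ensemble, .data$conformer_id == id)
    interproton_distance(cf, pairs)
  }, numeric(nrow(pairs))))
  rownames(X) <- reps$component
  X
}

#' Noise-free effective distances of a synthetic bundle
#'
#' The ground-truth restraint distances implied by a bundle: for every
#' proton pair, the r^-6 average of the per-component representative
#' distances weighted by the true populations.
#'
#' @param bundle A `sam_bundle` from [sample_ensemble()].
#' @param pairs Proton pairs (columns `atom1`, `atom2`); defaults to the
#'   39 pairs of the packaged SAM restraint table.
#' @return A tibble with columns `atom1`, `atom2`, `distance`.
#' @export
noise_free_distances <- function(bundle, pairs = NULL) {
  if (is.null(pairs)) pairs <- sam_restraints()[, c("atom1", "atom2")]
  X <- bundle_distance_matrix(bundle, pairs)
  tibble::tibble(
    atom1 = normalize_proton_label(pairs$atom1),
    atom2 = normalize_proton_label(pairs$atom2),
    distance = r6_average(X, bundle$true_populations$weight)
  )
}

#' Simulate noisy ROESY cross-peak intensities from a bundle
#'
#' Inverts the isolated spin-pair relation: each pair's noise-free
#' effective distance `d` (see [noise_free_distances()]) becomes an
#' intensity `I = I_ref * (r_ref / d)^6`, multiplied by lognormal noise
#' `exp(N(0, sigma))`. The reported per-peak intensity error is the
#' lognormal standard deviation `I * sqrt(exp(sigma^2) - 1)`, consistent
#' with the noise actually applied. With `noise_sigma = 0`,
#' [intensity_to_distance()] recovers the noise-free distances exactly.
#'
#' @param bundle A `sam_bundle`.
#' @param cal A [roesy_calibration()].
#' @param noise_sigma Lognormal sigma; defaults to the bundle spec's.
#' @param seed Seed for the noise draws; defaults to the bundle spec's.
#' @param pairs Proton pairs; defaults to the packaged SAM table's 39.
#' @return A cross-peak tibble (`atom1`, `atom2`, `intensity`,
#'   `intensity_error`).
#' @export
simulate_roesy <- function(bundle, cal, noise_sigma = NULL, seed = NULL, pairs = NULL) {
  stopifnot(inherits(bundle, "sam_bundle"), inherits(cal, "sam_calibration"))
  if (is.null(noise_sigma)) noise_sigma <- bundle$spec$noise_sigma
  if (is.null(seed)) seed <- bundle$spec$seed
  nf <- noise_free_distances(bundle, pairs)
  set.seed(seed)
  noise <- exp(rnorm(nrow(nf), 0, noise_sigma))
  intensity <- cal$i_ref * (cal$r_ref / nf$distance)^6 * noise
  tibble::tibble(
    atom1 = nf$atom1, atom2 = nf$atom2,
    intensity = intensity,
    intensity_error = intensity * sqrt(exp(noise_sigma^2) - 1)
  )
}

#' Write a synthetic SAM-protein complex as a PDB file
#'
#' Places short glycine backbone strands around a template SAM ligand.
#' The `compact` style mimics a knotted-methyltransferase site: backbone
#' strands sandwich the adenine base from two sides (loop-like and
#' wall-like), guaranteeing backbone contacts within 5 A of adenine
#' atoms. The `open` style puts the same strands far from the base, so
#' the adenine is solvent-exposed and only the ribose-side contacts
#' remain.
#'
#' @param site_style `"compact"` or `"open"`.
#' @param path Output PDB path.
#' @param seed Seed for the small coordinate jitter.
#' @return `path`, invisibly.
#' @export
build_synthetic_complex <- function(site_style = c("compact", "open"),
                                    path = tempfile(fileext = ".pdb"),
                                    seed = 1) {
  site_style <- match.arg(site_style)
  set.seed(seed)
  lig <- sam_template(chi = 0, id = "ligand") # anti1, extended
  xyz <- conformer_coords(lig)
  ade_atoms <- c("N9", "C8", "N7", "C5", "C4", "C6", "N6", "N1", "C2", "N3")
  A <- xyz[ade_atoms, ]
  centroid <- colMeans(A)
  sv <- svd(sweep(A, 2, centroid))
  normal <- sv$v[, 3] # adenine plane normal
  e1 <- sv$v[, 1]
  # point the strand axis away from the sugar so the sandwich stays over
  # the base rather than colliding with the ribose
  if (sum(e1 * (centroid - xyz["C1'", ])) < 0) e1 <- -e1

  rib_anchor <- xyz["O2'", ]
  rib_dir <- unit3(rib_anchor - colMeans(xyz[c("C1'", "C4'"), ]))

  strand <- function(origin, dir, n_res = 3, spacing = 3.4) {
    purrr::map_dfr(seq_len(n_res), function(i) {
      base <- origin + (i - (n_res + 1) / 2) * spacing * dir
      tibble::tibble(
        atom = c("N", "CA", "C", "O"),
        x = base[1] + c(-0.8, 0, 1.0, 1.4) + rnorm(4, 0, 0.02),
        y = base[2] + c(0.6, 0, 0.7, 1.8) + rnorm(4, 0, 0.02),
        z = base[3] + c(0, 0, 0, 0) + rnorm(4, 0, 0.02),
        resno_local = i
      )
    })
  }

  offset <- if (site_style == "compact") 4.0 else 14.0
  s1 <- strand(centroid + offset * normal + 1.2 * e1, e1)
  s2 <- strand(centroid - offset * normal + 1.2 * e1, e1)
  s3 <- strand(rib_anchor + 4.0 * rib_dir, unit3(cross3(rib_dir, normal)), n_res = 2)

  prot <- dplyr::bind_rows(s1, s2, s3)
  n_per <- 4L
  prot$resno <- rep(seq_len(nrow(prot) / n_per), each = n_per)

  lig_xyz <- conformer_coords(lig)
  all_xyz <- rbind(as.matrix(prot[, c("x", "y", "z")]), lig_xyz)
  n_prot <- nrow(prot)
  n_lig <- nrow(lig_xyz)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(all_xyz)),
    type = c(rep("ATOM", n_prot), rep("HETATM", n_lig)),
    resno = c(prot$resno, rep(401L, n_lig)),
    resid = c(rep("GLY", n_prot), rep("SAM", n_lig)),
    eleno = seq_len(n_prot + n_lig),
    elety = c(prot$atom, rownames(lig_xyz)),
    chain = c(rep("A", n_prot), rep("L", n_lig)),
    o = rep(1, n_prot + n_lig),
    b = rep(0, n_prot + n_lig),
    elesy = c(guess_element(prot$atom), guess_element(rownames(lig_xyz)))
  )
  invisible(path)
}

#' Serialize / restore a ground-truth bundle as a plain-text directory
#'
#' Writes the ensemble as a multi-MODEL PDB, the per-conformer component
#' labels and true populations as TSV, and a JSON manifest with the spec
#' parameters, so downstream steps can run file-based.
#'
#' @param bundle A `sam_bundle`.
#' @param dir Target directory (created if missing).
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()`
#'   returns a list with `ensemble`, `labels`, `true_populations` and
#'   `manifest`.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sam_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- conformer_ids(bundle$ensemble)
  parts <- split(bundle$ensemble, factor(bundle$ensemble$conformer_id, levels = ids))
  atoms <- parts[[1]]$atom
  xyz <- do.call(rbind, lapply(parts, function(cf) {
    as.numeric(t(conformer_coords(cf, atoms)))
  }))
  bio3d::write.pdb(
    file = file.path(dir, "ensemble.pdb"),
    xyz = xyz,
    type = rep("HETATM", length(atoms)),
    resno = rep(401L, length(atoms)),
    resid = rep("SAM", length(atoms)),
    eleno = seq_along(atoms),
    elety = atoms,
    chain = rep("L", length(atoms)),
    o = rep(1, length(atoms)),
    b = rep(0, length(atoms)),
    elesy = guess_element(atoms)
  )
  readr::write_tsv(bundle$labels, file.path(dir, "labels.tsv"), progress = FALSE)
  readr::write_tsv(bundle$true_populations, file.path(dir, "populations.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(
      n_conformers = bundle$spec$n_conformers,
      noise_sigma = bundle$spec$noise_sigma,
      seed = bundle$spec$seed,
      components = lapply(bundle$spec$components, function(cc) {
        list(name = cc$name, chi_mean = cc$chi_mean, chi_sd = cc$chi_sd,
             met_torsions = as.list(cc$met_torsions), weight = cc$weight)
      }),
      conformer_ids = ids
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  ens <- extract_ligands(file.path(dir, "ensemble.pdb"), all_models = TRUE)
  # restore the original conformer ids (models are read in order)
  old <- conformer_ids(ens)
  ens$conformer_id <- manifest$conformer_ids[match(ens$conformer_id, old)]
  list(
    ensemble = ens,
    labels = readr::read_tsv(file.path(dir, "labels.tsv"), show_col_types = FALSE, progress = FALSE),
    true_populations = readr::read_tsv(file.path(dir, "populations.tsv"), show_col_types = FALSE, progress = FALSE),
    manifest = manifest
  )
}
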