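#' Pairwise heavy-atom RMSD matrix of an ensemble
#'
#' Symmetric matrix of least-squares (Kabsch) RMSD values between every
#' pair of conformers, computed over a shared atom subset.
#'
#' @param ensemble An ensemble tibble.
#' @param atoms Atom subset; defaults to the 27 heavy atoms of SAM.
#' @return A symmetric numeric matrix (A) with zero diagonal, dimnames the
#'   conformer ids.
#' @export
pairwise_rmsd <- function(ensemble, atoms = sam_heavy_atoms) {
  arr <- ensemble_coord_array(ensemble, atoms)
  out <- pairwise_rmsd_cpp(arr)
  ids <- dimnames(arr)[[3]]
  dimnames(out) <- list(ids, ids)
  out
}

#' GROMOS neighbour-count clustering of a conformer ensemble
#'
#' The iterative neighbour-count algorithm of the GROMOS clustering
#' scheme: the conformer with the largest number of neighbours within
#' `cutoff` becomes a cluster centre (medoid); it and its neighbours are
#' removed from the pool; the procedure repeats until the pool is empty.
#' Clusters are numbered in the order they are extracted (cluster 1 is the
#' most populated at extraction time). Ties in neighbour count are broken
#' by the lowest ensemble index, which makes the result deterministic.
#'
#' The medoid is the selected neighbour-count centre itself — an actual
#' ensemble member, not an averaged structure.
#'
#' @param x Either a symmetric pairwise RMSD matrix (e.g. from
#'   [pairwise_rmsd()]) or an ensemble tibble, in which case the matrix is
#'   computed over `atoms` first.
#' @param cutoff Neighbour cutoff in Angstrom (default 1.25).
#' @param atoms Atom subset used when `x` is an ensemble.
#' @return An object of class `sam_clusters`: a list with `assignment`
#'   (tibble `conformer_id`, `cluster`), `clusters` (tibble `cluster`,
#'   `medoid_id`, `size`, `population`) and `cutoff`. Populations sum
#'   to 1.
#' @export
cluster_conformers <- function(x, cutoff = 1.25, atoms = sam_heavy_atoms) {
  if (is.data.frame(x)) x <- pairwise_rmsd(x, atoms)
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    abort("`x` must be a square RMSD matrix or an ensemble tibble.")
  }
  if (nrow(x) == 0) abort("Cannot cluster an empty ensemble.")
  if (max(abs(x - t(x))) > 1e-8) abort("RMSD matrix must be symmetric.")
  if (cutoff <= 0) abort("`cutoff` must be positive.")
  n <- nrow(x)
  ids <- rownames(x) %||% as.character(seq_len(n))
  adj <- x <= cutoff
  remaining <- rep(TRUE, n)
  label <- integer(n)
  medoid <- integer(0)
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    counts <- colSums(adj[remaining, , drop = FALSE]) # includes self
    counts[!remaining] <- -Inf
    centre <- which.max(counts) # ties -> lowest index
    members <- which(remaining & adj[centre, ])
    label[members] <- k
    medoid[k] <- centre
    remaining[members] <- FALSE
  }
  sizes <- tabulate(label, nbins = k)
  structure(
    list(
      assignment = tibble::tibble(conformer_id = ids, cluster = label),
      clusters = tibble::tibble(
        cluster = seq_len(k),
        medoid_id = ids[medoid],
        size = sizes,
        population = sizes / n
      ),
      cutoff = cutoff
    ),
    class = "sam_clusters"
  )
}

#' @export
print.sam_clusters <- function(x, ...) {
  cat(sprintf(
    "GROMOS clustering: %d conformers -> %d clusters at cutoff %.2f A\n",
    nrow(x$assignment), nrow(x$clusters), x$cutoff
  ))
  print(x$clusters, ...)
  invisible(x)
}

#' @rdname cluster_conformers
#' @param x,object A `sam_clusters` object.
#' @param ... Unused.
#' @export
tidy.sam_clusters <- function(x, ...) {
  x$clusters
}

#' @rdname cluster_conformers
#' @export
glance.sam_clusters <- function(x, ...) {
  tibble::tibble(
    n_conformers = nrow(x$assignment),
    n_clusters = nrow(x$clusters),
    cutoff = x$cutoff,
    max_population = max(x$clusters$population)
  )
}

#' Interproton distances measured on cluster medoids
#'
#' For every cluster medoid, the interproton distance of each restraint
#' pair (methyl pseudo-atom pairs use r^-6-effective averaging; see
#' [interproton_distance()]). These per-cluster distance vectors are the
#' inputs of the population fit.
#'
#' @param clusters A `sam_clusters` object.
#' @param ensemble The ensemble the clustering was computed on (must
#'   contain the medoid conformers with their protons).
#' @param pairs A data frame with columns `atom1`, `atom2`, e.g. a
#'   restraint table.
#' @param method Pseudo-atom handling, passed to
#'   [interproton_distance()].
#' @return A tibble with columns `cluster`, `medoid_id`, `atom1`, `atom2`,
#'   `distance`.
#' @export
medoid_distances <- function(clusters, ensemble, pairs, method = c("r6", "centroid")) {
  stopifnot(inherits(clusters, "sam_clusters"))
  method <- match.arg(method)
  a1 <- normalize_proton_label(pairs$atom1)
  a2 <- normalize_proton_label(pairs$atom2)
  purrr::map2_dfr(
    clusters$clusters$cluster, clusters$clusters$medoid_id,
    function(cl, mid) {
      cf <- dplyr::filter(ensemble, .data$conformer_id == mid)
      if (nrow(cf) == 0) abort(sprintf("Medoid conformer %s not found in ensemble.", mid))
      tibble::tibble(
        cluster = cl, medoid_id = mid, atom1 = a1, atom2 = a2,
        distance = interproton_distance(cf, tibble::tibble(atom1 = a1, atom2 = a2), method)
      )
    }
  )
}
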