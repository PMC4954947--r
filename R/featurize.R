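# per-frame minimum distance between one atom's trajectory and a group of
# atoms' trajectories; coords is T x n_atoms x 3.  `box` switches on the
# minimum-image convention for a cubic periodic box of that edge length.
min_dist_to_group <- function(coords, atom, group, box = NULL) {
  T_ <- dim(coords)[1]
  dmin <- rep(Inf, T_)
  a <- coords[, atom, , drop = FALSE]
  for (g in group) {
    dx <- a[, 1, ] - coords[, g, ]
    if (!is.null(box)) {
      dx <- dx - box * round(dx / box)
    }
    d2 <- rowSums(dx^2)
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

# minimum over two atom groups, per frame
min_dist_groups <- function(coords, group_a, group_b, box = NULL) {
  dmin <- rep(Inf, dim(coords)[1])
  for (a in group_a) {
    dmin <- pmin(dmin, min_dist_to_group(coords, a, group_b, box = box))
  }
  dmin
}

#' Binary receptor-ligand contact-map features
#'
#' For every frame, computes a binary vector over the receptor reference
#' atoms: a feature is 1 exactly when the minimum Euclidean distance from
#' that receptor atom to any ligand atom is strictly less than `cutoff`
#' (default 8 Angstrom).  This is the standard protein-ligand contact map
#' over alpha-carbons (receptor) and heavy atoms (ligand).
#'
#' @param stream A per-ligand stream from [split_ligand_copies()], or a
#'   `T x n_atoms x 3` coordinate array (then `receptor_atoms`,
#'   `ligand_atoms` and `frame_dt` must be given).
#' @param receptor_atoms,ligand_atoms Atom index vectors (taken from the
#'   stream when omitted).
#' @param cutoff Contact cutoff in Angstrom, strict `<`.
#' @param frame_dt Frame spacing in ns (taken from the stream when omitted).
#' @param minimum_image Optional box edge (Angstrom); when given, distances
#'   use the minimum-image convention for a cubic periodic box.
#' @return A [feature_trajectory()] with one column per receptor atom.
#' @export
contact_map_features <- function(stream, receptor_atoms = NULL,
                                 ligand_atoms = NULL, cutoff = 8,
                                 frame_dt = NULL, minimum_image = NULL) {
  check_scalar_positive(cutoff, "cutoff")
  if (is.list(stream) && !is.null(stream$coords)) {
    coords <- stream$coords
    receptor_atoms <- receptor_atoms %||% stream$receptor_atoms
    ligand_atoms <- ligand_atoms %||% stream$ligand_atoms
    frame_dt <- frame_dt %||% stream$frame_dt
    source <- stream$source
  } else {
    coords <- stream
    source <- NULL
  }
  if (length(receptor_atoms) == 0L || length(ligand_atoms) == 0L) {
    stop_ligandmsm("receptor and ligand atom selections must be nonempty")
  }
  if (is.null(frame_dt)) stop_ligandmsm("`frame_dt` is required")
  if (!is.null(minimum_image)) check_scalar_positive(minimum_image, "minimum_image")
  feats <- vapply(receptor_atoms, function(a) {
    as.numeric(min_dist_to_group(coords, a, ligand_atoms,
                                 box = minimum_image) < cutoff)
  }, numeric(dim(coords)[1]))
  feature_trajectory(feats, frame_dt = frame_dt,
                     feature_names = paste0("contact_", receptor_atoms),
                     source = source)
}

#' Ion-coordination flags
#'
#' Flags every frame in which any phosphate atom of the ligand is within
#' `cutoff` (strictly, default 4 Angstrom) of any declared ion — the
#' criterion used to split geometric clusters by whether the ligand's
#' phosphate group is coordinated to a catalytic ion.
#'
#' @param stream A per-ligand stream from [split_ligand_copies()], or a
#'   `T x n_atoms x 3` coordinate array.
#' @param phosphate_atoms,ion_atoms Atom index vectors (taken from the
#'   stream when omitted).
#' @param cutoff Coordination cutoff in Angstrom, strict `<`.
#' @return A logical vector of length `T` (class `coordination_flags`).
#'   With no ions declared, all flags are `FALSE` and a warning is issued
#'   (ion-free batches).
#' @export
coordination_flags <- function(stream, phosphate_atoms = NULL,
                               ion_atoms = NULL, cutoff = 4) {
  check_scalar_positive(cutoff, "cutoff")
  if (is.list(stream) && !is.null(stream$coords)) {
    coords <- stream$coords
    phosphate_atoms <- phosphate_atoms %||% stream$phosphate_atoms
    ion_atoms <- ion_atoms %||% stream$ion_atoms
  } else {
    coords <- stream
  }
  T_ <- dim(coords)[1]
  if (length(ion_atoms) == 0L) {
    warning("no ion atoms declared; all coordination flags are FALSE")
    return(structure(rep(FALSE, T_), class = "coordination_flags"))
  }
  if (length(phosphate_atoms) == 0L) {
    stop_ligandmsm("`phosphate_atoms` must be nonempty when ions are declared")
  }
  d <- min_dist_groups(coords, phosphate_atoms, ion_atoms)
  structure(d < cutoff, class = "coordination_flags")
}
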