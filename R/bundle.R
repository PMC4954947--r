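#' Trajectory bundle
#'
#' A set of simulation runs sharing one topology: per-run coordinate arrays,
#' a frame spacing, and the atom roles needed for featurization — receptor
#' reference atoms (typically alpha-carbons), one atom group per ligand copy,
#' ion atoms, and optionally the phosphate atoms of each ligand used for
#' ion-coordination flags.
#'
#' @param runs List of coordinate arrays, each `T x n_atoms x 3` (Angstrom).
#' @param frame_dt Frame spacing in ns.
#' @param receptor_atoms Integer indices of receptor reference atoms.
#' @param ligand_groups List of disjoint integer index vectors, one per
#'   ligand copy.
#' @param ion_atoms Integer indices of ions (may be empty).
#' @param phosphate_atoms Optional list parallel to `ligand_groups` giving
#'   each ligand's phosphate atom indices.
#' @param topology Optional path to a reference PDB.
#' @return A `trajectory_bundle` object.
#' @export
trajectory_bundle <- function(runs, frame_dt, receptor_atoms, ligand_groups,
                              ion_atoms = integer(), phosphate_atoms = NULL,
                              topology = NULL) {
  if (!is.list(runs)) stop_ligandmsm("`runs` must be a list of T x n_atoms x 3 arrays")
  check_scalar_positive(frame_dt, "frame_dt")
  receptor_atoms <- as.integer(receptor_atoms)
  ligand_groups <- lapply(ligand_groups, as.integer)
  ion_atoms <- as.integer(ion_atoms)
  if (length(ligand_groups)) {
    all_lig <- unlist(ligand_groups)
    if (anyDuplicated(all_lig)) {
      stop_ligandmsm("`ligand_groups` must be disjoint")
    }
    if (any(vapply(ligand_groups, length, 1L) == 0L)) {
      stop_ligandmsm("empty ligand group")
    }
  }
  if (!is.null(phosphate_atoms)) {
    if (length(phosphate_atoms) != length(ligand_groups)) {
      stop_ligandmsm("`phosphate_atoms` must have one entry per ligand group")
    }
    phosphate_atoms <- lapply(phosphate_atoms, as.integer)
  }
  for (r in runs) {
    d <- dim(r)
    if (length(d) != 3L || d[3] != 3L) {
      stop_ligandmsm("each run must be a T x n_atoms x 3 array")
    }
    idx <- c(receptor_atoms, unlist(ligand_groups), ion_atoms,
             unlist(phosphate_atoms))
    if (length(idx) && (any(idx < 1L) || any(idx > d[2]))) {
      stop_ligandmsm("atom index out of range for run coordinates")
    }
  }
  if (length(runs) == 0L) {
    warning("bundle contains no runs")
  }
  structure(
    list(runs = runs, frame_dt = frame_dt, receptor_atoms = receptor_atoms,
         ligand_groups = ligand_groups, ion_atoms = ion_atoms,
         phosphate_atoms = phosphate_atoms, topology = topology),
    class = "trajectory_bundle"
  )
}

#' @export
print.trajectory_bundle <- function(x, ...) {
  cat(sprintf(
    "Trajectory bundle: %d run(s), %d ligand copy(ies), frame_dt = %g ns\n",
    length(x$runs), length(x$ligand_groups), x$frame_dt))
  invisible(x)
}

#' Write a trajectory bundle in the portable text format
#'
#' The portable format is a directory holding `bundle.json` (frame spacing,
#' atom roles, provenance) and one CSV per run with a flattened frame per
#' row (`x1, y1, z1, x2, ...`).  It is the canonical on-disk form for both
#' synthetic and converted real trajectories, so the full pipeline runs
#' identically on either.
#'
#' @param bundle A [trajectory_bundle()].
#' @param path Directory to create/write.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  if (!inherits(bundle, "trajectory_bundle")) {
    stop_ligandmsm("`bundle` must be a trajectory_bundle")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format = "ligandmsm-bundle-v1",
    frame_dt_ns = bundle$frame_dt,
    receptor_atoms = bundle$receptor_atoms,
    ligand_groups = bundle$ligand_groups,
    ion_atoms = bundle$ion_atoms,
    phosphate_atoms = bundle$phosphate_atoms,
    n_runs = length(bundle$runs)
  )
  jsonlite::write_json(meta, file.path(path, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(bundle$runs)) {
    r <- bundle$runs[[i]]
    flat <- matrix(aperm(r, c(1, 3, 2)), nrow = dim(r)[1])
    utils::write.table(flat, file.path(path, sprintf("run_%03d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a trajectory bundle from the portable text format
#'
#' @param path Directory written by [write_bundle()].
#' @return A [trajectory_bundle()].
#' @export
read_bundle <- function(path) {
  meta_file <- file.path(path, "bundle.json")
  if (!file.exists(meta_file)) {
    stop_ligandmsm(sprintf("no bundle.json under '%s'", path))
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (key in c("frame_dt_ns", "receptor_atoms", "ligand_groups", "n_runs")) {
    if (is.null(meta[[key]])) {
      stop_ligandmsm(sprintf("bundle metadata is missing '%s'", key))
    }
  }
  if (!is.numeric(meta$frame_dt_ns) || meta$frame_dt_ns <= 0) {
    stop_ligandmsm("bundle metadata frame_dt_ns must be positive")
  }
  runs <- lapply(seq_len(meta$n_runs), function(i) {
    f <- file.path(path, sprintf("run_%03d.csv", i))
    if (!file.exists(f)) stop_ligandmsm(sprintf("missing coordinate file '%s'", f))
    flat <- as.matrix(utils::read.table(f, sep = ","))
    dimnames(flat) <- NULL
    n_atoms <- ncol(flat) / 3L
    aperm(array(flat, dim = c(nrow(flat), 3L, n_atoms)), c(1, 3, 2))
  })
  lig <- meta$ligand_groups
  if (is.matrix(lig)) lig <- lapply(seq_len(nrow(lig)), function(i) lig[i, ])
  phos <- meta$phosphate_atoms
  if (is.matrix(phos)) phos <- lapply(seq_len(nrow(phos)), function(i) phos[i, ])
  trajectory_bundle(runs, frame_dt = meta$frame_dt_ns,
                    receptor_atoms = meta$receptor_atoms,
                    ligand_groups = lig,
                    ion_atoms = meta$ion_atoms %||% integer(),
                    phosphate_atoms = phos)
}

#' Read an MD trajectory bundle (PDB topology + DCD coordinates)
#'
#' Loads standard MD files through \pkg{bio3d} and converts them to the
#' portable in-memory representation, normalizing units to Angstrom and ns.
#'
#' @param topology Path to a PDB file.
#' @param coord_files Character vector of DCD files, one per run.
#' @param frame_dt Frame spacing in ns.
#' @param receptor_atoms,ligand_groups,ion_atoms,phosphate_atoms Atom roles,
#'   as in [trajectory_bundle()].
#' @return A [trajectory_bundle()].
#' @export
read_md_bundle <- function(topology, coord_files, frame_dt, receptor_atoms,
                           ligand_groups, ion_atoms = integer(),
                           phosphate_atoms = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop_ligandmsm("reading PDB/DCD bundles requires the 'bio3d' package")
  }
  pdb <- bio3d::read.pdb(topology)
  n_atoms <- nrow(pdb$atom)
  runs <- lapply(coord_files, function(f) {
    xyz <- bio3d::read.dcd(f, verbose = FALSE)
    if (ncol(xyz) != 3L * n_atoms) {
      stop_ligandmsm(sprintf(
        "atom count mismatch: topology has %d atoms, '%s' has %d",
        n_atoms, f, ncol(xyz) / 3L))
    }
    aperm(array(t(xyz), dim = c(3L, n_atoms, nrow(xyz))), c(3, 2, 1))
  })
  trajectory_bundle(runs, frame_dt = frame_dt, receptor_atoms = receptor_atoms,
                    ligand_groups = ligand_groups, ion_atoms = ion_atoms,
                    phosphate_atoms = phosphate_atoms, topology = topology)
}

#' Split multi-ligand runs into independent per-ligand streams
#'
#' Each (run, ligand copy) pair becomes one stream sharing the receptor and
#' ion coordinates: a box with five ligand copies yields five independent
#' trajectories per run, which is how multi-copy binding simulations are
#' analysed.
#'
#' @param bundle A [trajectory_bundle()] with at least one ligand group.
#' @return List of streams; each stream is a list with `coords`
#'   (`T x n_atoms x 3`), the atom roles for that ligand, `frame_dt` and a
#'   `source = c(run, ligand)` identifier.
#' @export
split_ligand_copies <- function(bundle) {
  if (!inherits(bundle, "trajectory_bundle")) {
    stop_ligandmsm("`bundle` must be a trajectory_bundle")
  }
  if (length(bundle$ligand_groups) == 0L) {
    stop_ligandmsm("bundle declares no ligand groups")
  }
  out <- vector("list", length(bundle$runs) * length(bundle$ligand_groups))
  k <- 0L
  for (r in seq_along(bundle$runs)) {
    for (l in seq_along(bundle$ligand_groups)) {
      k <- k + 1L
      out[[k]] <- list(
        coords = bundle$runs[[r]],
        receptor_atoms = bundle$receptor_atoms,
        ligand_atoms = bundle$ligand_groups[[l]],
        ion_atoms = bundle$ion_atoms,
        phosphate_atoms = if (!is.null(bundle$phosphate_atoms))
          bundle$phosphate_atoms[[l]] else integer(),
        frame_dt = bundle$frame_dt,
        source = c(run = r, ligand = l)
      )
    }
  }
  out
}
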