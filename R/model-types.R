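#' Build an anion record
#'
#' An anion record names, by absolute atom index into the topology, the atoms
#' that drive the per-anion analyses: the two carboxylate carbons whose
#' joining vector defines the orientation angle theta, the four-atom backbone
#' quadruple whose torsion chi classifies anti/gauche conformers, the amino
#' nitrogen (absent in succinate), and the two carboxylate groups (one carbon
#' with its two oxygens each) whose stretch dynamics carry the infrared
#' signal.
#'
#' @param molecule_id Integer molecule id of the anion.
#' @param atoms Integer indices of all atoms belonging to the anion.
#' @param carboxylate_carbons Length-2 integer vector.
#' @param dihedral Length-4 integer vector (ordered backbone quadruple).
#' @param amino_n Integer index or `NA` for succinate.
#' @param carboxylate_groups List of two lists, each `list(C = i, O = c(j, k))`.
#' @return A list of class `anion_record`.
#' @export
anion_record <- function(molecule_id, atoms, carboxylate_carbons, dihedral,
                         amino_n = NA_integer_, carboxylate_groups = list()) {
  rec <- list(
    molecule_id = as.integer(molecule_id),
    atoms = as.integer(atoms),
    carboxylate_carbons = as.integer(carboxylate_carbons),
    dihedral = as.integer(dihedral),
    amino_n = as.integer(amino_n),
    carboxylate_groups = carboxylate_groups
  )
  class(rec) <- "anion_record"
  rec
}

#' Construct a topology
#'
#' A topology is the static description of the system: one row per atom
#' (element, partial charge, molecule membership, role tag) plus the per-anion
#' records and bookkeeping metadata.  Coordinates live in the trajectory, not
#' here; the same topology serves every frame.
#'
#' @param elements Character vector of chemical symbols.
#' @param charges Numeric partial charges (elementary-charge units).
#' @param molecule_ids Integer molecule ids (>= 0).
#' @param roles Character role tags, see [atom_roles()].
#' @param anion_records List of [anion_record()] objects.
#' @param anion_type `"ASP"`, `"GLU"` or `"SUC"`.
#' @param n_layers Number of inorganic layers, if known (used by
#'   [detect_slab_geometry()] as the cluster count).
#' @return An object of class `topology`.
#' @export
topology <- function(elements, charges, molecule_ids, roles,
                     anion_records = list(), anion_type = NULL,
                     n_layers = NULL) {
  top <- list(
    elements = as.character(elements),
    charges = as.numeric(charges),
    molecule_ids = as.integer(molecule_ids),
    roles = as.character(roles),
    anion_records = anion_records,
    anion_type = anion_type,
    n_layers = if (is.null(n_layers)) NULL else as.integer(n_layers)
  )
  class(top) <- "topology"
  validate_topology(top)
  top
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", n_atoms(x), " atoms, ",
      length(x$anion_records), " anion(s)",
      if (!is.null(x$anion_type)) paste0(" [", x$anion_type, "]"), "\n",
      sep = "")
  invisible(x)
}

#' Number of atoms in a topology or trajectory
#' @param x A `topology` or `trajectory`.
#' @return Integer count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  length(x$elements)
}

#' Validate a topology
#'
#' Checks the structural invariants: non-empty elements, equal field lengths,
#' non-negative molecule ids, known roles, in-range and mutually distinct
#' anion-record indices, absence of an amino nitrogen for succinate, and a net
#' charge of -2 per anion (tolerance 1e-6).
#'
#' @param top A `topology`.
#' @return `top`, invisibly; stops on violation.
#' @export
validate_topology <- function(top) {
  n <- length(top$elements)
  if (n == 0L) stop("topology has no atoms")
  if (any(!nzchar(top$elements))) stop("empty element symbol in topology")
  lens <- c(length(top$charges), length(top$molecule_ids), length(top$roles))
  if (any(lens != n)) stop("topology fields have inconsistent lengths")
  if (any(top$molecule_ids < 0L)) stop("molecule_id must be >= 0")
  bad <- setdiff(unique(top$roles), atom_roles())
  if (length(bad)) stop("unknown atom role(s): ", paste(bad, collapse = ", "))
  for (k in seq_along(top$anion_records)) {
    rec <- top$anion_records[[k]]
    idx <- c(rec$carboxylate_carbons, rec$dihedral,
             if (!is.na(rec$amino_n)) rec$amino_n)
    if (any(idx < 1L | idx > n)) {
      stop("anion record ", k, ": atom index out of range")
    }
    if (anyDuplicated(rec$carboxylate_carbons) ||
        anyDuplicated(rec$dihedral)) {
      stop("anion record ", k, ": indices must be mutually distinct")
    }
    if (identical(top$anion_type, "SUC") && !is.na(rec$amino_n)) {
      stop("anion record ", k, ": succinate has no amino nitrogen")
    }
    q <- sum(top$charges[rec$atoms])
    if (abs(q - (-2)) > 1e-6) {
      stop(sprintf("anion record %d: net charge %.8f != -2", k, q))
    }
  }
  invisible(top)
}

#' Construct a trajectory
#'
#' Frames are stored as a dense `n_atoms x 3 x n_frames` array of coordinates
#' in angstrom; velocities (angstrom/fs), when present, use the same layout.
#' The box is orthorhombic and constant (edge lengths in angstrom); `dt` is
#' the time between stored frames in femtoseconds.
#'
#' @param topology A [topology()].
#' @param coords Numeric array `n_atoms x 3 x n_frames` (a matrix is accepted
#'   for a single frame).
#' @param box Length-3 numeric vector of box edge lengths (angstrom).
#' @param dt Time step between frames (fs).
#' @param velocities Optional array matching `coords`.
#' @param time0 Time of the first frame (fs).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, box, dt = 1,
                       velocities = NULL, time0 = 0) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != n_atoms(topology)) {
    stop("coordinate count (", dim(coords)[1],
         ") does not match topology atom count (", n_atoms(topology), ")")
  }
  if (length(box) != 3L || any(box <= 0)) stop("box edges must be 3 positive lengths")
  if (dt <= 0) stop("dt must be > 0")
  if (!is.null(velocities)) {
    if (is.matrix(velocities)) {
      velocities <- array(velocities, dim = c(dim(velocities), 1L))
    }
    stopifnot(identical(dim(velocities), dim(coords)))
  }
  traj <- list(
    topology = topology,
    coords = coords,
    box = as.numeric(box),
    dt = as.numeric(dt),
    time0 = as.numeric(time0),
    velocities = velocities
  )
  class(traj) <- "trajectory"
  traj
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Frame times of a trajectory (fs)
#' @param traj A `trajectory`.
#' @return Numeric vector of length `n_frames(traj)`.
#' @export
frame_times <- function(traj) traj$time0 + (seq_len(n_frames(traj)) - 1) * traj$dt

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_atoms(x), " atoms x ", n_frames(x), " frames, dt = ",
      x$dt, " fs, box = [", paste(signif(x$box, 6), collapse = ", "), "] A",
      if (!is.null(x$velocities)) ", velocities present", "\n", sep = "")
  invisible(x)
}

#' Extract one frame
#'
#' @param traj A `trajectory`.
#' @param i Frame index (1-based).
#' @return A list of class `frame` with `coordinates` (matrix `n_atoms x 3`),
#'   optional `velocities`, `box` and `time` (fs).
#' @export
get_frame <- function(traj, i) {
  nf <- n_frames(traj)
  if (i < 1L || i > nf) stop("frame index ", i, " out of range 1..", nf)
  fr <- list(
    coordinates = traj$coords[, , i, drop = TRUE],
    velocities = if (!is.null(traj$velocities)) {
      traj$velocities[, , i, drop = TRUE]
    },
    box = traj$box,
    time = traj$time0 + (i - 1) * traj$dt
  )
  dim(fr$coordinates) <- c(dim(traj$coords)[1], 3L)
  if (!is.null(fr$velocities)) dim(fr$velocities) <- dim(fr$coordinates)
  class(fr) <- "frame"
  fr
}
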