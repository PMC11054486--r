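## Trajectory and topology file I/O.
##
## XYZ is the native text format: the comment line of every frame carries
## "box: Lx Ly Lz time: t" so a round trip preserves the box and the time
## axis.  PDB frames are written as MODEL blocks under a CRYST1 record and
## read back through bio3d; DCD is the CHARMM binary layout, read through
## bio3d::read.dcd and written by a minimal writer below (no installed R
## package writes DCD).  Topologies are YAML documents.

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xyz", "pdb", "dcd")) return(ext)
  stop("cannot guess trajectory format from extension '", ext,
       "'; pass format = \"xyz\", \"pdb\" or \"dcd\"")
}

#' Write a trajectory to disk
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @param format `"xyz"`, `"pdb"`, `"dcd"`, or `"auto"` (from the extension).
#' @param digits Decimal places for text formats (3 matches the common XYZ
#'   convention; round-trip error is then at most 5e-4 angstrom).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = "auto", digits = 3) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 1L) stop("refusing to write an empty trajectory")
  format <- match.arg(format, c("auto", "xyz", "pdb", "dcd"))
  if (format == "auto") format <- guess_format(path)
  switch(format,
    xyz = write_xyz_traj(traj, path, digits),
    pdb = write_pdb_traj(traj, path),
    dcd = write_dcd_traj(traj, path)
  )
  invisible(path)
}

#' Read a trajectory from disk
#'
#' The topology is supplied separately (coordinate formats carry no charges
#' or role tags); the atom count and ordering of the file must match it.
#'
#' @param path Input file path.
#' @param topology A [topology()] describing the atoms, in file order.
#' @param format `"xyz"`, `"pdb"`, `"dcd"`, or `"auto"`.
#' @param dt Frame spacing in fs.  For XYZ it is inferred from the per-frame
#'   times when possible; PDB and DCD carry no usable time axis here, so `dt`
#'   defaults to 1 fs unless given.
#' @param box Length-3 box override (angstrom) for formats whose box record
#'   is absent or untrusted.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, topology, format = "auto", dt = NULL,
                            box = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- match.arg(format, c("auto", "xyz", "pdb", "dcd"))
  if (format == "auto") format <- guess_format(path)
  switch(format,
    xyz = read_xyz_traj(path, topology, dt, box),
    pdb = read_pdb_traj(path, topology, dt, box),
    dcd = read_dcd_traj(path, topology, dt, box)
  )
}

## ---- XYZ ------------------------------------------------------------------

write_xyz_traj <- function(traj, path, digits = 3) {
  n <- n_atoms(traj)
  nf <- n_frames(traj)
  el <- traj$topology$elements
  times <- frame_times(traj)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%-3s %", ".", digits, "f %.", digits, "f %.", digits, "f")
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f]
    writeLines(c(
      as.character(n),
      sprintf("box: %.6f %.6f %.6f time: %.6f",
              traj$box[1], traj$box[2], traj$box[3], times[f]),
      sprintf(fmt, el, xyz[, 1], xyz[, 2], xyz[, 3])
    ), con)
  }
}

read_xyz_traj <- function(path, topology, dt = NULL, box = NULL) {
  lines <- readLines(path)
  n_top <- n_atoms(topology)
  pos <- 1L
  f <- 0L
  coord_list <- list()
  times <- numeric()
  boxes <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    f <- f + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop("parse error in frame ", f, ": bad atom-count line")
    if (n != n_top) {
      stop("atom-count mismatch in frame ", f, ": file has ", n,
           ", topology has ", n_top)
    }
    if (pos + 1L + n > length(lines)) {
      stop("parse error in frame ", f, ": truncated frame")
    }
    comment <- lines[pos + 1L]
    m <- regmatches(comment, regexec(
      "box:\\s*([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)", comment))[[1]]
    if (length(m) == 4L) boxes <- as.numeric(m[2:4])
    tm <- regmatches(comment, regexec("time:\\s*([-0-9.eE+]+)", comment))[[1]]
    times[f] <- if (length(tm) == 2L) as.numeric(tm[2]) else NA_real_
    body <- lines[(pos + 2L):(pos + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    nt <- lengths(toks)
    if (any(nt < 4L)) {
      stop("parse error in frame ", f, ": malformed coordinate record")
    }
    xyz <- matrix(as.numeric(vapply(toks, function(t) t[2:4], character(3))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(xyz)) stop("parse error in frame ", f, ": non-numeric coordinate")
    coord_list[[f]] <- xyz
    pos <- pos + 2L + n
  }
  if (f == 0L) stop("no frames found in ", path)
  coords <- array(unlist(coord_list), dim = c(n_top, 3L, f))
  if (is.null(dt)) {
    dt <- if (f >= 2L && !anyNA(times)) {
      d <- diff(times)
      if (max(abs(d - d[1])) > 1e-6) {
        stop("non-uniform frame times in ", path, "; pass dt explicitly")
      }
      d[1]
    } else 1
  }
  trajectory(topology, coords, box %||% boxes %||% stop("no box in file"),
             dt = dt, time0 = if (!anyNA(times)) times[1] else 0)
}

## ---- PDB ------------------------------------------------------------------

write_pdb_traj <- function(traj, path) {
  n <- n_atoms(traj)
  top <- traj$topology
  el <- top$elements
  name <- sprintf("%-4s", substr(paste0(el, seq_len(n) %% 100), 1, 4))
  resno <- top$molecule_ids %% 10000L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj$box[1], traj$box[2], traj$box[3], 90, 90, 90), con)
  eleno <- seq_len(n) %% 100000L
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f]
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %s MOL A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      eleno, name, resno, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      sprintf("%2s", el)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

read_pdb_traj <- function(path, topology, dt = NULL, box = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_top <- n_atoms(topology)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * n_top) {
    stop("atom-count mismatch: PDB has ", ncol(xyz) / 3,
         " atoms, topology has ", n_top)
  }
  nf <- nrow(xyz)
  coords <- array(0, dim = c(n_top, 3L, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  if (is.null(box)) {
    cl <- grep("^CRYST1", readLines(path, n = 50L), value = TRUE)
    if (length(cl) >= 1L) {
      box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                          substr(cl[1], 25, 33)))
    }
    if (length(box) != 3L || anyNA(box)) {
      stop("no CRYST1 record in ", path, "; pass box explicitly")
    }
  }
  trajectory(topology, coords, box, dt = dt %||% 1)
}

## ---- DCD ------------------------------------------------------------------

## Minimal CHARMM-layout DCD writer: CORD header with the crystal flag set,
## one 6-double unit-cell record plus three float32 coordinate records per
## frame.  Coordinates are single precision on disk, so round trips are good
## to ~1e-5 relative.
write_dcd_traj <- function(traj, path) {
  n <- n_atoms(traj)
  nf <- n_frames(traj)
  con <- file(path, "wb")
  on.exit(close(con))
  wmark <- function(bytes) writeBin(as.integer(bytes), con, size = 4)
  ## header record: "CORD" + 20 control ints (delta stored as float32)
  wmark(84L)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(as.integer(c(nf, 1L, 1L, nf, 0L, 0L, 0L, 3L * n, 0L)),
           con, size = 4)
  writeBin(traj$dt, con, size = 4)              # DELTA, float32
  writeBin(as.integer(c(1L, rep(0L, 8L), 24L)), con, size = 4)
  wmark(84L)
  ## title record
  title <- sprintf("%-80s", "ldhtraj synthetic/analysis trajectory")
  wmark(4L + 80L)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  wmark(4L + 80L)
  ## natom record
  wmark(4L); writeBin(as.integer(n), con, size = 4); wmark(4L)
  cell <- c(traj$box[1], 0, traj$box[2], 0, 0, traj$box[3])
  for (f in seq_len(nf)) {
    wmark(48L); writeBin(cell, con, size = 8); wmark(48L)
    xyz <- traj$coords[, , f]
    for (j in 1:3) {
      wmark(4L * n)
      writeBin(as.numeric(xyz[, j]), con, size = 4)
      wmark(4L * n)
    }
  }
}

read_dcd_traj <- function(path, topology, dt = NULL, box = NULL) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  n_top <- n_atoms(topology)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * n_top) {
    stop("atom-count mismatch: DCD has ", ncol(xyz) / 3,
         " atoms, topology has ", n_top)
  }
  nf <- nrow(xyz)
  coords <- array(0, dim = c(n_top, 3L, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  if (is.null(box)) {
    cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                     error = function(e) NULL)
    if (!is.null(cell)) box <- as.numeric(cell[1, 1:3])
  }
  if (is.null(box)) stop("no unit cell in ", path, "; pass box explicitly")
  trajectory(topology, coords, box, dt = dt %||% 1)
}

## ---- topology files -------------------------------------------------------

#' Write a topology to a YAML file
#'
#' @param top A [topology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  validate_topology(top)
  doc <- list(
    format = "ldhtraj-topology-1",
    anion_type = top$anion_type,
    n_layers = top$n_layers,
    atoms = list(
      element = top$elements,
      charge = top$charges,
      molecule_id = top$molecule_ids,
      role = top$roles
    ),
    anions = lapply(top$anion_records, function(rec) {
      list(
        molecule_id = rec$molecule_id,
        atoms = rec$atoms,
        carboxylate_carbons = rec$carboxylate_carbons,
        dihedral = rec$dihedral,
        amino_n = if (is.na(rec$amino_n)) NULL else rec$amino_n,
        carboxylate_groups = lapply(rec$carboxylate_groups, function(g) {
          list(C = g$C, O = g$O)
        })
      )
    })
  )
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' Read a topology from a YAML file
#'
#' @param path Input path, as written by [write_topology()].
#' @return A [topology()].
#' @export
read_topology <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "ldhtraj-topology-1")) {
    stop("not an ldhtraj topology file: ", path)
  }
  recs <- lapply(doc$anions, function(a) {
    anion_record(
      molecule_id = a$molecule_id,
      atoms = unlist(a$atoms),
      carboxylate_carbons = unlist(a$carboxylate_carbons),
      dihedral = unlist(a$dihedral),
      amino_n = a$amino_n %||% NA_integer_,
      carboxylate_groups = lapply(a$carboxylate_groups, function(g) {
        list(C = g$C, O = unlist(g$O))
      })
    )
  })
  topology(
    elements = doc$atoms$element,
    charges = doc$atoms$charge,
    molecule_ids = doc$atoms$molecule_id,
    roles = doc$atoms$role,
    anion_records = recs,
    anion_type = doc$anion_type,
    n_layers = doc$n_layers
  )
}
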