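# Helix trajectory container and trajectory I/O.
#
# Coordinates are stored in nanometres in an array [frame, atom, xyz];
# atom metadata lives in a data.frame.  PDB files (single or multi-model)
# are the text interchange format; DCD is supported for bulk coordinates
# (written natively, read back through bio3d).

#' Construct a helix trajectory
#'
#' @param atoms data.frame with columns \code{residue_index},
#'   \code{residue_number}, \code{residue} (one-letter), \code{atom}
#'   (PDB-style name: N, H, CA, C, O, CB, OG1, HG1, ...),
#'   \code{element}.
#' @param coords Numeric array \code{[n_frames, n_atoms, 3]} in nm.
#' @param frame_interval_ps Time between frames (ps).
#' @return Object of class \code{helix_trajectory}.
#' @export
helix_trajectory <- function(atoms, coords, frame_interval_ps = 10) {
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3L,
            dim(coords)[2] == nrow(atoms), dim(coords)[3] == 3L)
  structure(list(atoms = atoms, coords = coords,
                 frame_interval_ps = frame_interval_ps),
            class = "helix_trajectory")
}

#' @export
print.helix_trajectory <- function(x, ...) {
  rn <- range(x$atoms$residue_number)
  cat(sprintf(
    "helix_trajectory: %d frames x %d atoms, residues %d-%d, dt = %g ps\n",
    n_frames(x), nrow(x$atoms), rn[1], rn[2], x$frame_interval_ps))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj \code{helix_trajectory}.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Residue numbers present in a trajectory
#' @param traj \code{helix_trajectory}.
#' @export
traj_residues <- function(traj) sort(unique(traj$atoms$residue_number))

# index of one atom; NA if absent
atom_index <- function(traj, residue_number, atom) {
  i <- which(traj$atoms$residue_number == residue_number &
             traj$atoms$atom == atom)
  if (length(i)) i[1] else NA_integer_
}

# frames x 3 coordinate matrix of one atom
atom_xyz <- function(traj, residue_number, atom) {
  i <- atom_index(traj, residue_number, atom)
  if (is.na(i)) return(NULL)
  matrix(traj$coords[, i, , drop = FALSE], ncol = 3)
}

# frames x n x 3 array for several atom indices
atoms_xyz <- function(traj, idx) traj$coords[, idx, , drop = FALSE]

#' Extract a single frame as an atom-coordinate matrix
#'
#' @param traj \code{helix_trajectory}.
#' @param frame Frame index.
#' @return Matrix \code{[n_atoms, 3]} (nm).
#' @export
frame_coords <- function(traj, frame) {
  traj$coords[frame, , , drop = FALSE][1, , ]
}

.element_of <- function(atom) substring(gsub("[0-9]", "", atom), 1, 1)

#' Write a trajectory as a (multi-model) PDB file
#'
#' @param traj \code{helix_trajectory}.
#' @param path Output path.
#' @param frames Frames to write (default all).
#' @export
write_trajectory_pdb <- function(traj, path, frames = seq_len(n_frames(traj))) {
  at <- traj$atoms
  res3 <- AA3[at$residue]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   frame interval %g ps", traj$frame_interval_ps),
             con)
  for (f in frames) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f) * 10        # nm -> Angstrom
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)),
      ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom),
      res3, at$residue_number, xyz[, 1], xyz[, 2], xyz[, 3],
      at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write trajectory coordinates as a DCD file
#'
#' Plain (non-CHARMM-extended) binary DCD, little endian, readable by
#' standard trajectory tools.  Coordinates are written in Angstrom.
#'
#' @param traj \code{helix_trajectory}.
#' @param path Output path.
#' @export
write_trajectory_dcd <- function(traj, path) {
  nf <- n_frames(traj); na <- nrow(traj$atoms)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  # header block: "CORD" + 20 control integers (frames, start, stride, ...)
  wint(84); writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  wint(icntrl); wint(84)
  title <- sprintf("%-80s", "written by helixdx")
  wint(4 + 80); wint(1L)
  writeChar(title, con, nchars = 80, eos = NULL); wint(4 + 80)
  wint(4); wint(na); wint(4)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f) * 10
    for (d in 1:3) {
      wint(4 * na)
      writeBin(as.numeric(xyz[, d]), con, size = 4, endian = "little")
      wint(4 * na)
    }
  }
  invisible(path)
}

# build the atoms table from a bio3d pdb object
.atoms_from_pdb <- function(pdb) {
  sel <- pdb$atom
  aa1 <- names(AA3)[match(sel$resid, AA3)]
  if (anyNA(aa1)) {
    stop("non-canonical residue name(s) in topology: ",
         paste(unique(sel$resid[is.na(aa1)]), collapse = ", "))
  }
  resno <- as.integer(sel$resno)
  data.frame(residue_index = match(resno, sort(unique(resno))),
             residue_number = resno,
             residue = aa1,
             atom = sel$elety,
             element = .element_of(sel$elety),
             stringsAsFactors = FALSE)
}

#' Read a trajectory from PDB (and optionally DCD) files
#'
#' With only a topology path, all models of the PDB are read as frames.
#' With a DCD coordinate file, the PDB provides the topology and the DCD
#' the frames.  Coordinates are converted to nm.
#'
#' @param topology Path to a PDB file.
#' @param coordinates Optional path to a DCD file.
#' @param frame_interval_ps Frame spacing (ps); if the PDB was written by
#'   \code{\link{write_trajectory_pdb}} the value stored in its REMARK is
#'   used when this is NULL.
#' @return \code{helix_trajectory}.
#' @export
read_trajectory <- function(topology, coordinates = NULL,
                            frame_interval_ps = NULL) {
  if (!file.exists(topology)) stop("topology file not found: ", topology)
  pdb <- bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE)
  atoms <- .atoms_from_pdb(pdb)
  if (is.null(frame_interval_ps)) {
    rem <- grep("frame interval", readLines(topology, n = 5), value = TRUE)
    frame_interval_ps <- if (length(rem)) {
      as.numeric(sub(".*frame interval ([0-9.]+) ps.*", "\\1", rem[1]))
    } else 10
  }
  need <- c("N", "CA", "C", "O")
  have <- unique(atoms$atom)
  if (!all(need %in% have)) {
    stop("topology lacks backbone atom(s): ",
         paste(setdiff(need, have), collapse = ", "))
  }
  if (is.null(coordinates)) {
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  } else {
    if (!file.exists(coordinates)) stop("coordinate file not found: ",
                                        coordinates)
    xyz <- bio3d::read.dcd(coordinates, verbose = FALSE)
  }
  na <- nrow(atoms)
  if (ncol(xyz) != 3 * na) {
    stop("atom-count mismatch: topology has ", na, " atoms, coordinates ",
         ncol(xyz) / 3)
  }
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, na, 3))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, 3 * na, by = 3)] / 10
  helix_trajectory(atoms, coords, frame_interval_ps)
}
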