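#' Molecular system container
#'
#' The central data model: an atom table plus an ordered list of coordinate
#' frames. All coordinates are stored in Angstrom regardless of the source
#' format; unit conversion happens only at the I/O boundary.
#'
#' The atom table has one row per atom with columns
#' \describe{
#'   \item{name}{atom name, e.g. `"CA"`, `"P"`, `"OW"`}
#'   \item{element}{element symbol, inferred from the name when absent}
#'   \item{resid}{internal residue index, 1-based, sequential over the system}
#'   \item{resname}{3-letter residue name}
#'   \item{resseq}{author residue numbering (1-based; the public addressing
#'     scheme used by every analysis)}
#'   \item{chain}{chain identifier}
#'   \item{charge}{per-atom charge in elementary charges (metadata; `NA` when
#'     unknown)}
#' }
#'
#' @param atoms data.frame as described above.
#' @param frames list of frames from [new_frame()].
#' @param time_ps optional numeric vector of frame times (ps).
#' @return an object of class `mh_system`.
#' @export
new_system <- function(atoms, frames = list(), time_ps = NULL) {
  need <- c("name", "element", "resid", "resname", "resseq", "chain", "charge")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  atoms <- as.data.frame(atoms[need], stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  for (fr in frames) validate_frame(fr, nrow(atoms))
  structure(list(atoms = atoms, frames = frames, time_ps = time_ps),
            class = "mh_system")
}

#' Single coordinate frame
#'
#' @param xyz N x 3 numeric matrix of coordinates (Angstrom).
#' @param box optional length-3 numeric of orthorhombic box edges (Angstrom).
#' @return an object of class `mh_frame`.
#' @export
new_frame <- function(xyz, box = NULL) {
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- NULL
  if (ncol(xyz) != 3L) stop("xyz must be an N x 3 matrix", call. = FALSE)
  if (!all(is.finite(xyz))) stop("non-finite coordinates in frame", call. = FALSE)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be 3 positive edge lengths (orthorhombic)", call. = FALSE)
  }
  structure(list(xyz = xyz, box = box), class = "mh_frame")
}

validate_frame <- function(frame, n_atoms) {
  if (!inherits(frame, "mh_frame")) stop("not an mh_frame", call. = FALSE)
  if (nrow(frame$xyz) != n_atoms)
    stop("frame has ", nrow(frame$xyz), " atoms; topology has ", n_atoms,
         call. = FALSE)
  invisible(frame)
}

#' @export
print.mh_system <- function(x, ...) {
  cat(sprintf("<mh_system> %d atoms, %d residues, %d frame(s)\n",
              nrow(x$atoms), length(unique(x$atoms$resid)), length(x$frames)))
  invisible(x)
}

n_frames <- function(system) length(system$frames)

#' Extract one frame from a system
#' @param system an `mh_system`.
#' @param i frame index (1-based).
#' @return an `mh_frame`.
#' @export
get_frame <- function(system, i = 1L) {
  if (i < 1L || i > length(system$frames))
    stop("frame index out of range", call. = FALSE)
  system$frames[[i]]
}

#' Replace all frames of a system
#' @param system an `mh_system`.
#' @param frames list of `mh_frame` objects.
#' @return the modified system.
#' @export
set_frames <- function(system, frames) {
  for (fr in frames) validate_frame(fr, nrow(system$atoms))
  system$frames <- frames
  system
}

#' One-letter sequence of a system
#'
#' @param system an `mh_system`.
#' @param chain optional chain id; default uses all protein residues.
#' @return named character vector of 1-letter codes, names = `resseq`.
#' @export
system_sequence <- function(system, chain = NULL) {
  at <- system$atoms
  keep <- at$resname %in% names(.aa_three_to_one)
  if (!is.null(chain)) keep <- keep & at$chain == chain
  at <- at[keep, , drop = FALSE]
  first <- !duplicated(at$resid)
  out <- .aa_three_to_one[at$resname[first]]
  names(out) <- at$resseq[first]
  out
}

# Residue-level bookkeeping: first atom row and atom rows per residue.
residue_table <- function(system) {
  at <- system$atoms
  first <- which(!duplicated(at$resid))
  data.frame(resid = at$resid[first], resname = at$resname[first],
             resseq = at$resseq[first], chain = at$chain[first],
             stringsAsFactors = FALSE)
}

atoms_of_residue <- function(system, resid) which(system$atoms$resid == resid)

# Map author numbering (+ optional chain) to the internal residue index.
resid_of_resseq <- function(system, resseq, chain = NULL) {
  rt <- residue_table(system)
  if (!is.null(chain)) rt <- rt[rt$chain == chain, , drop = FALSE]
  hits <- rt[rt$resseq == resseq, , drop = FALSE]
  if (nrow(hits) > 1L)  # prefer protein residues in mixed systems
    hits <- hits[hits$resname %in% names(.aa_three_to_one), , drop = FALSE]
  if (nrow(hits) == 0L) stop("no residue with resseq ", resseq, call. = FALSE)
  if (nrow(hits) > 1L)
    stop("resseq ", resseq, " is ambiguous across chains; give `chain`",
         call. = FALSE)
  hits$resid
}

# Index of a named atom in a residue, NA when absent.
atom_in_residue <- function(system, resid, name) {
  idx <- which(system$atoms$resid == resid & system$atoms$name %in% name)
  if (length(idx) == 0L) NA_integer_ else idx[1L]
}

.aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

.aa_one_to_three <- stats::setNames(names(.aa_three_to_one),
                                    unname(.aa_three_to_one))

# Guess an element from a PDB-style atom name.
guess_element <- function(name) {
  stripped <- sub("^[0-9]+", "", trimws(name))
  two <- toupper(substr(stripped, 1L, 2L))
  one <- toupper(substr(stripped, 1L, 1L))
  ifelse(two %in% c("CL", "NA", "BR", "MG", "ZN", "FE", "CA2"),
         paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))),
         one)
}

is_hydrogen <- function(atoms) atoms$element == "H"
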