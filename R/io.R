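#' Read a molecular structure file
#'
#' Reads PDB (via bio3d; one frame per `MODEL` block) or GROMACS GRO files
#' into the package's system container. GRO coordinates (nm) are converted to
#' Angstrom on the way in; PDB coordinates are already Angstrom.
#'
#' @param path path to the structure file.
#' @param format `"pdb"` or `"gro"`; default guessed from the file extension.
#' @return an [new_system()] object with at least one frame.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("pdb", "gro"))
      stop("cannot guess format from extension '", ext,
           "'; pass format explicitly", call. = FALSE)
    format <- ext
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format, pdb = read_pdb_system(path), gro = read_gro_system(path))
}

read_pdb_system <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse PDB '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  # new residue whenever the (chain, resno, resname) triple changes
  key <- paste(at$chain, at$resno, at$resid)
  resid <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- guess_element(at$elety[is.na(elem) | elem == ""])
  atoms <- data.frame(
    name = at$elety, element = trimws(elem), resid = resid,
    resname = at$resid, resseq = at$resno,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    charge = NA_real_, stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    new_frame(matrix(xyz[i, ], ncol = 3L, byrow = TRUE), box = pdb_box(path)))
  new_system(atoms, frames)
}

# CRYST1 record -> orthorhombic box, NULL when absent or angles != 90.
pdb_box <- function(path) {
  lines <- readLines(path, n = 500L, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) == 0L) return(NULL)
  f <- function(a, b) suppressWarnings(as.numeric(substr(cr[1L], a, b)))
  edges <- c(f(7, 15), f(16, 24), f(25, 33))
  angles <- c(f(34, 40), f(41, 47), f(48, 54))
  if (any(is.na(edges)) || any(edges <= 1)) return(NULL)
  if (any(abs(angles - 90) > 1e-3))
    stop("triclinic PDB box: periodic analyses support orthorhombic boxes only",
         call. = FALSE)
  edges
}

read_gro_system <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("GRO file too short: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n)) stop("GRO format error at line 2 (atom count): ", path,
                     call. = FALSE)
  if (length(lines) < 2L + n + 1L)
    stop("GRO file truncated: expected ", n, " atom lines", call. = FALSE)
  rec <- lines[3:(2L + n)]
  num <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) {
      bad <- which(is.na(v))[1L]
      stop("GRO format error at atom line ", bad, ": '", rec[bad], "'",
           call. = FALSE)
    }
    v
  }
  resseq  <- num(substr(rec, 1, 5))
  resname <- trimws(substr(rec, 6, 10))
  name    <- trimws(substr(rec, 11, 15))
  x <- num(substr(rec, 21, 28)) * 10   # nm -> Angstrom
  y <- num(substr(rec, 29, 36)) * 10
  z <- num(substr(rec, 37, 44)) * 10
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L + n + 1L]),
                                               "\\s+")[[1L]]))
  box <- if (length(boxv) >= 3L && all(is.finite(boxv[1:3])) &&
             all(boxv[1:3] > 0)) boxv[1:3] * 10 else NULL
  resid <- cumsum(c(TRUE, (resseq[-1] != resseq[-n]) |
                      (resname[-1] != resname[-n])))
  atoms <- data.frame(
    name = name, element = guess_element(name), resid = resid,
    resname = resname, resseq = resseq, chain = "A", charge = NA_real_,
    stringsAsFactors = FALSE)
  new_system(atoms, list(new_frame(cbind(x, y, z), box = box)))
}

#' Write a system to PDB or GRO
#'
#' Multi-frame systems become multi-`MODEL` PDB files; GRO output writes the
#' first (or a chosen) frame, converting Angstrom back to nm.
#'
#' @param system an `mh_system`.
#' @param path output path.
#' @param format `"pdb"` or `"gro"`; default guessed from the extension.
#' @param frame frame index for GRO output (default 1).
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path, format = c("auto", "pdb", "gro"),
                            frame = 1L) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  if (!format %in% c("pdb", "gro")) stop("unsupported format: ", format,
                                         call. = FALSE)
  if (format == "pdb") write_pdb_system(system, path) else
    write_gro_system(system, path, frame = frame)
  invisible(path)
}

write_pdb_system <- function(system, path) {
  at <- system$atoms
  xyz <- do.call(rbind, lapply(system$frames, function(fr) as.vector(t(fr$xyz))))
  box <- system$frames[[1L]]$box
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(box))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      box[1L], box[2L], box[3L], 90, 90, 90), con)
  multi <- nrow(xyz) > 1L
  for (m in seq_len(nrow(xyz))) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    nm <- ifelse(nchar(at$name) < 4L, paste0(" ", at$name), at$name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (seq_len(nrow(at)) - 1L) %% 99999L + 1L, nm, substr(at$resname, 1L, 3L),
      substr(at$chain, 1L, 1L), at$resseq %% 10000L,
      co[, 1L], co[, 2L], co[, 3L], 1, 0, at$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

write_gro_system <- function(system, path, frame = 1L) {
  at <- system$atoms
  fr <- get_frame(system, frame)
  co <- fr$xyz / 10   # Angstrom -> nm
  box <- if (is.null(fr$box)) c(0, 0, 0) else fr$box / 10
  lines <- c(
    "memhelix system",
    sprintf("%5d", nrow(at)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            at$resseq %% 100000L, substr(at$resname, 1L, 5L),
            substr(at$name, 1L, 5L), seq_len(nrow(at)) %% 100000L,
            co[, 1L], co[, 2L], co[, 3L]),
    sprintf("%10.5f%10.5f%10.5f", box[1L], box[2L], box[3L]))
  writeLines(lines, path)
}

#' Append trajectory frames to a topology
#'
#' DCD files are read through [bio3d::read.dcd()]; multi-model PDB files are
#' also accepted as a plain-text trajectory carrier. XTC and TRR have no
#' reader in this installation and raise an informative error.
#'
#' @param system an `mh_system` supplying the topology.
#' @param path trajectory file.
#' @param format one of `"dcd"`, `"pdb"`, `"xtc"`, `"trr"`; default guessed
#'   from the extension.
#' @return the system with frames appended in file order.
#' @export
attach_trajectory <- function(system, path,
                              format = c("auto", "dcd", "pdb", "xtc", "trr")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  if (format %in% c("xtc", "trr"))
    stop("no ", toupper(format), " reader is available in this installation; ",
         "convert to DCD or multi-model PDB", call. = FALSE)
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    if (ncol(xyz) != 3L * nrow(system$atoms))
      stop("topology mismatch: trajectory has ", ncol(xyz) / 3,
           " atoms, topology has ", nrow(system$atoms), call. = FALSE)
    box <- if (length(system$frames) > 0) system$frames[[1L]]$box else NULL
    add <- lapply(seq_len(nrow(xyz)), function(i)
      new_frame(matrix(xyz[i, ], ncol = 3L, byrow = TRUE), box = box))
  } else if (format == "pdb") {
    other <- read_pdb_system(path)
    if (nrow(other$atoms) != nrow(system$atoms))
      stop("topology mismatch: trajectory has ", nrow(other$atoms),
           " atoms, topology has ", nrow(system$atoms), call. = FALSE)
    add <- other$frames
  } else stop("unsupported trajectory format: ", format, call. = FALSE)
  set_frames(system, c(system$frames, add))
}
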