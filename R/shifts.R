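#' Read a chemical-shift table
#'
#' Delimited text with columns `residue_seq`, `residue_name`, `atom`,
#' `shift_ppm` (tab- or whitespace-separated; `#` comments allowed).
#'
#' @param path file path.
#' @param atom keep only this atom type (default `"HA"`).
#' @return data.frame with `resseq`, `resname`, `atom`, `shift_ppm`.
#' @export
read_shift_table <- function(path, atom = "HA") {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("residue_seq", "residue_name", "atom", "shift_ppm")
  if (!all(need %in% names(df)))
    stop("shift table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[df$atom == atom, , drop = FALSE]
  data.frame(resseq = as.integer(df$residue_seq), resname = df$residue_name,
             atom = df$atom, shift_ppm = as.numeric(df$shift_ppm),
             stringsAsFactors = FALSE)
}

#' Random-coil HA shifts for a sequence
#'
#' Looks up the packaged per-residue-type random-coil HA shift table
#' (editable TSV under `inst/extdata/`).
#'
#' @param sequence 1-letter sequence string, or a character vector of
#'   3-letter residue names.
#' @param start author number of the first residue (default 1).
#' @param path optional alternative table.
#' @return shift table as from [read_shift_table()], source random-coil.
#' @export
random_coil_shifts <- function(sequence, start = 1L, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "random_coil_ha.tsv", package = "memhelix")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (length(sequence) == 1L && nchar(sequence[1L]) > 1L) {
    codes <- strsplit(sequence, "")[[1L]]
    resn <- .aa_one_to_three[codes]
  } else {
    resn <- toupper(sequence)
  }
  if (anyNA(resn) || !all(resn %in% tab$resname))
    stop("unknown residue code in sequence", call. = FALSE)
  data.frame(resseq = seq_along(resn) + start - 1L, resname = unname(resn),
             atom = "HA",
             shift_ppm = tab$shift_ppm[match(resn, tab$resname)],
             stringsAsFactors = FALSE)
}

#' Secondary chemical shifts
#'
#' `delta_delta = delta - delta_rc` per residue covered by both tables.
#' Upfield (negative) HA secondary shifts are flagged as helix-consistent.
#'
#' @param shifts observed or predicted shift table ([read_shift_table()]).
#' @param random_coil random-coil reference table ([random_coil_shifts()]).
#' @return data.frame with `resseq`, `shift_ppm`, `rc_ppm`, `delta_ppm`,
#'   `helix_consistent`. Residues covered by only one table are dropped;
#'   disjoint coverage is an error.
#' @export
secondary_shifts <- function(shifts, random_coil) {
  shared <- intersect(shifts$resseq, random_coil$resseq)
  if (length(shared) == 0L)
    stop("shift tables have no residues in common", call. = FALSE)
  a <- shifts[match(shared, shifts$resseq), ]
  b <- random_coil[match(shared, random_coil$resseq), ]
  d <- a$shift_ppm - b$shift_ppm
  data.frame(resseq = shared, shift_ppm = a$shift_ppm, rc_ppm = b$shift_ppm,
             delta_ppm = d, helix_consistent = d < 0)
}

#' Fraction of secondary shifts agreeing within a tolerance
#'
#' Counts shared residues whose secondary shifts differ by at most `tol`
#' ppm, e.g. predicted against experimental profiles.
#'
#' @param a,b secondary-shift profiles ([secondary_shifts()]).
#' @param tol agreement tolerance in ppm (default 0.2).
#' @return fraction in `[0, 1]`.
#' @export
fraction_within <- function(a, b, tol = 0.2) {
  shared <- intersect(a$resseq, b$resseq)
  if (length(shared) == 0L) stop("no shared residues", call. = FALSE)
  da <- a$delta_ppm[match(shared, a$resseq)]
  db <- b$delta_ppm[match(shared, b$resseq)]
  mean(abs(da - db) <= tol)
}
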