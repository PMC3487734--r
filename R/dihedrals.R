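#' Backbone dihedral angles
#'
#' Standard IUPAC phi (C'(i-1)-N(i)-CA(i)-C'(i)) and psi
#' (N(i)-CA(i)-C'(i)-N(i+1)) for every protein residue and frame, degrees in
#' (-180, 180], right-handed sign convention. Chain termini (and residues
#' with missing backbone atoms or degenerate geometry) are `NA`.
#'
#' @param system an `mh_system` with protein residues.
#' @return an object of class `mh_dihedrals`: list with `phi` and `psi`
#'   (n_residue x n_frame matrices, rownames = author residue numbers) and
#'   `resseq`.
#' @export
backbone_dihedrals <- function(system) {
  rt <- residue_table(system)
  rt <- rt[rt$resname %in% names(.aa_three_to_one), , drop = FALSE]
  nr <- nrow(rt); nf <- n_frames(system)
  idx <- function(resid, name) atom_in_residue(system, resid, name)
  N  <- vapply(rt$resid, idx, integer(1), name = "N")
  CA <- vapply(rt$resid, idx, integer(1), name = "CA")
  C  <- vapply(rt$resid, idx, integer(1), name = "C")
  phi <- matrix(NA_real_, nr, nf)
  psi <- matrix(NA_real_, nr, nf)
  same_chain <- function(i, j) rt$chain[i] == rt$chain[j]
  for (f in seq_len(nf)) {
    co <- system$frames[[f]]$xyz
    for (i in seq_len(nr)) {
      if (any(is.na(c(N[i], CA[i], C[i])))) next
      if (i > 1L && !is.na(C[i - 1L]) && same_chain(i - 1L, i))
        phi[i, f] <- torsion_angle(co[C[i - 1L], ], co[N[i], ],
                                   co[CA[i], ], co[C[i], ])
      if (i < nr && !is.na(N[i + 1L]) && same_chain(i, i + 1L))
        psi[i, f] <- torsion_angle(co[N[i], ], co[CA[i], ],
                                   co[C[i], ], co[N[i + 1L], ])
    }
  }
  rownames(phi) <- rownames(psi) <- rt$resseq
  structure(list(phi = phi, psi = psi, resseq = rt$resseq),
            class = "mh_dihedrals")
}

#' @export
print.mh_dihedrals <- function(x, ...) {
  cat(sprintf("<mh_dihedrals> %d residues x %d frames\n",
              nrow(x$phi), ncol(x$phi)))
  invisible(x)
}

#' Per-block circular spread of backbone dihedrals
#'
#' Divides the frame series into `n_bins` contiguous blocks and reports, per
#' block and residue, the circular standard deviation
#' `sqrt(-2 log Rbar)` (degrees), where `Rbar` is the mean resultant length
#' of the block's angles. Circular statistics avoid wrap artefacts near
#' +/-180 degrees.
#'
#' @param dihedrals an `mh_dihedrals` object.
#' @param residues author residue numbers to report.
#' @param n_bins number of contiguous blocks (default 100).
#' @param angle `"phi"`, `"psi"` or both.
#' @return data.frame with columns `block`, `resseq`, `angle`, `circ_sd_deg`,
#'   `n`. Empty blocks yield `NA`.
#' @export
dihedral_fluctuation <- function(dihedrals, residues = dihedrals$resseq,
                                 n_bins = 100L, angle = c("phi", "psi")) {
  angle <- match.arg(angle, several.ok = TRUE)
  nf <- ncol(dihedrals$phi)
  blocks <- block_indices(nf, n_bins)
  out <- list()
  for (an in angle) {
    M <- dihedrals[[an]]
    rows <- match(as.character(residues), rownames(M))
    if (anyNA(rows)) stop("residue(s) not present: ",
                          paste(residues[is.na(rows)], collapse = ", "),
                          call. = FALSE)
    for (b in seq_along(blocks)) {
      for (k in seq_along(rows)) {
        v <- M[rows[k], blocks[[b]]]
        v <- v[!is.na(v)]
        out[[length(out) + 1L]] <- data.frame(
          block = b, resseq = residues[k], angle = an,
          circ_sd_deg = circular_sd_deg(v), n = length(v))
      }
    }
  }
  do.call(rbind, out)
}

circular_sd_deg <- function(deg) {
  if (length(deg) == 0L) return(NA_real_)
  th <- deg2rad(deg)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  if (rbar <= 0) return(Inf)
  rad2deg(sqrt(-2 * log(rbar)))
}
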