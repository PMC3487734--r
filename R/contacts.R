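# Side-chain contact criterion: two residues are in contact in a frame when
# any pair of their side-chain heavy atoms (the CA atom for glycine) is
# closer than 4.5 A (strict "<"), under the minimum image.

#' Side-chain contact occupancy map
#'
#' @param system an `mh_system`.
#' @param cutoff contact cutoff in Angstrom (default 4.5, strict `<`).
#' @param frames frame range (see [resolve_frames()]).
#' @param min_separation minimum sequence separation `|i - j|` reported
#'   (default 1, i.e. everything off the diagonal).
#' @return data.frame in long form: `res_i`, `res_j` (author numbers,
#'   `res_i < res_j`), `occupancy`.
#' @export
sidechain_contact_map <- function(system, cutoff = 4.5, frames = NULL,
                                  min_separation = 1L) {
  stopifnot(cutoff > 0)
  at <- system$atoms
  rt <- residue_table(system)
  rt <- rt[rt$resname %in% names(.aa_three_to_one), , drop = FALSE]
  sc <- sidechain_heavy_mask(at)
  groups <- lapply(rt$resid, function(r) which(at$resid == r & sc))
  keep <- lengths(groups) > 0L
  rt <- rt[keep, , drop = FALSE]; groups <- groups[keep]
  nr <- nrow(rt)
  fr_idx <- resolve_frames(n_frames(system), frames)
  counts <- matrix(0, nr, nr)
  for (fi in fr_idx) {
    fr <- system$frames[[fi]]
    for (i in seq_len(nr - 1L)) {
      for (j in (i + 1L):nr) {
        if (abs(rt$resseq[j] - rt$resseq[i]) < min_separation) next
        d <- pair_distances(fr$xyz[groups[[i]], , drop = FALSE],
                            fr$xyz[groups[[j]], , drop = FALSE], fr$box)
        if (any(d < cutoff)) counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  idx <- which(upper.tri(counts), arr.ind = TRUE)
  sep_ok <- abs(rt$resseq[idx[, 2L]] - rt$resseq[idx[, 1L]]) >= min_separation
  idx <- idx[sep_ok, , drop = FALSE]
  data.frame(res_i = rt$resseq[idx[, 1L]], res_j = rt$resseq[idx[, 2L]],
             occupancy = counts[idx] / length(fr_idx))
}

#' Peptide-lipid headgroup contact counts
#'
#' Per frame, the number of distinct lipids with at least one heavy
#' head-group atom within the cutoff of any peptide heavy atom, then block
#' means over `n_blocks` contiguous time blocks.
#'
#' @param system an `mh_system`.
#' @param headgroup selection of lipid head-group heavy atoms (grouped by
#'   their parent lipid via the residue index).
#' @param peptide selection of peptide heavy atoms.
#' @param cutoff distance cutoff in Angstrom (default 4.5, strict `<`).
#' @param n_blocks number of time blocks (default 100).
#' @param frames frame range.
#' @return list with `counts` (per frame) and `blocks` (per-block means).
#' @export
headgroup_contacts <- function(system, headgroup, peptide, cutoff = 4.5,
                               n_blocks = 100L, frames = NULL) {
  stopifnot(cutoff > 0)
  hg <- as.integer(headgroup); pep <- as.integer(peptide)
  at <- system$atoms
  hg <- hg[!is_hydrogen(at[hg, , drop = FALSE])]
  pep <- pep[!is_hydrogen(at[pep, , drop = FALSE])]
  lipid_of <- at$resid[hg]
  fr_idx <- resolve_frames(n_frames(system), frames)
  counts <- vapply(fr_idx, function(fi) {
    fr <- system$frames[[fi]]
    d <- pair_distances(fr$xyz[hg, , drop = FALSE],
                        fr$xyz[pep, , drop = FALSE], fr$box)
    touching <- apply(d < cutoff, 1L, any)
    length(unique(lipid_of[touching]))
  }, numeric(1))
  list(counts = counts, blocks = block_average(counts, n_blocks))
}

# Contiguous block index sets: blocks of size ceiling(n / n_blocks); the
# tail block may be shorter.
block_indices <- function(n, n_blocks) {
  if (n_blocks < 1L) stop("n_blocks must be >= 1", call. = FALSE)
  size <- ceiling(n / n_blocks)
  starts <- seq(1L, n, by = size)
  lapply(starts, function(s) s:min(n, s + size - 1L))
}

#' Block averages of a per-frame series
#'
#' Splits the series into contiguous blocks (tail block possibly shorter)
#' and returns the per-block means. The size-weighted mean of the block
#' means equals the global mean.
#'
#' @param series numeric per-frame values.
#' @param n_blocks requested number of blocks (default 100).
#' @return numeric vector of block means, with block sizes as the `"sizes"`
#'   attribute.
#' @export
block_average <- function(series, n_blocks = 100L) {
  n <- length(series)
  if (n < 1L) stop("empty series", call. = FALSE)
  bl <- block_indices(n, n_blocks)
  structure(vapply(bl, function(ix) mean(series[ix]), numeric(1)),
            sizes = lengths(bl))
}
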