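#' Assign lipids to leaflets
#'
#' A lipid's phosphorus reference above the median phosphorus z goes to the
#' upper leaflet, otherwise to the lower. Frames are assumed recentred.
#'
#' @param system an `mh_system`.
#' @param phosphorus selection of phosphorus reference atoms (one per lipid).
#' @param frame frame index (default 1).
#' @return data.frame with `resid` (lipid), `resname`, `p_index`, `leaflet`.
#' @export
assign_leaflets <- function(system, phosphorus, frame = 1L) {
  idx <- as.integer(phosphorus)
  at <- system$atoms
  lip <- at$resid[idx]
  if (anyNA(lip) || any(duplicated(lip)))
    stop("phosphorus selection must give exactly one reference per lipid",
         call. = FALSE)
  z <- get_frame(system, frame)$xyz[idx, 3L]
  # split at the midrange, which stays put when leaflets lose members
  mid <- (min(z) + max(z)) / 2
  if (max(z) - min(z) < 1e-6)
    warning("all phosphorus atoms at one z; assigning a single leaflet",
            call. = FALSE)
  data.frame(resid = lip, resname = at$resname[idx], p_index = idx,
             leaflet = ifelse(z >= mid, "upper", "lower"),
             stringsAsFactors = FALSE)
}

# Minimum-image xy distance matrix between grid-cell centres and reference
# points.
grid_xy_dist2 <- function(cx, cy, rx, ry, box) {
  dx <- outer(cx, rx, "-"); dy <- outer(cy, ry, "-")
  dx <- dx - box[1L] * round(dx / box[1L])
  dy <- dy - box[2L] * round(dy / box[2L])
  dx * dx + dy * dy
}

#' Grid-based area per lipid
#'
#' Partitions the xy plane of each leaflet into `grid_n x grid_n` cells and
#' assigns every cell to the xy-nearest (minimum-image) phosphorus reference
#' of that leaflet; a lipid's area is its owned-cell count times the cell
#' area, so the per-leaflet areas always sum exactly to the box xy area.
#' With a protein present, protein heavy atoms whose z falls within 5 A of
#' the leaflet's phosphorus z-range compete for cells, mirroring
#' protein-aware grid partitioning.
#'
#' @param system an `mh_system`.
#' @param phosphorus phosphorus selection (one per lipid).
#' @param grid_n grid resolution per axis (default 100, minimum 8).
#' @param protein optional selection of protein atoms.
#' @param frames frame range.
#' @param protein_slack z-slack around the phosphorus range for protein
#'   competition (default 5 A).
#' @return list with `per_lipid` (frame-averaged area per lipid),
#'   `species` (per-species mean and sd over frames of the per-frame species
#'   means), and `protein_area` (mean area occupied by the protein per
#'   leaflet).
#' @export
area_per_lipid <- function(system, phosphorus, grid_n = 100L, protein = NULL,
                           frames = NULL, protein_slack = 5) {
  if (grid_n < 8L) stop("grid_n must be at least 8", call. = FALSE)
  at <- system$atoms
  fr_idx <- resolve_frames(n_frames(system), frames)
  la0 <- assign_leaflets(system, phosphorus, frame = fr_idx[1L])
  prot_idx <- if (is.null(protein)) integer(0) else {
    pi_ <- as.integer(protein)
    pi_[!is_hydrogen(at[pi_, , drop = FALSE])]
  }
  per_lipid_acc <- matrix(0, nrow(la0), length(fr_idx))
  species_frames <- list()
  protein_area <- numeric(length(fr_idx))
  for (t in seq_along(fr_idx)) {
    fr <- system$frames[[fr_idx[t]]]
    if (is.null(fr$box)) stop("area_per_lipid needs a periodic box",
                              call. = FALSE)
    cell_area <- fr$box[1L] * fr$box[2L] / grid_n^2
    cx <- (seq_len(grid_n) - 0.5) * fr$box[1L] / grid_n
    cy <- (seq_len(grid_n) - 0.5) * fr$box[2L] / grid_n
    cells <- expand.grid(x = cx, y = cy)
    la <- assign_leaflets(system, phosphorus, frame = fr_idx[t])
    for (lf in c("upper", "lower")) {
      rows <- which(la$leaflet == lf)
      if (length(rows) == 0L) next
      rows <- rows[order(la$resid[rows])]  # tie-break: lowest lipid index
      refs <- la$p_index[rows]
      rxy <- fr$xyz[refs, , drop = FALSE]
      zr <- range(fr$xyz[refs, 3L])
      pz <- fr$xyz[prot_idx, 3L]
      pin <- prot_idx[pz >= zr[1L] - protein_slack &
                        pz <= zr[2L] + protein_slack]
      all_x <- c(rxy[, 1L], fr$xyz[pin, 1L])
      all_y <- c(rxy[, 2L], fr$xyz[pin, 2L])
      d2 <- grid_xy_dist2(cells$x, cells$y, all_x, all_y, fr$box)
      owner <- max.col(-d2, ties.method = "first")
      n_lip <- length(rows)
      own_counts <- tabulate(owner, nbins = length(all_x))
      per_lipid_acc[rows, t] <- own_counts[seq_len(n_lip)] * cell_area
      if (length(pin) > 0L)
        protein_area[t] <- protein_area[t] +
          sum(own_counts[-seq_len(n_lip)]) * cell_area
    }
    species_frames[[t]] <- tapply(per_lipid_acc[, t], la$resname, mean)
  }
  sp <- do.call(rbind, species_frames)
  species <- data.frame(species = colnames(sp),
                        mean_area = colMeans(sp),
                        sd = apply(sp, 2L, stats::sd),
                        n_frames = length(fr_idx), row.names = NULL)
  list(per_lipid = data.frame(resid = la0$resid, resname = la0$resname,
                              leaflet = la0$leaflet,
                              area = rowMeans(per_lipid_acc)),
       species = species,
       protein_area = mean(protein_area))
}

#' Grid-based bilayer thickness
#'
#' Per grid cell, the z of the xy-nearest upper-leaflet phosphorus minus the
#' z of the xy-nearest lower-leaflet phosphorus (the phosphorus-phosphorus
#' distance from the top to the bottom leaflet), averaged over cells and
#' frames.
#'
#' @param system an `mh_system`.
#' @param phosphorus phosphorus selection.
#' @param grid_n grid resolution (default 100).
#' @param frames frame range.
#' @return list with `mean` (A), `sd` over frames, `per_frame`.
#' @export
bilayer_thickness <- function(system, phosphorus, grid_n = 100L,
                              frames = NULL) {
  if (grid_n < 8L) stop("grid_n must be at least 8", call. = FALSE)
  fr_idx <- resolve_frames(n_frames(system), frames)
  per_frame <- vapply(fr_idx, function(fi) {
    fr <- system$frames[[fi]]
    if (is.null(fr$box)) stop("bilayer_thickness needs a periodic box",
                              call. = FALSE)
    la <- assign_leaflets(system, phosphorus, frame = fi)
    up <- la$p_index[la$leaflet == "upper"]
    lo <- la$p_index[la$leaflet == "lower"]
    if (length(up) == 0L || length(lo) == 0L)
      stop("empty leaflet; cannot measure thickness", call. = FALSE)
    cx <- (seq_len(grid_n) - 0.5) * fr$box[1L] / grid_n
    cy <- (seq_len(grid_n) - 0.5) * fr$box[2L] / grid_n
    cells <- expand.grid(x = cx, y = cy)
    zu <- fr$xyz[up, 3L][max.col(-grid_xy_dist2(cells$x, cells$y,
                                                fr$xyz[up, 1L],
                                                fr$xyz[up, 2L], fr$box),
                                 ties.method = "first")]
    zl <- fr$xyz[lo, 3L][max.col(-grid_xy_dist2(cells$x, cells$y,
                                                fr$xyz[lo, 1L],
                                                fr$xyz[lo, 2L], fr$box),
                                 ties.method = "first")]
    mean(zu - zl)
  }, numeric(1))
  list(mean = mean(per_frame), sd = stats::sd(per_frame),
       per_frame = per_frame)
}

#' Acyl-chain deuterium order parameters
#'
#' For each interior chain carbon i the molecular z-axis is the unit vector
#' from C(i-1) to C(i+1); y is perpendicular to z in the C(i-1), C(i),
#' C(i+1) plane and x completes the right-handed frame (the standard
#' united-atom construction). With theta measured against the bilayer normal
#' (box z), `S_ab = <(3 cos theta_a cos theta_b - delta_ab) / 2>` and the
#' reported order parameter is `S_cd = -(2/3) S_xx - (1/3) S_yy`, the
#' positive-for-ordered convention. For straight (collinear) pseudo-chains
#' the local frame is azimuthally degenerate and the axially symmetric limit
#' `S_cd = S_zz / 2` is used, which the full construction reduces to.
#'
#' @param system an `mh_system`.
#' @param chains named list: species (resname) -> character vector of chain
#'   carbon atom names in chain order (>= 3 carbons).
#' @param frames frame range.
#' @return list with `profile` (per species and carbon index, frame- and
#'   lipid-averaged S_cd), `grand_mean`, `grand_sd` (sd of the per-frame
#'   grand means), `per_frame`.
#' @export
order_parameters <- function(system, chains, frames = NULL) {
  at <- system$atoms
  fr_idx <- resolve_frames(n_frames(system), frames)
  # per species: matrix of atom indices (lipid x carbon)
  chain_idx <- list()
  for (sp in names(chains)) {
    cn <- chains[[sp]]
    if (length(cn) < 3L) stop("chain for ", sp, " needs >= 3 carbons",
                              call. = FALSE)
    lips <- unique(at$resid[at$resname == sp])
    if (length(lips) == 0L) next
    m <- matrix(NA_integer_, length(lips), length(cn))
    key_all <- paste(at$resid, at$name)
    if (anyDuplicated(key_all[at$resname == sp]))
      stop("broken chain ordering for species ", sp, call. = FALSE)
    for (ci in seq_along(cn)) {
      a <- match(paste(lips, cn[ci]), key_all)
      if (anyNA(a))
        stop("broken chain ordering for species ", sp, ": atom ", cn[ci],
             call. = FALSE)
      m[, ci] <- a
    }
    chain_idx[[sp]] <- m
  }
  if (length(chain_idx) == 0L) stop("no lipids match the chain spec",
                                    call. = FALSE)
  profile <- list(); per_frame_grand <- numeric(length(fr_idx))
  acc <- list()
  for (t in seq_along(fr_idx)) {
    co <- system$frames[[fr_idx[t]]]$xyz
    vals_frame <- c()
    for (sp in names(chain_idx)) {
      m <- chain_idx[[sp]]
      nc <- ncol(m)
      scd <- matrix(NA_real_, nrow(m), nc - 2L)
      for (li in seq_len(nrow(m))) {
        for (ci in 2:(nc - 1L)) {
          p0 <- co[m[li, ci - 1L], ]; p1 <- co[m[li, ci], ]
          p2 <- co[m[li, ci + 1L], ]
          scd[li, ci - 1L] <- scd_carbon(p0, p1, p2)
        }
      }
      key <- sp
      acc[[key]] <- if (is.null(acc[[key]])) scd / length(fr_idx) else
        acc[[key]] + scd / length(fr_idx)
      vals_frame <- c(vals_frame, as.numeric(scd))
    }
    per_frame_grand[t] <- mean(vals_frame, na.rm = TRUE)
  }
  prof <- do.call(rbind, lapply(names(acc), function(sp) {
    data.frame(species = sp, carbon = seq_len(ncol(acc[[sp]])) + 1L,
               s_cd = colMeans(acc[[sp]], na.rm = TRUE))
  }))
  list(profile = prof, grand_mean = mean(per_frame_grand),
       grand_sd = stats::sd(per_frame_grand), per_frame = per_frame_grand)
}

# S_cd for one interior carbon given its neighbours; bilayer normal = +z.
scd_carbon <- function(p0, p1, p2) {
  zv <- p2 - p0
  nz <- vec_norm(zv)
  if (nz < 1e-9) return(NA_real_)
  zv <- zv / nz
  v1 <- p0 - p1; v2 <- p2 - p1
  xp <- cross3(v1, v2)
  p2fun <- function(c_) (3 * c_^2 - 1) / 2
  if (vec_norm(xp) < 1e-8) {
    # collinear pseudo-chain: axially symmetric limit S_cd = S_zz / 2
    return(p2fun(zv[3L]) / 2)
  }
  xv <- unit_vec(xp)                    # normal to the chain plane
  yv <- cross3(zv, xv)                  # in-plane, perpendicular to z
  s_xx <- p2fun(xv[3L]); s_yy <- p2fun(yv[3L])
  -(2 / 3) * s_xx - (1 / 3) * s_yy
}

#' Radial distribution function with periodic boundaries
#'
#' Histogram of reference-target minimum-image distances normalised by the
#' ideal-gas shell count `rho * V_shell` with the whole-box target density
#' `rho = N_target / V`, averaged over frames.
#'
#' @param system an `mh_system` with periodic boxes.
#' @param reference,target selections; identical atoms appearing in both are
#'   never paired with themselves.
#' @param dr bin width in Angstrom (default 0.1).
#' @param r_max maximum distance; default (and upper clip) `min(box) / 2`.
#' @param frames frame range.
#' @return list with `r` (bin centres), `g`, `n_cum` (cumulative
#'   coordination number per reference), `rho` (bulk target density,
#'   Angstrom^-3), `edges`.
#' @export
rdf <- function(system, reference, target, dr = 0.1, r_max = NULL,
                frames = NULL) {
  ref <- as.integer(reference); tgt <- as.integer(target)
  fr_idx <- resolve_frames(n_frames(system), frames)
  box0 <- system$frames[[fr_idx[1L]]]$box
  if (is.null(box0)) stop("rdf needs a periodic box", call. = FALSE)
  half <- min(box0) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9) {
    warning("r_max clipped to min(box)/2 = ", signif(half, 4), call. = FALSE)
    r_max <- half
  }
  edges <- seq(0, r_max, by = dr)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- numeric(nb); rho_acc <- 0
  for (fi in fr_idx) {
    fr <- system$frames[[fi]]
    d <- pair_distances(fr$xyz[ref, , drop = FALSE],
                        fr$xyz[tgt, , drop = FALSE], fr$box)
    same <- outer(ref, tgt, "==")
    d <- d[!same]
    d <- d[d <= r_max]
    bin <- pmin(nb, findInterval(d, edges, rightmost.closed = TRUE))
    counts <- counts + tabulate(bin, nbins = nb)
    rho_acc <- rho_acc + length(tgt) / prod(fr$box)
  }
  rho <- rho_acc / length(fr_idx)
  vshell <- 4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  norm <- length(fr_idx) * length(ref) * rho * vshell
  g <- counts / norm
  n_cum <- cumsum(counts) / (length(fr_idx) * length(ref))
  list(r = (edges[-1L] + edges[-length(edges)]) / 2, g = g, n_cum = n_cum,
       rho = rho, edges = edges)
}

#' Coordination number from an RDF
#'
#' `N(r_cut) = rho * sum_bins 4 pi r^2 g(r) dr` over bins up to `r_cut`,
#' evaluated with exact shell volumes; at 3 A around a phosphate against
#' water oxygens this is the hydration number.
#'
#' @param rdf_result result of [rdf()].
#' @param r_cut integration limit in Angstrom (default 3).
#' @return coordination number (count).
#' @export
coordination_number <- function(rdf_result, r_cut = 3.0) {
  edges <- rdf_result$edges
  if (r_cut > edges[length(edges)] + 1e-9)
    stop("rdf bins do not cover r_cut", call. = FALSE)
  vshell <- 4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  take <- edges[-1L] <= r_cut + 1e-9
  sum(rdf_result$rho * rdf_result$g[take] * vshell[take])
}
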