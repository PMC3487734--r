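# Slab pseudo-bilayer generator: two leaflets of bead lipids (phosphorus
# reference + head-group bead + straight acyl pseudo-chain) on a jittered
# square lattice, a uniform-density water slab, and optional counterions.
# No physics is modelled: the geometry is exactly what the bilayer analyses
# consume, so every observable has a constructed ground truth.

#' Slab bilayer specification
#'
#' Defaults mirror the DOPC/DOPS membrane studied by the analyses: 88 DOPC
#' and 40 DOPS split evenly over two leaflets (64 lipids each, an 8 x 8
#' lattice), area per lipid 64 A^2 (so the box is 64 x 64 A), a 38 A
#' phosphorus-plane separation inside an 80 A box, and SPC-like water at
#' 0.0334 A^-3. DOPS carries -1 head-group charge; DOPC is neutral.
#'
#' @param counts named lipid counts per species.
#' @param area_per_lipid target area per lipid (A^2).
#' @param p_separation phosphorus-plane separation (A).
#' @param box_z box height (A).
#' @param chain_beads number of acyl pseudo-beads per chain.
#' @param chain_tilt chain tilt from the bilayer normal (degrees).
#' @param chain_spacing distance between consecutive chain beads (A).
#' @param water_density water-oxygen number density (A^-3).
#' @param charges per-species head-group charge (elementary charges).
#' @param jitter lattice jitter sd in the xy plane (A).
#' @param seed RNG seed (species placement, jitter, water).
#' @return spec list for [build_slab_bilayer()].
#' @export
slab_bilayer_spec <- function(counts = c(DOPC = 88L, DOPS = 40L),
                              area_per_lipid = 64, p_separation = 38,
                              box_z = 80, chain_beads = 8L, chain_tilt = 0,
                              chain_spacing = 1.8,
                              water_density = 0.0334,
                              charges = c(DOPC = 0, DOPS = -1),
                              jitter = 0.5, seed = 1L) {
  stopifnot(area_per_lipid > 0, p_separation > 0, box_z > p_separation,
            all(counts > 0), chain_beads >= 3L)
  total <- sum(counts)
  if (total %% 2L != 0L)
    stop("total lipid count must split evenly over two leaflets",
         call. = FALSE)
  list(counts = counts, area_per_lipid = area_per_lipid,
       p_separation = p_separation, box_z = box_z,
       chain_beads = chain_beads, chain_tilt = chain_tilt,
       chain_spacing = chain_spacing, water_density = water_density,
       charges = charges, jitter = jitter, seed = seed)
}

#' Build a slab pseudo-bilayer with water
#'
#' Per leaflet, lipids sit on a (jittered) square lattice with spacing
#' `sqrt(area_per_lipid)`; each lipid is a phosphorus bead `P` at the
#' leaflet plane, a head-group bead `HG` 2 A toward the water, and a
#' straight chain of `C1..Cn` beads descending toward the midplane at the
#' spec tilt (each lipid gets a seeded random tilt azimuth). Species are
#' assigned randomly at the requested ratio within each leaflet. Water
#' oxygens (`SOL`/`OW`) fill the remaining z-volume uniformly. The bilayer
#' is centred at `box_z / 2`.
#'
#' @param spec a [slab_bilayer_spec()].
#' @return an `mh_system` with one frame and an orthorhombic box; per-atom
#'   `charge` carries the head-group charge on the P bead.
#' @export
build_slab_bilayer <- function(spec = slab_bilayer_spec()) {
  n_leaf <- sum(spec$counts) / 2L
  nx <- ceiling(sqrt(n_leaf))
  if (nx * nx != n_leaf)
    stop("lipids per leaflet (", n_leaf, ") must be a perfect square for ",
         "the lattice build", call. = FALSE)
  spacing <- sqrt(spec$area_per_lipid)
  box <- c(nx * spacing, nx * spacing, spec$box_z)
  zmid <- spec$box_z / 2
  zp <- c(upper = zmid + spec$p_separation / 2,
          lower = zmid - spec$p_separation / 2)
  # even species split per leaflet (+-1 handled by rounding one leaflet up)
  half <- floor(spec$counts / 2L)
  rem <- spec$counts - 2L * half
  leaf_counts <- list(upper = half + rem, lower = half)
  with_seed(spec$seed, {
    atoms <- list(); coords <- list(); resid <- 0L
    for (lf in c("upper", "lower")) {
      cnt <- leaf_counts[[lf]]
      species <- sample(rep(names(cnt), times = cnt))
      lattice <- expand.grid(ix = seq_len(nx) - 0.5, iy = seq_len(nx) - 0.5)
      down <- if (lf == "upper") -1 else 1
      for (k in seq_len(n_leaf)) {
        resid <- resid + 1L
        sp <- species[k]
        px <- lattice$ix[k] * spacing + stats::rnorm(1L, sd = spec$jitter)
        py <- lattice$iy[k] * spacing + stats::rnorm(1L, sd = spec$jitter)
        px <- px %% box[1L]; py <- py %% box[2L]
        p_xyz <- c(px, py, zp[[lf]])
        hg_xyz <- p_xyz + c(0, 0, -down * 2)
        tau <- deg2rad(spec$chain_tilt)
        phi_az <- stats::runif(1L, 0, 2 * pi)
        dirv <- c(sin(tau) * cos(phi_az), sin(tau) * sin(phi_az),
                  down * cos(tau))
        ch <- t(vapply(seq_len(spec$chain_beads), function(b)
          p_xyz + dirv * spec$chain_spacing * b, numeric(3)))
        nm <- c("P", "HG", paste0("C", seq_len(spec$chain_beads)))
        atoms[[resid]] <- data.frame(
          name = nm, element = c("P", "O", rep("C", spec$chain_beads)),
          resid = resid, resname = sp, resseq = resid, chain = "L",
          charge = c(spec$charges[[sp]], rep(0, 1L + spec$chain_beads)),
          stringsAsFactors = FALSE)
        coords[[resid]] <- rbind(p_xyz, hg_xyz, ch)
      }
    }
    # water slab: uniform density outside the leaflet planes (+- 1 A pad)
    pad <- 1
    zlo <- c(0, zp[["upper"]] + pad)
    zhi <- c(zp[["lower"]] - pad, spec$box_z)
    for (w in 1:2) {
      vol <- box[1L] * box[2L] * (zhi[w] - zlo[w])
      nw <- round(spec$water_density * vol)
      if (nw < 1L) next
      xyz <- cbind(stats::runif(nw, 0, box[1L]), stats::runif(nw, 0, box[2L]),
                   stats::runif(nw, zlo[w], zhi[w]))
      ids <- resid + seq_len(nw)
      atoms[[length(atoms) + 1L]] <- data.frame(
        name = "OW", element = "O", resid = ids, resname = "SOL",
        resseq = ids, chain = "W", charge = 0, stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <- xyz
      resid <- resid + nw
    }
    new_system(do.call(rbind, atoms),
               list(new_frame(do.call(rbind, coords), box = box)))
  })
}

#' Counterion count to neutralise a composition
#'
#' @param counts named species counts (lipids, peptides, ...).
#' @param charges named per-species charges (elementary charges).
#' @param mode `"cation"` (default) returns the number of +1 ions needed for
#'   a net negative composition; `"anion"` the number of -1 ions for a net
#'   positive one.
#' @return non-negative integer ion count.
#' @examples
#' neutralize(c(DOPC = 88, DOPS = 40), c(DOPC = 0, DOPS = -1))  # 40
#' @export
neutralize <- function(counts, charges, mode = c("cation", "anion")) {
  mode <- match.arg(mode)
  if (!all(names(counts) %in% names(charges)))
    stop("charges missing for: ",
         paste(setdiff(names(counts), names(charges)), collapse = ", "),
         call. = FALSE)
  net <- sum(counts * charges[names(counts)])
  if (abs(net - round(net)) > 1e-9)
    stop("non-integer net charge: ", net, call. = FALSE)
  net <- round(net)
  if (mode == "cation") max(0L, -net) else max(0L, net)
}

#' Add monovalent counterions to the water region
#'
#' Places `n` ion beads uniformly (seeded) inside the water slab of a built
#' bilayer system.
#'
#' @param system a bilayer `mh_system` (from [build_slab_bilayer()]).
#' @param n ion count (e.g. from [neutralize()]).
#' @param ion residue/atom name (default `"NA"`, charge +1).
#' @param charge per-ion charge.
#' @param seed RNG seed.
#' @return the system with ions appended.
#' @export
add_counterions <- function(system, n, ion = "NA", charge = 1, seed = 1L) {
  if (n == 0L) return(system)
  fr <- get_frame(system, 1L)
  wat <- which(system$atoms$resname %in% water_resnames())
  if (length(wat) == 0L) stop("no water region to place ions in",
                              call. = FALSE)
  zr <- range(fr$xyz[wat, 3L])
  with_seed(seed, {
    xyz <- cbind(stats::runif(n, 0, fr$box[1L]), stats::runif(n, 0, fr$box[2L]),
                 stats::runif(n, zr[1L], zr[2L]))
    maxr <- max(system$atoms$resid)
    ions <- data.frame(name = ion, element = ion, resid = maxr + seq_len(n),
                       resname = ion, resseq = maxr + seq_len(n), chain = "I",
                       charge = charge, stringsAsFactors = FALSE)
    sys <- new_system(rbind(system$atoms, ions),
                      list(new_frame(rbind(fr$xyz, xyz), box = fr$box)),
                      system$time_ps)
    sys
  })
}
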