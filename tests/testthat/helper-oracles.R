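# Independent oracles and small constructed systems used across the suite.
# Oracles are deliberately brute-force (image enumeration, all-pairs loops)
# and share no code with the implementation paths they check.

# Minimum-image distance by explicit enumeration of the 27 periodic images.
oracle_min_image <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- b + c(ix * box[1], iy * box[2], iz * box[3]) - a
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# Exhaustive H-bond checker: plain loops, raw geometry, no shared helpers.
oracle_hbonds <- function(xyz, donors, acceptors, box = NULL,
                          dist_cut = 3.5, ang_cut = 30) {
  hits <- list()
  for (dn in donors) {
    for (a in acceptors) {
      if (a == dn$d || (!is.na(dn$h) && a == dn$h)) next
      da <- xyz[a, ] - xyz[dn$d, ]
      if (!is.null(box)) {
        for (k in 1:3) da[k] <- da[k] - box[k] * round(da[k] / box[k])
      }
      r <- sqrt(sum(da^2))
      if (r >= dist_cut) next
      hx <- if (is.na(dn$h)) dn$h_xyz else xyz[dn$h, ]
      dh <- hx - xyz[dn$d, ]
      cosang <- sum(dh * da) / sqrt(sum(dh^2) * sum(da^2))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang >= ang_cut) next
      hits[[length(hits) + 1]] <- c(dn$d, a)
    }
  }
  if (length(hits) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, hits)
}

# All-pairs side-chain contact oracle for one frame.
oracle_contacts <- function(xyz, groups, box = NULL, cutoff = 4.5) {
  n <- length(groups)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    found <- FALSE
    for (a in groups[[i]]) {
      for (b in groups[[j]]) {
        d <- xyz[b, ] - xyz[a, ]
        if (!is.null(box))
          for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
        if (sqrt(sum(d^2)) < cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    m[i, j] <- m[j, i] <- found
  }
  m
}

# Brute-force simplified Kabsch-Sander assignment: recompute everything from
# raw coordinates with independent arithmetic (all donor-acceptor pairs).
oracle_kabsch_sander <- function(system, frame_i = 1) {
  at <- system$atoms
  co <- system$frames[[frame_i]]$xyz
  rids <- unique(at$resid[at$resname %in% names(memhelix:::.aa_three_to_one)])
  nr <- length(rids)
  get1 <- function(rid, nm) {
    w <- which(at$resid == rid & at$name %in% nm)
    if (length(w) == 0) NULL else co[w[1], ]
  }
  resname <- vapply(rids, function(r) at$resname[at$resid == r][1], "")
  HB <- matrix(FALSE, nr, nr)
  for (i in seq_len(nr)) {
    if (resname[i] == "PRO") next
    Ni <- get1(rids[i], "N")
    Hi <- get1(rids[i], c("H", "HN"))
    if (is.null(Hi) && i > 1) {
      Cp <- get1(rids[i - 1], "C"); CAi <- get1(rids[i], "CA")
      if (!is.null(Cp) && !is.null(CAi) && !is.null(Ni)) {
        u1 <- (Ni - Cp) / sqrt(sum((Ni - Cp)^2))
        u2 <- (Ni - CAi) / sqrt(sum((Ni - CAi)^2))
        u <- u1 + u2
        Hi <- Ni + u / sqrt(sum(u^2))
      }
    }
    if (is.null(Ni) || is.null(Hi)) next
    for (j in seq_len(nr)) {
      if (abs(i - j) < 2) next
      Cj <- get1(rids[j], "C"); Oj <- get1(rids[j], "O")
      if (is.null(Cj) || is.null(Oj)) next
      E <- 27.888 * (1 / sqrt(sum((Oj - Ni)^2)) + 1 / sqrt(sum((Cj - Hi)^2)) -
                       1 / sqrt(sum((Oj - Hi)^2)) - 1 / sqrt(sum((Cj - Ni)^2)))
      HB[i, j] <- E < -0.5
    }
  }
  memhelix:::ks_assign_codes(HB)
}

# Tiny two-residue system with an explicit serine side-chain donor whose
# geometry can be toggled on/off against a backbone carbonyl acceptor.
make_hbond_pair_system <- function(bonded_frames, n_frames) {
  at <- data.frame(
    name = c("N", "CA", "C", "O", "N", "CA", "C", "O", "OG", "HG"),
    element = c("N", "C", "C", "O", "N", "C", "C", "O", "O", "H"),
    resid = c(rep(1L, 4), rep(2L, 6)),
    resname = c(rep("LEU", 4), rep("SER", 6)),
    resseq = c(rep(16L, 4), rep(20L, 6)),
    chain = "A", charge = NA_real_, stringsAsFactors = FALSE)
  base <- rbind(
    c(0, 0, 0), c(1.5, 0, 0), c(2.5, 1, 0), c(2.5, 2.2, 0),   # LEU16, O acceptor
    c(10, 10, 0), c(11.5, 10, 0), c(12.5, 11, 0), c(12.5, 12.2, 0),
    c(2.5, 5.0, 0),   # OG placeholder (overwritten per frame)
    c(2.5, 4.0, 0))   # HG placeholder
  frames <- lapply(seq_len(n_frames), function(i) {
    xyz <- base
    if (i %in% bonded_frames) {
      xyz[9, ] <- c(2.5, 5.0, 0)   # OG 2.8 A from O, H-O-..A collinear
      xyz[10, ] <- c(2.5, 4.0, 0)
    } else {
      xyz[9, ] <- c(2.5, 9.0, 0)   # far away: no bond possible
      xyz[10, ] <- c(2.5, 8.0, 0)
    }
    new_frame(xyz)
  })
  new_system(at, frames)
}

# A raw atom table for ad-hoc geometric systems (one residue per atom).
point_system <- function(xyz, names = "X", resnames = "UNK", box = NULL,
                         elements = NULL) {
  n <- nrow(xyz)
  names <- rep_len(names, n); resnames <- rep_len(resnames, n)
  if (is.null(elements)) elements <- memhelix:::guess_element(names)
  at <- data.frame(name = names, element = elements, resid = seq_len(n),
                   resname = resnames, resseq = seq_len(n), chain = "X",
                   charge = 0, stringsAsFactors = FALSE)
  new_system(at, list(new_frame(xyz, box = box)))
}
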