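test_that("hydrogen-bond detection honours both cutoffs strictly", {
  don <- list(list(d = 1L, h = 2L, h_xyz = NULL))
  sys <- point_system(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)),
                      names = c("N", "H", "O"))
  expect_equal(nrow(detect_hbonds(get_frame(sys), don, 3L)), 1L)
  # distance boundary: exactly at and just under the cutoff
  sys2 <- point_system(rbind(c(0, 0, 0), c(1, 0, 0), c(3.6, 0, 0)),
                       names = c("N", "H", "O"))
  expect_equal(nrow(detect_hbonds(get_frame(sys2), don, 3L)), 0L)
  sys3 <- point_system(rbind(c(0, 0, 0), c(1, 0, 0), c(3.5, 0, 0)),
                       names = c("N", "H", "O"))
  expect_equal(nrow(detect_hbonds(get_frame(sys3), don, 3L)), 0L)  # strict <
  # angle boundary: H-D-A = 30 deg exactly is not bonded, 29 deg is
  mk_angle <- function(deg) {
    a <- deg * pi / 180
    point_system(rbind(c(0, 0, 0), c(cos(a), sin(a), 0), c(3, 0, 0)),
                 names = c("N", "H", "O"))
  }
  expect_equal(nrow(detect_hbonds(get_frame(mk_angle(30.001)), don, 3L)), 0L)
  expect_equal(nrow(detect_hbonds(get_frame(mk_angle(29.999)), don, 3L)), 1L)
})

test_that("hydrogen-bond detection matches the exhaustive oracle", {
  set.seed(61)
  box <- c(18, 18, 18)
  n <- 120
  xyz <- cbind(runif(n, 0, 18), runif(n, 0, 18), runif(n, 0, 18))
  # donors: atoms 1..40 with an attached hydrogen 1 A away
  donors <- lapply(1:40, function(i)
    list(d = i, h = NA_integer_,
         h_xyz = xyz[i, ] + {
           v <- rnorm(3); v / sqrt(sum(v^2))
         }))
  acceptors <- 41:120
  sys <- point_system(xyz, names = "O", box = box)
  got <- detect_hbonds(get_frame(sys), donors, acceptors)
  want <- oracle_hbonds(xyz, donors, acceptors, box = box)
  got_keys <- sort(paste(got$donor, got$acceptor))
  want_keys <- if (nrow(want) > 0) sort(paste(want[, 1], want[, 2])) else
    character(0)
  expect_gt(length(got_keys), 0)  # the random frame does contain bonds
  expect_identical(got_keys, want_keys)
})

test_that("hydrogen-bond occupancy reproduces a constructed truth", {
  set.seed(17)
  bonded <- sort(sample(500, 419))
  sys <- make_hbond_pair_system(bonded, 500)
  occ <- hbond_occupancy(sys, 16L, 20L, "mainchain", "sidechain")
  expect_equal(occ$occupancy, 0.838)
  expect_identical(which(occ$present), bonded)
  # per-block fractions: 100 frames in 100 blocks are 0/1 and conserve the
  # overall mean
  sys100 <- make_hbond_pair_system(1:58, 100)
  occ100 <- hbond_occupancy(sys100, 16L, 20L, "mainchain", "sidechain",
                            n_blocks = 100)
  expect_true(all(occ100$blocks %in% c(0, 1)))
  expect_equal(mean(occ100$blocks), occ100$occupancy)
  expect_equal(occ100$occupancy, 0.58)
  # occupancy is invariant under frame reordering
  perm <- sample(500)
  sys_perm <- set_frames(sys, sys$frames[perm])
  occ_perm <- hbond_occupancy(sys_perm, 16L, 20L, "mainchain", "sidechain")
  expect_equal(occ_perm$occupancy, occ$occupancy)
  # unresolvable pair errors
  expect_error(hbond_occupancy(sys, 16L, 16L, "sidechain", "sidechain"),
               "no donor")
})

test_that("contact maps use strict cutoffs and match the all-pairs oracle", {
  # two side-chain beads at exactly 4.5 A: not in contact; 4.4: in contact
  mk <- function(d) {
    at <- data.frame(
      name = rep(c("N", "CA", "C", "O", "SCB"), 2),
      element = rep(c("N", "C", "C", "O", "C"), 2),
      resid = rep(1:2, each = 5), resname = "LEU",
      resseq = rep(c(1L, 5L), each = 5), chain = "A", charge = NA)
    xyz <- rbind(
      c(0, 0, 0), c(1.5, 0, 0), c(2, 1, 0), c(2, 2, 0), c(1.5, -2, 0),
      c(40, 0, 0), c(41.5, 0, 0), c(42, 1, 0), c(42, 2, 0),
      c(1.5, -2 - d, 0))
    new_system(at, list(new_frame(xyz)))
  }
  expect_equal(sidechain_contact_map(mk(4.5))$occupancy, 0)
  expect_equal(sidechain_contact_map(mk(4.4))$occupancy, 1)
  # random frames against the brute-force oracle
  helix <- build_ideal_helix()
  ens <- build_kinked_ensemble(helix, 90, sigma = 1.2, n_frames = 10,
                               seed = 41)
  got <- sidechain_contact_map(ens)
  at <- ens$atoms
  sc <- memhelix:::sidechain_heavy_mask(at)
  rids <- unique(at$resid[at$resname %in% names(memhelix:::.aa_three_to_one)])
  groups <- lapply(rids, function(r) which(at$resid == r & sc))
  keep <- lengths(groups) > 0
  groups <- groups[keep]; rids <- rids[keep]
  occ <- matrix(0, length(rids), length(rids))
  for (f in seq_along(ens$frames))
    occ <- occ + oracle_contacts(ens$frames[[f]]$xyz, groups)
  occ <- occ / length(ens$frames)
  for (k in seq_len(nrow(got))) {
    i <- match(got$res_i[k], rids); j <- match(got$res_j[k], rids)
    expect_equal(got$occupancy[k], occ[i, j])
  }
})

test_that("L-shaped build with ring beads puts Phe15/Phe23 in contact", {
  # place two extra ring beads on each Phe side chain 4.0 A apart across
  # the kink
  helix <- build_ideal_helix()
  k <- build_kinked_ensemble(helix, 90)
  at <- k$atoms
  fr <- get_frame(k)
  scb15 <- which(at$resseq == 15 & at$name == "SCB")
  scb23 <- which(at$resseq == 23 & at$name == "SCB")
  mid <- (fr$xyz[scb15, ] + fr$xyz[scb23, ]) / 2
  ring <- rbind(mid + c(2, 0, 0), mid - c(2, 0, 0))
  at2 <- rbind(at,
               data.frame(name = "SCR", element = "C", resid = at$resid[scb15],
                          resname = "PHE", resseq = 15L, chain = "A",
                          charge = NA),
               data.frame(name = "SCR", element = "C", resid = at$resid[scb23],
                          resname = "PHE", resseq = 23L, chain = "A",
                          charge = NA))
  # keep atoms grouped by residue
  ord <- order(at2$resid)
  sys <- new_system(at2[ord, ], list(new_frame(rbind(fr$xyz, ring)[ord, ])))
  cm <- sidechain_contact_map(sys)
  expect_equal(cm$occupancy[cm$res_i == 15 & cm$res_j == 23], 1)
})

test_that("headgroup contacts count distinct lipids and grow with cutoff", {
  bl <- build_slab_bilayer(slab_bilayer_spec(counts = c(DOPC = 24, DOPS = 8),
                                             jitter = 0, seed = 3))
  pep <- build_ideal_helix(sequence = "KCNTATCAT", span = c(2, 9))
  emb <- embed_peptide(bl, pep, embed_spec(depth = 4, buried = c(6L),
                                           exposed = c(5L), span = c(2L, 9L)))
  hg <- select_atoms(emb, "headgroup-heavy")
  pp <- select_atoms(emb, "protein and heavy")
  n1 <- headgroup_contacts(emb, hg, pp, cutoff = 4.5, n_blocks = 1)
  n2 <- headgroup_contacts(emb, hg, pp, cutoff = 9.0, n_blocks = 1)
  expect_gte(n2$counts[1], n1$counts[1])
  far <- headgroup_contacts(emb, hg, pp, cutoff = 0.1, n_blocks = 1)
  expect_equal(far$counts[1], 0)
})

test_that("block averages conserve the mean and handle edge cases", {
  ramp <- 0:99
  ba <- block_average(ramp, 10)
  expect_equal(as.numeric(ba), seq(4.5, 94.5, by = 10))
  expect_equal(sum(ba * attr(ba, "sizes")) / sum(attr(ba, "sizes")),
               mean(ramp), tolerance = 1e-12)
  expect_equal(as.numeric(block_average(rep(3.3, 17), 5)), rep(3.3, 5))
  expect_equal(as.numeric(block_average(1:7, 7)), as.numeric(1:7))
  set.seed(3)
  x <- rnorm(103)
  ba2 <- block_average(x, 10)
  expect_equal(sum(ba2 * attr(ba2, "sizes")) / sum(attr(ba2, "sizes")),
               mean(x), tolerance = 1e-12)
  expect_error(block_average(numeric(0), 10), "empty")
  expect_error(block_average(1:10, 0), "n_blocks")
})

test_that("cutoff criteria are invariant to a box-vector shift", {
  set.seed(23)
  box <- c(20, 20, 20)
  xyz <- cbind(runif(40, 0, 20), runif(40, 0, 20), runif(40, 0, 20))
  donors <- lapply(1:10, function(i)
    list(d = i, h = NA_integer_, h_xyz = xyz[i, ] + c(1, 0, 0)))
  sys <- point_system(xyz, names = "O", box = box)
  base <- detect_hbonds(get_frame(sys), donors, 11:40)
  shifted_xyz <- sweep(xyz, 2, box, "+")
  donors_s <- lapply(1:10, function(i)
    list(d = i, h = NA_integer_, h_xyz = shifted_xyz[i, ] + c(1, 0, 0)))
  sys_s <- point_system(shifted_xyz, names = "O", box = box)
  shifted <- detect_hbonds(get_frame(sys_s), donors_s, 11:40)
  expect_equal(base[c("donor", "acceptor")], shifted[c("donor", "acceptor")])
})
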