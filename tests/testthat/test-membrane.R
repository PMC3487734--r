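test_that("leaflet assignment splits a slab and survives xy translation", {
  bl <- build_slab_bilayer(slab_bilayer_spec(counts = c(DOPC = 24, DOPS = 8),
                                             seed = 4))
  p <- select_atoms(bl, "phosphorus")
  la <- assign_leaflets(bl, p)
  expect_equal(sum(la$leaflet == "upper"), 16L)
  expect_equal(sum(la$leaflet == "lower"), 16L)
  zu <- get_frame(bl)$xyz[la$p_index[la$leaflet == "upper"], 3]
  zl <- get_frame(bl)$xyz[la$p_index[la$leaflet == "lower"], 3]
  expect_true(min(zu) > max(zl))
  shifted <- bl
  fr <- get_frame(shifted)
  fr$xyz[, 1] <- fr$xyz[, 1] + 7.3
  shifted$frames[[1]] <- fr
  expect_equal(assign_leaflets(shifted, p)$leaflet, la$leaflet)
  # degenerate: all P at one z
  flat <- bl
  fr2 <- get_frame(flat)
  fr2$xyz[as.integer(p), 3] <- 40
  flat$frames[[1]] <- fr2
  expect_warning(la2 <- assign_leaflets(flat, p), "one z")
  expect_equal(unique(la2$leaflet), "upper")
})

test_that("lattice area per lipid equals spacing^2 with exact conservation", {
  bl <- build_slab_bilayer(slab_bilayer_spec(counts = c(DOPC = 96, DOPS = 32),
                                             area_per_lipid = 64, jitter = 0,
                                             seed = 6))
  p <- select_atoms(bl, "phosphorus")
  # grid commensurate with the 8 x 8 lattice so cell ownership is exact
  apl <- area_per_lipid(bl, p, grid_n = 96)
  expect_true(all(abs(apl$per_lipid$area - 64) < 1e-6))
  expect_equal(apl$species$mean_area, c(64, 64), tolerance = 1e-9)
  box <- get_frame(bl)$box
  for (lf in c("upper", "lower")) {
    tot <- sum(apl$per_lipid$area[apl$per_lipid$leaflet == lf])
    expect_equal(tot, box[1] * box[2], tolerance = 1e-9)
  }
  # no species bias for identically placed species (jittered lattice)
  blj <- build_slab_bilayer(slab_bilayer_spec(counts = c(DOPC = 96,
                                                         DOPS = 32),
                                              jitter = 1.0, seed = 8))
  aj <- area_per_lipid(blj, select_atoms(blj, "phosphorus"), grid_n = 60)
  spread <- stats::sd(aj$per_lipid$area)
  expect_lt(abs(diff(aj$species$mean_area)), spread)
  expect_error(area_per_lipid(bl, p, grid_n = 4), "at least 8")
})

test_that("protein-aware partition conserves the box area", {
  bl <- build_slab_bilayer(slab_bilayer_spec(counts = c(DOPC = 24, DOPS = 8),
                                             seed = 5))
  pep <- build_ideal_helix()
  emb <- embed_peptide(bl, pep)
  p <- select_atoms(emb, "phosphorus")
  prot <- select_atoms(emb, "protein")
  apl <- area_per_lipid(emb, p, grid_n = 80, protein = prot)
  box <- get_frame(emb)$box
  upper <- apl$per_lipid$leaflet == "upper"
  expect_gt(apl$protein_area, 0)
  expect_equal(sum(apl$per_lipid$area[upper]) + apl$protein_area,
               box[1] * box[2], tolerance = 1e-9)
})

test_that("bilayer thickness equals the built plane separation", {
  for (sep in c(34, 38)) {
    bl <- build_slab_bilayer(slab_bilayer_spec(counts = c(DOPC = 24,
                                                          DOPS = 8),
                                               p_separation = sep, seed = 7))
    p <- select_atoms(bl, "phosphorus")
    th <- bilayer_thickness(bl, p, grid_n = 20)
    expect_equal(th$mean, sep, tolerance = 1e-9)
  }
  # xy jitter of P positions leaves the mean thickness unchanged
  bl <- build_slab_bilayer(slab_bilayer_spec(counts = c(DOPC = 24, DOPS = 8),
                                             jitter = 0, seed = 7))
  p <- select_atoms(bl, "phosphorus")
  t0 <- bilayer_thickness(bl, p, grid_n = 16)$mean
  fr <- get_frame(bl)
  set.seed(10)
  fr$xyz[as.integer(p), 1:2] <- fr$xyz[as.integer(p), 1:2] +
    matrix(rnorm(2 * length(p), sd = 0.8), ncol = 2)
  jit <- set_frames(bl, list(fr))
  expect_equal(bilayer_thickness(jit, p, grid_n = 16)$mean, t0,
               tolerance = 1e-9)
  # tilted-but-parallel planes: separation along z is preserved
  fr2 <- get_frame(bl)
  slope <- 0.08
  zoff <- slope * fr2$xyz[as.integer(p), 1]
  fr2$xyz[as.integer(p), 3] <- fr2$xyz[as.integer(p), 3] + zoff
  tilted <- set_frames(bl, list(fr2))
  expect_equal(bilayer_thickness(tilted, p, grid_n = 64)$mean, 38,
               tolerance = 0.05)
})

test_that("order parameters: aligned, tilted, magic-angle and isotropic chains", {
  chains <- list(DOPC = paste0("C", 1:8), DOPS = paste0("C", 1:8))
  bl0 <- build_slab_bilayer(slab_bilayer_spec(counts = c(DOPC = 24, DOPS = 8),
                                              chain_tilt = 0, seed = 1))
  expect_equal(order_parameters(bl0, chains)$grand_mean, 0.5)
  # rigid straight chains tilted by tau: S_cd = (3 cos^2 tau - 1) / 4
  for (tau in c(30, 54.7356, 90)) {
    bl <- build_slab_bilayer(slab_bilayer_spec(counts = c(DOPC = 24,
                                                          DOPS = 8),
                                               chain_tilt = tau, seed = 2))
    expect_equal(order_parameters(bl, chains)$grand_mean,
                 (3 * cos(tau * pi / 180)^2 - 1) / 4, tolerance = 1e-9)
  }
  # isotropically oriented rigid chains average to zero
  set.seed(19)
  n <- 1e4
  u <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  dirs <- cbind(sqrt(1 - u^2) * cos(phi), sqrt(1 - u^2) * sin(phi), u)
  xyz <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(c(0, 0, 0), dirs[i, ] * 1.5, dirs[i, ] * 3)))
  at <- data.frame(name = rep(c("C1", "C2", "C3"), n), element = "C",
                   resid = rep(seq_len(n), each = 3), resname = "DOPC",
                   resseq = rep(seq_len(n), each = 3), chain = "L", charge = 0)
  iso <- new_system(at, list(new_frame(xyz)))
  s_iso <- order_parameters(iso, list(DOPC = c("C1", "C2", "C3")))$grand_mean
  expect_lt(abs(s_iso), 0.02)
})

test_that("order parameters match brute-force hydrogen reconstruction", {
  # zigzag (all-trans-like) chains in random orientations: the local-frame
  # formula must agree with explicitly rebuilding both H positions and
  # averaging -(3 cos^2 theta_CH - 1) / 2 over them
  set.seed(27)
  for (rep in 1:10) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 360))
    nC <- 6
    base <- t(vapply(seq_len(nC), function(i)
      c(0.5 * (i %% 2), 0, 1.25 * i), numeric(3)))
    xyz <- base %*% t(R)
    at <- data.frame(name = paste0("C", seq_len(nC)), element = "C",
                     resid = 1L, resname = "DOPC", resseq = 1L,
                     chain = "L", charge = 0)
    sys <- new_system(at, list(new_frame(xyz)))
    got <- order_parameters(sys, list(DOPC = paste0("C", seq_len(nC))))
    # brute force: tetrahedral H on each interior carbon
    want <- numeric(0)
    for (i in 2:(nC - 1)) {
      zv <- xyz[i + 1, ] - xyz[i - 1, ]; zv <- zv / sqrt(sum(zv^2))
      bis <- (xyz[i - 1, ] - xyz[i, ]) + (xyz[i + 1, ] - xyz[i, ])
      bis <- bis / sqrt(sum(bis^2))
      oop <- cross3(xyz[i - 1, ] - xyz[i, ], xyz[i + 1, ] - xyz[i, ])
      oop <- oop / sqrt(sum(oop^2))
      half <- 109.47122 / 2 * pi / 180
      h1 <- cos(half) * bis + sin(half) * oop
      h2 <- cos(half) * bis - sin(half) * oop
      s_ch <- mean(c((3 * h1[3]^2 - 1) / 2, (3 * h2[3]^2 - 1) / 2))
      want <- c(want, -s_ch)
    }
    expect_equal(got$grand_mean, mean(want), tolerance = 1e-6)
  }
})

test_that("RDF of an ideal gas is flat and integrates to the sphere volume", {
  set.seed(44)
  n <- 5000
  nref <- 200
  box <- c(36, 36, 36)
  at <- data.frame(
    name = c(rep("P", nref), rep("OW", n)),
    element = c(rep("P", nref), rep("O", n)),
    resid = seq_len(n + nref),
    resname = c(rep("DOPC", nref), rep("SOL", n)),
    resseq = seq_len(n + nref), chain = "X", charge = 0)
  frames <- lapply(1:10, function(f)
    new_frame(cbind(runif(n + nref, 0, 36), runif(n + nref, 0, 36),
                    runif(n + nref, 0, 36)), box = box))
  sys <- new_system(at, frames)
  r <- rdf(sys, select_atoms(sys, "phosphorus"),
           select_atoms(sys, "water-oxygen"), dr = 0.5)
  flat <- r$g[r$r > 2]
  expect_true(all(abs(flat - 1) < 0.05))
  rho <- n / prod(box)
  expect_equal(coordination_number(r, 3), 4 / 3 * pi * 27 * rho,
               tolerance = 0.05)
  # monotone in the cutoff
  expect_true(all(diff(vapply(c(2, 3, 4, 5), coordination_number,
                              numeric(1), rdf_result = r)) >= 0))
})

test_that("RDF resolves isolated pairs and lattice shells", {
  sys <- point_system(rbind(c(5, 5, 5), c(5, 5, 11.5)),
                      names = c("P", "OW"), resnames = c("DOPC", "SOL"),
                      box = c(30, 30, 30))
  r <- rdf(sys, as_selection(1L), as_selection(2L), dr = 0.1)
  hot <- which(r$g > 0)
  expect_equal(length(hot), 1L)
  expect_equal(r$r[hot], 6.45, tolerance = 0.1)
  # g(r) invariant to a box-vector translation of all targets
  sys2 <- point_system(rbind(c(5, 5, 5), c(5, 5, 11.5) + c(30, 0, 0)),
                       names = c("P", "OW"), resnames = c("DOPC", "SOL"),
                       box = c(30, 30, 30))
  r2 <- rdf(sys2, as_selection(1L), as_selection(2L), dr = 0.1)
  expect_equal(r2$g, r$g)
  # simple cubic lattice: first peak exactly at the lattice constant
  a <- 5
  pts <- as.matrix(expand.grid(x = (0:5) * a + 2.5, y = (0:5) * a + 2.5,
                               z = (0:5) * a + 2.5))
  lat <- point_system(pts, names = "OW", resnames = "SOL", box = c(30, 30, 30))
  rl <- rdf(lat, as_selection(seq_len(nrow(pts))),
            as_selection(seq_len(nrow(pts))), dr = 0.2)
  occupied <- rl$r[rl$g > 0]
  expect_equal(min(occupied), a, tolerance = 0.2)
  shells <- a * sqrt(c(1, 2, 3, 4))
  for (s in shells[shells < 15])
    expect_true(any(abs(occupied - s) < 0.21))
})
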