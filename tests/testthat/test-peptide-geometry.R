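test_that("backbone dihedrals recover the builder torsions and flip chirality", {
  helix <- build_ideal_helix(span = c(1, 25))
  dh <- backbone_dihedrals(helix)
  interior <- 3:23
  expect_true(all(abs(dh$phi[interior, 1] + 57) < 0.5))
  expect_true(all(abs(dh$psi[interior, 1] + 47) < 0.5))
  expect_true(is.na(dh$phi[1, 1]))    # no preceding carbonyl
  expect_true(is.na(dh$psi[25, 1]))   # no following amide
  # mirror image negates every defined dihedral
  mirror <- helix
  fr <- get_frame(mirror)
  fr$xyz[, 1] <- -fr$xyz[, 1]
  mirror$frames[[1]] <- fr
  dm <- backbone_dihedrals(mirror)
  ok <- !is.na(dh$phi[, 1])
  expect_equal(dm$phi[ok, 1], -dh$phi[ok, 1], tolerance = 1e-9)
  ok <- !is.na(dh$psi[, 1])
  expect_equal(dm$psi[ok, 1], -dh$psi[ok, 1], tolerance = 1e-9)
})

test_that("degenerate collinear backbone yields NA dihedrals", {
  expect_true(is.na(torsion_angle(c(0, 0, 0), c(1, 0, 0),
                                  c(2, 0, 0), c(3, 0, 0))))
})

test_that("secondary structure: full ideal helix is H, strand has no helix", {
  helix <- build_ideal_helix(span = c(1, 25))
  ss <- assign_secondary_structure(helix)
  expect_true(all(ss[5:22, 1] == "H"))
  expect_false(ss[1, 1] %in% c("H", "G", "I"))
  expect_false(ss[25, 1] %in% c("H", "G", "I"))
  strand <- build_ideal_helix(phi = -120, psi = 120, span = c(1, 25))
  ss_e <- assign_secondary_structure(strand)
  expect_false(any(ss_e %in% c("H", "G", "I")))
  empty <- set_frames(helix, list())
  ss0 <- assign_secondary_structure(empty)
  expect_equal(ncol(ss0), 0L)
})

test_that("secondary structure matches the brute-force Kabsch-Sander oracle", {
  helix <- build_ideal_helix()
  set.seed(31)
  for (rep in 1:20) {
    fr <- get_frame(helix)
    fr$xyz <- fr$xyz + matrix(rnorm(length(fr$xyz), sd = 0.25), ncol = 3)
    noisy <- set_frames(helix, list(fr))
    expect_equal(as.vector(assign_secondary_structure(noisy)[, 1]),
                 oracle_kabsch_sander(noisy))
  }
})

test_that("helicity counts helical-code fractions and aggregates replicas", {
  codes <- matrix(rep(c("H", "C"), 50), nrow = 1)
  rownames(codes) <- "10"
  class(codes) <- "mh_ss"
  expect_equal(helicity(codes)$helicity, 0.5)
  all_h <- matrix("H", 2, 10, dimnames = list(c("1", "2"), NULL))
  class(all_h) <- "mh_ss"
  expect_equal(helicity(all_h)$helicity, c(1, 1))
  # noisy ideal-helix ensemble keeps interior helicity high
  helix <- build_ideal_helix()
  ens <- build_kinked_ensemble(helix, 0, sigma = 0.15, n_frames = 200,
                               seed = 77)
  prof <- helicity(assign_secondary_structure(ens))
  interior <- prof$resseq >= 8 & prof$resseq <= 20
  expect_true(all(prof$helicity[interior] >= 0.9))
  expect_true(all(prof$helicity >= 0 & prof$helicity <= 1))
  # replicate aggregation
  reps <- lapply(c(5, 6), function(s)
    assign_secondary_structure(build_kinked_ensemble(helix, 0, sigma = 0.15,
                                                     n_frames = 20, seed = s)))
  agg <- helicity(reps)
  expect_equal(agg$n_replicas[1], 2L)
  expect_true(all(agg$sd >= 0, na.rm = TRUE))
})

test_that("interhelical angle: baseline, kink recovery, rigid-motion invariance", {
  helix <- build_ideal_helix()
  base <- as.numeric(interhelical_angle(helix))
  # an unkinked canonical helix subtends ~24 deg between the i->i+4 chords
  expect_lt(abs(base - 24), 4)
  expect_equal(as.numeric(interhelical_angle(helix, c(13, 17), c(13, 17))),
               0, tolerance = 1e-9)
  for (target in c(40, 90, 150)) {
    k <- build_kinked_ensemble(helix, target)
    expect_equal(as.numeric(interhelical_angle(k)), target, tolerance = 0.2)
  }
  # invariance under random rigid motions
  k <- build_kinked_ensemble(helix, 90)
  a0 <- as.numeric(interhelical_angle(k))
  set.seed(12)
  for (i in 1:5) {
    fr <- get_frame(k)
    fr$xyz <- rotate_about(fr$xyz, rnorm(3), runif(1, 0, 360)) +
      matrix(rep(rnorm(3, sd = 20), each = nrow(fr$xyz)), ncol = 3)
    moved <- set_frames(k, list(fr))
    expect_equal(as.numeric(interhelical_angle(moved)), a0,
                 tolerance = 1e-9)
  }
})

test_that("angle distributions are normalised with correct midpoints", {
  d <- angle_distribution(rep(42, 10))
  expect_equal(sum(d$frequency), 1, tolerance = 1e-9)
  expect_equal(d$midpoint[d$frequency == 1], 45)
  expect_equal(d$midpoint, seq(5, 175, by = 10))
  set.seed(4)
  d2 <- angle_distribution(runif(500, 0, 180))
  expect_equal(sum(d2$frequency), 1, tolerance = 1e-9)
  # modal-bin recovery for noisy kinked ensembles
  helix <- build_ideal_helix()
  for (target in c(40, 90)) {
    ens <- build_kinked_ensemble(helix, target, sigma = 0.3, n_frames = 200,
                                 seed = 21)
    d3 <- angle_distribution(interhelical_angle(ens))
    modal <- d3$midpoint[which.max(d3$frequency)]
    expect_lte(abs(modal - (target + 5)), 10)
  }
})

test_that("family classification splits at the boundary and recovers mixtures", {
  expect_equal(unname(classify_families(rep(20, 10))$fractions["compact"]), 1)
  two <- classify_families(c(50, 70), boundary = 60)
  expect_equal(unname(two$fractions), c(0.5, 0.5))
  expect_equal(classify_families(c(60), boundary = 60)$family, "L-shaped")
  helix <- build_ideal_helix()
  a40 <- interhelical_angle(build_kinked_ensemble(helix, 40, sigma = 0.3,
                                                  n_frames = 350, seed = 8))
  a90 <- interhelical_angle(build_kinked_ensemble(helix, 90, sigma = 0.3,
                                                  n_frames = 150, seed = 9))
  fam <- classify_families(c(a40, a90), boundary = 60)
  expect_equal(unname(fam$fractions["compact"]), 0.7, tolerance = 0.05)
  expect_equal(unname(fam$fractions["L-shaped"]), 0.3, tolerance = 0.05)
})

test_that("immersion depth obeys the buried-positive sign convention", {
  # upper leaflet at z = 59, lower at 21 (default slab)
  bl <- build_slab_bilayer(slab_bilayer_spec(counts = c(DOPC = 24, DOPS = 8),
                                             jitter = 0, seed = 2))
  p <- select_atoms(bl, "phosphorus")
  fr <- get_frame(bl)
  zup <- max(fr$xyz[as.integer(p), 3])
  probe_at <- function(z) {
    at <- bl$atoms
    at <- rbind(at, data.frame(name = "CA", element = "C",
                               resid = max(at$resid) + 1L, resname = "GLY",
                               resseq = 99000L, chain = "A", charge = NA))
    new_system(at, list(new_frame(rbind(fr$xyz, c(5, 5, z)), box = fr$box)))
  }
  probe <- probe_at(zup - 7)
  sel <- select_atoms(probe, "resid 99000")
  expect_equal(immersion_depth(probe, select_atoms(probe, "phosphorus"),
                               "upper", selection = sel), 7)
  expect_equal(immersion_depth(probe_at(zup), select_atoms(probe, "phosphorus"),
                               "upper",
                               selection = sel), 0)
  expect_equal(immersion_depth(probe_at(zup + 3),
                               select_atoms(probe, "phosphorus"), "upper",
                               selection = sel), -3)
  # moving atoms deeper by dz increases depth by exactly dz
  d1 <- immersion_depth(probe_at(zup - 2), select_atoms(probe, "phosphorus"),
                        "upper", selection = sel)
  d2 <- immersion_depth(probe_at(zup - 6.5), select_atoms(probe, "phosphorus"),
                        "upper", selection = sel)
  expect_equal(d2 - d1, 4.5, tolerance = 1e-12)
})

test_that("helix axis fitting recovers orientation and kink geometry", {
  helix <- build_ideal_helix()
  fr <- get_frame(helix)
  ca <- vapply(5:25, function(r)
    atom_in_residue(helix, resid_of_resseq(helix, r), "CA"), integer(1))
  ax <- fit_helix_axis(fr, as_selection(ca))
  expect_lt(vec_angle(ax$axis, c(1, 0, 0)), 2)
  rev_ax <- fit_helix_axis(fr, as_selection(rev(ca)))
  expect_lt(vec_angle(rev_ax$axis, ax$axis), 2)  # orientation rule fixes sign
  expect_error(fit_helix_axis(fr, as_selection(ca[1:3])), "at least 4")
  # kink build: angle between pre- and post-hinge fitted axes
  k <- build_kinked_ensemble(helix, 90)
  kfr <- get_frame(k)
  pre <- vapply(7:17, function(r)
    atom_in_residue(k, resid_of_resseq(k, r), "CA"), integer(1))
  post <- vapply(19:25, function(r)
    atom_in_residue(k, resid_of_resseq(k, r), "CA"), integer(1))
  ax1 <- fit_helix_axis(kfr, as_selection(pre))
  ax2 <- fit_helix_axis(kfr, as_selection(post))
  expect_equal(vec_angle(ax1$axis, ax2$axis), 90, tolerance = 8)
})

test_that("Kabsch superposition is exact, bounded and matches bio3d", {
  helix <- build_ideal_helix()
  X <- get_frame(helix)$xyz[1:40, ]
  R0 <- rotation_matrix(c(1, 2, 3), 71)
  Y <- X %*% t(R0) + matrix(rep(c(4, -2, 9), each = 40), ncol = 3)
  fit <- superpose_rmsd(X, Y)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(fit$rotation %*% t(fit$rotation), diag(3), tolerance = 1e-9)
  idfit <- superpose_rmsd(X, X)
  expect_equal(idfit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(idfit$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(idfit$rmsd, 1e-12)
  # superposed RMSD never exceeds the unsuperposed RMSD; pre-rotation
  # invariance
  set.seed(99)
  A <- matrix(rnorm(33), ncol = 3)
  B <- A + matrix(rnorm(33, sd = 0.4), ncol = 3)
  fit2 <- superpose_rmsd(A, B)
  expect_lte(fit2$rmsd, sqrt(mean(rowSums((A - B)^2))) + 1e-12)
  A2 <- A %*% t(rotation_matrix(c(0, 1, 1), 33))
  expect_equal(superpose_rmsd(A2, B)$rmsd, fit2$rmsd, tolerance = 1e-9)
  # independent route: bio3d's least-squares fit gives the same RMSD
  b3d <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(B)), mobile = as.vector(t(A))))
  rms_b3d <- sqrt(mean(colSums(matrix((b3d - as.vector(t(B)))^2, nrow = 3))))
  expect_equal(fit2$rmsd, rms_b3d, tolerance = 1e-6)
})

test_that("single displaced atom gives the closed-form RMSD", {
  # 11 pairs, one atom displaced by 1 A: RMSD -> 1/sqrt(11) when the
  # displacement survives the optimal fit; verify against a brute-force
  # rotation grid rather than assuming it
  helix <- build_ideal_helix()
  ca <- vapply(5:15, function(r)
    atom_in_residue(helix, resid_of_resseq(helix, r), "CA"), integer(1))
  X <- get_frame(helix)$xyz[ca, ]
  Y <- X
  Y[6, ] <- Y[6, ] + c(1, 0, 0)
  fit <- superpose_rmsd(X, Y)
  # the optimal fit can only shave a little off the naive d/sqrt(n) residual
  expect_lte(fit$rmsd, 1 / sqrt(11) + 1e-9)
  expect_gte(fit$rmsd, 0.9 / sqrt(11))
  # independent route: direct numerical minimisation over rotations
  obj <- function(par) {
    R <- rotation_matrix(c(sin(par[1]) * cos(par[2]),
                           sin(par[1]) * sin(par[2]), cos(par[1])), par[3])
    Xr <- sweep(X, 2, colMeans(X)) %*% t(R)
    sqrt(mean(rowSums((Xr - sweep(Y, 2, colMeans(Y)))^2)))
  }
  best <- Inf
  set.seed(5)
  for (i in 1:20) {
    o <- stats::optim(c(runif(1, 0, pi), runif(1, 0, 2 * pi),
                        runif(1, 0, 360)), obj)
    best <- min(best, o$value)
  }
  expect_equal(fit$rmsd, best, tolerance = 1e-5)
  expect_lte(fit$rmsd, best + 1e-9)
})

test_that("dihedral fluctuation: constant, uniform and wrapped-normal cases", {
  mk <- function(values) {
    m <- matrix(values, nrow = 1)
    rownames(m) <- "18"
    structure(list(phi = m, psi = m, resseq = 18L), class = "mh_dihedrals")
  }
  const <- dihedral_fluctuation(mk(rep(-60, 400)), 18L, n_bins = 4,
                                angle = "phi")
  expect_equal(const$circ_sd_deg, rep(0, 4))
  set.seed(14)
  unif <- dihedral_fluctuation(mk(runif(1e4, -180, 180)), 18L, n_bins = 1,
                               angle = "phi")
  expect_gt(unif$circ_sd_deg, 80)
  # wrapped normal with sd 10 deg centred near the wrap point
  wn <- ((rnorm(1e4, mean = 175, sd = 10) + 180) %% 360) - 180
  rec <- dihedral_fluctuation(mk(wn), 18L, n_bins = 1, angle = "phi")
  expect_equal(rec$circ_sd_deg, 10, tolerance = 1)
})
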