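# Constructed donor / hydrogen / acceptor geometries for the hydrogen-bond
# criteria, and occlusion fixtures for the surface-area quadrature.

test_that("donor-hydrogen pairing applies the covalent cutoff and tie rule", {
  topo <- toy_topology(c("N", "H1", "O", "H2"), c("N", "H", "O", "H"),
                       rep(0L, 4))
  fr <- aggtraj_frame(rbind(c(0, 0, 0), c(1.01, 0, 0),
                            c(10, 0, 0), c(10, 1.5, 0)),
                      c(100, 100, 100), 0)
  expect_warning(pairs <- find_donor_hydrogen_pairs(topo, fr), "ignored")
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$donor, 1L)
  expect_equal(pairs$hydrogen, 2L)

  # hydrogen exactly between two donors goes to the lower atom index
  topo2 <- toy_topology(c("N", "O", "HX"), c("N", "O", "H"), rep(0L, 3))
  fr2 <- aggtraj_frame(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0)),
                       c(100, 100, 100), 0)
  p2 <- find_donor_hydrogen_pairs(topo2, fr2)
  expect_equal(p2$donor, 1L)
})

test_that("hydrogen-bond distance and angle gates work", {
  topo <- toy_topology(c("OG", "HG", "O"), c("O", "H", "O"),
                       c(0L, 0L, 1L), residues = c(1L, 1L, 1L),
                       resnames = c("SER", "SER", "ALA"))
  mk <- function(acc) {
    aggtraj_frame(rbind(c(0, 0, 0), c(0.97, 0, 0), acc),
                  c(100, 100, 100), 0)
  }
  expect_equal(nrow(detect_hbonds(mk(c(2.8, 0, 0)), topo)), 1L)
  expect_equal(detect_hbonds(mk(c(2.8, 0, 0)), topo)$kind, "intermolecular")
  expect_equal(nrow(detect_hbonds(mk(c(3.2, 0, 0)), topo)), 0L)
  # 120 degree D-H-A angle rejected despite short distance
  h <- c(0.97, 0, 0)
  ang_at <- function(deg) {
    h + 1.6 * c(cos(deg * pi / 180) * -1, sin(deg * pi / 180), 0)
  }
  expect_equal(nrow(detect_hbonds(mk(ang_at(120)), topo)), 0L)
  # minimum-angle convention: just above the gate accepted, below rejected
  expect_equal(nrow(detect_hbonds(mk(ang_at(150.5)), topo)), 1L)
  expect_equal(nrow(detect_hbonds(mk(ang_at(149.5)), topo)), 0L)
})

test_that("bond detection is invariant under rotation and wrapping", {
  topo <- toy_topology(c("OG", "HG", "O"), c("O", "H", "O"),
                       c(0L, 0L, 1L))
  xyz <- rbind(c(0, 0, 0), c(0.97, 0, 0), c(2.8, 0, 0))
  box <- c(50, 50, 50)
  base <- nrow(detect_hbonds(aggtraj_frame(xyz + 10, box, 0), topo))
  expect_equal(base, 1L)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- xyz %*% t(R) + 25
  expect_equal(nrow(detect_hbonds(aggtraj_frame(rot, box, 0), topo)), 1L)
  # split the pair across the periodic boundary
  shifted <- xyz
  shifted[3, 1] <- shifted[3, 1] + 50 - 1.5
  shifted[1:2, 1] <- shifted[1:2, 1] + 48.5
  wrapped <- shifted %% 50
  expect_equal(nrow(detect_hbonds(aggtraj_frame(wrapped, box, 0), topo)), 1L)
})

test_that("hydrogen-bond series decomposes into inter plus intra", {
  # chain 0: donor with two acceptors (1 intra, 1 inter); chain 1: acceptor
  # plus its own donor-H bonded intramolecularly
  topo <- toy_topology(
    c("N", "H", "O", "OX", "N2", "H2", "O2"),
    c("N", "H", "O", "O", "N", "H", "O"),
    c(0L, 0L, 0L, 1L, 1L, 1L, 1L),
    residues = c(1L, 1L, 2L, 1L, 2L, 2L, 3L),
    resnames = rep("SER", 7)
  )
  xyz <- rbind(
    c(0, 0, 0), c(1.0, 0, 0),      # N-H of chain 0 pointing +x
    c(-2.8, 0, 0),                 # O on chain 0 (wrong side, no bond)
    c(2.9, 0, 0),                  # OX on chain 1: inter bond
    c(20, 0, 0), c(21, 0, 0),      # N2-H2 of chain 1
    c(22.8, 0, 0)                  # O2 on chain 1: intra bond
  )
  traj <- aggtraj_trajectory(
    topo, list(aggtraj_frame(xyz, c(100, 100, 100), 0)))
  ts <- hbond_timeseries(traj)
  expect_equal(ts$inter, 1L)
  expect_equal(ts$intra, 1L)
  expect_equal(ts$total, ts$inter + ts$intra)
})

test_that("contact map counts persistent bonds and matches series totals", {
  # persistent bond donor residue 2 (chain 0) -> acceptor residue 3
  # (chain 1) over 10 frames
  topo <- toy_topology(
    c("N", "H", "N", "O"), c("N", "H", "N", "O"),
    c(0L, 0L, 1L, 1L),
    residues = c(2L, 2L, 1L, 3L), resnames = rep("GLY", 4)
  )
  # chains must share one sequence of 3 residues for the map
  topo$sequences <- c("GGG", "GGG")
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(40, 40, 40), c(2.9, 0, 0))
  frames <- lapply(0:9, function(t) {
    aggtraj_frame(xyz, c(100, 100, 100), t * 100)
  })
  traj <- aggtraj_trajectory(topo, frames)
  ts <- hbond_timeseries(traj)
  cm <- hbond_contact_map(traj, "intermolecular", bonds = attr(ts, "bonds"))
  expect_equal(cm["GLY2", "GLY3"], 10)
  expect_equal(sum(cm), sum(ts$inter))
})

test_that("Shrake-Rupley areas are exact for isolated atoms and additive", {
  atoms <- data.frame(name = "C", element = "C", vdw_radius = 1.70,
                      mass = 12.011, residue_index = 1L,
                      residue_name = "ALA", chain_index = 0L)
  topo1 <- aggtraj_topology(atoms, "A")
  fr1 <- aggtraj_frame(matrix(c(0, 0, 0), 1), c(300, 300, 300), 0)
  s1 <- shrake_rupley_sasa(fr1, topo1)
  expect_equal(s1$area, 4 * pi * 3.10^2, tolerance = 0.005)

  topo2 <- toy_topology(c("C1", "C2"), c("C", "C"), c(0L, 1L))
  fr2 <- aggtraj_frame(rbind(c(0, 0, 0), c(100, 0, 0)),
                       c(300, 300, 300), 0)
  s2 <- shrake_rupley_sasa(fr2, topo2)
  expect_equal(sum(s2$area), 2 * s1$area, tolerance = 1e-9)

  # atom fully enclosed by a cage of occluders has zero area
  shell <- aggtraj:::golden_spiral_points(60) * 2.0
  names_all <- c("C0", sprintf("S%d", 1:60))
  topo3 <- toy_topology(names_all, c("C", rep("S", 60)), rep(0L, 61))
  fr3 <- aggtraj_frame(rbind(c(0, 0, 0), shell), c(300, 300, 300), 0)
  s3 <- shrake_rupley_sasa(fr3, topo3)
  expect_equal(s3$area[1], 0)
  expect_error(shrake_rupley_sasa(fr1, topo1, n_points = 8), "16")
})

test_that("SASA decomposition partitions the total exactly", {
  bb <- build_backbone("AAAA", -57, -47)
  atoms <- bb$atoms
  atoms$chain_index <- 0L
  topo <- aggtraj_topology(atoms, "AAAA")
  fr <- aggtraj_frame(bb$xyz, c(300, 300, 300), 0)
  s <- shrake_rupley_sasa(fr, topo)
  dec <- sasa_decomposition(s, topo)
  expect_equal(dec$hydrophobic, dec$total)  # all-Ala is all hydrophobic
  expect_equal(dec$non_hydrophobic, 0)

  mixed <- build_backbone("ADAD", -57, -47)
  atoms_m <- mixed$atoms
  atoms_m$chain_index <- 0L
  topo_m <- aggtraj_topology(atoms_m, "ADAD")
  s_m <- shrake_rupley_sasa(aggtraj_frame(mixed$xyz, c(300, 300, 300), 0),
                            topo_m)
  dec_m <- sasa_decomposition(s_m, topo_m)
  expect_equal(dec_m$hydrophobic + dec_m$non_hydrophobic, dec_m$total,
               tolerance = 1e-12)
  expect_gt(dec_m$non_hydrophobic, 0)
})

test_that("SASA decreases monotonically as two chains approach", {
  bb <- build_backbone("AAAA", -57, -47)
  n1 <- nrow(bb$xyz)
  atoms2 <- rbind(bb$atoms, bb$atoms)
  atoms2$chain_index <- rep(c(0L, 1L), each = n1)
  topo <- aggtraj_topology(atoms2, c("AAAA", "AAAA"))
  seps <- seq(30, 3, length.out = 10)
  areas <- vapply(seps, function(d) {
    xyz <- rbind(bb$xyz, sweep(bb$xyz, 2, c(d, 0, 0), "+"))
    shrake_rupley_sasa(aggtraj_frame(xyz, c(300, 300, 300), 0),
                       topo, n_points = 480)$total_nm2
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("hydrophobic atom fraction of the study peptides is plausible", {
  # backbone-only topology; the printed ~55 percent refers to all-atom
  # topologies, so this is a range check, not an equality
  seq33 <- blg_peptide("1-33")
  bb <- build_backbone(seq33, -139, 135)
  atoms <- bb$atoms
  atoms$chain_index <- 0L
  topo <- aggtraj_topology(atoms, seq33)
  f <- hydrophobic_atom_fraction(topo)
  expect_gt(f, 0.3)
  expect_lt(f, 0.8)
})
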