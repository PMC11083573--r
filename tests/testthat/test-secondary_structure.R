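test_that("amide hydrogen reconstruction follows the trans-amide convention", {
  bb <- build_backbone("AAAA", -57, -47)
  # strip the hydrogens the builder placed
  keep <- bb$atoms$name != "H"
  atoms <- bb$atoms[keep, ]
  atoms$chain_index <- 0L
  topo <- aggtraj_topology(atoms)
  fr <- aggtraj_frame(bb$xyz[keep, ], c(500, 500, 500), 0)
  rec <- reconstruct_amide_hydrogens(fr, topo)
  expect_equal(nrow(rec), 3L)  # residues 2..4
  for (r in seq_len(nrow(rec))) {
    iN <- which(atoms$residue_index == rec$residue[r] & atoms$name == "N")
    dist <- sqrt(sum((c(rec$x[r], rec$y[r], rec$z[r]) - fr$xyz[iN, ])^2))
    expect_equal(dist, 1.01, tolerance = 1e-9)
  }

  # prolines get no amide hydrogen
  bbp <- build_backbone("APA", -57, -47)
  expect_false(any(bbp$atoms$name == "H" & bbp$atoms$residue_name == "PRO"))
  atomsp <- bbp$atoms[bbp$atoms$name != "H", ]
  atomsp$chain_index <- 0L
  topop <- aggtraj_topology(atomsp)
  frp <- aggtraj_frame(bbp$xyz[bbp$atoms$name != "H", ], c(500, 500, 500), 0)
  recp <- reconstruct_amide_hydrogens(frp, topop)
  expect_false(2L %in% recp$residue)

  # pre-existing hydrogens are preserved, not rebuilt
  atoms_full <- bb$atoms
  atoms_full$chain_index <- 0L
  topo_full <- aggtraj_topology(atoms_full)
  fr_full <- aggtraj_frame(bb$xyz, c(500, 500, 500), 0)
  expect_equal(nrow(reconstruct_amide_hydrogens(fr_full, topo_full)), 0L)
})

test_that("Kabsch-Sander energy has the right symmetry and limits", {
  # all four distances equal -> E = 0
  s <- 1 / sqrt(2)
  N <- c(0, 0, 0); H <- c(1, 0, 0)
  C <- c(0.5, 2, 0); O <- c(0.5, 2, 0)
  # place C and O symmetric to both N and H
  C <- c(0.5, 2, 0); O <- c(0.5, -2, 0)
  expect_equal(ks_hbond_energy(N, H, C, O), 0, tolerance = 1e-12)
  # far away -> energy about zero, no bond
  expect_lt(abs(ks_hbond_energy(N, H, c(20, 0, 0), c(21, 0, 0))), 0.5)
  expect_error(ks_hbond_energy(N, H, C, N), "coincident")

  # canonical alpha-helix i+4 -> i geometry is a bond
  bb <- build_backbone(paste(rep("A", 8), collapse = ""), -57, -47)
  atoms <- bb$atoms
  atoms$chain_index <- 0L
  topo <- aggtraj_topology(atoms)
  fr <- aggtraj_frame(bb$xyz, c(500, 500, 500), 0)
  at <- topo$atoms
  pos <- function(res, nm) fr$xyz[at$residue_index == res & at$name == nm, ]
  E <- ks_hbond_energy(pos(5, "N"), pos(5, "H"), pos(1, "C"), pos(1, "O"))
  expect_lt(E, -0.5)
})

test_that("ideal helices label H, sheets label E, lone extended chains C", {
  helix <- build_backbone(paste(rep("A", 15), collapse = ""), -57, -47)
  atoms <- helix$atoms
  atoms$chain_index <- 0L
  topo <- aggtraj_topology(atoms)
  lab <- assign_secondary_structure(
    aggtraj_frame(helix$xyz, c(500, 500, 500), 0), topo)[[1]]
  interior <- lab[3:13]
  expect_gte(mean(interior == "H"), 0.8)

  sheet <- make_sheet(2, 8, "antiparallel")
  labs <- assign_secondary_structure(sheet$frame, sheet$topology)
  for (ch in labs) {
    expect_gte(mean(ch[2:7] == "E"), 0.8)
  }

  ext <- build_backbone(paste(rep("A", 10), collapse = ""), -139, 135)
  atoms_e <- ext$atoms
  atoms_e$chain_index <- 0L
  topo_e <- aggtraj_topology(atoms_e)
  lab_e <- assign_secondary_structure(
    aggtraj_frame(ext$xyz, c(500, 500, 500), 0), topo_e)[[1]]
  expect_true(all(lab_e == "C"))

  # chains shorter than 3 residues are coil
  short <- build_backbone("AA", -57, -47)
  atoms_s <- short$atoms
  atoms_s$chain_index <- 0L
  topo_s <- aggtraj_topology(atoms_s)
  lab_s <- assign_secondary_structure(
    aggtraj_frame(short$xyz, c(500, 500, 500), 0), topo_s)[[1]]
  expect_true(all(lab_s == "C"))
})

test_that("assignment is invariant under box wrapping", {
  sheet <- make_sheet(2, 8, "antiparallel")
  ref <- assign_secondary_structure(sheet$frame, sheet$topology)
  wrapped <- sheet$frame$xyz
  for (ax in 1:3) wrapped[, ax] <- wrapped[, ax] %% sheet$frame$box[ax]
  lab_w <- assign_secondary_structure(
    aggtraj_frame(wrapped, sheet$frame$box, 0), sheet$topology)
  expect_identical(lab_w, ref)
})

test_that("largest-cluster content percentages are a partition", {
  assignments <- list(fake_assignment(list(c(0L, 1L), 2L)))
  ssm <- fake_ssmatrix(list(list(rep("H", 4), rep("H", 4), rep("E", 4))))
  cont <- ss_content_of_largest_cluster(assignments, ssm)
  expect_equal(cont$helix, 100)
  expect_equal(cont$strand + cont$coil, 0)

  ssm2 <- fake_ssmatrix(list(list(c("E", "E", "C", "C"),
                                  c("C", "C", "E", "E"),
                                  rep("C", 4))))
  cont2 <- ss_content_of_largest_cluster(assignments, ssm2)
  expect_equal(cont2$strand, 50)
  expect_equal(cont2$coil, 50)

  set.seed(3)
  for (k in 1:5) {
    labs <- list(lapply(1:3, function(i) {
      sample(c("H", "E", "C"), 6, replace = TRUE)
    }))
    ssm3 <- fake_ssmatrix(labs)
    a3 <- list(fake_assignment(list(0:2)))
    c3 <- ss_content_of_largest_cluster(a3, ssm3)
    expect_equal(c3$helix + c3$strand + c3$coil, 100)
  }
})

test_that("beta peptide fraction follows its definition", {
  a <- list(fake_assignment(list(0:3)))
  ssm <- fake_ssmatrix(list(list(c("E", "C"), c("C", "E"),
                                 c("C", "C"), c("H", "H"))))
  expect_equal(beta_peptide_fraction(a, ssm)$beta_fraction, 0.5)
  ssm0 <- fake_ssmatrix(list(list(c("C", "C"), c("C", "C"),
                                  c("C", "C"), c("H", "H"))))
  expect_equal(beta_peptide_fraction(a, ssm0)$beta_fraction, 0)
  ssmE <- fake_ssmatrix(list(lapply(1:4, function(i) c("E", "E"))))
  expect_equal(beta_peptide_fraction(a, ssmE)$beta_fraction, 1)
})

test_that("beta propensity normalizes by frames times chains", {
  # residue 1 strand in half of the (frame, chain) events
  labs <- list(
    list(c("E", "C"), c("C", "C")),
    list(c("C", "C"), c("E", "C"))
  )
  ssm <- fake_ssmatrix(labs, sequences = c("AA", "AA"))
  prop <- residue_beta_propensity(ssm)
  expect_equal(prop$propensity, c(0.5, 0))
  expect_equal(prop$resname, c("ALA1", "ALA2"))
  expect_true(all(prop$propensity >= 0 & prop$propensity <= 1))

  ssm_all <- fake_ssmatrix(list(list(c("E"), c("E"))),
                           sequences = c("A", "A"))
  expect_equal(residue_beta_propensity(ssm_all)$propensity, 1)

  ssm_bad <- fake_ssmatrix(labs, sequences = c("AA", "AC"))
  expect_error(residue_beta_propensity(ssm_bad), "one sequence")
})
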