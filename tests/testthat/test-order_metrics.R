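test_that("chain axis is the principal gyration direction", {
  # straight CA chain along x
  n <- 6L
  atoms <- data.frame(name = rep("CA", n), element = "C",
                      vdw_radius = 1.70, mass = 12.011,
                      residue_index = seq_len(n), residue_name = "ALA",
                      chain_index = 0L)
  topo <- aggtraj_topology(atoms)
  xyz <- cbind(seq(0, 20, length.out = n), 0, 0)
  ax <- chain_axis(xyz, topo, 0)
  expect_equal(abs(ax), c(1, 0, 0), tolerance = 1e-12)

  # planar L-shaped chain: axis lies in the plane and matches an
  # independent eigensolver (SVD of the centered coordinates)
  xyzL <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0), c(8, 2, 0),
                c(8, 4, 0), c(8, 6, 0))
  axL <- chain_axis(xyzL, topo, 0)
  expect_equal(axL[3], 0, tolerance = 1e-12)
  sv <- svd(scale(xyzL, scale = FALSE))
  ref <- sv$v[, 1]
  expect_equal(abs(sum(axL * ref)), 1, tolerance = 1e-9)

  # rotation equivariance
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ax_rot <- chain_axis(xyzL %*% t(R), topo, 0)
  expect_equal(abs(sum(ax_rot * (R %*% axL))), 1, tolerance = 1e-9)

  # end-to-end mode
  ax_e2e <- chain_axis(xyz, topo, 0, mode = "end_to_end")
  expect_equal(ax_e2e, c(1, 0, 0))
})

test_that("nematic order parameter has the liquid-crystal limits", {
  expect_equal(nematic_order(rbind(c(0, 0, 1), c(0, 0, 1))), 1,
               tolerance = 1e-12)
  # sign flips do not matter
  expect_equal(nematic_order(rbind(c(0, 0, 1), c(0, 0, -1))), 1,
               tolerance = 1e-12)
  expect_equal(nematic_order(diag(3)), 0, tolerance = 1e-12)
  rb <- rod_bundle(10000, 0, seed = 2024)
  expect_lt(nematic_order(rb$vectors), 0.05)
  # bounds and rotation invariance on random sets
  set.seed(8)
  for (k in 1:10) {
    v <- matrix(rnorm(30), 10, 3)
    p2 <- nematic_order(v)
    expect_gte(p2, -0.5 - 1e-12)
    expect_lte(p2, 1 + 1e-12)
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
               c(0, 0, 1))
    expect_equal(nematic_order(v %*% t(R)), p2, tolerance = 1e-9)
  }
  expect_error(nematic_order(rbind(c(0, 0, 0), c(1, 0, 0))), "zero")
  expect_error(nematic_order(rbind(c(1, 0, 0))), "at least 2")
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  expect_equal(radius_of_gyration(rbind(c(5, 5, 5))), 0)
  cube <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5),
                                c(-0.5, 0.5)))
  expect_equal(radius_of_gyration(cube), sqrt(0.75), tolerance = 1e-12)
  # mass weighting moves the center of mass
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)),
                                  masses = c(3, 1)),
               sqrt((3 * 0.5^2 + 1 * 1.5^2) / 4), tolerance = 1e-12)
  expect_error(radius_of_gyration(rbind(c(0, 0, 0)), masses = 0),
               "mass")
})

test_that("order histogram normalizes and finds planted basins", {
  rec1 <- data.frame(frame = 1:5, time = 0:4, cluster_size = 3L,
                     P2 = rep(0.4, 5), n_inter_hbonds = rep(7L, 5),
                     Rg = 10, n_contacts = 2L, hbonds_per_contact = 3.5)
  h1 <- order_hbond_histogram(rec1, 5, 5)
  expect_equal(sum(h1$counts), 1)
  expect_equal(max(h1$counts), 1)  # all records in a single cell

  rec2 <- rbind(rec1, transform(rec1, P2 = 0.9, n_inter_hbonds = 30L))
  h2 <- order_hbond_histogram(rec2, 4, 4)
  expect_equal(sort(h2$counts[h2$counts > 0]), c(0.5, 0.5))

  # planted bimodal stream: two local maxima at the planted cells
  set.seed(21)
  basin <- function(nh, p2, n) {
    data.frame(frame = seq_len(n), time = seq_len(n), cluster_size = 5L,
               P2 = p2 + runif(n, -0.02, 0.02),
               n_inter_hbonds = nh + sample(-1:1, n, replace = TRUE),
               Rg = 12, n_contacts = 4L, hbonds_per_contact = 1)
  }
  rec3 <- rbind(basin(10L, 0.2, 60), basin(40L, 0.6, 60))
  h3 <- order_hbond_histogram(rec3, 8, 8)
  expect_equal(sum(h3$counts), 1)
  expect_gte(nrow(h3$peaks), 2L)
  # the two strongest peaks sit near the planted centers
  top2 <- h3$peaks[order(-h3$peaks$mass), ][1:2, ]
  expect_equal(sort(round(top2$x_mid / 10) * 10), c(10, 40))
  expect_equal(sort(round(top2$y_mid, 1)), c(0.2, 0.6))
})

test_that("hydrogen bonds per contact follows its definition", {
  edges <- rbind(c(0L, 1L), c(1L, 2L))
  a <- fake_assignment(list(0:2, 3L), n = 4L, edges = edges)
  bonds <- data.frame(
    donor = 1:4, hydrogen = 1:4, acceptor = 1:4,
    donor_chain = c(0L, 0L, 1L, 2L), acceptor_chain = c(1L, 1L, 2L, 0L),
    donor_residue = 1L, acceptor_residue = 1L,
    kind = rep("intermolecular", 4)
  )
  expect_equal(hbonds_per_contact(a, bonds), 2.0)  # 4 bonds / 2 contacts
  none <- bonds[0, ]
  expect_equal(hbonds_per_contact(a, none), 0)

  # random fixtures against a direct recount
  set.seed(33)
  for (k in 1:10) {
    n <- 6L
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) - 1L
    edges_k <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    comps <- union_find_components(n, edges_k)
    a_k <- fake_assignment(comps, n = n, edges = edges_k)
    big <- comps[[which.max(lengths(comps))]]
    nb <- sample(0:8, 1)
    if (nb > 0) {
      dc <- sample(big, nb, replace = TRUE)
      ac <- sample(big, nb, replace = TRUE)
      keep <- dc != ac
      dc <- dc[keep]; ac <- ac[keep]
    } else dc <- ac <- integer(0)
    bonds_k <- data.frame(
      donor = seq_along(dc), hydrogen = seq_along(dc),
      acceptor = seq_along(dc), donor_chain = dc, acceptor_chain = ac,
      donor_residue = rep(1L, length(dc)),
      acceptor_residue = rep(1L, length(dc)),
      kind = rep("intermolecular", length(dc))
    )
    contacts <- sum(edges_k[, 1] %in% big & edges_k[, 2] %in% big)
    expected <- if (contacts == 0) 0 else length(dc) / contacts
    expect_equal(hbonds_per_contact(a_k, bonds_k, cluster = big),
                 expected)
  }
})

test_that("order records integrate clustering, axes and bonds", {
  sc <- aggregation_script(n_chains = 5L, box = c(120, 120, 120),
                           n_frames = 3L,
                           events = list(list(frame = 2L, type = "merge",
                                              a = 0L, b = 1L),
                                         list(frame = 3L, type = "merge",
                                              a = 0L, b = 2L)),
                           seed = 9L)
  out <- scripted_aggregation_trajectory(sc)
  rec <- order_records(out$trajectory)
  expect_equal(rec$cluster_size, c(1L, 2L, 3L))
  expect_true(is.na(rec$P2[1]))  # single chain: no order parameter
  # rigid identical copies share one axis: perfect alignment
  expect_equal(rec$P2[2], 1, tolerance = 1e-9)
  expect_equal(rec$P2[3], 1, tolerance = 1e-9)
  expect_true(all(rec$Rg > 0))
  expect_true(all(rec$n_contacts[2:3] >= c(1L, 2L)))
})
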