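# Geometric hydrogen-bond detection (donor-hydrogen pairing, D-A distance
# and D-H-A angle criteria), inter/intra decomposition and residue contact
# maps; Shrake-Rupley solvent-accessible surface area with a hydrophobicity
# decomposition.

#' Default residue hydrophobicity classification
#'
#' Partition of the 20 standard residues into hydrophobic
#' (A, V, L, I, P, F, M, W), neutral (G, S, T, C, Y, N, Q) and hydrophilic
#' (D, E, K, R, H) classes; neutral and hydrophilic together form the
#' "non-hydrophobic" group of the SASA decomposition.
#'
#' @return Named character vector: one-letter code -> class.
#' @export
default_residue_classes <- function() {
  cls <- c(A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
           I = "hydrophobic", P = "hydrophobic", F = "hydrophobic",
           M = "hydrophobic", W = "hydrophobic",
           G = "neutral", S = "neutral", T = "neutral", C = "neutral",
           Y = "neutral", N = "neutral", Q = "neutral",
           D = "hydrophilic", E = "hydrophilic", K = "hydrophilic",
           R = "hydrophilic", H = "hydrophilic")
  cls[sort(names(cls))]
}

# --- hydrogen bonds -------------------------------------------------------

#' Pair hydrogens with their covalent donors
#'
#' A donor is an N or O atom; a hydrogen belongs to the donor on its own
#' chain nearer than `dh_cutoff` (1.2 Angstrom — the covalent D-H pairing
#' criterion). A hydrogen equidistant from two donors goes to the lower
#' atom index; hydrogens with no donor in range are skipped with a
#' warning.
#'
#' @param topology An [aggtraj_topology].
#' @param frame An [aggtraj_frame].
#' @param dh_cutoff Donor-hydrogen distance cutoff (Angstrom, default 1.2).
#' @return data.frame with columns `donor`, `hydrogen` (topology row
#'   indices), `chain`.
#' @export
find_donor_hydrogen_pairs <- function(topology, frame, dh_cutoff = 1.2) {
  at <- topology$atoms
  h_idx <- which(at$element == "H")
  d_idx <- which(at$element %in% c("N", "O"))
  if (length(h_idx) == 0L || length(d_idx) == 0L) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      chain = integer(0)))
  }
  pairs <- vector("list", length(h_idx))
  orphan <- 0L
  for (k in seq_along(h_idx)) {
    h <- h_idx[k]
    cand <- d_idx[at$chain_index[d_idx] == at$chain_index[h]]
    if (length(cand) == 0L) { orphan <- orphan + 1L; next }
    d2 <- pairwise_min_image_dist2(frame$xyz[h, , drop = FALSE],
                                   frame$xyz[cand, , drop = FALSE],
                                   frame$box)
    best <- min(d2)
    if (sqrt(best) >= dh_cutoff) { orphan <- orphan + 1L; next }
    donor <- cand[which(d2 == best)]
    pairs[[k]] <- c(donor = min(donor), hydrogen = h)
  }
  if (orphan > 0L) {
    warning(orphan, " hydrogen(s) without a donor within ", dh_cutoff,
            " Angstrom were ignored")
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      chain = integer(0)))
  }
  data.frame(donor = pairs[, "donor"], hydrogen = pairs[, "hydrogen"],
             chain = at$chain_index[pairs[, "donor"]])
}

#' Detect hydrogen bonds in one frame
#'
#' A bond D-H...A is declared when the acceptor is an N or O atom distinct
#' from the donor group, the minimum-image donor-acceptor distance is
#' below `da_cutoff` (3.0 Angstrom) and the D-H-A angle (vertex at H) is
#' at least `angle_min` (150 degrees). The bond is intermolecular when
#' donor and acceptor sit on different chains.
#'
#' @param frame An [aggtraj_frame].
#' @param topology Matching [aggtraj_topology].
#' @param da_cutoff Donor-acceptor distance cutoff (Angstrom, default 3.0).
#' @param angle_min Minimum D-H-A angle in degrees (default 150).
#' @param dh_cutoff Covalent donor-hydrogen pairing cutoff (default 1.2).
#' @return data.frame of class columns `donor`, `hydrogen`, `acceptor`
#'   (topology row indices), `donor_chain`, `acceptor_chain`,
#'   `donor_residue`, `acceptor_residue`, `kind`
#'   (`"intermolecular"`/`"intramolecular"`).
#' @export
detect_hbonds <- function(frame, topology, da_cutoff = 3.0, angle_min = 150,
                          dh_cutoff = 1.2) {
  at <- topology$atoms
  dh <- find_donor_hydrogen_pairs(topology, frame, dh_cutoff)
  acc_idx <- which(at$element %in% c("N", "O"))
  if (nrow(dh) == 0L || length(acc_idx) == 0L) {
    return(empty_hbond_frame())
  }
  box <- frame$box
  xyz <- frame$xyz
  out <- vector("list", nrow(dh))
  for (k in seq_len(nrow(dh))) {
    d <- dh$donor[k]; h <- dh$hydrogen[k]
    cand <- acc_idx[acc_idx != d & acc_idx != h]
    d2 <- drop(pairwise_min_image_dist2(xyz[d, , drop = FALSE],
                                        xyz[cand, , drop = FALSE], box))
    cand <- cand[d2 < da_cutoff^2]
    if (length(cand) == 0L) next
    # D-H-A angle at vertex H, minimum-image legs
    hd <- wrap_displacement(matrix(xyz[d, ], 1) -
                            matrix(xyz[h, ], 1), box)
    keep <- logical(length(cand))
    for (m in seq_along(cand)) {
      ha <- drop(wrap_displacement(matrix(xyz[cand[m], ], 1) -
                                   matrix(xyz[h, ], 1), box))
      cosang <- sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      keep[m] <- ang >= angle_min
    }
    cand <- cand[keep]
    if (length(cand) == 0L) next
    out[[k]] <- data.frame(
      donor = d, hydrogen = h, acceptor = cand,
      donor_chain = at$chain_index[d],
      acceptor_chain = at$chain_index[cand],
      donor_residue = at$residue_index[d],
      acceptor_residue = at$residue_index[cand]
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_hbond_frame())
  res$kind <- ifelse(res$donor_chain == res$acceptor_chain,
                     "intramolecular", "intermolecular")
  rownames(res) <- NULL
  res
}

empty_hbond_frame <- function() {
  data.frame(donor = integer(0), hydrogen = integer(0),
             acceptor = integer(0), donor_chain = integer(0),
             acceptor_chain = integer(0), donor_residue = integer(0),
             acceptor_residue = integer(0), kind = character(0))
}

#' Hydrogen-bond counts over a trajectory
#'
#' @param traj An [aggtraj_trajectory].
#' @param ... Passed to [detect_hbonds].
#' @return data.frame with columns `frame`, `time`, `total`, `inter`,
#'   `intra` (total = inter + intra in every frame), carrying the
#'   per-frame bond tables as attribute `"bonds"`.
#' @export
hbond_timeseries <- function(traj, ...) {
  bonds <- lapply(traj$frames, detect_hbonds, topology = traj$topology, ...)
  inter <- vapply(bonds, function(b) sum(b$kind == "intermolecular"),
                  integer(1))
  intra <- vapply(bonds, function(b) sum(b$kind == "intramolecular"),
                  integer(1))
  out <- data.frame(
    frame = seq_along(bonds),
    time = vapply(traj$frames, function(f) f$time, numeric(1)),
    total = inter + intra, inter = inter, intra = intra
  )
  attr(out, "bonds") <- bonds
  out
}

#' Residue-pair hydrogen-bond contact map
#'
#' Counts bonds of the requested kind by (donor residue, acceptor residue)
#' position over all frames and chain pairs. All chains must share one
#' sequence so residue positions are comparable; entries are labeled with
#' residue names (e.g. SER30).
#'
#' @param traj An [aggtraj_trajectory].
#' @param kind `"intermolecular"`, `"intramolecular"`, or `"all"`.
#' @param bonds Optional precomputed per-frame bond list (the `"bonds"`
#'   attribute of [hbond_timeseries]); recomputed when missing.
#' @param ... Passed to [detect_hbonds] when recomputing.
#' @return Square numeric matrix (donor residue x acceptor residue) with
#'   dimnames like `"SER30"`.
#' @export
hbond_contact_map <- function(traj, kind = c("intermolecular",
                                             "intramolecular", "all"),
                              bonds = NULL, ...) {
  kind <- match.arg(kind)
  seqs <- traj$topology$sequences
  if (is.null(seqs) || length(unique(seqs)) != 1L) {
    stop("contact map requires all chains to share one sequence")
  }
  letters1 <- strsplit(seqs[[1]], "")[[1]]
  n_res <- length(letters1)
  labels <- paste0(ONE_TO_THREE[letters1], seq_len(n_res))
  M <- matrix(0, n_res, n_res, dimnames = list(labels, labels))
  if (is.null(bonds)) {
    bonds <- lapply(traj$frames, detect_hbonds,
                    topology = traj$topology, ...)
  }
  for (b in bonds) {
    if (kind != "all") b <- b[b$kind == kind, , drop = FALSE]
    if (nrow(b) == 0L) next
    for (r in seq_len(nrow(b))) {
      M[b$donor_residue[r], b$acceptor_residue[r]] <-
        M[b$donor_residue[r], b$acceptor_residue[r]] + 1
    }
  }
  M
}

# --- solvent-accessible surface area --------------------------------------

# Deterministic golden-section spiral point set on the unit sphere.
golden_spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere (default 1.4 Angstrom, water-sized) over the atomic
#' van der Waals spheres: each atom's sphere of radius r + probe is sampled
#' with a deterministic golden-section spiral of `n_points` test points,
#' and the exposed fraction times 4 pi (r + probe)^2 is its area.
#' Coordinates must be unwrapped (no periodic occlusion is considered).
#'
#' @param frame An [aggtraj_frame] (or bare coordinate matrix).
#' @param topology Matching [aggtraj_topology] supplying radii.
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param n_points Test points per atom (default 960; >= 16 required).
#' @param subset Optional integer vector of topology row indices: compute
#'   areas for (and occlusion by) this atom set only.
#' @return List of class `aggtraj_sasa`: `area` (per-atom, Angstrom^2,
#'   zero for atoms outside `subset`), `total_nm2`.
#' @export
shrake_rupley_sasa <- function(frame, topology, probe = 1.4,
                               n_points = 960L, subset = NULL) {
  if (n_points < 16L) stop("n_points must be at least 16")
  xyz <- if (inherits(frame, "aggtraj_frame")) frame$xyz else as.matrix(frame)
  radii <- topology$atoms$vdw_radius
  n <- nrow(xyz)
  if (is.null(subset)) subset <- seq_len(n)
  pts <- golden_spiral_points(n_points)
  area <- numeric(n)
  ext <- radii + probe
  sx <- xyz[subset, , drop = FALSE]
  sr <- ext[subset]
  for (ii in seq_along(subset)) {
    i <- subset[ii]
    ri <- ext[i]
    # neighbors whose extended spheres can occlude atom i's test sphere
    dc <- sqrt(rowSums(sweep(sx, 2, xyz[i, ])^2))
    nb <- which(dc < ri + sr & subset != i)
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * ri^2
      next
    }
    tp <- sweep(pts * ri, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (m in nb) {
      if (!any(exposed)) break
      d2 <- rowSums(sweep(tp[exposed, , drop = FALSE], 2,
                          sx[m, ])^2)
      exposed[exposed] <- d2 >= sr[m]^2
    }
    area[i] <- 4 * pi * ri^2 * sum(exposed) / n_points
  }
  structure(list(area = area, total_nm2 = sum(area) / 100),
            class = "aggtraj_sasa")
}

#' Decompose per-atom SASA by residue hydrophobicity
#'
#' Sums per-atom areas into hydrophobic and non-hydrophobic (neutral +
#' hydrophilic) groups; the two parts add exactly to the total. Areas are
#' reported in nm^2, the customary unit for whole-aggregate surfaces.
#'
#' @param sasa An `aggtraj_sasa` (per-atom areas in Angstrom^2).
#' @param topology Matching [aggtraj_topology].
#' @param classes Residue classification (one-letter code -> class); see
#'   [default_residue_classes].
#' @return data.frame (one row) with `total`, `hydrophobic`,
#'   `non_hydrophobic` in nm^2.
#' @export
sasa_decomposition <- function(sasa, topology,
                               classes = default_residue_classes()) {
  one <- residue_one_letter(topology$atoms$residue_name)
  cls <- classes[one]
  if (any(is.na(cls))) {
    stop("classification missing for residue(s): ",
         paste(unique(one[is.na(cls)]), collapse = ", "))
  }
  phob <- sum(sasa$area[cls == "hydrophobic"]) / 100
  nonphob <- sum(sasa$area[cls != "hydrophobic"]) / 100
  data.frame(total = phob + nonphob, hydrophobic = phob,
             non_hydrophobic = nonphob)
}

#' SASA time series with hydrophobicity decomposition
#'
#' Computes the whole-system Shrake-Rupley SASA per frame on unwrapped
#' coordinates (each contact-connected cluster unwrapped as a unit) and
#' decomposes it by residue class.
#'
#' @param traj An [aggtraj_trajectory].
#' @param cutoff Contact cutoff used for per-cluster unwrapping.
#' @param assignments Optional precomputed per-frame clusters.
#' @param ... Passed to [shrake_rupley_sasa].
#' @return data.frame with columns `frame`, `time`, `total`,
#'   `hydrophobic`, `non_hydrophobic` (nm^2).
#' @export
sasa_timeseries <- function(traj, cutoff = 4.0, assignments = NULL, ...) {
  if (is.null(assignments)) assignments <- cluster_frames(traj, cutoff)
  topo <- traj$topology
  out <- data.frame(frame = seq_along(traj$frames),
                    time = vapply(traj$frames, function(f) f$time,
                                  numeric(1)),
                    total = 0, hydrophobic = 0, non_hydrophobic = 0)
  for (t in seq_along(traj$frames)) {
    fr <- traj$frames[[t]]
    xyz <- fr$xyz
    for (cl in assignments[[t]]$clusters) {
      uw <- unwrap_chains_and_cluster(fr, topo, cl, cutoff)
      xyz[attr(uw, "atom_indices"), ] <- uw
    }
    # clusters are far apart; occlusion across clusters is not modeled
    sasa <- shrake_rupley_sasa(aggtraj_frame(xyz, fr$box, fr$time),
                               topo, ...)
    dec <- sasa_decomposition(sasa, topo)
    out$total[t] <- dec$total
    out$hydrophobic[t] <- dec$hydrophobic
    out$non_hydrophobic[t] <- dec$non_hydrophobic
  }
  out
}

#' Fraction of atoms in hydrophobic residues
#'
#' Reporting helper for comparing a topology's composition against the
#' hydrophobic/non-hydrophobic SASA split.
#'
#' @param topology An [aggtraj_topology].
#' @param classes Residue classification.
#' @return Fraction in [0, 1].
#' @export
hydrophobic_atom_fraction <- function(topology,
                                      classes = default_residue_classes()) {
  one <- residue_one_letter(topology$atoms$residue_name)
  mean(classes[one] == "hydrophobic")
}
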