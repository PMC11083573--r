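# Helix/strand/coil assignment from backbone geometry via Kabsch-Sander
# hydrogen bonds, and the beta-content statistics built on it.
#
# The assignment is a 3-state mapping: 4-turn ladders give H, beta bridges
# (parallel or antiparallel, intra- or inter-chain) give E, everything
# else C. E overrides H, since the beta content of aggregates is the
# headline statistic downstream.

KS_COUPLING <- 27.888       # kcal/mol * Angstrom (0.084 e^2 * 332)
KS_HBOND_CUTOFF <- -0.5     # kcal/mol
KS_CA_PREFILTER <- 9.0      # Angstrom; standard N-CA distance gate

# Per-residue backbone atom bookkeeping: one row per (chain, residue) with
# topology row indices of N, CA, C, O and the amide H (NA when absent).
backbone_table <- function(topology) {
  at <- topology$atoms
  key <- paste(at$chain_index, at$residue_index)
  res <- !duplicated(key)
  bt <- data.frame(chain = at$chain_index[res],
                   residue = at$residue_index[res],
                   resname = at$residue_name[res])
  find_atom <- function(names_wanted) {
    idx <- rep(NA_integer_, nrow(bt))
    sel <- at$name %in% names_wanted
    k <- match(paste(bt$chain, bt$residue), key[sel])
    idx[!is.na(k)] <- which(sel)[k[!is.na(k)]]
    idx
  }
  bt$iN <- find_atom("N")
  bt$iCA <- find_atom("CA")
  bt$iC <- find_atom("C")
  bt$iO <- find_atom(c("O", "O1", "OT1"))
  bt$iH <- find_atom(c("H", "HN"))
  bt <- bt[order(bt$chain, bt$residue), , drop = FALSE]
  rownames(bt) <- NULL
  bt
}

#' Reconstruct missing backbone amide hydrogens
#'
#' For every residue i > 1 lacking an amide hydrogen (prolines and chain
#' starts get none), H is placed 1.01 Angstrom from N(i) along the unit
#' vector from O(i-1) to C(i-1) — the standard trans-amide construction
#' that puts N-H anti to the preceding carbonyl.
#'
#' @param frame An [aggtraj_frame].
#' @param topology Matching [aggtraj_topology].
#' @return data.frame with columns `chain`, `residue`, `x`, `y`, `z` for
#'   the reconstructed hydrogens only; pre-existing hydrogens are left
#'   untouched (and absent from the result).
#' @export
reconstruct_amide_hydrogens <- function(frame, topology) {
  bt <- backbone_table(topology)
  hc <- amide_h_coords(frame, topology, bt)
  rec <- which(attr(hc, "reconstructed"))
  data.frame(chain = bt$chain[rec], residue = bt$residue[rec],
             x = hc[rec, 1], y = hc[rec, 2], z = hc[rec, 3])
}

# Amide H position per backbone-table row: existing H coordinates where
# present, reconstructed ones where possible, NA rows otherwise
# (chain-start residues and prolines).
amide_h_coords <- function(frame, topology, bt) {
  n <- nrow(bt)
  H <- matrix(NA_real_, n, 3)
  reconstructed <- rep(FALSE, n)
  have <- !is.na(bt$iH)
  H[have, ] <- frame$xyz[bt$iH[have], , drop = FALSE]
  for (r in which(!have)) {
    if (bt$resname[r] == "PRO") next
    if (r == 1L || bt$chain[r - 1L] != bt$chain[r]) next  # chain start
    prev <- r - 1L
    if (is.na(bt$iN[r])) {
      stop("missing backbone N for chain ", bt$chain[r],
           " residue ", bt$residue[r])
    }
    if (is.na(bt$iC[prev]) || is.na(bt$iO[prev])) {
      stop("missing backbone C/O for chain ", bt$chain[prev],
           " residue ", bt$residue[prev])
    }
    d <- frame$xyz[bt$iC[prev], ] - frame$xyz[bt$iO[prev], ]
    d <- d / sqrt(sum(d^2))
    H[r, ] <- frame$xyz[bt$iN[r], ] + 1.01 * d
    reconstructed[r] <- TRUE
  }
  attr(H, "reconstructed") <- reconstructed
  H
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic dipole-dipole proxy between a donor N-H group and an
#' acceptor C=O group: E = 27.888 (1/rON + 1/rCH - 1/rOH - 1/rCN)
#' kcal/mol. A backbone hydrogen bond is declared when E < -0.5 kcal/mol.
#'
#' @param N,H Donor nitrogen and amide hydrogen positions (3-vectors, A).
#' @param C,O Acceptor carbonyl carbon and oxygen positions (3-vectors, A).
#' @return Energy in kcal/mol.
#' @export
ks_hbond_energy <- function(N, H, C, O) {
  pts <- rbind(N, H, C, O)
  if (any(!is.finite(pts))) stop("atom positions must be finite")
  rON <- sqrt(sum((O - N)^2))
  rCH <- sqrt(sum((C - H)^2))
  rOH <- sqrt(sum((O - H)^2))
  rCN <- sqrt(sum((C - N)^2))
  if (min(rON, rCH, rOH, rCN) <= 0) stop("coincident atoms in energy evaluation")
  KS_COUPLING * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

# Residue-level Kabsch-Sander H-bond matrix: HB[i, j] TRUE when the N-H of
# backbone-table row i donates to the C=O of row j. Distances use the
# minimum image so wrapped frames assign identically to whole ones.
ks_hbond_matrix <- function(frame, topology, bt = backbone_table(topology)) {
  n <- nrow(bt)
  box <- frame$box
  xyz <- frame$xyz
  Hpos <- amide_h_coords(frame, topology, bt)
  HB <- matrix(FALSE, n, n)
  miss <- is.na(bt$iN) | is.na(bt$iCA) | is.na(bt$iC) | is.na(bt$iO)
  if (any(miss)) {
    stop("incomplete backbone (N/CA/C/O) at chain ", bt$chain[miss][1],
         " residue ", bt$residue[miss][1])
  }
  CA <- xyz[bt$iCA, , drop = FALSE]
  Np <- xyz[bt$iN, , drop = FALSE]
  Cp <- xyz[bt$iC, , drop = FALSE]
  Op <- xyz[bt$iO, , drop = FALSE]
  donors <- which(!is.na(Hpos[, 1]))
  # CA-CA prefilter (standard 9 A gate; no qualifying bond exists beyond it)
  d2ca <- pairwise_min_image_dist2(CA, CA, box)
  for (i in donors) {
    js <- which(d2ca[i, ] < KS_CA_PREFILTER^2)
    js <- js[js != i]
    for (j in js) {
      rON <- sqrt(sum(wrap_displacement(Op[j, ] - Np[i, ], box)^2))
      rCH <- sqrt(sum(wrap_displacement(Cp[j, ] - Hpos[i, ], box)^2))
      rOH <- sqrt(sum(wrap_displacement(Op[j, ] - Hpos[i, ], box)^2))
      rCN <- sqrt(sum(wrap_displacement(Cp[j, ] - Np[i, ], box)^2))
      if (min(rON, rCH, rOH, rCN) <= 1e-6) next
      E <- KS_COUPLING * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      HB[i, j] <- E < KS_HBOND_CUTOFF
    }
  }
  HB
}

#' Assign 3-state secondary structure to one frame
#'
#' Kabsch-Sander hydrogen bonds HB(i -> j) (N-H of residue i donating to
#' C=O of residue j) drive the assignment: a 4-turn exists at i when
#' HB(i+4 -> i) within a chain; residues i..i+3 are labeled H when 4-turns
#' exist at both i-1 and i. A parallel bridge (i, j) exists when
#' HB(j -> i-1) and HB(i+1 -> j), or HB(i -> j-1) and HB(j+1 -> i); an
#' antiparallel bridge when HB(i -> j) and HB(j -> i), or HB(j+1 -> i-1)
#' and HB(i+1 -> j-1). Bridge partners may sit on different chains;
#' within a chain |i - j| >= 3 is required. Bridge residues are labeled E,
#' and E overrides H. Chains shorter than 3 residues are all C.
#'
#' @param frame An [aggtraj_frame].
#' @param topology Matching [aggtraj_topology] (backbone N, CA, C, O
#'   required; amide H reconstructed when absent).
#' @return List of character vectors (one per chain) with labels
#'   `"H"`, `"E"`, `"C"`.
#' @export
assign_secondary_structure <- function(frame, topology) {
  bt <- backbone_table(topology)
  HB <- ks_hbond_matrix(frame, topology, bt)
  n <- nrow(bt)
  chain <- bt$chain
  label <- rep("C", n)
  # ---- helix from 4-turns ------------------------------------------------
  turn4 <- rep(FALSE, n)
  for (i in seq_len(n)) {
    i4 <- i + 4L
    if (i4 <= n && chain[i4] == chain[i] && HB[i4, i]) turn4[i] <- TRUE
  }
  for (i in 2:max(2L, n)) {
    if (i > n) break
    if (turn4[i] && i - 1L >= 1L && chain[i - 1L] == chain[i] &&
        turn4[i - 1L]) {
      span <- i:min(i + 3L, n)
      span <- span[chain[span] == chain[i]]
      label[span] <- "H"
    }
  }
  # ---- beta bridges ------------------------------------------------------
  bridge <- rep(FALSE, n)
  same_chain_prev <- function(i) i - 1L >= 1L && chain[i - 1L] == chain[i]
  same_chain_next <- function(i) i + 1L <= n && chain[i + 1L] == chain[i]
  hb_any <- which(HB, arr.ind = TRUE)
  cand <- unique(c(hb_any[, 1], hb_any[, 2],
                   hb_any[, 1] - 1L, hb_any[, 1] + 1L,
                   hb_any[, 2] - 1L, hb_any[, 2] + 1L))
  cand <- sort(cand[cand >= 1L & cand <= n])
  for (i in cand) {
    for (j in cand) {
      if (j <= i) next
      if (chain[i] == chain[j] && abs(bt$residue[i] - bt$residue[j]) < 3L) next
      par <- (same_chain_prev(i) && same_chain_next(i) &&
                HB[j, i - 1L] && HB[i + 1L, j]) ||
             (same_chain_prev(j) && same_chain_next(j) &&
                HB[i, j - 1L] && HB[j + 1L, i])
      anti <- (HB[i, j] && HB[j, i]) ||
              (same_chain_prev(i) && same_chain_next(i) &&
                 same_chain_prev(j) && same_chain_next(j) &&
                 HB[j + 1L, i - 1L] && HB[i + 1L, j - 1L])
      if (par || anti) {
        bridge[i] <- TRUE
        bridge[j] <- TRUE
      }
    }
  }
  label[bridge] <- "E"
  # short chains are coil by definition
  for (ch in unique(chain)) {
    sel <- chain == ch
    if (sum(sel) < 3L) label[sel] <- "C"
  }
  split(label, chain)[as.character(sort(unique(chain)))]
}

#' Assign secondary structure to every frame
#'
#' @param traj An [aggtraj_trajectory].
#' @return An object of class `aggtraj_ssmatrix`: list with `labels`
#'   (list over frames of per-chain label vectors), `n_chains`,
#'   `n_frames`.
#' @export
assign_ss_trajectory <- function(traj) {
  labels <- lapply(traj$frames, assign_secondary_structure,
                   topology = traj$topology)
  structure(list(labels = labels, n_frames = length(labels),
                 n_chains = traj$topology$n_chains,
                 sequences = traj$topology$sequences),
            class = "aggtraj_ssmatrix")
}

#' Secondary-structure content of the largest cluster, per frame
#'
#' Percentage of residues (over all chains of each frame's largest
#' cluster, lowest-chain tie rule) labeled helix, strand, and coil.
#'
#' @param assignments List of `aggtraj_clusters` (one per frame).
#' @param ssmatrix An `aggtraj_ssmatrix` for the same frames.
#' @return data.frame with columns `frame`, `helix`, `strand`, `coil`
#'   (percentages summing to 100).
#' @export
ss_content_of_largest_cluster <- function(assignments, ssmatrix) {
  stopifnot(length(assignments) == ssmatrix$n_frames)
  out <- data.frame(frame = seq_along(assignments), helix = 0,
                    strand = 0, coil = 0)
  for (t in seq_along(assignments)) {
    ci <- rank_cluster_index(assignments[[t]], 1L)
    chains <- assignments[[t]]$clusters[[ci]]
    lab <- unlist(ssmatrix$labels[[t]][as.character(chains)],
                  use.names = FALSE)
    out$helix[t] <- 100 * mean(lab == "H")
    out$strand[t] <- 100 * mean(lab == "E")
    out$coil[t] <- 100 * mean(lab == "C")
  }
  out
}

#' Fraction of largest-cluster peptides containing beta structure
#'
#' Per frame: the number of chains in the largest cluster with at least
#' one residue labeled E, divided by the cluster size. 1 means every
#' peptide in the cluster carries a beta strand.
#'
#' @inheritParams ss_content_of_largest_cluster
#' @return data.frame with columns `frame`, `cluster_size`,
#'   `beta_fraction`.
#' @export
beta_peptide_fraction <- function(assignments, ssmatrix) {
  stopifnot(length(assignments) == ssmatrix$n_frames)
  out <- data.frame(frame = seq_along(assignments),
                    cluster_size = 0L, beta_fraction = 0)
  for (t in seq_along(assignments)) {
    ci <- rank_cluster_index(assignments[[t]], 1L)
    chains <- assignments[[t]]$clusters[[ci]]
    has_beta <- vapply(as.character(chains), function(ch) {
      any(ssmatrix$labels[[t]][[ch]] == "E")
    }, logical(1))
    out$cluster_size[t] <- length(chains)
    out$beta_fraction[t] <- mean(has_beta)
  }
  out
}

#' Per-residue beta-strand propensity
#'
#' For each residue position r: the number of (frame, chain) events with
#' label E at r, divided by n_frames * n_chains — the per-snapshot,
#' per-peptide probability of strand conformation. All chains must share
#' one sequence.
#'
#' @param ssmatrix An `aggtraj_ssmatrix`.
#' @return data.frame with columns `residue`, `resname` (when sequences
#'   are known), `propensity` in [0, 1].
#' @export
residue_beta_propensity <- function(ssmatrix) {
  lens <- unique(unlist(lapply(ssmatrix$labels[[1]], length)))
  if (length(lens) != 1L ||
      (!is.null(ssmatrix$sequences) &&
         length(unique(ssmatrix$sequences)) != 1L)) {
    stop("beta propensity requires all chains to share one sequence")
  }
  n_res <- lens
  events <- numeric(n_res)
  for (t in seq_len(ssmatrix$n_frames)) {
    for (lab in ssmatrix$labels[[t]]) {
      events <- events + (lab == "E")
    }
  }
  norm <- ssmatrix$n_frames * ssmatrix$n_chains
  out <- data.frame(residue = seq_len(n_res), propensity = events / norm)
  if (!is.null(ssmatrix$sequences)) {
    letters1 <- strsplit(ssmatrix$sequences[[1]], "")[[1]]
    out$resname <- paste0(ONE_TO_THREE[letters1], out$residue)
    out <- out[, c("residue", "resname", "propensity")]
  }
  out
}
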