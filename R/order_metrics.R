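# Aggregate orderliness: nematic order parameter of chain axes, radius of
# gyration, the order-vs-hydrogen-bond histogram, and hydrogen bonds per
# chain contact.

#' Principal axis of one chain
#'
#' The molecular direction used for the nematic order parameter: the
#' principal eigenvector of the gyration tensor of the chain's C-alpha
#' atoms (chains here are folded, so end-to-end vectors degenerate; the
#' gyration axis is robust). Coordinates must be unwrapped. The sign of
#' the axis is arbitrary — the downstream Q tensor is sign-invariant.
#'
#' @param xyz Unwrapped coordinate matrix of the whole system or cluster.
#' @param topology An [aggtraj_topology].
#' @param chain 0-based chain index.
#' @param atom_indices Optional mapping from `xyz` rows to topology rows
#'   (the `atom_indices` attribute of [unwrap_chains_and_cluster]); by
#'   default `xyz` is assumed to be in full topology order.
#' @param mode `"gyration"` (default) or `"end_to_end"`.
#' @return Unit 3-vector.
#' @export
chain_axis <- function(xyz, topology, chain, atom_indices = NULL,
                       mode = c("gyration", "end_to_end")) {
  mode <- match.arg(mode)
  rows <- chain_atom_indices(topology, chain)
  ca <- rows[topology$atoms$name[rows] == "CA"]
  if (length(ca) < 3L) stop("chain ", chain, " has fewer than 3 CA atoms")
  if (!is.null(atom_indices)) ca <- match(ca, atom_indices)
  P <- xyz[ca, , drop = FALSE]
  if (mode == "end_to_end") {
    v <- P[nrow(P), ] - P[1L, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("degenerate end-to-end vector")
    return(v / nv)
  }
  Pc <- sweep(P, 2, colMeans(P))
  S <- crossprod(Pc) / nrow(Pc)  # 3x3 gyration tensor
  eg <- eigen(S, symmetric = TRUE)
  # eigen orders decreasing; exact ties resolved by the lowest-index axis
  v <- eg$vectors[, 1L]
  v / sqrt(sum(v^2))
}

#' Nematic order parameter of a set of axes
#'
#' P2 is the largest eigenvalue of Q = (1/N) sum over chains of
#' (3 u u^T - I) / 2. P2 = 1 for perfect alignment, 0 for an isotropic
#' set, and is bounded in [-0.5, 1]; it is invariant under per-vector sign
#' flips and global rotations. Fibrillar order corresponds to P2 above
#' roughly 0.8; the pre-fibrillar aggregates this package targets live in
#' the 0.15-0.65 range.
#'
#' @param vectors n x 3 matrix (or list) of direction vectors; normalized
#'   internally.
#' @return P2 (numeric scalar).
#' @export
nematic_order <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) stop("need at least 2 direction vectors")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero direction vector")
  u <- vectors / nrm
  Q <- matrix(0, 3, 3)
  for (i in seq_len(nrow(u))) {
    Q <- Q + (3 * tcrossprod(u[i, ]) - diag(3)) / 2
  }
  Q <- Q / nrow(u)
  max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
}

#' Mass-weighted radius of gyration
#'
#' @param coords n x 3 coordinate matrix (Angstrom), unwrapped.
#' @param masses Atom masses (amu); unit masses by default.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 1L) stop("need at least one atom")
  if (is.null(masses)) masses <- rep(1, n)
  M <- sum(masses)
  if (M <= 0) stop("total mass must be positive")
  com <- colSums(coords * masses) / M
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * d2) / M)
}

#' Per-frame order record of the largest cluster
#'
#' For every frame: the largest cluster (lowest-chain tie rule), its
#' nematic order parameter over chain gyration axes, the number of
#' intermolecular hydrogen bonds within it, its mass-weighted radius of
#' gyration, and the number of chain-pair contacts.
#'
#' @param traj An [aggtraj_trajectory].
#' @param cutoff Contact cutoff (Angstrom).
#' @param assignments Optional precomputed clusters (with contact graphs
#'   attached, as from [cluster_frames]).
#' @param hbonds Optional precomputed per-frame bond tables (the
#'   `"bonds"` attribute of [hbond_timeseries]).
#' @param ... Passed to [detect_hbonds] when bonds are recomputed.
#' @return data.frame of class `aggtraj_order_records`: columns `frame`,
#'   `time`, `cluster_size`, `P2`, `n_inter_hbonds`, `Rg`, `n_contacts`,
#'   `hbonds_per_contact`.
#' @export
order_records <- function(traj, cutoff = 4.0, assignments = NULL,
                          hbonds = NULL, ...) {
  topo <- traj$topology
  if (is.null(assignments)) assignments <- cluster_frames(traj, cutoff)
  if (is.null(hbonds)) {
    hbonds <- lapply(traj$frames, detect_hbonds, topology = topo, ...)
  }
  n_fr <- length(traj$frames)
  out <- data.frame(frame = seq_len(n_fr),
                    time = vapply(traj$frames, function(f) f$time,
                                  numeric(1)),
                    cluster_size = 0L, P2 = NA_real_,
                    n_inter_hbonds = 0L, Rg = NA_real_,
                    n_contacts = 0L, hbonds_per_contact = 0)
  for (t in seq_len(n_fr)) {
    a <- assignments[[t]]
    ci <- rank_cluster_index(a, 1L)
    chains <- a$clusters[[ci]]
    out$cluster_size[t] <- length(chains)
    uw <- unwrap_chains_and_cluster(traj$frames[[t]], topo, chains, cutoff)
    ai <- attr(uw, "atom_indices")
    out$Rg[t] <- radius_of_gyration(uw, topo$atoms$mass[ai])
    if (length(chains) >= 2L) {
      axes <- t(vapply(chains, function(ch) {
        chain_axis(uw, topo, ch, atom_indices = ai)
      }, numeric(3)))
      out$P2[t] <- nematic_order(axes)
    }
    b <- hbonds[[t]]
    inter <- b$kind == "intermolecular" &
      b$donor_chain %in% chains & b$acceptor_chain %in% chains
    out$n_inter_hbonds[t] <- sum(inter)
    out$hbonds_per_contact[t] <- hbonds_per_contact(a, b, cluster = chains)
    g <- attr(a, "graph")
    if (!is.null(g) && nrow(g$edges) > 0) {
      within <- g$edges[, 1] %in% chains & g$edges[, 2] %in% chains
      out$n_contacts[t] <- sum(within)
    }
  }
  class(out) <- c("aggtraj_order_records", class(out))
  out
}

#' Intermolecular hydrogen bonds per chain contact
#'
#' The number of intermolecular hydrogen bonds within a cluster divided by
#' the number of chain pairs in contact (contact-graph edges restricted to
#' the cluster); 0 when there are no contacts.
#'
#' @param assignment An `aggtraj_clusters` (with its `"graph"` attribute)
#'   for the frame.
#' @param bonds Bond table for the frame (from [detect_hbonds]).
#' @param cluster Chain set to restrict to; default the largest cluster.
#' @return Numeric scalar.
#' @export
hbonds_per_contact <- function(assignment, bonds, cluster = NULL) {
  if (is.null(cluster)) {
    cluster <- assignment$clusters[[rank_cluster_index(assignment, 1L)]]
  }
  g <- attr(assignment, "graph")
  if (is.null(g)) stop("assignment carries no contact graph")
  n_contacts <- if (nrow(g$edges) == 0) 0L else {
    sum(g$edges[, 1] %in% cluster & g$edges[, 2] %in% cluster)
  }
  if (n_contacts == 0L) return(0)
  n_hb <- sum(bonds$kind == "intermolecular" &
                bonds$donor_chain %in% cluster &
                bonds$acceptor_chain %in% cluster)
  n_hb / n_contacts
}

#' 2D histogram of intermolecular H-bond count versus nematic order
#'
#' Bins the per-frame (n_inter_hbonds, P2) pairs of the largest cluster
#' and normalizes counts to sum to 1 (probability mass). Basin cells are
#' reported as local maxima over the 8-neighborhood.
#'
#' @param records An `aggtraj_order_records` data.frame.
#' @param x_bins Number of H-bond-count bins (or explicit edge vector).
#' @param y_bins Number of P2 bins (or explicit edge vector).
#' @return Object of class `aggtraj_histogram2d`: `x_edges`, `y_edges`,
#'   `counts` (normalized, rows = x bins), `peaks` (data.frame of local
#'   maxima: x_bin, y_bin, x_mid, y_mid, mass).
#' @export
order_hbond_histogram <- function(records, x_bins = 12, y_bins = 12) {
  rec <- records[!is.na(records$P2), , drop = FALSE]
  if (nrow(rec) < 1L) stop("need at least one record with a defined P2")
  edges <- function(v, bins) {
    if (length(bins) > 1L) return(bins)
    rng <- range(v)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)  # degenerate axis
    seq(rng[1], rng[2], length.out = bins + 1L)
  }
  xe <- edges(rec$n_inter_hbonds, x_bins)
  ye <- edges(rec$P2, y_bins)
  ix <- pmin(findInterval(rec$n_inter_hbonds, xe,
                          rightmost.closed = TRUE), length(xe) - 1L)
  iy <- pmin(findInterval(rec$P2, ye, rightmost.closed = TRUE),
             length(ye) - 1L)
  cnt <- matrix(0, length(xe) - 1L, length(ye) - 1L)
  for (k in seq_along(ix)) cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1
  cnt <- cnt / sum(cnt)
  peaks <- local_maxima_2d(cnt)
  peaks$x_mid <- (xe[peaks$x_bin] + xe[peaks$x_bin + 1L]) / 2
  peaks$y_mid <- (ye[peaks$y_bin] + ye[peaks$y_bin + 1L]) / 2
  structure(list(x_edges = xe, y_edges = ye, counts = cnt, peaks = peaks),
            class = "aggtraj_histogram2d")
}

# local maxima over the 8-neighborhood of a nonnegative matrix; a cell
# qualifies when positive and no neighbor exceeds it (plateau cells all
# qualify, which is documented behavior for degenerate histograms)
local_maxima_2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  hits <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (m[i, j] <= 0) next
      nb <- m[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      if (all(nb <= m[i, j])) {
        hits[[length(hits) + 1L]] <- data.frame(x_bin = i, y_bin = j,
                                                mass = m[i, j])
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(x_bin = integer(0), y_bin = integer(0),
                      mass = numeric(0)))
  }
  do.call(rbind, hits)
}
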