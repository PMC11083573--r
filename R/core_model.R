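# Domain types shared by all analysis stages: topology, frames, trajectories,
# and minimum-image geometry in orthorhombic periodic boxes.
# Internal length unit is Angstrom throughout; times are picoseconds.

#' Orthorhombic periodic box
#'
#' @param lengths Numeric vector of three positive box edge lengths in
#'   Angstrom. Only orthorhombic (rectangular) boxes are supported; the
#'   systems this package targets use cubic boxes of 150-165 Angstrom.
#' @return A numeric vector of length 3 with class `aggtraj_box`.
#' @export
aggtraj_box <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3L || any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("box must be three finite positive edge lengths (orthorhombic); ",
         "triclinic boxes are not supported")
  }
  structure(lengths, class = "aggtraj_box")
}

#' Molecular topology: chains, residues, atoms
#'
#' The static half of a system: atom names, elements, van der Waals radii,
#' masses, and the chain/residue bookkeeping. Chains are indexed 0..n-1 in
#' file order; residues are 1-based within each chain, matching the mature
#' beta-lactoglobulin chain numbering ("1-33", "1-52").
#'
#' @param atoms A data.frame with columns `name` (atom name), `element`
#'   (element symbol), `vdw_radius` (Angstrom, > 0), `mass` (amu, > 0),
#'   `residue_index` (1-based within chain), `residue_name` (3-letter code),
#'   and `chain_index` (0-based).
#' @param sequences Character vector of one-letter sequences, one per chain.
#' @return An object of class `aggtraj_topology`.
#' @export
aggtraj_topology <- function(atoms, sequences = NULL) {
  required <- c("name", "element", "vdw_radius", "mass",
                "residue_index", "residue_name", "chain_index")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("topology must contain at least one atom")
  if (any(atoms$vdw_radius <= 0)) stop("all vdw radii must be positive")
  if (any(atoms$mass <= 0)) stop("all atom masses must be positive")
  if (any(atoms$residue_index < 1L)) stop("residue indices are 1-based")
  n_chains <- max(atoms$chain_index) + 1L
  if (any(atoms$chain_index < 0L)) stop("chain indices are 0-based")
  if (!is.null(sequences) && length(sequences) != n_chains) {
    stop("need one sequence per chain (", n_chains, " chains)")
  }
  structure(
    list(atoms = atoms, n_chains = n_chains, sequences = sequences),
    class = "aggtraj_topology"
  )
}

#' @export
print.aggtraj_topology <- function(x, ...) {
  cat(sprintf("aggtraj topology: %d chains, %d atoms\n",
              x$n_chains, nrow(x$atoms)))
  invisible(x)
}

#' Number of chains in a topology
#' @param topology An `aggtraj_topology`.
#' @return Integer chain count.
#' @export
n_chains <- function(topology) topology$n_chains

#' Row indices of the atoms of one chain
#' @param topology An `aggtraj_topology`.
#' @param chain 0-based chain index.
#' @return Integer vector of atom row indices.
#' @export
chain_atom_indices <- function(topology, chain) {
  idx <- which(topology$atoms$chain_index == chain)
  if (length(idx) == 0L) stop("chain ", chain, " has no atoms")
  idx
}

#' Single trajectory frame
#'
#' @param xyz Numeric n_atoms x 3 coordinate matrix (Angstrom).
#' @param box An `aggtraj_box` (or three lengths).
#' @param time Frame time in picoseconds (>= 0).
#' @return An object of class `aggtraj_frame`.
#' @export
aggtraj_frame <- function(xyz, box, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("coordinates must be an n x 3 matrix")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  if (!inherits(box, "aggtraj_box")) box <- aggtraj_box(box)
  if (!is.finite(time) || time < 0) stop("frame time must be >= 0 ps")
  structure(list(xyz = xyz, box = box, time = as.numeric(time)),
            class = "aggtraj_frame")
}

#' Trajectory: a topology plus time-ordered frames
#'
#' @param topology An `aggtraj_topology`.
#' @param frames List of `aggtraj_frame` objects with strictly increasing
#'   times and atom counts equal to the topology atom count.
#' @return An object of class `aggtraj_trajectory`.
#' @export
aggtraj_trajectory <- function(topology, frames) {
  if (length(frames) == 0L) stop("trajectory must contain at least one frame")
  n_atoms <- nrow(topology$atoms)
  times <- vapply(frames, function(f) f$time, numeric(1))
  counts <- vapply(frames, function(f) nrow(f$xyz), integer(1))
  if (any(counts != n_atoms)) {
    stop("frame atom counts differ from topology (", n_atoms, " atoms)")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames),
            class = "aggtraj_trajectory")
}

#' @export
print.aggtraj_trajectory <- function(x, ...) {
  times <- vapply(x$frames, function(f) f$time, numeric(1))
  cat(sprintf("aggtraj trajectory: %d frames (%g..%g ps), %d chains, %d atoms\n",
              length(x$frames), min(times), max(times),
              x$topology$n_chains, nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `aggtraj_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

# Wrap a displacement matrix/vector into [-L/2, L/2) per axis.
# floor(d/L + 1/2) maps the half-box boundary d = +L/2 to -L/2,
# giving deterministic handling of exact ties.
wrap_displacement <- function(d, box) {
  if (is.null(dim(d))) d <- matrix(d, ncol = 3)
  for (k in 1:3) {
    L <- box[k]
    d[, k] <- d[, k] - L * floor(d[, k] / L + 0.5)
  }
  d
}

#' Minimum-image displacement between two points
#'
#' Displacement from `q` to `p` under the minimum-image convention in an
#' orthorhombic box. Each component of the result lies in `[-L/2, L/2)`
#' for the corresponding box length `L`.
#'
#' @param p,q Numeric 3-vectors (Angstrom).
#' @param box An `aggtraj_box` (or three lengths).
#' @return Numeric 3-vector; its Euclidean norm is the minimum-image
#'   distance between the points.
#' @export
min_image_displacement <- function(p, q, box) {
  if (!inherits(box, "aggtraj_box")) box <- aggtraj_box(box)
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != 3L || length(q) != 3L) stop("p and q must be 3-vectors")
  if (any(!is.finite(p)) || any(!is.finite(q))) {
    stop("coordinates must be finite")
  }
  drop(wrap_displacement(p - q, box))
}

# All pairwise minimum-image squared distances between coordinate sets
# A (na x 3) and B (nb x 3); returns na x nb matrix.
pairwise_min_image_dist2 <- function(A, B, box) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    L <- box[k]
    dk <- dk - L * floor(dk / L + 0.5)
    d2 <- d2 + dk * dk
  }
  d2
}

#' Minimum distance between atoms of two chains
#'
#' Minimum over all inter-chain atom pairs of the minimum-image distance;
#' the quantity the 4 Angstrom aggregation contact criterion is applied to.
#'
#' @param frame An `aggtraj_frame`.
#' @param topology Matching `aggtraj_topology`.
#' @param chain_a,chain_b Distinct 0-based chain indices.
#' @return Minimum inter-atomic distance in Angstrom.
#' @export
min_interchain_distance <- function(frame, topology, chain_a, chain_b) {
  if (chain_a == chain_b) stop("chain_a and chain_b must differ")
  ia <- chain_atom_indices(topology, chain_a)
  ib <- chain_atom_indices(topology, chain_b)
  d2 <- pairwise_min_image_dist2(frame$xyz[ia, , drop = FALSE],
                                 frame$xyz[ib, , drop = FALSE],
                                 frame$box)
  sqrt(min(d2))
}

# Make one chain internally whole: walk consecutive atoms, replacing each
# raw step by its minimum image so no bonded step spans more than L/2.
make_chain_whole <- function(xyz, box) {
  n <- nrow(xyz)
  if (n <= 1L) return(xyz)
  steps <- wrap_displacement(xyz[-1L, , drop = FALSE] -
                             xyz[-n, , drop = FALSE], box)
  out <- xyz
  out[-1L, ] <- matrix(out[1L, ], n - 1L, 3, byrow = TRUE) +
    apply(steps, 2, cumsum)
  out
}

#' Unwrap the chains of one cluster across periodic boundaries
#'
#' Makes each chain internally whole, then translates whole chains by box
#' lattice vectors along a breadth-first traversal of the intra-cluster
#' contact graph so that every contacting pair sits at its minimum-image
#' separation. The result is suitable for radius-of-gyration, gyration-axis
#' and surface-area calculations that must not see periodic seams.
#'
#' @param frame An `aggtraj_frame`.
#' @param topology Matching `aggtraj_topology`.
#' @param cluster Integer vector of 0-based chain indices forming one
#'   contact-connected cluster.
#' @param cutoff Contact cutoff (Angstrom) defining the intra-cluster
#'   contact graph; default 4.0.
#' @return Coordinate matrix (rows = atoms of the cluster chains in
#'   topology order) with `chains` and `atom_indices` attributes.
#' @export
unwrap_chains_and_cluster <- function(frame, topology, cluster, cutoff = 4.0) {
  cluster <- sort(unique(as.integer(cluster)))
  if (length(cluster) == 0L) stop("cluster must be nonempty")
  box <- frame$box
  idx <- lapply(cluster, function(ch) chain_atom_indices(topology, ch))
  whole <- lapply(idx, function(ii) {
    make_chain_whole(frame$xyz[ii, , drop = FALSE], box)
  })
  names(whole) <- as.character(cluster)
  m <- length(cluster)
  if (m > 1L) {
    # contact adjacency among cluster chains (on wrapped coordinates)
    adj <- matrix(FALSE, m, m)
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        d <- min_interchain_distance(frame, topology,
                                     cluster[a], cluster[b])
        adj[a, b] <- adj[b, a] <- d < cutoff
      }
    }
    placed <- rep(FALSE, m)
    placed[1L] <- TRUE
    queue <- 1L
    while (length(queue) > 0L) {
      a <- queue[1L]; queue <- queue[-1L]
      for (b in which(adj[a, ] & !placed)) {
        # lattice shift making the closest (a,b) atom pair contiguous
        d2 <- pairwise_min_image_dist2(whole[[a]], whole[[b]], box)
        hit <- which(d2 == min(d2), arr.ind = TRUE)[1L, ]
        raw <- whole[[b]][hit[2L], ] - whole[[a]][hit[1L], ]
        mi <- drop(wrap_displacement(raw, box))
        shift <- mi - raw
        whole[[b]] <- sweep(whole[[b]], 2, shift, "+")
        placed[b] <- TRUE
        queue <- c(queue, b)
      }
    }
    if (!all(placed)) {
      stop("cluster is not connected under the ", cutoff,
           " Angstrom contact cutoff")
    }
  }
  out <- do.call(rbind, whole)
  attr(out, "chains") <- cluster
  attr(out, "atom_indices") <- unlist(idx, use.names = FALSE)
  out
}
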