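# Per-frame cluster identification (head-and-list single-linkage contact
# clustering), cluster statistics over time, and the cluster-size
# transition network.

#' Build the inter-chain contact graph of one frame
#'
#' Two chains are in contact when any pair of atoms, one from each chain,
#' lies closer than `cutoff` under the minimum-image convention. All atoms
#' (hydrogens included) participate by default, matching an atom-atom
#' contact criterion of 4 Angstrom; `heavy_only` restricts to non-hydrogen
#' atoms. A chain-level bounding-sphere prefilter skips far-apart pairs but
#' the resulting edge set is identical to the exhaustive double loop.
#'
#' @param frame An [aggtraj_frame].
#' @param topology Matching [aggtraj_topology].
#' @param cutoff Contact distance cutoff in Angstrom (default 4.0).
#' @param heavy_only Exclude hydrogens from the contact test (default FALSE).
#' @return An object of class `aggtraj_contact_graph`: list with `n_chains`
#'   and `edges` (two-column matrix of 0-based chain pairs, i < j).
#' @export
build_contact_graph <- function(frame, topology, cutoff = 4.0,
                                heavy_only = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- topology$n_chains
  box <- frame$box
  coords <- vector("list", n)
  for (ch in seq_len(n) - 1L) {
    ii <- chain_atom_indices(topology, ch)
    if (heavy_only) ii <- ii[topology$atoms$element[ii] != "H"]
    if (length(ii) == 0L) stop("chain ", ch, " has no atoms for contact test")
    coords[[ch + 1L]] <- frame$xyz[ii, , drop = FALSE]
  }
  # bounding spheres: centroid (minimum-image consistent within a whole
  # chain) + max atom radius from centroid
  centers <- matrix(0, n, 3)
  radii <- numeric(n)
  for (k in seq_len(n)) {
    w <- make_chain_whole(coords[[k]], box)
    centers[k, ] <- colMeans(w)
    radii[k] <- sqrt(max(rowSums(sweep(w, 2, centers[k, ])^2)))
    coords[[k]] <- w
  }
  edges <- matrix(integer(0), ncol = 2)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      dc <- sqrt(sum(min_image_displacement(centers[a, ], centers[b, ],
                                            box)^2))
      if (dc - radii[a] - radii[b] >= cutoff) next
      d2 <- pairwise_min_image_dist2(coords[[a]], coords[[b]], box)
      if (min(d2) < cutoff^2) {
        edges <- rbind(edges, c(a - 1L, b - 1L))
      }
    }
  }
  structure(list(n_chains = n, edges = edges, cutoff = cutoff),
            class = "aggtraj_contact_graph")
}

#' Cluster chains by the head-and-list algorithm
#'
#' Literal implementation of the linked-list cluster bookkeeping used for
#' molecular aggregation analysis. Four vectors of length n are kept:
#' CLUSTER (cluster id per molecule), HEAD (first molecule of each cluster,
#' 0 when the cluster has been absorbed), LIST (next molecule in the same
#' cluster, 0-terminated), and SIZE (cluster sizes). All molecules start as
#' single-molecule clusters; iterating over contacting pairs i < j, two
#' molecules in different clusters have their clusters spliced: the list of
#' j's cluster is appended to i's, cluster ids are updated, the absorbed
#' head is zeroed and SIZE adjusted. The resulting partition equals the
#' connected components of the contact graph (single linkage).
#'
#' @param graph An `aggtraj_contact_graph`.
#' @return An object of class `aggtraj_clusters`: list with `clusters`
#'   (list of 0-based chain-index vectors, each sorted; ordered by lowest
#'   member), `sizes` (the SIZE values for the surviving clusters), and
#'   `membership` (per-chain cluster ordinal, 1-based).
#' @export
head_and_list_clusters <- function(graph) {
  n <- graph$n_chains
  CLUSTER <- seq_len(n)
  HEAD <- seq_len(n)
  LIST <- integer(n)
  SIZE <- rep(1L, n)
  ed <- graph$edges
  if (nrow(ed) > 0) {
    ord <- order(ed[, 1], ed[, 2])
    for (e in ord) {
      i <- ed[e, 1] + 1L
      j <- ed[e, 2] + 1L
      ci <- CLUSTER[i]
      cj <- CLUSTER[j]
      if (ci == cj) next
      # splice cluster cj onto the tail of cluster ci
      tail <- HEAD[ci]
      while (LIST[tail] != 0L) tail <- LIST[tail]
      LIST[tail] <- HEAD[cj]
      m <- HEAD[cj]
      while (m != 0L) {
        CLUSTER[m] <- ci
        m <- LIST[m]
      }
      HEAD[cj] <- 0L
      SIZE[ci] <- SIZE[ci] + SIZE[cj]
      SIZE[cj] <- 0L
    }
  }
  heads <- which(HEAD != 0L)
  clusters <- lapply(heads, function(h) {
    members <- integer(0)
    m <- HEAD[h]
    while (m != 0L) {
      members <- c(members, m)
      m <- LIST[m]
    }
    sort(members) - 1L
  })
  ord <- order(vapply(clusters, min, integer(1)))
  clusters <- clusters[ord]
  sizes <- SIZE[heads][ord]
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]] + 1L] <- k
  structure(list(clusters = clusters, sizes = as.integer(sizes),
                 membership = membership, n_chains = n),
            class = "aggtraj_clusters")
}

#' Cluster every frame of a trajectory
#'
#' @param traj An [aggtraj_trajectory].
#' @param cutoff Contact cutoff in Angstrom (default 4.0).
#' @param heavy_only Passed to [build_contact_graph].
#' @return List of `aggtraj_clusters`, one per frame, each carrying the
#'   frame's contact graph as attribute `"graph"`.
#' @export
cluster_frames <- function(traj, cutoff = 4.0, heavy_only = FALSE) {
  lapply(traj$frames, function(fr) {
    g <- build_contact_graph(fr, traj$topology, cutoff, heavy_only)
    cl <- head_and_list_clusters(g)
    attr(cl, "graph") <- g
    cl
  })
}

# k-th largest cluster size of one assignment; ties among equal-size
# clusters are broken by lowest contained chain index; missing rank -> 0.
rank_size <- function(assignment, k) {
  sizes <- assignment$sizes
  if (k > length(sizes)) return(0L)
  mins <- vapply(assignment$clusters, min, integer(1))
  ord <- order(-sizes, mins)
  sizes[ord[k]]
}

# Index (into assignment$clusters) of the rank-k cluster under the same
# tie rule; NA when the rank is missing.
rank_cluster_index <- function(assignment, k = 1L) {
  sizes <- assignment$sizes
  if (k > length(sizes)) return(NA_integer_)
  mins <- vapply(assignment$clusters, min, integer(1))
  order(-sizes, mins)[k]
}

#' Time series of the k-th largest cluster size
#'
#' @param traj An [aggtraj_trajectory], or a list of `aggtraj_clusters`
#'   produced by [cluster_frames] (to avoid re-clustering).
#' @param cutoff Contact cutoff (used only when `traj` is a trajectory).
#' @param rank Which rank: 1 = largest, 2 = second largest, ...
#' @return Integer vector of per-frame sizes (0 where the rank is absent).
#' @export
cluster_timeseries <- function(traj, cutoff = 4.0, rank = 1L) {
  if (rank < 1L) stop("rank must be >= 1")
  assignments <- if (inherits(traj, "aggtraj_trajectory")) {
    cluster_frames(traj, cutoff)
  } else traj
  vapply(assignments, rank_size, integer(1), k = rank)
}

#' Trailing running average of a series
#'
#' Mean over the trailing `window` points (fewer at the start of the
#' series); smooths out short-lived cluster transitions. With 100 ps
#' between frames the default 10-frame window averages over 1 ns.
#'
#' @param series Numeric vector.
#' @param window Window length in frames (>= 1); default 10.
#' @return Numeric vector of the same length.
#' @export
running_average <- function(series, window = 10L) {
  if (length(series) == 0L) stop("series must be nonempty")
  if (window < 1L) stop("window must be >= 1")
  cs <- cumsum(as.numeric(series))
  n <- length(series)
  t_idx <- seq_len(n)
  lower <- pmax(t_idx - window, 0L)
  (cs - c(0, cs)[lower + 1L]) / (t_idx - lower)
}

#' Cluster-size census over a whole trajectory
#'
#' Counts how many clusters of each size were observed, pooled over all
#' frames (and over multiple runs when a list of assignment lists is
#' given). Sizes satisfy sum(size * count) = n_chains * n_frames.
#'
#' @param traj An [aggtraj_trajectory], a list of `aggtraj_clusters`, or a
#'   list of such lists (several runs pooled).
#' @param cutoff Contact cutoff (trajectory input only).
#' @return data.frame with columns `size`, `count`, plus attributes
#'   `n_frames` (frames pooled) and `total_time_ps` when computable.
#' @export
size_distribution <- function(traj, cutoff = 4.0) {
  runs <- if (inherits(traj, "aggtraj_trajectory")) {
    list(cluster_frames(traj, cutoff))
  } else if (length(traj) > 0 && inherits(traj[[1]], "aggtraj_clusters")) {
    list(traj)
  } else traj
  counts <- integer(0)
  n_frames_total <- 0L
  for (run in runs) {
    n_frames_total <- n_frames_total + length(run)
    for (a in run) {
      for (s in a$sizes) {
        nm <- as.character(s)
        counts[nm] <- if (is.na(counts[nm])) 1L else counts[nm] + 1L
      }
    }
  }
  sizes <- as.integer(names(counts))
  ord <- order(sizes)
  out <- data.frame(size = sizes[ord], count = as.integer(counts[ord]))
  attr(out, "n_frames") <- n_frames_total
  out
}

new_transition_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges),
            class = "aggtraj_transition_network")
}

#' @export
print.aggtraj_transition_network <- function(x, ...) {
  cat(sprintf("cluster-size transition network: %d sizes, %d edges, %d events\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$count)))
  invisible(x)
}

#' Track cluster-size transitions between consecutive frames
#'
#' For every consecutive frame pair t -> t+1, each (predecessor cluster,
#' successor cluster) pair that shares at least one chain generates one
#' event from the predecessor's size to the successor's size. Self-events
#' (equal size AND identical membership, i.e. nothing happened) are
#' excluded; merges or splits between clusters of equal size do count.
#' Node weight is the total count of incident edge events (self-loop edges
#' counted once).
#'
#' @param assignments List of `aggtraj_clusters`, one per frame (>= 2).
#' @return An `aggtraj_transition_network`: `nodes` (data.frame size,
#'   weight) and `edges` (data.frame from, to, count).
#' @export
track_transitions <- function(assignments) {
  if (length(assignments) < 2L) stop("need at least 2 frames")
  n <- assignments[[1]]$n_chains
  counts <- new.env(parent = emptyenv())
  for (t in seq_len(length(assignments) - 1L)) {
    a <- assignments[[t]]
    b <- assignments[[t + 1L]]
    if (b$n_chains != n) stop("inconsistent chain count at frame ", t + 1L)
    for (ip in seq_along(a$clusters)) {
      pred <- a$clusters[[ip]]
      succ_ids <- unique(b$membership[pred + 1L])
      for (is_ in succ_ids) {
        succ <- b$clusters[[is_]]
        if (length(pred) == length(succ) && all(pred == succ)) next
        key <- paste(length(pred), length(succ))
        counts[[key]] <- if (is.null(counts[[key]])) 1L else counts[[key]] + 1L
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0L) {
    return(new_transition_network(
      data.frame(size = integer(0), weight = integer(0)),
      data.frame(from = integer(0), to = integer(0), count = integer(0))))
  }
  parts <- do.call(rbind, strsplit(keys, " "))
  edges <- data.frame(from = as.integer(parts[, 1]),
                      to = as.integer(parts[, 2]),
                      count = vapply(keys, function(k) counts[[k]],
                                     integer(1), USE.NAMES = FALSE))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new_transition_network(node_weights(edges), edges)
}

# node weight = sum of counts of incident edges; self-loops counted once
node_weights <- function(edges) {
  sizes <- sort(unique(c(edges$from, edges$to)))
  weight <- vapply(sizes, function(s) {
    sum(edges$count[edges$from == s | edges$to == s])
  }, integer(1))
  data.frame(size = sizes, weight = weight)
}

#' Keep only the k most frequent transitions
#'
#' @param network An `aggtraj_transition_network`.
#' @param k Number of edges to keep (default 40); ties are broken by
#'   (from, to) lexicographic order. Node weights are recomputed on the
#'   kept edges.
#' @return A pruned `aggtraj_transition_network`.
#' @export
top_k_edges <- function(network, k = 40L) {
  if (k < 1L) stop("k must be >= 1")
  ed <- network$edges
  if (nrow(ed) <= k) return(network)
  ord <- order(-ed$count, ed$from, ed$to)
  kept <- ed[sort(ord[seq_len(k)]), , drop = FALSE]
  rownames(kept) <- NULL
  new_transition_network(node_weights(kept), kept)
}
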