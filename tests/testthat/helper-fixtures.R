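# Shared fixtures and independent oracles for the test suite.

# Independent union-find (path compression) used as the clustering oracle;
# deliberately a different algorithm family than the head-and-list
# implementation it checks.
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1] + 1L)
      rb <- find(edges[e, 2] + 1L)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n) - 1L, roots)
  comps <- lapply(comps, function(v) sort(as.integer(v)))
  unname(comps[order(vapply(comps, min, integer(1)))])
}

# Frame of n single-atom (or few-atom) chains at random positions.
random_chain_frame <- function(n_chains, atoms_per_chain = 1L,
                               box = c(60, 60, 60), seed = 1L) {
  set.seed(seed)
  n_atoms <- n_chains * atoms_per_chain
  atoms <- data.frame(
    name = rep("CA", n_atoms), element = "C",
    vdw_radius = 1.70, mass = 12.011,
    residue_index = rep(seq_len(atoms_per_chain), n_chains),
    residue_name = "ALA",
    chain_index = rep(seq_len(n_chains) - 1L, each = atoms_per_chain)
  )
  topo <- aggtraj_topology(atoms)
  xyz <- matrix(runif(3 * n_atoms, 0, box[1]), n_atoms, 3)
  # keep multi-atom chains compact so they are unambiguous units
  if (atoms_per_chain > 1L) {
    for (ch in seq_len(n_chains) - 1L) {
      rows <- chain_atom_indices(topo, ch)
      base <- xyz[rows[1], ]
      xyz[rows, ] <- matrix(base, length(rows), 3, byrow = TRUE) +
        matrix(runif(3 * length(rows), -1, 1), length(rows), 3)
    }
  }
  list(topology = topo, frame = aggtraj_frame(xyz, box, 0))
}

# Minimal two-chain topology of named atoms for constructed geometries.
toy_topology <- function(names, elements, chains,
                         residues = rep(1L, length(names)),
                         resnames = rep("ALA", length(names))) {
  atoms <- data.frame(
    name = names, element = elements,
    vdw_radius = unname(c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                          S = 1.80)[elements]),
    mass = unname(c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06)[elements]),
    residue_index = residues, residue_name = resnames,
    chain_index = chains
  )
  aggtraj_topology(atoms)
}

# Brute-force minimum-image distance (component-wise wrap written out
# independently of the package helper).
bf_min_image_dist <- function(p, q, box) {
  d <- p - q
  for (k in 1:3) {
    while (d[k] >= box[k] / 2) d[k] <- d[k] - box[k]
    while (d[k] < -box[k] / 2) d[k] <- d[k] + box[k]
  }
  sqrt(sum(d^2))
}

# Exhaustive all-pairs minimum inter-chain distance oracle.
bf_min_interchain <- function(frame, topology, a, b) {
  ia <- chain_atom_indices(topology, a)
  ib <- chain_atom_indices(topology, b)
  best <- Inf
  for (i in ia) {
    for (j in ib) {
      d <- bf_min_image_dist(frame$xyz[i, ], frame$xyz[j, ], frame$box)
      if (d < best) best <- d
    }
  }
  best
}

# Exhaustive contact-graph edge oracle.
bf_contact_edges <- function(frame, topology, cutoff) {
  n <- n_chains(topology)
  edges <- matrix(integer(0), ncol = 2)
  for (a in seq_len(n - 1L) - 1L) {
    for (b in (a + 1L):(n - 1L)) {
      if (bf_min_interchain(frame, topology, a, b) < cutoff) {
        edges <- rbind(edges, c(a, b))
      }
    }
  }
  edges
}

# Fabricate an aggtraj_clusters object (with contact graph) for tests of
# downstream statistics that do not need geometry.
fake_assignment <- function(clusters, n = NULL, edges = NULL) {
  clusters <- lapply(clusters, function(v) sort(as.integer(v)))
  clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  if (is.null(n)) n <- length(unlist(clusters))
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]] + 1L] <- k
  a <- structure(list(clusters = clusters,
                      sizes = lengths(clusters),
                      membership = membership, n_chains = n),
                 class = "aggtraj_clusters")
  if (!is.null(edges)) {
    attr(a, "graph") <- structure(
      list(n_chains = n, edges = edges, cutoff = 4.0),
      class = "aggtraj_contact_graph")
  }
  a
}

# Fabricate an ssmatrix from a list (frames) of lists (chains) of labels.
fake_ssmatrix <- function(labels, sequences = NULL) {
  labels <- lapply(labels, function(fr) {
    names(fr) <- as.character(seq_along(fr) - 1L)
    fr
  })
  structure(list(labels = labels, n_frames = length(labels),
                 n_chains = length(labels[[1]]), sequences = sequences),
            class = "aggtraj_ssmatrix")
}

write_toy_pdb <- function(path, two_models = FALSE, ter = TRUE,
                          second_model_atoms = 4L) {
  atom_line <- function(serial, name, resn, chain, resno, x, y, z, el) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, resn, chain, resno, x, y, z, el)
  }
  lines <- c("CRYST1   40.000   40.000   40.000  90.00  90.00  90.00 P 1")
  body <- function(shift, n_atoms = 4L) {
    b <- c(atom_line(1, "N", "ALA", "A", 1, 1 + shift, 2, 3, "N"),
           atom_line(2, "CA", "ALA", "A", 1, 2.4 + shift, 2, 3, "C"))
    if (ter) b <- c(b, "TER")
    extra <- c(atom_line(3, "N", "GLY", if (ter) "A" else "B", 1,
                         11 + shift, 12, 13, "N"),
               atom_line(4, "CA", "GLY", if (ter) "A" else "B", 1,
                         12.4 + shift, 12, 13, "C"))
    c(b, extra[seq_len(max(0L, n_atoms - 2L))])
  }
  if (two_models) {
    lines <- c(lines, "MODEL        1", body(0), "ENDMDL",
               "MODEL        2", body(0.1, second_model_atoms), "ENDMDL")
  } else {
    lines <- c(lines, body(0))
  }
  writeLines(c(lines, "END"), path)
  path
}
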