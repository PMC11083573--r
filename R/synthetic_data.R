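# Synthetic inputs with known ground truth: ideal backbones built from
# internal coordinates, beta sheets with a deterministic register search,
# scripted aggregation trajectories (rigid chains realizing a prescribed
# per-frame partition), and oriented rod bundles for the order parameter.

# Standard backbone internal coordinates (Angstrom / degrees).
BB_LEN_N_CA <- 1.458
BB_LEN_CA_C <- 1.525
BB_LEN_C_N <- 1.329
BB_LEN_C_O <- 1.231
BB_LEN_N_H <- 1.01
BB_ANG_C_N_CA <- 121.7
BB_ANG_N_CA_C <- 111.2
BB_ANG_CA_C_N <- 116.2
BB_ANG_CA_C_O <- 120.8

# Natural-extension-reference-frame placement: position D given A, B, C
# with bond |C-D|, angle B-C-D and torsion A-B-C-D (degrees).
nerf_place <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal peptide backbone from torsion angles
#'
#' Places N, CA, C, O (and amide H, from residue 2 on, except prolines)
#' for every residue using standard bond lengths (N-CA 1.458, CA-C 1.525,
#' C-N 1.329, C-O 1.231 Angstrom), standard angles, planar trans peptide
#' bonds (omega = 180 degrees) and the supplied phi/psi angles. The amide
#' hydrogen is placed 1.01 Angstrom from N along the O(i-1) -> C(i-1)
#' direction, the same convention the secondary-structure stage uses for
#' reconstruction.
#'
#' @param sequence One-letter amino-acid string.
#' @param phi,psi Backbone torsions in degrees; scalars are recycled.
#'   phi = -57, psi = -47 gives an alpha helix; phi = -139, psi = 135 an
#'   extended (beta) strand.
#' @return List: `xyz` (n_atoms x 3), `atoms` (data.frame as in
#'   [aggtraj_topology] minus chain_index).
#' @export
build_backbone <- function(sequence, phi = -57, psi = -47) {
  letters1 <- validate_sequence(sequence)
  n_res <- length(letters1)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  if (any(!is.finite(c(phi, psi)))) stop("phi/psi must be finite")
  resname <- unname(ONE_TO_THREE[letters1])
  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3)
  # residue 1 laid out in the xy-plane
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB_LEN_N_CA, 0, 0)
  ang <- BB_ANG_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BB_LEN_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           BB_LEN_C_N, BB_ANG_CA_C_N, psi[i - 1])
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            BB_LEN_N_CA, BB_ANG_C_N_CA, 180)
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           BB_LEN_CA_C, BB_ANG_N_CA_C, phi[i])
    }
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         BB_LEN_C_O, BB_ANG_CA_C_O, psi[i] + 180)
  }
  rows <- list()
  xyz <- list()
  for (i in seq_len(n_res)) {
    names_i <- c("N", "CA", "C", "O")
    coords_i <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (i > 1 && resname[i] != "PRO") {
      d <- C[i - 1, ] - O[i - 1, ]
      d <- d / sqrt(sum(d^2))
      names_i <- c(names_i, "H")
      coords_i <- rbind(coords_i, N[i, ] + BB_LEN_N_H * d)
    }
    el <- substr(names_i, 1, 1)
    rows[[i]] <- data.frame(
      name = names_i, element = el,
      vdw_radius = lookup_radius(el), mass = lookup_mass(el),
      residue_index = i, residue_name = resname[i],
      stringsAsFactors = FALSE
    )
    xyz[[i]] <- coords_i
  }
  list(xyz = do.call(rbind, xyz), atoms = do.call(rbind, rows))
}

# Assemble chains (each a build_backbone-style list) into topology + frame.
chains_to_system <- function(chains, box) {
  atoms <- list()
  xyz <- list()
  seqs <- character(length(chains))
  for (k in seq_along(chains)) {
    a <- chains[[k]]$atoms
    a$chain_index <- k - 1L
    atoms[[k]] <- a
    xyz[[k]] <- chains[[k]]$xyz
    res <- a[!duplicated(a$residue_index), ]
    seqs[k] <- paste(residue_one_letter(res$residue_name), collapse = "")
  }
  topology <- aggtraj_topology(do.call(rbind, atoms), seqs)
  list(topology = topology,
       frame = aggtraj_frame(do.call(rbind, xyz), aggtraj_box(box), 0))
}

# Rotation matrix about a unit axis by angle (radians).
rotation_matrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(theta); s <- sin(theta); C <- 1 - c_
  matrix(c(
    a[1]^2 * C + c_, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
    a[2] * a[1] * C + a[3] * s, a[2]^2 * C + c_, a[2] * a[3] * C - a[1] * s,
    a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3]^2 * C + c_
  ), 3, 3, byrow = TRUE)
}

#' Build an ideal multi-strand beta sheet
#'
#' Strands are ideal extended backbones (phi = -139, psi = 135). Each
#' added strand is placed next to the previous one at the requested
#' spacing and its register (axial shift, face flip, fine spacing) is
#' chosen by a deterministic grid search maximizing the number of
#' inter-strand Kabsch-Sander hydrogen bonds; ties resolve to the
#' smallest (flip, spacing, shift) triple, so the result is reproducible.
#'
#' @param n_strands Number of strands (>= 2).
#' @param length Residues per strand.
#' @param arrangement `"antiparallel"` (default) or `"parallel"`.
#' @param spacing Target inter-strand spacing in Angstrom (default 4.8).
#' @param sequence Residues to use (recycled); default all-valine.
#' @return List: `topology`, `frame` (box comfortably larger than the
#'   sheet), `n_hbonds` (inter-strand Kabsch-Sander bonds found).
#' @export
make_sheet <- function(n_strands, length = 8,
                       arrangement = c("antiparallel", "parallel"),
                       spacing = 4.8, sequence = NULL) {
  arrangement <- match.arg(arrangement)
  if (n_strands < 2L) stop("a sheet needs at least 2 strands")
  if (is.null(sequence)) {
    sequence <- paste(rep("V", length), collapse = "")
  }
  # standard strand torsions: antiparallel sheets are more extended than
  # parallel ones
  angles <- if (arrangement == "antiparallel") c(-139, 135) else c(-119, 113)
  strand <- build_backbone(sequence, phi = angles[1], psi = angles[2])
  # strand axis along the first principal direction; center at origin
  ctr <- colMeans(strand$xyz)
  strand$xyz <- sweep(strand$xyz, 2, ctr)
  ax <- eigen(crossprod(strand$xyz) / nrow(strand$xyz),
              symmetric = TRUE)$vectors[, 1]
  # rotate so the strand axis is x (about ax cross e1)
  v <- c(0, ax[3], -ax[2])
  s <- sqrt(sum(v^2))
  if (s > 1e-9) {
    theta <- acos(max(-1, min(1, ax[1])))
    strand$xyz <- strand$xyz %*% t(rotation_matrix(v / s, theta))
  }
  # two-strand scratch system reused across the register search
  pair_sys <- chains_to_system(list(strand, strand), rep(1e4, 3))
  pair_bt <- backbone_table(pair_sys$topology)
  n1 <- nrow(strand$xyz)
  count_hb <- function(xyz1, xyz2) {
    fr <- aggtraj_frame(rbind(xyz1, xyz2), pair_sys$frame$box, 0)
    HB <- ks_hbond_matrix(fr, pair_sys$topology, pair_bt)
    inter <- outer(pair_bt$chain, pair_bt$chain, "!=")
    sum(HB & inter)
  }
  flip_antiparallel <- arrangement == "antiparallel"
  # pair search: best placement of a new strand next to `prev_xyz`,
  # scanning face flip, fine spacing and axial register shift; `flip`
  # reverses the strand direction relative to the base orientation
  pair_search <- function(ref_xyz, prev_xyz, flip) {
    best <- NULL
    for (face in c(0, 180)) {
      R <- diag(3)
      if (flip) {
        R <- rotation_matrix(c(0, 1, 0), pi) %*% R  # reverse direction
      }
      if (face == 180) {
        R <- rotation_matrix(c(1, 0, 0), pi) %*% R  # other H-bond face
      }
      base <- ref_xyz %*% t(R)
      base <- sweep(base, 2, colMeans(base) - colMeans(prev_xyz))
      for (sp in seq(spacing - 0.6, spacing + 0.6, by = 0.2)) {
        for (shift in seq(-3.5, 3.5, by = 0.25)) {
          cand_xyz <- sweep(base, 2, c(shift, sp, 0), "+")
          if (min_pair_distance(prev_xyz, cand_xyz) < 2.0) next
          nhb <- count_hb(prev_xyz, cand_xyz)
          if (is.null(best) || nhb > best$nhb) {
            best <- list(xyz = cand_xyz, nhb = nhb)
          }
        }
      }
    }
    if (is.null(best)) stop("no clash-free strand placement found")
    best
  }
  # sheet-plane orientation of the template strand about its own axis:
  # pick the rotation maximizing first-pair hydrogen bonds (parallel
  # pleats only bond for particular orientations)
  best_orient <- NULL
  for (orient in seq(0, 150, by = 30)) {
    Ro <- rotation_matrix(c(1, 0, 0), orient * pi / 180)
    ref <- strand$xyz %*% t(Ro)
    hit <- pair_search(ref, ref, flip = flip_antiparallel)
    if (is.null(best_orient) || hit$nhb > best_orient$nhb) {
      best_orient <- list(ref = ref, nhb = hit$nhb, pair = hit)
    }
  }
  strand$xyz <- best_orient$ref
  placed <- list(strand,
                 list(xyz = best_orient$pair$xyz, atoms = strand$atoms))
  if (n_strands > 2L) {
    for (k in 3:n_strands) {
      # strand directions alternate in an antiparallel sheet
      flip_k <- flip_antiparallel && (k %% 2L == 0L)
      hit <- pair_search(strand$xyz, placed[[k - 1]]$xyz, flip = flip_k)
      placed[[k]] <- list(xyz = hit$xyz, atoms = strand$atoms)
    }
  }
  all_xyz <- do.call(rbind, lapply(placed, function(ch) ch$xyz))
  span <- apply(all_xyz, 2, function(v) diff(range(v)))
  L <- max(span) + 60
  shift_in <- -apply(all_xyz, 2, min) + 30
  placed <- lapply(placed, function(ch) {
    ch$xyz <- sweep(ch$xyz, 2, shift_in, "+")
    ch
  })
  sys <- chains_to_system(placed, rep(L, 3))
  total_nhb <- 0
  for (k in 2:n_strands) {
    total_nhb <- total_nhb + inter_strand_hbonds(placed[[k - 1]], placed[[k]])
  }
  c(sys, list(n_hbonds = total_nhb))
}

min_pair_distance <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

# Count Kabsch-Sander bonds between two strand objects (both directions),
# used by the register search. Non-periodic (isolated geometry).
inter_strand_hbonds <- function(s1, s2) {
  two <- chains_to_system(list(s1, s2), rep(1e4, 3))
  bt <- backbone_table(two$topology)
  HB <- ks_hbond_matrix(two$frame, two$topology, bt)
  inter <- outer(bt$chain, bt$chain, "!=")
  sum(HB & inter)
}

#' Aggregation script: scheduled cluster events with known ground truth
#'
#' @param n_chains Number of chains (default 20).
#' @param box Box edge lengths in Angstrom (default cubic 150, the
#'   15 nm box of the 20-peptide study systems).
#' @param n_frames Number of frames to realize (times 0, 100, 200, ... ps).
#' @param events List of events, each a list with `frame` (1-based frame
#'   at which the event takes effect) and `type` plus arguments:
#'   `merge(a, b)` joins the clusters containing chains `a` and `b`;
#'   `split(chain, parts)` splits the cluster containing `chain` into the
#'   given list of chain vectors; `exchange(chain, to)` moves `chain`
#'   into the cluster containing chain `to`.
#' @param seed Integer seed for the geometric jitter.
#' @return Object of class `aggtraj_aggregation_script`.
#' @export
aggregation_script <- function(n_chains = 20L, box = c(150, 150, 150),
                               n_frames = 10L, events = list(),
                               seed = 1L) {
  frames_of <- vapply(events, function(e) as.integer(e$frame), integer(1))
  if (length(frames_of) > 1L && is.unsorted(frames_of)) {
    stop("event frames must be non-decreasing")
  }
  if (any(frames_of > n_frames)) stop("event frame beyond n_frames")
  structure(list(n_chains = as.integer(n_chains), box = box,
                 n_frames = as.integer(n_frames), events = events,
                 seed = as.integer(seed)),
            class = "aggtraj_aggregation_script")
}

# Apply one scripted event to a partition (list of 0-based chain vectors).
apply_event <- function(partition, e) {
  find_cluster <- function(ch) {
    for (k in seq_along(partition)) if (ch %in% partition[[k]]) return(k)
    stop("chain ", ch, " not in any cluster")
  }
  if (e$type == "merge") {
    ka <- find_cluster(e$a); kb <- find_cluster(e$b)
    if (ka == kb) return(partition)
    partition[[ka]] <- sort(c(partition[[ka]], partition[[kb]]))
    partition[[kb]] <- NULL
  } else if (e$type == "split") {
    k <- find_cluster(e$chain)
    members <- partition[[k]]
    parts <- lapply(e$parts, function(p) sort(as.integer(p)))
    if (!identical(sort(unlist(parts)), sort(members))) {
      stop("split parts must partition the cluster containing chain ",
           e$chain)
    }
    partition[[k]] <- NULL
    partition <- c(partition, parts)
  } else if (e$type == "exchange") {
    kf <- find_cluster(e$chain); kt <- find_cluster(e$to)
    if (kf == kt) return(partition)
    partition[[kf]] <- setdiff(partition[[kf]], e$chain)
    partition[[kt]] <- sort(c(partition[[kt]], e$chain))
    if (length(partition[[kf]]) == 0L) partition[[kf]] <- NULL
  } else stop("unknown event type: ", e$type)
  # canonical order: by lowest member
  partition[order(vapply(partition, min, integer(1)))]
}

# Offset along a unit direction at which two copies of a rigid chain have
# minimum inter-copy atom distance equal to `target` (binary refinement of
# a coarse upward scan, so no monotonicity assumption is needed).
contact_offset <- function(xyz, target = 3.5, direction = c(1, 0, 0)) {
  mind <- function(t) {
    min_pair_distance(xyz, sweep(xyz, 2, t * direction, "+"))
  }
  t <- 0.5
  while (mind(t) < target) t <- t + 0.25
  lo <- t - 0.25; hi <- t
  for (k in 1:40) {
    mid <- (lo + hi) / 2
    if (mind(mid) < target) lo <- mid else hi <- mid
  }
  hi
}

#' Realize a scripted aggregation trajectory
#'
#' Chains are rigid copies of a template backbone. At every frame the
#' scripted partition is realized geometrically: the chains of a cluster
#' sit on consecutive sites of a compact lattice path with nearest-site
#' contacts of about 3.5 Angstrom (safely below the 4 Angstrom criterion,
#' with a small seeded jitter), clusters are mutually separated by more
#' than 12 Angstrom, each cluster gets a seeded random orientation, and
#' everything is wrapped into the periodic box.
#'
#' @param script An [aggregation_script].
#' @param template A [build_backbone]-style chain (default: the first
#'   8 residues of the 1-33 peptide as an ideal helix).
#' @param contact_distance Intra-cluster nearest-neighbor target
#'   (Angstrom, default 3.5).
#' @param min_separation Minimum distance between chains of different
#'   clusters (Angstrom, default 12).
#' @return List: `trajectory` (an [aggtraj_trajectory]) and `truth`
#'   (per-frame list of partitions, each a list of 0-based chain vectors
#'   ordered by lowest member).
#' @export
scripted_aggregation_trajectory <- function(script, template = NULL,
                                            contact_distance = 3.5,
                                            min_separation = 12) {
  if (is.null(template)) {
    template <- build_backbone(substr(blg_peptide("1-33"), 1, 8),
                               phi = -57, psi = -47)
  }
  template$xyz <- sweep(template$xyz, 2, colMeans(template$xyz))
  n <- script$n_chains
  box <- script$box
  # per-axis lattice spacings giving the target nearest-neighbor contact
  steps <- vapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  function(d) contact_offset(template$xyz,
                                             contact_distance, d),
                  numeric(1))
  partition <- lapply(seq_len(n) - 1L, function(ch) ch)
  truth <- vector("list", script$n_frames)
  frames <- vector("list", script$n_frames)
  ev_frames <- vapply(script$events, function(e) as.integer(e$frame),
                      integer(1))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  for (t in seq_len(script$n_frames)) {
    for (e in script$events[ev_frames == t]) {
      partition <- apply_event(partition, e)
    }
    truth[[t]] <- partition
    set.seed((script$seed * 7919L + t) %% 2147483647L)
    xyz_frame <- matrix(NA_real_, n * nrow(template$xyz), 3)
    n_atoms_chain <- nrow(template$xyz)
    # assemble each cluster on a boustrophedon lattice path
    cluster_coords <- vector("list", length(partition))
    radii <- numeric(length(partition))
    for (k in seq_along(partition)) {
      members <- partition[[k]]
      m <- length(members)
      g <- ceiling(m^(1 / 3))
      sites <- matrix(0, m, 3)
      idx <- 0L
      for (iz in seq_len(g)) {
        for (iy in seq_len(g)) {
          xs <- seq_len(g)
          if (iy %% 2 == 0) xs <- rev(xs)
          if (iz %% 2 == 0) xs <- rev(xs)
          for (ix in xs) {
            idx <- idx + 1L
            if (idx > m) break
            sites[idx, ] <- c(ix - 1, iy - 1, iz - 1) * steps
          }
          if (idx >= m) break
        }
        if (idx >= m) break
      }
      sites <- sites + matrix(runif(3 * m, -0.1, 0.1), m, 3)
      sites <- sweep(sites, 2, colMeans(sites))
      R <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
      coords <- lapply(seq_len(m), function(i) {
        sweep(template$xyz, 2, sites[i, ], "+") %*% t(R)
      })
      cluster_coords[[k]] <- coords
      all_c <- do.call(rbind, coords)
      radii[k] <- sqrt(max(rowSums(sweep(all_c, 2, colMeans(all_c))^2)))
    }
    # greedy packing of cluster bounding spheres: largest first, centers
    # drawn from a candidate lattice, minimum-image separation enforced
    n_cl <- length(partition)
    ng <- 8L
    cand <- as.matrix(expand.grid(x = seq_len(ng), y = seq_len(ng),
                                  z = seq_len(ng)))
    cand <- sweep(cand - 0.5, 2, box / ng, "*")
    order_big <- order(-radii)
    centers <- matrix(NA_real_, n_cl, 3)
    for (k in order_big) {
      placed_k <- which(!is.na(centers[, 1]))
      found <- FALSE
      for (p in seq_len(nrow(cand))) {
        ok <- TRUE
        for (q in placed_k) {
          d <- sqrt(sum(min_image_displacement(cand[p, ], centers[q, ],
                                               box)^2))
          if (d < radii[k] + radii[q] + min_separation + 1) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          centers[k, ] <- cand[p, ]
          found <- TRUE
          break
        }
      }
      if (!found) {
        stop("box too small to separate ", n_cl, " clusters by ",
             min_separation, " Angstrom")
      }
    }
    for (k in seq_along(partition)) {
      members <- partition[[k]]
      all_c <- do.call(rbind, cluster_coords[[k]])
      ctr <- colMeans(all_c)
      for (i in seq_along(members)) {
        ch <- members[i]
        rows <- ch * n_atoms_chain + seq_len(n_atoms_chain)
        xyz_frame[rows, ] <-
          sweep(cluster_coords[[k]][[i]], 2, centers[k, ] - ctr, "+")
      }
    }
    # wrap into [0, L)
    for (ax in 1:3) {
      xyz_frame[, ax] <- xyz_frame[, ax] %% box[ax]
    }
    frames[[t]] <- list(xyz = xyz_frame, time = (t - 1) * 100)
  }
  chains <- lapply(seq_len(n), function(i) template)
  sys <- chains_to_system(chains, box)
  traj <- aggtraj_trajectory(
    sys$topology,
    lapply(frames, function(fr) aggtraj_frame(fr$xyz, box, fr$time))
  )
  list(trajectory = traj, truth = truth)
}

#' Rod bundle with a prescribed aligned fraction
#'
#' Generates `n_chains` direction vectors: a fraction `f` share the z
#' axis, the rest are drawn uniformly on the sphere (seeded). As n grows
#' the nematic order parameter of the set converges to f.
#'
#' @param n_chains Number of chains.
#' @param aligned_fraction f in [0, 1].
#' @param seed Integer seed.
#' @return List: `vectors` (n x 3 unit rows), `expected_p2` (= f).
#' @export
rod_bundle <- function(n_chains, aligned_fraction, seed = 1L) {
  if (aligned_fraction < 0 || aligned_fraction > 1) {
    stop("aligned_fraction must be in [0, 1]")
  }
  n_aligned <- round(aligned_fraction * n_chains)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  vs <- matrix(0, n_chains, 3)
  if (n_aligned > 0) vs[seq_len(n_aligned), 3] <- 1
  n_iso <- n_chains - n_aligned
  if (n_iso > 0) {
    z <- stats::runif(n_iso, -1, 1)
    phi <- stats::runif(n_iso, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    vs[n_aligned + seq_len(n_iso), ] <- cbind(r * cos(phi), r * sin(phi), z)
  }
  list(vectors = vs, expected_p2 = aligned_fraction)
}

#' Shipped demonstration aggregation scripts
#'
#' Three scripts covering the event repertoire on the 20-chain study
#' system (150 Angstrom cubic box): `growth` (stepwise merging into one
#' large aggregate plus a stable small one), `competition` (two clusters
#' grow, one splits back), and `exchange` (a chain migrates between two
#' stable clusters). Ground truth for all pipeline recovery tests.
#'
#' @return Named list of [aggregation_script] objects.
#' @export
demo_aggregation_scripts <- function() {
  merge_ev <- function(frame, a, b) {
    list(frame = frame, type = "merge", a = a, b = b)
  }
  growth <- aggregation_script(
    n_chains = 20L, box = c(150, 150, 150), n_frames = 12L,
    events = c(
      lapply(1:7, function(k) merge_ev(k + 1L, 0L, k)),      # 8-chain core
      list(merge_ev(9L, 10L, 11L), merge_ev(10L, 10L, 12L),  # second cluster
           merge_ev(11L, 0L, 8L), merge_ev(12L, 0L, 9L))
    ),
    seed = 11L
  )
  competition <- aggregation_script(
    n_chains = 20L, box = c(150, 150, 150), n_frames = 10L,
    events = list(
      merge_ev(2L, 0L, 1L), merge_ev(2L, 2L, 3L),
      merge_ev(3L, 0L, 2L),                       # {0,1,2,3}
      merge_ev(4L, 10L, 11L), merge_ev(5L, 10L, 12L),
      merge_ev(6L, 0L, 4L),                       # {0..4}
      list(frame = 8L, type = "split", chain = 0L,
           parts = list(c(0L, 1L), c(2L, 3L, 4L)))
    ),
    seed = 12L
  )
  exchange <- aggregation_script(
    n_chains = 20L, box = c(150, 150, 150), n_frames = 8L,
    events = list(
      merge_ev(2L, 0L, 1L), merge_ev(2L, 0L, 2L),
      merge_ev(3L, 5L, 6L), merge_ev(3L, 5L, 7L),
      list(frame = 5L, type = "exchange", chain = 2L, to = 5L),
      list(frame = 7L, type = "exchange", chain = 2L, to = 0L)
    ),
    seed = 13L
  )
  list(growth = growth, competition = competition, exchange = exchange)
}

#' Molar concentration of n chains in a periodic box
#'
#' n / (N_A * V), reported in mmol/L.
#'
#' @param n_chains Number of solute copies.
#' @param box An [aggtraj_box] or three edge lengths (Angstrom).
#' @return Concentration in mmol/L.
#' @export
molar_concentration <- function(n_chains, box) {
  if (!inherits(box, "aggtraj_box")) box <- aggtraj_box(box)
  v_l <- prod(box) * 1e-27  # Angstrom^3 -> liters
  1000 * n_chains / (6.02214076e23 * v_l)
}
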