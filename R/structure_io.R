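# Reading topologies/trajectories (PDB, GRO, and a plain-text per-frame
# XYZB dialect) and writing analysis outputs (TSV / JSON).

# Bondi van der Waals radii (Angstrom) for the elements occurring in
# peptides; used for contact geometry and Shrake-Rupley surface areas.
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80)

ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

#' Infer an element symbol from a PDB atom name
#'
#' Follows the PDB convention: leading digits are stripped (e.g. "1HB" is a
#' hydrogen), then the leading alphabetic character names the element.
#' Only the peptide elements H, C, N, O, S are recognized.
#'
#' @param name Character vector of atom names.
#' @return Character vector of element symbols.
#' @export
infer_element <- function(name) {
  core <- sub("^[0-9']+", "", trimws(name))
  el <- toupper(substr(core, 1L, 1L))
  bad <- !(el %in% names(BONDI_RADII))
  if (any(bad)) {
    stop("cannot infer element for atom name(s): ",
         paste(unique(name[bad]), collapse = ", "))
  }
  el
}

lookup_radius <- function(element, radii = BONDI_RADII) {
  r <- radii[element]
  if (any(is.na(r))) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

lookup_mass <- function(element) {
  m <- ELEMENT_MASSES[element]
  if (any(is.na(m))) {
    stop("no mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

ONE_TO_THREE <- structure(names(THREE_TO_ONE), names = unname(THREE_TO_ONE))

residue_one_letter <- function(resname) {
  one <- THREE_TO_ONE[toupper(resname)]
  if (any(is.na(one))) {
    stop("unknown residue name(s): ",
         paste(unique(resname[is.na(one)]), collapse = ", "))
  }
  unname(one)
}

# Derive per-chain one-letter sequences from the atom table.
sequences_from_atoms <- function(atoms) {
  vapply(sort(unique(atoms$chain_index)), function(ch) {
    a <- atoms[atoms$chain_index == ch, , drop = FALSE]
    res <- a[!duplicated(a$residue_index), , drop = FALSE]
    res <- res[order(res$residue_index), , drop = FALSE]
    paste(residue_one_letter(res$residue_name), collapse = "")
  }, character(1))
}

# Renumber residues 1..k within each chain, preserving order of appearance.
renumber_residues <- function(resno, chain_index) {
  out <- integer(length(resno))
  for (ch in unique(chain_index)) {
    sel <- chain_index == ch
    key <- match(resno[sel], unique(resno[sel]))
    out[sel] <- key
  }
  out
}

# --- PDB ------------------------------------------------------------------

# Scan raw PDB lines for structure bio3d does not expose: the CRYST1 box,
# TER-based chain breaks, and per-MODEL atom-count consistency.
scan_pdb_records <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_ter <- startsWith(rec, "TER")
  is_model <- startsWith(rec, "MODEL")
  is_end <- startsWith(rec, "ENDMDL")
  box <- NULL
  cl <- lines[startsWith(rec, "CRYST1")]
  if (length(cl) > 0) {
    v <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33)))
    ang <- suppressWarnings(as.numeric(c(substr(cl[1], 34, 40),
                                         substr(cl[1], 41, 47),
                                         substr(cl[1], 48, 54))))
    if (any(is.finite(ang)) && any(abs(ang[is.finite(ang)] - 90) > 1e-6)) {
      stop("triclinic box in CRYST1 record; only orthorhombic boxes ",
           "are supported")
    }
    if (all(is.finite(v)) && all(v > 0)) box <- v
  }
  n_models <- sum(is_model)
  if (n_models > 0) {
    model_id <- cumsum(is_model)
    counts <- tabulate(model_id[is_atom], nbins = n_models)
    if (length(unique(counts)) > 1L) {
      stop("inconsistent atom count across MODEL records: ",
           paste(unique(counts), collapse = " vs "))
    }
  }
  # chain-break group per atom record of the FIRST model: increment on TER
  atom_lines <- which(is_atom)
  if (n_models > 1) {
    first_end <- which(is_end)[1]
    atom_lines <- atom_lines[atom_lines < first_end]
  }
  ter_breaks <- vapply(atom_lines, function(i) {
    sum(is_ter[seq_len(i)])
  }, integer(1))
  chain_id <- trimws(substr(lines[atom_lines], 22, 22))
  list(box = box, ter_group = ter_breaks, chain_id = chain_id,
       n_models = max(1L, n_models))
}

read_topology_pdb <- function(path) {
  lines <- readLines(path)
  meta <- scan_pdb_records(lines)
  pdb <- bio3d::read.pdb(path, multi = meta$n_models > 1, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no atoms in ", path)
  n_first <- length(meta$ter_group)
  at <- at[seq_len(n_first), , drop = FALSE]
  # chains: split on TER or on chain-ID change
  key <- paste(meta$ter_group, meta$chain_id)
  chain_index <- cumsum(c(TRUE, key[-1] != key[-n_first])) - 1L
  element <- at$elesy
  missing_el <- is.na(element) | trimws(element) == ""
  element[missing_el] <- infer_element(at$elety[missing_el])
  element <- toupper(trimws(element))
  unknown <- !(element %in% names(BONDI_RADII))
  if (any(unknown)) {
    stop("unsupported element(s) in ", path, ": ",
         paste(unique(element[unknown]), collapse = ", "))
  }
  atoms <- data.frame(
    name = trimws(at$elety),
    element = element,
    vdw_radius = lookup_radius(element),
    mass = lookup_mass(element),
    residue_index = renumber_residues(at$resno, chain_index),
    residue_name = toupper(trimws(at$resid)),
    chain_index = chain_index,
    stringsAsFactors = FALSE
  )
  topology <- aggtraj_topology(atoms, sequences_from_atoms(atoms))
  box <- if (is.null(meta$box)) {
    # fall back to a generous non-periodic bounding box
    span <- apply(pdb$xyz[1, , drop = TRUE] |>
                    matrix(ncol = 3, byrow = TRUE), 2, function(v) diff(range(v)))
    aggtraj_box(pmax(span, 1) + 1000)
  } else aggtraj_box(meta$box)
  xyz_all <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  list(topology = topology,
       frame = aggtraj_frame(xyz_all[seq_len(nrow(atoms)), , drop = FALSE],
                             box, 0),
       n_models = meta$n_models)
}

read_trajectory_pdb <- function(path, topology, dt = 100) {
  lines <- readLines(path)
  meta <- scan_pdb_records(lines)
  pdb <- bio3d::read.pdb(path, multi = meta$n_models > 1, verbose = FALSE)
  box <- if (is.null(meta$box)) {
    stop("trajectory PDB lacks a CRYST1 box record")
  } else aggtraj_box(meta$box)
  n_atoms <- nrow(topology$atoms)
  frames <- lapply(seq_len(nrow(pdb$xyz)), function(i) {
    xyz <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    if (nrow(xyz) != n_atoms) {
      stop("frame ", i, " has ", nrow(xyz), " atoms; topology has ", n_atoms)
    }
    aggtraj_frame(xyz, box, (i - 1) * dt)
  })
  aggtraj_trajectory(topology, frames)
}

# --- GRO ------------------------------------------------------------------

read_gro_frame <- function(lines, offset = 0L) {
  n <- as.integer(trimws(lines[offset + 2L]))
  if (is.na(n) || n <= 0L) stop("malformed GRO atom count")
  al <- lines[offset + 2L + seq_len(n)]
  if (length(al) < n || any(is.na(al))) stop("GRO file truncated")
  resno <- as.integer(substr(al, 1, 5))
  resname <- toupper(trimws(substr(al, 6, 10)))
  name <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28)) * 10 # nm -> Angstrom
  y <- as.numeric(substr(al, 29, 36)) * 10
  z <- as.numeric(substr(al, 37, 44)) * 10
  boxline <- as.numeric(strsplit(trimws(lines[offset + 3L + n]), "\\s+")[[1]])
  if (length(boxline) > 3 && any(abs(boxline[-(1:3)]) > 1e-9)) {
    stop("triclinic GRO box; only orthorhombic boxes are supported")
  }
  list(resno = resno, resname = resname, name = name,
       xyz = cbind(x, y, z), box = boxline[1:3] * 10, n = n,
       lines_used = n + 3L)
}

read_topology_gro <- function(path) {
  lines <- readLines(path)
  fr <- read_gro_frame(lines)
  # GRO has no chain field: new chain when the residue number does not
  # increase relative to the previous atom's residue
  chain_index <- cumsum(c(1L, diff(fr$resno) < 0L)) - 1L
  element <- infer_element(fr$name)
  atoms <- data.frame(
    name = fr$name, element = element,
    vdw_radius = lookup_radius(element), mass = lookup_mass(element),
    residue_index = renumber_residues(fr$resno, chain_index),
    residue_name = fr$resname, chain_index = chain_index,
    stringsAsFactors = FALSE
  )
  topology <- aggtraj_topology(atoms, sequences_from_atoms(atoms))
  list(topology = topology,
       frame = aggtraj_frame(fr$xyz, aggtraj_box(fr$box), 0),
       n_models = 1L)
}

# --- XYZB text dialect ----------------------------------------------------
# Per frame: header "t <time_ps> box <Lx> <Ly> <Lz>" (Angstrom), then one
# line per atom: "<chain> <resid> <resname> <atomname> <element> <x> <y> <z>".

parse_xyzb_header <- function(line) {
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(tok) != 6 || tok[1] != "t" || tok[3] != "box") {
    stop("malformed XYZB frame header: ", line)
  }
  list(time = as.numeric(tok[2]), box = as.numeric(tok[4:6]))
}

read_xyzb_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  i <- 1L
  n_atoms <- NA_integer_
  while (i <= length(lines)) {
    hdr <- parse_xyzb_header(lines[i])
    j <- i + 1L
    while (j <= length(lines) && !startsWith(trimws(lines[j]), "t ")) {
      j <- j + 1L
    }
    body <- lines[(i + 1L):(j - 1L)]
    if (i + 1L > j - 1L) stop("XYZB frame at line ", i, " has no atoms")
    tok <- strsplit(trimws(body), "\\s+")
    nf <- lengths(tok)
    if (any(nf != 8L)) {
      stop("malformed XYZB atom line (expect 8 fields) at frame starting line ", i)
    }
    m <- do.call(rbind, tok)
    if (is.na(n_atoms)) n_atoms <- nrow(m)
    if (nrow(m) != n_atoms) {
      stop("inconsistent atom count across XYZB frames: ",
           nrow(m), " vs ", n_atoms)
    }
    frames[[length(frames) + 1L]] <- list(
      time = hdr$time, box = hdr$box,
      chain = as.integer(m[, 1]), resid = as.integer(m[, 2]),
      resname = toupper(m[, 3]), name = m[, 4], element = toupper(m[, 5]),
      xyz = matrix(as.numeric(m[, 6:8]), ncol = 3)
    )
    i <- j
  }
  if (length(frames) == 0L) stop("no frames in ", path)
  frames
}

read_topology_xyzb <- function(path) {
  fr <- read_xyzb_frames(path)[[1]]
  atoms <- data.frame(
    name = fr$name, element = fr$element,
    vdw_radius = lookup_radius(fr$element),
    mass = lookup_mass(fr$element),
    residue_index = renumber_residues(fr$resid, fr$chain),
    residue_name = fr$resname, chain_index = fr$chain,
    stringsAsFactors = FALSE
  )
  topology <- aggtraj_topology(atoms, sequences_from_atoms(atoms))
  list(topology = topology,
       frame = aggtraj_frame(fr$xyz, aggtraj_box(fr$box), fr$time),
       n_models = NA_integer_)
}

#' Read a topology (plus first frame) from a structure file
#'
#' @param path Path to a PDB, GRO, or XYZB-text file.
#' @param format One of `"pdb"`, `"gro"`, `"xyzb"`; inferred from the file
#'   extension when missing.
#' @return A list with elements `topology` (an [aggtraj_topology]) and
#'   `frame` (the first coordinate frame).
#' @details PDB chains are split on chain-ID changes or TER records; GRO
#'   chains on residue-number restarts. Van der Waals radii come from the
#'   Bondi table (H 1.20, C 1.70, N 1.55, O 1.52, S 1.80 Angstrom); missing
#'   element fields are inferred from atom names by PDB convention.
#'   GRO coordinates (nm) are converted to Angstrom on input.
#' @export
read_topology <- function(path, format = c("auto", "pdb", "gro", "xyzb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro", xyzb = "xyzb",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  switch(format,
         pdb = read_topology_pdb(path),
         gro = read_topology_gro(path),
         xyzb = read_topology_xyzb(path))
}

#' Read a coordinate trajectory
#'
#' @param path Multi-model PDB or XYZB-text trajectory file.
#' @param topology The matching [aggtraj_topology] (from [read_topology]).
#' @param format `"pdb"` or `"xyzb"`; inferred from the extension by default.
#' @param dt Frame spacing in ps used when the format carries no time stamps
#'   (multi-model PDB); default 100 ps, the customary snapshot interval.
#' @return An [aggtraj_trajectory] with strictly increasing frame times.
#' @export
read_trajectory <- function(path, topology,
                            format = c("auto", "pdb", "xyzb"), dt = 100) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", xyzb = "xyzb",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "pdb") return(read_trajectory_pdb(path, topology, dt))
  raw <- read_xyzb_frames(path)
  n_atoms <- nrow(topology$atoms)
  frames <- lapply(raw, function(fr) {
    if (nrow(fr$xyz) != n_atoms) {
      stop("XYZB frame atom count ", nrow(fr$xyz),
           " does not match topology (", n_atoms, ")")
    }
    aggtraj_frame(fr$xyz, aggtraj_box(fr$box), fr$time)
  })
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("XYZB frame times must be increasing")
  aggtraj_trajectory(topology, frames)
}

#' Write a trajectory in the XYZB text dialect
#'
#' @param traj An [aggtraj_trajectory].
#' @param path Output file path.
#' @param digits Coordinate precision (decimal places); default 4.
#' @return `path`, invisibly.
#' @export
write_xyzb <- function(traj, path, digits = 4) {
  at <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%d %d %s %s %s %.", digits, "f %.", digits, "f %.",
                digits, "f")
  for (fr in traj$frames) {
    writeLines(sprintf("t %g box %g %g %g", fr$time,
                       fr$box[1], fr$box[2], fr$box[3]), con)
    writeLines(sprintf(fmt, at$chain_index, at$residue_index,
                       at$residue_name, at$name, at$element,
                       fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3]), con)
  }
  invisible(path)
}

# --- result writers -------------------------------------------------------

#' Write an analysis result to disk
#'
#' Tables are written as TSV with a deterministic column order and fixed
#' precision; transition networks as JSON node/edge lists; 2D histograms as
#' a TSV matrix with bin-edge header rows.
#'
#' @param x A data.frame, an `aggtraj_transition_network`, or an
#'   `aggtraj_histogram2d`.
#' @param path Output path.
#' @param digits Numeric precision for TSV floats (default 6 significant
#'   decimal places).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, digits = 6) {
  UseMethod("write_results")
}

#' @export
write_results.data.frame <- function(x, path, digits = 6) {
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- round(out[[j]], digits)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
write_results.aggtraj_transition_network <- function(x, path, digits = 6) {
  obj <- list(
    nodes = data.frame(size = x$nodes$size, weight = x$nodes$weight),
    edges = data.frame(from = x$edges$from, to = x$edges$to,
                       count = x$edges$count)
  )
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @export
write_results.aggtraj_histogram2d <- function(x, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#x_edges", format(x$x_edges, digits = 12)),
                   collapse = "\t"), con)
  writeLines(paste(c("#y_edges", format(x$y_edges, digits = 12)),
                   collapse = "\t"), con)
  utils::write.table(round(x$counts, digits), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back a transition network written by [write_results]
#' @param path JSON path.
#' @return An `aggtraj_transition_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_transition_network(as.data.frame(obj$nodes), as.data.frame(obj$edges))
}
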