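# Protonation-state and net-charge assignment from a fixed pKa rule.
#
# The MD systems this package analyzes were set up at pH 2, where the
# acidic side chains (Asp, Glu) and the C-terminus are protonated
# (neutral) and the basic sites carry +1. A hard threshold
# (protonated iff pH < pKa) yields the integer formal charges an MD
# topology needs; fractional Henderson-Hasselbalch occupancies and
# structure-based pKa shifts are deliberately out of scope.

#' Default side-chain and terminus pKa table
#'
#' Standard solution pKa values for ionizable sites: ASP 3.65, GLU 4.25,
#' HIS 6.0, CYS 8.3, TYR 10.5, LYS 10.5, ARG 12.5, N-terminus 8.0,
#' C-terminus 3.6.
#'
#' @return Named numeric vector of pKa values.
#' @export
default_pka_table <- function() {
  c(ASP = 3.65, GLU = 4.25, HIS = 6.0, CYS = 8.3, TYR = 10.5,
    LYS = 10.5, ARG = 12.5, NTERM = 8.0, CTERM = 3.6)
}

# Sites that carry +1 when protonated; all others carry -1 when
# deprotonated (acids) and 0 when protonated.
BASIC_SITES <- c("HIS", "LYS", "ARG", "NTERM")

ONE_TO_SITE <- c(D = "ASP", E = "GLU", H = "HIS", C = "CYS",
                 Y = "TYR", K = "LYS", R = "ARG")

#' N-terminal beta-lactoglobulin peptide sequences
#'
#' One-letter sequences of the fibril-forming N-terminal peptides of the
#' mature bovine beta-lactoglobulin chain (PDB 3npo numbering): residues
#' 1-33 and 1-52. These are the two peptides whose aggregation this
#' package's default analyses target.
#'
#' @param which `"1-33"` or `"1-52"`.
#' @return One-letter amino-acid string.
#' @export
blg_peptide <- function(which = c("1-33", "1-52")) {
  which <- match.arg(which)
  seq33 <- "LIVTQTMKGLDIQKVAGTWYSLAMAASDISLLD"
  if (which == "1-33") return(seq33)
  paste0(seq33, "AQSAPLRVYVEELKPTPEG")
}

validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) == 0L) {
    stop("sequence must be a nonempty one-letter string")
  }
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters1, unname(THREE_TO_ONE))
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  letters1
}

#' Assign protonation states and net charge at a given pH
#'
#' Every ionizable site (Asp, Glu, His, Cys, Tyr, Lys, Arg side chains plus
#' the two termini) is protonated iff `pH < pKa(site)`. Basic sites and the
#' N-terminus contribute +1 when protonated; acidic sites and the
#' C-terminus contribute -1 when deprotonated. At pH 2 this reproduces the
#' +3 and +5 net charges of the 1-33 and 1-52 peptides.
#'
#' @param sequence One-letter amino-acid string (or a FASTA file path; a
#'   path is recognized when the file exists).
#' @param pH Solution pH.
#' @param pka_table Named pKa vector; see [default_pka_table]. Partial
#'   overrides are merged over the default.
#' @return A list of class `aggtraj_protonation` with elements `sites`
#'   (data.frame: site, position, pka, protonated, charge) and
#'   `net_charge` (integer).
#' @export
assign_protonation <- function(sequence, pH, pka_table = NULL) {
  if (length(sequence) == 1L && file.exists(sequence)) {
    sequence <- read_fasta_sequence(sequence)
  }
  letters1 <- validate_sequence(sequence)
  pka <- default_pka_table()
  if (!is.null(pka_table)) pka[names(pka_table)] <- pka_table
  n <- length(letters1)
  side_pos <- which(letters1 %in% names(ONE_TO_SITE))
  site <- c("NTERM", unname(ONE_TO_SITE[letters1[side_pos]]), "CTERM")
  position <- c(1L, side_pos, n)
  pka_vals <- unname(pka[site])
  protonated <- pH < pka_vals
  charge <- ifelse(site %in% BASIC_SITES,
                   ifelse(protonated, 1L, 0L),
                   ifelse(protonated, 0L, -1L))
  sites <- data.frame(site = site, position = position, pka = pka_vals,
                      protonated = protonated, charge = charge,
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, net_charge = as.integer(sum(charge)),
                 pH = pH, sequence = paste(letters1, collapse = "")),
            class = "aggtraj_protonation")
}

#' @export
print.aggtraj_protonation <- function(x, ...) {
  cat(sprintf("protonation at pH %g: net charge %+d e (%d ionizable sites)\n",
              x$pH, x$net_charge, nrow(x$sites)))
  invisible(x)
}

#' Net charge as a function of pH
#'
#' Evaluates [assign_protonation] over a pH grid. The net charge is a
#' non-increasing step function of pH with steps only at table pKa values.
#'
#' @param sequence One-letter amino-acid string.
#' @param ph_grid Increasing numeric vector of pH values.
#' @param pka_table Optional pKa overrides.
#' @return data.frame with columns `pH`, `net_charge`.
#' @export
charge_vs_ph_profile <- function(sequence, ph_grid, pka_table = NULL) {
  if (length(ph_grid) == 0L) stop("pH grid must be nonempty")
  if (is.unsorted(ph_grid, strictly = TRUE)) {
    stop("pH grid must be strictly increasing")
  }
  data.frame(
    pH = ph_grid,
    net_charge = vapply(ph_grid, function(ph) {
      assign_protonation(sequence, ph, pka_table)$net_charge
    }, integer(1))
  )
}

#' Read the first sequence from a FASTA file
#' @param path FASTA file path.
#' @return One-letter sequence string.
#' @export
read_fasta_sequence <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  if (startsWith(lines[1], ">")) {
    stop_at <- which(startsWith(lines[-1], ">"))
    keep <- if (length(stop_at) > 0) lines[2:stop_at[1]] else lines[-1]
  } else keep <- lines
  seq <- gsub("\\s", "", paste(keep, collapse = ""))
  if (nchar(seq) == 0L) stop("no sequence in ", path)
  seq
}
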