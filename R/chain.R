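#' Construct a ChainStructure
#'
#' A `chain_structure` is the package's C-alpha-level model of one protein
#' chain: a one-letter sequence, an L x 3 matrix of C-alpha coordinates in
#' Angstrom, author residue numbers, and experimental metadata. It is the
#' container every downstream stage (alignment, TM-score, clustering,
#' conformational splitting) consumes.
#'
#' @param structure_id Identifier of the parent structure (e.g. a PDB id).
#' @param chain_id Chain identifier within the structure.
#' @param sequence One-letter amino-acid string over the 20 standard residues
#'   plus `"X"` for non-regular residues; uppercase.
#' @param ca_coords Numeric L x 3 matrix of C-alpha coordinates (Angstrom).
#' @param residue_numbers Integer vector of length L with author residue
#'   numbering (1-based source numbering preserved).
#' @param method Experimental method: one of `"xray"`, `"em"`, `"nmr"`,
#'   `"other"`.
#' @param resolution Resolution in Angstrom, or `NA` if not reported.
#' @param release_date ISO date string, or `NA`.
#' @param n_dropped_ca Number of residues dropped during parsing because they
#'   lacked a C-alpha atom (diagnostic only).
#'
#' @return An object of class `chain_structure`.
#' @export
chain_structure <- function(structure_id, chain_id, sequence, ca_coords,
                            residue_numbers = seq_len(nchar(sequence)),
                            method = c("xray", "em", "nmr", "other"),
                            resolution = NA_real_, release_date = NA_character_,
                            n_dropped_ca = 0L) {
  method <- match.arg(method)
  ca_coords <- as.matrix(ca_coords)
  storage.mode(ca_coords) <- "double"
  obj <- structure(list(
    structure_id = as.character(structure_id),
    chain_id = as.character(chain_id),
    sequence = toupper(as.character(sequence)),
    ca_coords = ca_coords,
    residue_numbers = as.integer(residue_numbers),
    method = method,
    resolution = as.numeric(resolution),
    release_date = as.character(release_date),
    n_dropped_ca = as.integer(n_dropped_ca)
  ), class = "chain_structure")
  validate_chain_structure(obj)
  obj
}

#' Validate a chain_structure's invariants
#'
#' Checks that sequence length, coordinate rows and residue numbers agree,
#' that coordinates are finite, and that the sequence uses the 21-letter
#' alphabet. Consecutive C-alpha distances above the chain-break threshold are
#' permitted (they are flagged by [chain_breaks()]), but non-finite
#' coordinates are not.
#'
#' @param x A `chain_structure`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_chain_structure <- function(x) {
  L <- nchar(x$sequence)
  if (nrow(x$ca_coords) != L || ncol(x$ca_coords) != 3)
    stop("chain_structure: sequence length (", L, ") != coordinate rows (",
         nrow(x$ca_coords), ") or coords not 3-column", call. = FALSE)
  if (length(x$residue_numbers) != L)
    stop("chain_structure: residue_numbers length mismatch", call. = FALSE)
  if (!all(is.finite(x$ca_coords)))
    stop("chain_structure: non-finite coordinates", call. = FALSE)
  bad <- setdiff(strsplit(x$sequence, "")[[1]], c(AA_ALPHABET, "X"))
  if (length(bad) > 0)
    stop("chain_structure: invalid sequence letters: ",
         paste(unique(bad), collapse = ""), call. = FALSE)
  invisible(x)
}

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

AA3_TO_1 <- c(ALA="A", ARG="R", ASN="N", ASP="D", CYS="C", GLN="Q", GLU="E",
              GLY="G", HIS="H", ILE="I", LEU="L", LYS="K", MET="M", PHE="F",
              PRO="P", SER="S", THR="T", TRP="W", TYR="Y", VAL="V",
              MSE="X", SEC="X", PYL="X", UNK="X")

AA1_TO_3 <- c(A="ALA", R="ARG", N="ASN", D="ASP", C="CYS", Q="GLN", E="GLU",
              G="GLY", H="HIS", I="ILE", L="LEU", K="LYS", M="MET", F="PHE",
              P="PRO", S="SER", T="THR", W="TRP", Y="TYR", V="VAL", X="UNK")

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> %s_%s  L=%d  method=%s  resolution=%s\n",
              x$structure_id, x$chain_id, chain_length(x), x$method,
              ifelse(is.na(x$resolution), "NA",
                     sprintf("%.2f", x$resolution))))
  invisible(x)
}

#' Chain length in residues
#' @param x A `chain_structure`.
#' @return Integer number of residues.
#' @export
chain_length <- function(x) nrow(x$ca_coords)

#' Unique identifier of a chain (`structure-id_chain-id`)
#' @param x A `chain_structure`.
#' @return Character scalar.
#' @export
chain_id <- function(x) paste0(x$structure_id, "_", x$chain_id)

#' Flag chain breaks from consecutive C-alpha distances
#'
#' A position i (2..L) is flagged as following a break when the distance
#' between C-alpha i-1 and i exceeds `break_dist`. Used for diagnostics and
#' by the automated curation step, never for corpus filtering.
#'
#' @param x A `chain_structure`.
#' @param break_dist Distance threshold in Angstrom (default 10).
#' @return Logical vector of length L; element 1 is always `FALSE`.
#' @export
chain_breaks <- function(x, break_dist = 10) {
  L <- chain_length(x)
  if (L < 2) return(logical(L))
  d <- sqrt(rowSums((x$ca_coords[-1, , drop = FALSE] -
                     x$ca_coords[-L, , drop = FALSE])^2))
  c(FALSE, d > break_dist)
}

#' Extract a sub-chain by residue indices
#'
#' @param x A `chain_structure`.
#' @param idx Integer vector of 1-based residue indices, strictly increasing.
#' @return A `chain_structure` containing exactly those residues, metadata
#'   inherited.
#' @export
subset_chain <- function(x, idx) {
  idx <- as.integer(idx)
  if (length(idx) == 0) stop("subset_chain: empty index set", call. = FALSE)
  if (any(idx < 1 | idx > chain_length(x)))
    stop("subset_chain: index out of range", call. = FALSE)
  if (is.unsorted(idx, strictly = TRUE))
    stop("subset_chain: indices must be strictly increasing", call. = FALSE)
  chain_structure(
    structure_id = x$structure_id, chain_id = x$chain_id,
    sequence = paste(strsplit(x$sequence, "")[[1]][idx], collapse = ""),
    ca_coords = x$ca_coords[idx, , drop = FALSE],
    residue_numbers = x$residue_numbers[idx],
    method = x$method, resolution = x$resolution,
    release_date = x$release_date, n_dropped_ca = x$n_dropped_ca
  )
}
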