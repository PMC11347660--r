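#' Global pairwise sequence alignment
#'
#' Needleman–Wunsch global alignment with affine gaps (via Biostrings),
#' returning the residue correspondence as an alignment map of 1-based index
#' pairs. A gap of length k costs `gap_open + k * gap_extend` (both given as
#' negative scores; the NCBI convention).
#'
#' @param seq_a,seq_b Amino-acid strings over the 20 standard letters plus
#'   `"X"`; non-empty.
#' @param gap_open Gap opening score (negative), default -11.
#' @param gap_extend Gap extension score per gap position (negative),
#'   default -1.
#' @param matrix Substitution matrix: `"blosum62"` (default) or `"identity"`
#'   (match = 1, mismatch = 0).
#'
#' @return An object of class `alignment_map`: list with `pairs` (n x 2
#'   integer matrix of 1-based indices into A and B), `n_identical`,
#'   `coverage_a`, `coverage_b`, `score`.
#' @export
global_align <- function(seq_a, seq_b, gap_open = -11, gap_extend = -1,
                         matrix = c("blosum62", "identity")) {
  matrix <- match.arg(matrix)
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("global_align: empty sequence", call. = FALSE)
  submat <- alignment_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, substitutionMatrix = submat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend),
    type = "global")
  # pattern()/subject() return the same gapped strings as
  # alignedPattern()/alignedSubject() for type = "global", with much less
  # S4 overhead
  ga <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  ia <- cumsum(ga != "-")
  ib <- cumsum(gb != "-")
  both <- ga != "-" & gb != "-"
  pairs <- cbind(i = ia[both], j = ib[both])
  n_identical <- sum(ga[both] == gb[both])
  new_alignment_map(pairs, n_identical,
                    nchar(seq_a), nchar(seq_b), Biostrings::score(pa))
}

# identity/coverage of the optimal global alignment(s) without materializing
# the residue correspondence (fast path for clustering, where only the counts
# matter). `seq_a` may be an AAStringSet: one vectorized call aligns every
# element against `seq_b` and all returned fields are vectors.
align_identity_stats <- function(seq_a, seq_b, gap_open = -11,
                                 gap_extend = -1) {
  seq_len_of <- function(s)
    if (is.character(s)) nchar(s)
    else if (methods::is(s, "XStringSet")) Biostrings::width(s)
    else length(s)
  la <- seq_len_of(seq_a); lb <- seq_len_of(seq_b)
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, substitutionMatrix = alignment_matrix("blosum62"),
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend),
    type = "global")
  n_id <- Biostrings::nmatch(pa)
  n_pairs <- n_id + Biostrings::nmismatch(pa)
  list(identity = n_id / pmin(la, lb),
       coverage_a = n_pairs / la,
       coverage_b = n_pairs / lb)
}

.matrix_cache <- new.env(parent = emptyenv())

alignment_matrix <- function(name) {
  if (!is.null(.matrix_cache[[name]])) return(.matrix_cache[[name]])
  m <- if (name == "identity") {
    letters21 <- c(AA_ALPHABET, "X")
    mm <- diag(1, 21)
    dimnames(mm) <- list(letters21, letters21)
    mm
  } else {
    # BLOSUM62 shipped with Biostrings
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  }
  assign(name, m, envir = .matrix_cache)
  m
}

new_alignment_map <- function(pairs, n_identical, len_a, len_b, score = NA) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  structure(list(
    pairs = pairs,
    n_identical = as.integer(n_identical),
    len_a = as.integer(len_a), len_b = as.integer(len_b),
    coverage_a = nrow(pairs) / len_a,
    coverage_b = nrow(pairs) / len_b,
    score = score
  ), class = "alignment_map")
}

#' Identity-correspondence alignment map for equal-length chains
#'
#' Convenience constructor pairing residue i of A with residue i of B, with
#' `n_identical` counted from the sequences. Used when two structures share
#' the same residue indexing (e.g. extracted aligned regions).
#'
#' @param seq_a,seq_b Equal-length sequences.
#' @return An `alignment_map`.
#' @export
identity_alignment <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("identity_alignment: unequal lengths", call. = FALSE)
  L <- nchar(seq_a)
  n_id <- sum(strsplit(seq_a, "")[[1]] == strsplit(seq_b, "")[[1]])
  new_alignment_map(cbind(seq_len(L), seq_len(L)), n_id, L, L)
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("<alignment_map> %d pairs, %d identical, coverage %.2f/%.2f\n",
              nrow(x$pairs), x$n_identical, x$coverage_a, x$coverage_b))
  invisible(x)
}

#' Fraction sequence identity of an alignment
#'
#' @param aln An `alignment_map`.
#' @param denominator `"shorter_seq"` (default; the convention of common
#'   clustering tools) or `"aligned_columns"`.
#' @return Fraction in `[0, 1]`.
#' @export
sequence_identity <- function(aln,
                              denominator = c("shorter_seq", "aligned_columns")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "shorter_seq") min(aln$len_a, aln$len_b)
         else nrow(aln$pairs)
  if (den == 0) stop("sequence_identity: zero-length denominator", call. = FALSE)
  aln$n_identical / den
}

#' Extract the aligned region of a chain as a sub-chain
#'
#' @param chain A [chain_structure()].
#' @param aln An `alignment_map` in which this chain is side `"a"` or `"b"`.
#' @param side Which side of the alignment `chain` is.
#' @return A `chain_structure` containing exactly the aligned residues, order
#'   preserved, metadata inherited.
#' @export
extract_aligned_region <- function(chain, aln, side = c("a", "b")) {
  side <- match.arg(side)
  if (nrow(aln$pairs) == 0)
    stop("extract_aligned_region: empty alignment", call. = FALSE)
  idx <- aln$pairs[, if (side == "a") 1 else 2]
  subset_chain(chain, idx)
}
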