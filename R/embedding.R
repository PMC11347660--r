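#' Construct an embedding pair
#'
#' Holds the single-sequence embeddings (L x d matrices) and pair embeddings
#' (L x L x c arrays) of two predictions of the same target, intercepted
#' before a predictor's structure module.
#'
#' @param single_a,single_b L x d numeric matrices.
#' @param pair_a,pair_b L x L x c numeric arrays (optional, may be `NULL`).
#' @return An object of class `embedding_pair`.
#' @export
embedding_pair <- function(single_a, single_b, pair_a = NULL, pair_b = NULL) {
  single_a <- as.matrix(single_a); single_b <- as.matrix(single_b)
  if (!identical(dim(single_a), dim(single_b)))
    stop("embedding_pair: single embedding shapes differ", call. = FALSE)
  if (!all(is.finite(single_a)) || !all(is.finite(single_b)))
    stop("embedding_pair: non-finite single embeddings", call. = FALSE)
  if (!is.null(pair_a)) {
    if (!identical(dim(pair_a), dim(pair_b)))
      stop("embedding_pair: pair embedding shapes differ", call. = FALSE)
    if (length(dim(pair_a)) != 3 || dim(pair_a)[1] != dim(pair_a)[2] ||
        dim(pair_a)[1] != nrow(single_a))
      stop("embedding_pair: pair embeddings must be L x L x c", call. = FALSE)
  }
  structure(list(single_a = single_a, single_b = single_b,
                 pair_a = pair_a, pair_b = pair_b,
                 length = nrow(single_a)),
            class = "embedding_pair")
}

#' Cosine similarity of two single-sequence embeddings
#'
#' Two conventions for the length-normalized cosine similarity
#' `A.B / (|A| |B|) * 1/L` of L x d embeddings:
#' `per_residue_mean` (default) averages the per-residue (row-wise) cosines,
#' yielding a calibrated score in `[-1, 1]`; `frobenius_over_L` is the literal
#' flattened-tensor reading, bounded by `[-1/L, 1/L]`.
#'
#' @param p An `embedding_pair`.
#' @param convention `"per_residue_mean"` or `"frobenius_over_L"`.
#' @return Scalar similarity with attribute `"convention"`.
#' @export
single_embedding_similarity <- function(p,
    convention = c("per_residue_mean", "frobenius_over_L")) {
  convention <- match.arg(convention)
  a <- p$single_a; b <- p$single_b
  if (convention == "per_residue_mean") {
    na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
    zero <- which(na == 0 | nb == 0)
    if (length(zero))
      stop("single_embedding_similarity: zero-norm row(s): ",
           paste(zero, collapse = ", "), call. = FALSE)
    val <- mean(rowSums(a * b) / (na * nb))
  } else {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0)
      stop("single_embedding_similarity: zero-norm embedding", call. = FALSE)
    val <- sum(a * b) / (na * nb) / p$length
  }
  attr(val, "convention") <- convention
  val
}

#' Mean elementwise difference of two pair embeddings
#'
#' `(1/n) * sum(sqrt((C - D)^2))` over all n elements — the mean absolute
#' elementwise difference. A root-mean-square variant is available for
#' sensitivity checks.
#'
#' @param p An `embedding_pair` with pair tensors.
#' @param rms If `TRUE`, return `sqrt(mean((C - D)^2))` instead.
#' @return Non-negative scalar; 0 iff the tensors are identical.
#' @export
pair_embedding_difference <- function(p, rms = FALSE) {
  if (is.null(p$pair_a) || is.null(p$pair_b))
    stop("pair_embedding_difference: no pair embeddings present",
         call. = FALSE)
  if (!identical(dim(p$pair_a), dim(p$pair_b)))
    stop("pair_embedding_difference: shape mismatch", call. = FALSE)
  if (rms) sqrt(mean((p$pair_a - p$pair_b)^2))
  else mean(abs(p$pair_a - p$pair_b))
}

#' Association between embedding differences and structural outcomes
#'
#' Spearman rank correlation (average ranks on ties) between per-target
#' embedding differences and TM-score outcomes, with a permutation p-value
#' from seeded label permutations (two-sided on |rho|).
#'
#' @param deltas Numeric vector of embedding differences.
#' @param outcomes Paired numeric vector of TM-scores.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return List with `rho`, `p_value`, `degenerate` (TRUE when either input
#'   is constant, in which case `rho` is `NA`).
#' @export
embedding_structure_association <- function(deltas, outcomes,
                                            n_perm = 10000, seed = 1) {
  if (length(deltas) != length(outcomes) || length(deltas) < 5)
    stop("embedding_structure_association: need >= 5 paired values",
         call. = FALSE)
  if (stats::sd(deltas) == 0 || stats::sd(outcomes) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, degenerate = TRUE))
  rd <- rank(deltas); ro <- rank(outcomes)
  rho <- stats::cor(rd, ro)
  set.seed(as.integer(seed))
  perm <- replicate(n_perm, stats::cor(rd, sample(ro)))
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_value = p, degenerate = FALSE)
}

#' Write / read an embedding tensor as a portable binary array
#'
#' Row-major little-endian float64 with a JSON sidecar (`<path>.json`)
#' holding the dimensions, so tensors can be exchanged with numpy-style
#' tooling without a network dependency.
#'
#' @param x Numeric array (any number of dimensions).
#' @param path Output path (sidecar written to `paste0(path, ".json")`).
#' @return `write_embedding_array`: `path` invisibly; `read_embedding_array`:
#'   the array with its dimensions restored.
#' @export
write_embedding_array <- function(x, path) {
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  # row-major serialization: transpose index order
  perm <- rev(seq_along(dims))
  flat <- if (length(dims) > 1) as.numeric(aperm(array(x, dims), perm))
          else as.numeric(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(flat, con, size = 8, endian = "little")
  jsonlite::write_json(list(shape = dims, dtype = "float64",
                            order = "C"),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_embedding_array
#' @export
read_embedding_array <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  flat <- readBin(con, "double", n = prod(dims), size = 8, endian = "little")
  if (length(dims) == 1) return(flat)
  aperm(array(flat, rev(dims)), rev(seq_along(dims)))
}
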