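#' Greedy sequence-identity clustering
#'
#' Incremental greedy centroid clustering in the style of CD-HIT/MMseqs2
#' cluster semantics: sequences are visited longest-first (ties broken by
#' lexicographic id); each sequence joins the first existing cluster whose
#' representative it matches at `>= min_identity` with coverage of the member
#' (shorter/target) side `>= min_coverage`, otherwise it founds a new cluster.
#' Deterministic for fixed input. This emulates the threshold semantics of
#' `mmseqs easy-cluster --min-seq-id X -c 0.8 --cov-mode 1`; exact
#' reproduction of MMseqs2 output is a non-goal.
#'
#' @param records data.frame with columns `id` (unique) and `sequence`, or a
#'   named character vector of sequences.
#' @param min_identity Minimum fraction identity to the representative
#'   (identity over the shorter sequence).
#' @param min_coverage Minimum fraction of the member sequence covered by the
#'   alignment (default 0.8).
#' @return List of `sequence_cluster` objects: list(`cluster_id`,
#'   `representative_id`, `member_ids`, `identity_threshold`,
#'   `coverage_threshold`).
#' @export
greedy_sequence_cluster <- function(records, min_identity,
                                    min_coverage = 0.8) {
  if (is.character(records))
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(records$id))
    stop("greedy_sequence_cluster: duplicate ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "),
         call. = FALSE)
  ord <- order(-nchar(records$sequence), records$id)
  records <- records[ord, , drop = FALSE]
  seqs <- Biostrings::AAStringSet(records$sequence)
  reps <- character(0); rep_rows <- integer(0)
  members <- list()
  for (k in seq_len(nrow(records))) {
    id <- records$id[k]
    placed <- FALSE
    if (length(reps) > 0) {
      # one vectorized alignment of the member against every representative,
      # in founding order; the member joins the first that qualifies
      st <- align_identity_stats(seqs[rep_rows], seqs[[k]])
      hit <- which(st$coverage_b >= min_coverage &
                     st$identity >= min_identity)
      if (length(hit) > 0) {
        c <- hit[1]
        members[[c]] <- c(members[[c]], id)
        placed <- TRUE
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      rep_rows <- c(rep_rows, k)
      members[[length(reps)]] <- id
    }
  }
  lapply(seq_along(reps), function(c) structure(list(
    cluster_id = sprintf("seq%03d_%s", c, reps[c]),
    representative_id = reps[c],
    member_ids = members[[c]],
    identity_threshold = min_identity,
    coverage_threshold = min_coverage
  ), class = "sequence_cluster"))
}

#' TM-threshold structural clustering within a sequence cluster
#'
#' Greedy representative scheme: members are visited longest-first; each
#' joins the first structural cluster whose representative it matches at
#' `tm_min >= tm_threshold` (TM normalized by the longer chain, the
#' conservative choice), otherwise it founds a new cluster. Structures whose
#' pairwise alignment fails preconditions against every representative they
#' are tested against are reported as unclusterable rather than raising,
#' mirroring a corpus in which a fraction of structures cannot be aligned.
#'
#' @param members List of [chain_structure()] objects from one sequence
#'   cluster.
#' @param tm_threshold Minimum `tm_min` to the representative (default 0.8).
#' @param parent_cluster_id Optional id of the parent sequence cluster.
#' @return List with `clusters` (list of `structural_cluster`: `cluster_id`,
#'   `parent_sequence_cluster_id`, `representative_id`, `member_ids`,
#'   `tm_threshold`) and `unclusterable` (character vector of ids).
#' @export
structural_cluster <- function(members, tm_threshold = 0.8,
                               parent_cluster_id = NA_character_) {
  ids <- vapply(members, chain_id, character(1))
  ord <- order(-vapply(members, chain_length, integer(1)), ids)
  members <- members[ord]; ids <- ids[ord]
  rep_idx <- integer(0)
  cl_members <- list()
  unclusterable <- character(0)
  for (k in seq_along(members)) {
    placed <- FALSE; failed <- 0L
    for (c in seq_along(rep_idx)) {
      s <- tryCatch(
        structural_align(members[[rep_idx[c]]], members[[k]])$superposition,
        error = function(e) NULL)
      if (is.null(s)) { failed <- failed + 1L; next }
      if (s$tm_min >= tm_threshold) {
        cl_members[[c]] <- c(cl_members[[c]], ids[k])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      if (length(rep_idx) > 0 && failed == length(rep_idx)) {
        # could not be aligned against any representative
        unclusterable <- c(unclusterable, ids[k])
      } else {
        rep_idx <- c(rep_idx, k)
        cl_members[[length(rep_idx)]] <- ids[k]
      }
    }
  }
  clusters <- lapply(seq_along(rep_idx), function(c) structure(list(
    cluster_id = sprintf("%s.str%02d", parent_cluster_id, c),
    parent_sequence_cluster_id = parent_cluster_id,
    representative_id = ids[rep_idx[c]],
    member_ids = cl_members[[c]],
    tm_threshold = tm_threshold
  ), class = "structural_cluster"))
  list(clusters = clusters, unclusterable = unclusterable)
}

#' Summarize a list of clusters
#'
#' @param clusters List of `sequence_cluster` or `structural_cluster` objects.
#' @return data.frame with one row per cluster (`cluster_id`, `size`,
#'   `representative`), ordered by decreasing size then id, plus attributes
#'   `total_members` and `n_multi_member`.
#' @export
cluster_summary <- function(clusters) {
  if (length(clusters) == 0) {
    out <- data.frame(cluster_id = character(0), size = integer(0),
                      representative = character(0))
    attr(out, "total_members") <- 0L
    attr(out, "n_multi_member") <- 0L
    return(out)
  }
  out <- do.call(rbind, lapply(clusters, function(cl) data.frame(
    cluster_id = cl$cluster_id, size = length(cl$member_ids),
    representative = cl$representative_id, stringsAsFactors = FALSE)))
  out <- out[order(-out$size, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_members") <- sum(out$size)
  attr(out, "n_multi_member") <- sum(out$size > 1)
  out
}

#' Write cluster assignments as TSV
#'
#' @param clusters List of cluster objects.
#' @param path Output TSV path.
#' @param tier Label written in the `tier` column (e.g. `"seq30"`, `"seq90"`,
#'   `"structural"`).
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clusters, path, tier) {
  rows <- do.call(rbind, lapply(clusters, function(cl) data.frame(
    member_id = cl$member_ids, cluster_id = cl$cluster_id,
    representative_id = cl$representative_id, tier = tier,
    stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(member_id = character(0), cluster_id = character(0),
                       representative_id = character(0), tier = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
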