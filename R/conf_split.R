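#' Find 90%-identity clusters spanning several structural clusters
#'
#' Candidate carriers of alternative conformations are the high-identity
#' (90%) sequence clusters whose members fall into at least two different
#' structural clusters: near-identical sequences solved in structurally
#' distinct states.
#'
#' @param seq90_clusters List of `sequence_cluster` objects (90% tier).
#' @param struct_clusters List of `structural_cluster` objects covering the
#'   same structures.
#' @return data.frame with columns `seq90_cluster_id` and
#'   `struct_cluster_ids` (list-column), one row per candidate.
#' @export
detect_candidate_clusters <- function(seq90_clusters, struct_clusters) {
  member2struct <- member_to_cluster_map(struct_clusters)
  rows <- list()
  for (sc in seq90_clusters) {
    scl <- member2struct[sc$member_ids]
    if (anyNA(scl))
      stop("detect_candidate_clusters: structures without structural cluster: ",
           paste(sc$member_ids[is.na(scl)], collapse = ", "), call. = FALSE)
    u <- sort(unique(scl))
    if (length(u) >= 2)
      rows[[length(rows) + 1]] <-
        data.frame(seq90_cluster_id = sc$cluster_id,
                   struct_cluster_ids = I(list(u)),
                   stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(seq90_cluster_id = character(0),
               struct_cluster_ids = I(list()))
}

member_to_cluster_map <- function(clusters) {
  ids <- unlist(lapply(clusters, `[[`, "member_ids"))
  cl <- rep(vapply(clusters, `[[`, character(1), "cluster_id"),
            vapply(clusters, function(c) length(c$member_ids), integer(1)))
  stats::setNames(cl, ids)
}

#' Score a putative conformer pair on its aligned region
#'
#' Aligns the two sequences globally, extracts the aligned region on each
#' side, and computes the TM-score (minimum normalization) on the regions
#' alone. Two structures whose aligned regions still differ (TM below
#' `alt_threshold`, i.e. more than 0.2 from self-identity at the default) are
#' putative alternative conformations; differences confined to unaligned
#' termini are excluded by construction.
#'
#' @param a,b [chain_structure()] objects sharing a 90% sequence cluster.
#' @param alt_threshold Aligned-region TM below which the pair counts as
#'   alternative (default 0.8).
#' @param struct_cluster_a,struct_cluster_b Optional structural-cluster ids
#'   recorded in the result.
#' @param seq90_cluster_id Optional 90% cluster id recorded in the result.
#' @return An object of class `conformer_pair`: list with `id_a`, `id_b`,
#'   `seq90_cluster_id`, `struct_cluster_a`, `struct_cluster_b`,
#'   `overlap_length`, `overlap_fraction` (of the shorter chain),
#'   `tm_aligned_region` (tm_min on the regions), `is_alternative`,
#'   `change_type` (initially `"unassigned"`).
#' @export
score_conformer_pair <- function(a, b, alt_threshold = 0.8,
                                 struct_cluster_a = NA_character_,
                                 struct_cluster_b = NA_character_,
                                 seq90_cluster_id = NA_character_) {
  aln <- global_align(a$sequence, b$sequence)
  if (nrow(aln$pairs) < 5)
    stop("score_conformer_pair: fewer than 5 aligned positions", call. = FALSE)
  ra <- extract_aligned_region(a, aln, "a")
  rb <- extract_aligned_region(b, aln, "b")
  sup <- tm_score(ra$ca_coords, rb$ca_coords,
                  identity_alignment(ra$sequence, rb$sequence))
  structure(list(
    id_a = chain_id(a), id_b = chain_id(b),
    seq90_cluster_id = seq90_cluster_id,
    struct_cluster_a = struct_cluster_a, struct_cluster_b = struct_cluster_b,
    overlap_length = nrow(aln$pairs),
    overlap_fraction = nrow(aln$pairs) / min(chain_length(a), chain_length(b)),
    tm_aligned_region = sup$tm_min,
    is_alternative = sup$tm_min < alt_threshold,
    change_type = "unassigned",
    alt_threshold = alt_threshold
  ), class = "conformer_pair")
}

#' @export
print.conformer_pair <- function(x, ...) {
  cat(sprintf(
    "<conformer_pair> %s vs %s  overlap=%d (%.2f)  tm_region=%.3f  alt=%s\n",
    x$id_a, x$id_b, x$overlap_length, x$overlap_fraction,
    x$tm_aligned_region, x$is_alternative))
  invisible(x)
}

#' Select one representative pair per structural-cluster pair
#'
#' Within each 90% cluster and each unordered pair of structural clusters,
#' keeps the scored pair maximizing `(overlap_fraction,
#' 1 - tm_aligned_region)` lexicographically (longest overlap first, then
#' biggest TM difference), ties broken by lexicographic ids.
#'
#' @param pairs List of `conformer_pair` objects.
#' @return Filtered list of `conformer_pair` objects.
#' @export
select_representatives <- function(pairs) {
  if (length(pairs) == 0) return(pairs)
  key <- vapply(pairs, function(p) {
    sc <- sort(c(p$struct_cluster_a, p$struct_cluster_b))
    paste(p$seq90_cluster_id, sc[1], sc[2], sep = "||")
  }, character(1))
  out <- lapply(split(seq_along(pairs), key), function(ii) {
    ps <- pairs[ii]
    ov <- vapply(ps, `[[`, numeric(1), "overlap_fraction")
    dt <- 1 - vapply(ps, `[[`, numeric(1), "tm_aligned_region")
    ida <- vapply(ps, `[[`, character(1), "id_a")
    idb <- vapply(ps, `[[`, character(1), "id_b")
    ps[[order(-ov, -dt, ida, idb)[1]]]
  })
  unname(out[order(names(out))])
}

#' Automated curation of putative alternative-conformation pairs
#'
#' A documented automated surrogate for manual inspection: rejects pairs
#' whose structural difference is explained by (i) terminal/loop mobility —
#' the aligned-region TM rises to or above the alternative threshold once
#' `trim_terminal` residues are trimmed from each end of the aligned region;
#' (ii) chain breaks — more than `max_break_count` backbone gaps (consecutive
#' C-alpha distance > 10 Angstrom) inside the aligned region of either chain;
#' or (iii) insufficient overlap (`overlap_fraction < min_overlap_fraction`).
#' Pairs must already satisfy `is_alternative`.
#'
#' @param pairs List of scored `conformer_pair` objects.
#' @param chains Named list of [chain_structure()] objects keyed by
#'   [chain_id()], providing the structures referenced by the pairs.
#' @param min_overlap_fraction Minimum overlap fraction (default 0.8).
#' @param max_break_count Maximum tolerated chain breaks (default 0).
#' @param trim_terminal Residues trimmed from each aligned-region end for the
#'   terminal-mobility re-score (default 10).
#' @return List of retained `conformer_pair` objects (the final
#'   alternative-conformation set), with attribute `"rejected"` naming the
#'   rejected pairs and the triggering rule.
#' @export
automated_curation <- function(pairs, chains, min_overlap_fraction = 0.8,
                               max_break_count = 0, trim_terminal = 10) {
  keep <- list(); rejected <- list()
  for (p in pairs) {
    if (!isTRUE(p$is_alternative)) {
      rejected[[length(rejected) + 1]] <- c(p$id_a, p$id_b, "not_alternative")
      next
    }
    a <- chains[[p$id_a]]; b <- chains[[p$id_b]]
    if (is.null(a) || is.null(b))
      stop("automated_curation: missing chain for pair ", p$id_a, "/", p$id_b,
           call. = FALSE)
    if (p$overlap_fraction < min_overlap_fraction) {
      rejected[[length(rejected) + 1]] <- c(p$id_a, p$id_b, "low_overlap")
      next
    }
    aln <- global_align(a$sequence, b$sequence)
    ra <- extract_aligned_region(a, aln, "a")
    rb <- extract_aligned_region(b, aln, "b")
    if (sum(chain_breaks(ra)) > max_break_count ||
        sum(chain_breaks(rb)) > max_break_count) {
      rejected[[length(rejected) + 1]] <- c(p$id_a, p$id_b, "chain_break")
      next
    }
    n <- chain_length(ra)
    lo <- trim_terminal + 1; hi <- n - trim_terminal
    if (hi - lo + 1 >= 5) {
      ta <- subset_chain(ra, lo:hi); tb <- subset_chain(rb, lo:hi)
      sup <- tm_score(ta$ca_coords, tb$ca_coords,
                      identity_alignment(ta$sequence, tb$sequence))
      if (sup$tm_min >= p$alt_threshold) {
        rejected[[length(rejected) + 1]] <- c(p$id_a, p$id_b, "terminal_only")
        next
      }
    }
    keep[[length(keep) + 1]] <- p
  }
  rej <- if (length(rejected))
    as.data.frame(do.call(rbind, rejected), stringsAsFactors = FALSE) else
    data.frame(V1 = character(0), V2 = character(0), V3 = character(0))
  names(rej) <- c("id_a", "id_b", "rule")
  attr(keep, "rejected") <- rej
  keep
}

#' Build the conformational train/validation/test split
#'
#' Alternative-conformation sets are the connected components of the curated
#' pair graph over structural clusters. Per set, one cluster is chosen
#' uniformly at random (seeded) for the training pool; the remaining clusters
#' of the set go to the test partition. All structural clusters untouched by
#' any curated pair join the training pool, and `val_fraction` of the
#' non-alternative training pool is sampled without replacement as the
#' validation partition. Deterministic given `seed`.
#'
#' @param struct_clusters List of `structural_cluster` objects (or character
#'   vector of cluster ids).
#' @param curated_pairs List of curated `conformer_pair` objects.
#' @param seed Integer RNG seed.
#' @param val_fraction Fraction of the train pool used for validation,
#'   in (0, 0.5); default 0.05.
#' @return An object of class `split_manifest`: list with `assignment`
#'   (named character vector cluster_id -> `"train"`/`"val"`/`"test"`),
#'   `alternative_sets` (list of character vectors of cluster ids), `seed`,
#'   `val_fraction`.
#' @export
make_split <- function(struct_clusters, curated_pairs, seed,
                       val_fraction = 0.05) {
  if (val_fraction <= 0 || val_fraction >= 0.5)
    stop("make_split: val_fraction must be in (0, 0.5)", call. = FALSE)
  cluster_ids <- if (is.character(struct_clusters)) struct_clusters else
    vapply(struct_clusters, `[[`, character(1), "cluster_id")
  cluster_ids <- sort(unique(cluster_ids))
  edges <- lapply(curated_pairs, function(p)
    c(p$struct_cluster_a, p$struct_cluster_b))
  for (e in edges)
    if (!all(e %in% cluster_ids))
      stop("make_split: curated pair references unknown structural cluster: ",
           paste(setdiff(e, cluster_ids), collapse = ", "), call. = FALSE)
  sets <- connected_components(cluster_ids, edges)
  sets <- sets[order(vapply(sets, `[[`, character(1), 1))]

  set.seed(as.integer(seed))
  assignment <- stats::setNames(rep("train", length(cluster_ids)), cluster_ids)
  for (s in sets) {
    train_one <- if (length(s) == 1) s else s[sample.int(length(s), 1)]
    assignment[setdiff(s, train_one)] <- "test"
  }
  alt_members <- unlist(sets)
  val_pool <- sort(setdiff(names(assignment)[assignment == "train"],
                           alt_members))
  n_val <- round(val_fraction * length(val_pool))
  if (n_val > 0)
    assignment[sample(val_pool, n_val)] <- "val"
  structure(list(assignment = assignment, alternative_sets = sets,
                 seed = as.integer(seed), val_fraction = val_fraction),
            class = "split_manifest")
}

# connected components of an undirected graph over `nodes` given a list of
# 2-element edges; singletons (no incident edge) are excluded.
connected_components <- function(nodes, edges) {
  touched <- as.character(unique(unlist(edges)))
  if (length(touched) == 0) return(list())
  parent <- stats::setNames(touched, touched)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (e in edges) {
    ra <- find(e[1]); rb <- find(e[2])
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(touched, find, character(1))
  unname(lapply(split(touched, roots), function(v) sort(unname(v))))
}

#' @export
print.split_manifest <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = c("train", "val", "test")))
  cat(sprintf(
    "<split_manifest> train=%d val=%d test=%d  alternative_sets=%d  seed=%d\n",
    tab["train"], tab["val"], tab["test"], length(x$alternative_sets),
    x$seed))
  invisible(x)
}

#' Verify a split manifest against the curated pairs
#'
#' Asserts that every structural cluster has exactly one partition, that no
#' curated pair has both of its clusters on the training side (train/val) —
#' the property guaranteeing that evaluation conformations were never seen
#' during training — and that every alternative set keeps exactly one
#' training-side cluster with all remaining conformations in test. Two
#' clusters of one pair may both sit in test: when a sequence has three or
#' more conformations, one trains and all others are evaluated.
#'
#' @param manifest A `split_manifest`.
#' @param struct_clusters Structural clusters (or ids) the manifest covers.
#' @param curated_pairs Curated `conformer_pair` list.
#' @return List with `ok` (logical), `violations` (character vector), and
#'   `counts` (named partition counts).
#' @export
verify_split <- function(manifest, struct_clusters, curated_pairs) {
  cluster_ids <- if (is.character(struct_clusters)) struct_clusters else
    vapply(struct_clusters, `[[`, character(1), "cluster_id")
  violations <- character(0)
  missing <- setdiff(cluster_ids, names(manifest$assignment))
  if (length(missing))
    violations <- c(violations,
                    paste0("unassigned clusters: ",
                           paste(missing, collapse = ", ")))
  if (!all(manifest$assignment %in% c("train", "val", "test")))
    violations <- c(violations, "invalid partition labels")
  for (p in curated_pairs) {
    pa <- manifest$assignment[p$struct_cluster_a]
    pb <- manifest$assignment[p$struct_cluster_b]
    train_side <- c("train", "val")
    if ((pa %in% train_side) && (pb %in% train_side))
      violations <- c(violations, sprintf(
        "pair %s/%s: clusters %s (%s) and %s (%s) both on the training side",
        p$id_a, p$id_b, p$struct_cluster_a, pa, p$struct_cluster_b, pb))
  }
  for (s in manifest$alternative_sets) {
    n_train_side <- sum(manifest$assignment[s] %in% c("train", "val"))
    n_test <- sum(manifest$assignment[s] == "test")
    if (n_train_side != 1 || n_test < 1)
      violations <- c(violations, sprintf(
        "alternative set {%s}: %d train-side, %d test members",
        paste(s, collapse = ","), n_train_side, n_test))
  }
  counts <- table(factor(manifest$assignment,
                         levels = c("train", "val", "test")))
  list(ok = length(violations) == 0, violations = violations,
       counts = c(train = unname(counts["train"]), val = unname(counts["val"]),
                  test = unname(counts["test"])))
}

#' Serialize a split manifest
#'
#' Writes a TSV (`structural_cluster_id`, `partition`, `alternative_set_id`)
#' plus a JSON sidecar carrying seed and parameters.
#'
#' @param manifest A `split_manifest`.
#' @param path TSV output path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(manifest, path) {
  set_id <- stats::setNames(rep(NA_character_, length(manifest$assignment)),
                            names(manifest$assignment))
  for (k in seq_along(manifest$alternative_sets))
    set_id[manifest$alternative_sets[[k]]] <- sprintf("altset%03d", k)
  df <- data.frame(structural_cluster_id = names(manifest$assignment),
                   partition = unname(manifest$assignment),
                   alternative_set_id = unname(set_id),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = manifest$seed, val_fraction = manifest$val_fraction,
         n_alternative_sets = length(manifest$alternative_sets)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
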