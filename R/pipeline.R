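#' Default pipeline configuration
#'
#' Collects every threshold of the corpus-processing pipeline with its
#' standard value: corpus filters (min length 50, non-regular fraction 0.8,
#' resolution 5 Angstrom), sequence-identity tiers (0.3 and 0.9 with coverage
#' 0.8), structural clustering (TM >= 0.8), the alternative-conformation rule
#' (aligned-region TM < 0.8, i.e. a difference > 0.2 from self-identity),
#' the prediction success threshold (TM > 0.8), and the fold-level baseline
#' for evaluable targets (TM >= 0.6 from one prediction).
#'
#' @param ... Named overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_len = 50, max_nonregular_frac = 0.8, max_resolution = 5.0,
              seq_identity_broad = 0.3, seq_identity_fine = 0.9,
              min_coverage = 0.8, tm_cluster = 0.8, alt_tm = 0.8,
              success_tm = 0.8, fold_baseline_tm = 0.6,
              val_fraction = 0.05, seed = 1,
              min_overlap_fraction = 0.8, max_break_count = 0,
              trim_terminal = 10)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown option(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the conformational-split pipeline on a corpus
#'
#' Executes the full stage order: filter -> broad (30%) sequence clustering ->
#' structural clustering within sequence clusters -> fine (90%) sequence
#' clustering -> candidate detection -> conformer-pair scoring ->
#' representative selection -> automated curation -> train/val/test split ->
#' verification. Returns all intermediate artifacts plus a run summary with
#' per-stage counts; when `out_dir` is given, manifests are also written as
#' TSV/JSON with content hashes. Deterministic for fixed input and config.
#'
#' @param chains List of [chain_structure()] objects (the corpus).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for manifests.
#' @return List with `filter`, `seq_clusters`, `struct_clusters`,
#'   `unclusterable`, `seq90_clusters`, `candidates`, `pairs`,
#'   `representatives`, `curated`, `manifest`, `verification`, `summary`.
#' @export
run_pipeline <- function(chains, config = pipeline_config(), out_dir = NULL) {
  flt <- filter_chains(chains, min_len = config$min_len,
                       max_nonregular_frac = config$max_nonregular_frac,
                       max_resolution = config$max_resolution)
  kept <- flt$kept
  chain_map <- stats::setNames(kept, vapply(kept, chain_id, character(1)))
  records <- data.frame(id = names(chain_map),
                        sequence = vapply(kept, `[[`, character(1),
                                          "sequence"),
                        stringsAsFactors = FALSE)

  seq_clusters <- greedy_sequence_cluster(records,
                                          config$seq_identity_broad,
                                          config$min_coverage)

  struct_clusters <- list(); unclusterable <- character(0)
  for (sc in seq_clusters) {
    res <- structural_cluster(chain_map[sc$member_ids],
                              tm_threshold = config$tm_cluster,
                              parent_cluster_id = sc$cluster_id)
    struct_clusters <- c(struct_clusters, res$clusters)
    unclusterable <- c(unclusterable, res$unclusterable)
  }

  clusterable <- setdiff(names(chain_map), unclusterable)
  seq90_clusters <- greedy_sequence_cluster(
    records[records$id %in% clusterable, , drop = FALSE],
    config$seq_identity_fine, config$min_coverage)

  candidates <- detect_candidate_clusters(seq90_clusters, struct_clusters)

  member2struct <- member_to_cluster_map(struct_clusters)
  member2seq90 <- member_to_cluster_map(seq90_clusters)
  pairs <- list()
  for (r in seq_len(nrow(candidates))) {
    s90 <- candidates$seq90_cluster_id[r]
    ids <- seq90_clusters[[which(vapply(seq90_clusters, `[[`, character(1),
                                        "cluster_id") == s90)]]$member_ids
    by_struct <- split(ids, member2struct[ids])
    sc_ids <- names(by_struct)
    for (i in seq_along(sc_ids)[-length(sc_ids)])
      for (j in (i + 1):length(sc_ids))
        for (ia in by_struct[[i]]) for (ib in by_struct[[j]]) {
          p <- tryCatch(score_conformer_pair(
            chain_map[[ia]], chain_map[[ib]], alt_threshold = config$alt_tm,
            struct_cluster_a = sc_ids[i], struct_cluster_b = sc_ids[j],
            seq90_cluster_id = s90), error = function(e) NULL)
          if (!is.null(p)) pairs[[length(pairs) + 1]] <- p
        }
  }

  reps <- select_representatives(Filter(function(p) p$is_alternative, pairs))
  curated <- automated_curation(reps, chain_map,
                                min_overlap_fraction = config$min_overlap_fraction,
                                max_break_count = config$max_break_count,
                                trim_terminal = config$trim_terminal)

  manifest <- make_split(struct_clusters, curated, seed = config$seed,
                         val_fraction = config$val_fraction)
  verification <- verify_split(manifest, struct_clusters, curated)

  summary <- list(
    n_input = length(chains), n_kept = length(kept),
    n_seq_clusters = length(seq_clusters),
    n_struct_clusters = length(struct_clusters),
    n_unclusterable = length(unclusterable),
    n_seq90_clusters = length(seq90_clusters),
    n_candidates = nrow(candidates),
    n_scored_pairs = length(pairs),
    n_representative_pairs = length(reps),
    n_curated_pairs = length(curated),
    n_alternative_sets = length(manifest$alternative_sets),
    partition_counts = verification$counts,
    split_ok = verification$ok, seed = config$seed)

  out <- list(filter = flt, seq_clusters = seq_clusters,
              struct_clusters = struct_clusters,
              unclusterable = unclusterable,
              seq90_clusters = seq90_clusters, candidates = candidates,
              pairs = pairs, representatives = reps, curated = curated,
              manifest = manifest, verification = verification,
              summary = summary)
  if (!is.null(out_dir)) write_run_artifacts(out, chains, out_dir)
  out
}

write_run_artifacts <- function(run, chains, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus_manifest(chains, run$filter$decisions,
                        file.path(out_dir, "corpus.tsv"))
  write_cluster_tsv(run$seq_clusters, file.path(out_dir, "seq30.tsv"),
                    "seq30")
  write_cluster_tsv(run$seq90_clusters, file.path(out_dir, "seq90.tsv"),
                    "seq90")
  write_cluster_tsv(run$struct_clusters,
                    file.path(out_dir, "structural.tsv"), "structural")
  write_conformer_pairs(run$curated, file.path(out_dir, "curated_pairs.tsv"))
  write_split_manifest(run$manifest, file.path(out_dir, "split.tsv"))
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("hashes", files)]
  hashes <- tools::md5sum(files)
  utils::write.table(
    data.frame(file = basename(names(hashes)), md5 = unname(hashes)),
    file.path(out_dir, "hashes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Serialize conformer pairs as TSV
#' @param pairs List of `conformer_pair` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_conformer_pairs <- function(pairs, path) {
  rows <- do.call(rbind, lapply(pairs, function(p) data.frame(
    seq90_cluster_id = p$seq90_cluster_id, id_a = p$id_a, id_b = p$id_b,
    struct_cluster_a = p$struct_cluster_a,
    struct_cluster_b = p$struct_cluster_b,
    overlap_length = p$overlap_length,
    overlap_fraction = p$overlap_fraction,
    tm_aligned_region = p$tm_aligned_region,
    is_alternative = p$is_alternative, change_type = p$change_type,
    stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(seq90_cluster_id = character(0), id_a = character(0),
                       id_b = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retain targets predictable at the fold level
#'
#' A target enters conformational evaluation only when a single baseline
#' prediction reaches the train conformation at `tm_min >= min_single_tm`
#' (minimum TM normalization; 0.6 by default, well above the 0.5 same-fold
#' level), so that failures to sample alternative conformations are not
#' confounded with failures to predict the fold at all.
#'
#' @param baselines data.frame with columns `target_id` and `baseline_tm_min`.
#' @param min_single_tm Baseline threshold (default 0.6, inclusive).
#' @return The retained rows of `baselines`.
#' @export
select_evaluable_targets <- function(baselines, min_single_tm = 0.6) {
  baselines[baselines$baseline_tm_min >= min_single_tm, , drop = FALSE]
}
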