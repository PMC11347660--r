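#' Build a conformational-sampling schedule
#'
#' Enumerates the prediction jobs for one target under either sampling
#' strategy: `"msa_clustering"` takes `samples_per_size` samples at each MSA
#' cluster-size in `cluster_sizes` (defaults: sizes 16, 32, 64, 128, 256,
#' 512, 1024, 5120 with 13 samples each, 104 jobs); `"dropout"` takes
#' `n_total_dropout` samples (default 100). Each job carries a distinct
#' derived seed `base_seed + i`.
#'
#' @param strategy `"msa_clustering"` or `"dropout"`.
#' @param cluster_sizes Integer vector of MSA cluster counts
#'   (msa_clustering only).
#' @param samples_per_size Samples per cluster size (msa_clustering only).
#' @param n_total_dropout Total dropout samples.
#' @param recycles Recycling iterations recorded in the job metadata.
#' @param base_seed Base RNG seed.
#' @return An object of class `sampling_schedule`: list with `strategy`,
#'   `recycles`, `base_seed` and `jobs` (data.frame `job`, `cluster_size`,
#'   `seed`).
#' @export
build_schedule <- function(strategy = c("msa_clustering", "dropout"),
                           cluster_sizes = c(16, 32, 64, 128, 256, 512,
                                             1024, 5120),
                           samples_per_size = 13,
                           n_total_dropout = 100,
                           recycles = 3, base_seed = 1) {
  strategy <- match.arg(strategy)
  if (strategy == "msa_clustering") {
    if (length(cluster_sizes) == 0)
      stop("build_schedule: empty cluster-size list", call. = FALSE)
    if (any(cluster_sizes < 1) || samples_per_size < 1)
      stop("build_schedule: sizes and samples_per_size must be positive",
           call. = FALSE)
    jobs <- data.frame(
      job = seq_len(length(cluster_sizes) * samples_per_size),
      cluster_size = rep(as.integer(cluster_sizes),
                         each = samples_per_size))
  } else {
    if (n_total_dropout < 1)
      stop("build_schedule: n_total_dropout must be positive", call. = FALSE)
    jobs <- data.frame(job = seq_len(n_total_dropout),
                       cluster_size = NA_integer_)
  }
  jobs$seed <- as.integer(base_seed) + jobs$job
  structure(list(strategy = strategy, recycles = as.integer(recycles),
                 base_seed = as.integer(base_seed), jobs = jobs),
            class = "sampling_schedule")
}

#' Read an A3M multiple sequence alignment
#'
#' A3M is FASTA with lowercase letters marking insertions relative to the
#' query; removing lowercase yields equal-length match-column rows.
#'
#' @param path A3M file path.
#' @return data.frame with columns `id` and `sequence` (raw A3M rows, query
#'   first).
#' @export
read_a3m <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("read_a3m: no records in ", path, call. = FALSE)
  ids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(k)
    paste(lines[(hdr[k] + 1):ends[k]], collapse = ""), character(1))
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

a3m_match_columns <- function(seqs) gsub("[a-z.]", "", seqs)

#' Subsample an MSA into cluster centers
#'
#' Emulates the MSA-clustering input perturbation used to sample alternative
#' conformations: the query (first record) is always a center;
#' `min(n_clusters - 1, N - 1)` further centers are sampled uniformly without
#' replacement (seeded); the remaining sequences are assigned to the nearest
#' center by Hamming distance over match columns. The returned MSA contains
#' the centers in input order — the representation a predictor would consume.
#'
#' @param msa data.frame from [read_a3m()] (query first).
#' @param n_clusters Number of cluster centers (>= 1).
#' @param seed Integer seed.
#' @return data.frame of the center records, with attribute `"assignment"`
#'   (integer vector over input rows giving each sequence's center row index).
#' @export
msa_cluster_sample <- function(msa, n_clusters, seed) {
  if (n_clusters < 1) stop("msa_cluster_sample: n_clusters < 1", call. = FALSE)
  n <- nrow(msa)
  if (n == 0) stop("msa_cluster_sample: empty MSA", call. = FALSE)
  set.seed(as.integer(seed))
  k_extra <- min(n_clusters - 1, n - 1)
  centers <- sort(c(1L, if (k_extra > 0)
    sample(2:n, k_extra, replace = FALSE)))
  match_seq <- a3m_match_columns(msa$sequence)
  mat <- do.call(rbind, strsplit(match_seq, ""))
  assignment <- integer(n)
  assignment[centers] <- centers
  rest <- setdiff(seq_len(n), centers)
  for (r in rest) {
    dists <- vapply(centers, function(c) sum(mat[r, ] != mat[c, ]),
                    numeric(1))
    assignment[r] <- centers[which.min(dists)]
  }
  out <- msa[centers, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assignment") <- assignment
  out
}

#' Read a prediction ensemble from a directory of model PDB files
#'
#' Model files are read at the C-alpha level; per-residue confidence (plDDT)
#' is taken from the B-factor column, the de-facto convention for predicted
#' models.
#'
#' @param dir Directory containing `.pdb` model files.
#' @param target_id Identifier recorded on the ensemble.
#' @return A `prediction_ensemble`: list with `target_id` and `samples`, each
#'   sample a list with `chain` ([chain_structure()]) and `plddt`.
#' @export
read_prediction_ensemble <- function(dir, target_id = basename(dir)) {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (length(files) == 0)
    stop("read_prediction_ensemble: no .pdb files in ", dir, call. = FALSE)
  samples <- lapply(files, function(f) {
    pdb <- bio3d::read.pdb(f, verbose = FALSE)
    at <- pdb$atom
    ca <- at[at$elety == "CA" & at$resid %in% names(AA3_TO_1), , drop = FALSE]
    seq1 <- unname(AA3_TO_1[ca$resid]); seq1[is.na(seq1)] <- "X"
    ch <- chain_structure(
      structure_id = sub("\\.pdb$", "", basename(f)),
      chain_id = if (is.na(ca$chain[1])) "A" else ca$chain[1],
      sequence = paste(seq1, collapse = ""),
      ca_coords = as.matrix(ca[, c("x", "y", "z")]),
      residue_numbers = ca$resno, method = "other")
    list(chain = ch, plddt = ca$b)
  })
  new_prediction_ensemble(target_id, samples)
}

new_prediction_ensemble <- function(target_id, samples) {
  L <- vapply(samples, function(s) chain_length(s$chain), integer(1))
  if (length(unique(L)) > 1)
    stop("prediction_ensemble: samples differ in length", call. = FALSE)
  for (s in samples)
    if (length(s$plddt) != chain_length(s$chain))
      stop("prediction_ensemble: plddt length mismatch", call. = FALSE)
  structure(list(target_id = target_id, samples = samples),
            class = "prediction_ensemble")
}

#' Best-of-N scores of an ensemble against the two native conformations
#'
#' Scores every sample against each native with [structural_align()], taking
#' the maximum-normalization TM (`tm_max`) per comparison to absorb length
#' differences between the natives' resolved regions and the full predicted
#' sequence, and records the per-native maxima over samples. The structural
#' distance between the two natives (`native_delta_tm`) is the aligned-region
#' TM from [score_conformer_pair()].
#'
#' @param ensemble A `prediction_ensemble`.
#' @param native_train,native_test The two native conformations as
#'   [chain_structure()] objects.
#' @return An `evaluation_record`: list with `target_id`, `tm_best_train`,
#'   `tm_best_test`, `native_delta_tm`, `mean_plddt_best_test`,
#'   `change_type`, and `per_sample` (data.frame `sample`, `tm_train`,
#'   `tm_test`, `mean_plddt`).
#' @export
best_sample_scores <- function(ensemble, native_train, native_test) {
  rows <- lapply(seq_along(ensemble$samples), function(k) {
    s <- ensemble$samples[[k]]
    st <- tryCatch(structural_align(s$chain, native_train)$superposition,
                   error = function(e) NULL)
    se <- tryCatch(structural_align(s$chain, native_test)$superposition,
                   error = function(e) NULL)
    if (is.null(st) && is.null(se)) return(NULL)
    data.frame(sample = k,
               tm_train = if (is.null(st)) NA_real_ else st$tm_max,
               tm_test = if (is.null(se)) NA_real_ else se$tm_max,
               mean_plddt = mean(s$plddt))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0)
    stop("best_sample_scores: no scoreable samples", call. = FALSE)
  delta <- score_conformer_pair(native_train, native_test)$tm_aligned_region
  best_test_row <- rows[which.max(rows$tm_test), ]
  structure(list(
    target_id = ensemble$target_id,
    tm_best_train = max(rows$tm_train, na.rm = TRUE),
    tm_best_test = max(rows$tm_test, na.rm = TRUE),
    native_delta_tm = delta,
    mean_plddt_best_test = best_test_row$mean_plddt,
    change_type = "unassigned",
    per_sample = rows
  ), class = "evaluation_record")
}

#' Count successful predictions at a TM threshold
#'
#' Strict `>` comparison at the threshold (a score of exactly the threshold
#' does not count as success).
#'
#' @param records List of `evaluation_record` objects (or a data.frame with
#'   columns `tm_best_train`, `tm_best_test`).
#' @param threshold Success threshold (default 0.8).
#' @return Named integer vector: `train`, `test`, `both`, `total`.
#' @export
success_table <- function(records, threshold = 0.8) {
  df <- records_frame(records)
  if (nrow(df) == 0) stop("success_table: no records", call. = FALSE)
  c(train = sum(df$tm_best_train > threshold),
    test = sum(df$tm_best_test > threshold),
    both = sum(df$tm_best_train > threshold & df$tm_best_test > threshold),
    total = nrow(df))
}

records_frame <- function(records) {
  if (is.data.frame(records)) return(records)
  do.call(rbind, lapply(records, function(r) data.frame(
    target_id = r$target_id, tm_best_train = r$tm_best_train,
    tm_best_test = r$tm_best_test, native_delta_tm = r$native_delta_tm,
    mean_plddt_best_test = r$mean_plddt_best_test,
    change_type = r$change_type, stringsAsFactors = FALSE)))
}

#' Fractions of samples resembling the test, train or neither conformation
#'
#' Each sample is labeled `test` when its TM to the test conformation exceeds
#' the threshold and its TM to the train conformation; `train` analogously
#' (ties above threshold go to `train`); otherwise `neither`.
#'
#' @param per_sample data.frame with columns `tm_train` and `tm_test` (e.g.
#'   pooled from `evaluation_record$per_sample`).
#' @param threshold TM threshold (default 0.8).
#' @return Named numeric vector `frac_test`, `frac_train`, `frac_neither`
#'   summing to 1.
#' @export
sample_outcome_fractions <- function(per_sample, threshold = 0.8) {
  tt <- per_sample$tm_test; tr <- per_sample$tm_train
  test <- !is.na(tt) & tt > threshold & (is.na(tr) | tt > tr)
  train <- !is.na(tr) & tr > threshold & !test
  neither <- !test & !train
  n <- nrow(per_sample)
  c(frac_test = sum(test) / n, frac_train = sum(train) / n,
    frac_neither = sum(neither) / n)
}

#' Three-state secondary structure from C-alpha geometry
#'
#' Assigns H (helix), E (strand) or C (coil) per residue from the
#' characteristic short-range C-alpha distances d(i, i+2) and d(i, i+3).
#' Each 4-residue window is labeled by its nearest ideal prototype in
#' (d2, d3) space — helix (5.43, 5.05 Angstrom; from 1.5 Angstrom rise,
#' 100 degrees/residue, 2.3 Angstrom radius) or extended strand
#' (6.60, 10.08 Angstrom) — when within `cutoff` of it, else coil. Residues
#' take the majority label of the windows covering them (junction windows sit
#' far from both prototypes and vote coil), and runs shorter than `min_run`
#' are relabeled coil. Designed for C-alpha-only corpora in the spirit of
#' P-SEA; the prototype/vote scheme keeps the assignment stable under
#' sub-Angstrom coordinate noise.
#'
#' @param chain A [chain_structure()] (or an L x 3 coordinate matrix).
#' @param min_run Minimum run length kept as structured (default 3).
#' @param cutoff Acceptance radius around a prototype in Angstrom
#'   (default 1.6).
#' @return Character vector over `{"H", "E", "C"}` of length L.
#' @export
assign_ss_ca <- function(chain, min_run = 3, cutoff = 1.6) {
  xyz <- if (inherits(chain, "chain_structure")) chain$ca_coords else
    as.matrix(chain)
  L <- nrow(xyz)
  ss <- rep("C", L)
  if (L >= 4) {
    d2 <- sqrt(rowSums((xyz[3:L, , drop = FALSE] -
                        xyz[1:(L - 2), , drop = FALSE])^2))
    d3 <- sqrt(rowSums((xyz[4:L, , drop = FALSE] -
                        xyz[1:(L - 3), , drop = FALSE])^2))
    n_w <- L - 3
    dh <- sqrt((d2[1:n_w] - 5.43)^2 + (d3 - 5.05)^2)
    de <- sqrt((d2[1:n_w] - 6.60)^2 + (d3 - 10.08)^2)
    wlab <- ifelse(dh <= de & dh < cutoff, "H",
                   ifelse(de < dh & de < cutoff, "E", "C"))
    for (i in 1:L) {
      w <- max(1, i - 3):min(i, n_w)
      v <- table(factor(wlab[w], levels = c("H", "E", "C")))
      top <- names(v)[which.max(v)]
      ss[i] <- if (v[top] > length(w) / 2) top else "C"
    }
  }
  smooth_ss(ss, min_run)
}

smooth_ss <- function(ss, min_run) {
  r <- rle(ss)
  r$values[r$lengths < min_run & r$values != "C"] <- "C"
  inverse.rle(r)
}

#' Classify the type of a conformational change
#'
#' Automated surrogate for manual typing of conformational changes:
#' \enumerate{
#'   \item secondary structure is assigned to both conformations over their
#'     aligned region; if more than `ss_switch_frac` of residues change state
#'     in blocks of at least `ss_block` residues, the change is a
#'     \emph{fold switch};
#'   \item otherwise the aligned region is segmented into rigid bodies from
#'     the distance-difference matrix (maximal contiguous blocks with
#'     internal |d_ij(A) - d_ij(B)| < `rigid_tol`); when at least two bodies
#'     of `min_body` residues or more each superpose individually at
#'     TM >= 0.8 while the global aligned-region TM is below 0.8, the change
#'     is a \emph{hinge};
#'   \item anything else is a \emph{rearrangement}.
#' }
#'
#' @param pair A scored `conformer_pair` with `is_alternative = TRUE`.
#' @param a,b The two [chain_structure()] objects of the pair.
#' @param ss_switch_frac Fraction of switching residues calling a fold switch
#'   (default 0.15, strict `>`).
#' @param ss_block Minimum block length of switching residues (default 6).
#' @param rigid_tol Distance-difference tolerance in Angstrom (default 2).
#' @param min_body Minimum rigid-body size in residues (default 25).
#' @return One of `"hinge"`, `"rearrangement"`, `"fold_switch"`,
#'   `"unassigned"`.
#' @export
classify_conformational_change <- function(pair, a, b,
                                           ss_switch_frac = 0.15,
                                           ss_block = 6, rigid_tol = 2,
                                           min_body = 25) {
  if (!isTRUE(pair$is_alternative))
    stop("classify_conformational_change: pair is not an alternative ",
         "conformation", call. = FALSE)
  aln <- global_align(a$sequence, b$sequence)
  if (nrow(aln$pairs) < 50) return("unassigned")
  ra <- extract_aligned_region(a, aln, "a")
  rb <- extract_aligned_region(b, aln, "b")
  n <- chain_length(ra)

  ssa <- assign_ss_ca(ra); ssb <- assign_ss_ca(rb)
  switched <- ssa != ssb
  r <- rle(switched)
  in_block <- inverse.rle(list(
    lengths = r$lengths, values = r$values & r$lengths >= ss_block))
  if (sum(in_block) / n > ss_switch_frac) return("fold_switch")

  bodies <- rigid_segments(ra$ca_coords, rb$ca_coords, rigid_tol)
  bodies <- bodies[vapply(bodies, length, integer(1)) >= min_body]
  if (length(bodies) >= 2 && pair$tm_aligned_region < 0.8) {
    ok <- vapply(bodies, function(idx) {
      sa <- subset_chain(ra, idx); sb <- subset_chain(rb, idx)
      sup <- tm_score(sa$ca_coords, sb$ca_coords,
                      identity_alignment(sa$sequence, sb$sequence))
      sup$tm_min >= 0.8
    }, logical(1))
    if (sum(ok) >= 2) return("hinge")
  }
  "rearrangement"
}

# maximal contiguous blocks whose internal distance matrices agree within tol
# (95th-percentile criterion: robust to coordinate-noise tails, which would
# otherwise fragment genuinely rigid domains)
rigid_segments <- function(xa, xb, tol = 2) {
  n <- nrow(xa)
  da <- as.matrix(stats::dist(xa)); db <- as.matrix(stats::dist(xb))
  dd <- abs(da - db)
  segs <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n &&
           stats::quantile(dd[i:(j + 1), j + 1], 0.95, names = FALSE) < tol)
      j <- j + 1
    segs[[length(segs) + 1]] <- i:j
    i <- j + 1
  }
  segs
}

#' Accuracy vs structural-change running average
#'
#' Bins evaluation records by the TM distance between their native
#' conformations at the given step and reports the per-bin mean best test
#' TM, plus the Pearson correlation on the unbinned records.
#'
#' @param records List of `evaluation_record` objects or equivalent
#'   data.frame.
#' @param step Bin width on the native-delta axis (default 0.02).
#' @return List with `curve` (data.frame `bin_mid`, `mean_tm_test`, `n`),
#'   `pearson_r`, `degenerate` (TRUE when a correlation is undefined, e.g.
#'   zero variance).
#' @export
accuracy_vs_change_curve <- function(records, step = 0.02) {
  df <- records_frame(records)
  if (nrow(df) < 2)
    stop("accuracy_vs_change_curve: need at least 2 records", call. = FALSE)
  bin <- floor(df$native_delta_tm / step)
  agg <- stats::aggregate(df$tm_best_test, by = list(bin = bin), FUN = mean)
  curve <- data.frame(bin_mid = (agg$bin + 0.5) * step,
                      mean_tm_test = agg$x,
                      n = as.integer(table(bin)[as.character(agg$bin)]))
  degenerate <- stats::sd(df$native_delta_tm) == 0 ||
    stats::sd(df$tm_best_test) == 0
  r <- if (degenerate) NA_real_ else
    stats::cor(df$native_delta_tm, df$tm_best_test)
  list(curve = curve, pearson_r = r, degenerate = degenerate)
}

#' Pearson correlation between confidence (plDDT) and TM-score
#'
#' @param plddt,tm Paired numeric vectors (n >= 3, finite).
#' @return List with `r` (Pearson coefficient) and `degenerate` (TRUE when
#'   either input has zero variance, in which case `r` is `NA`).
#' @export
plddt_tm_correlation <- function(plddt, tm) {
  ok <- is.finite(plddt) & is.finite(tm)
  plddt <- plddt[ok]; tm <- tm[ok]
  if (length(plddt) < 3)
    stop("plddt_tm_correlation: need at least 3 finite pairs", call. = FALSE)
  degenerate <- stats::sd(plddt) == 0 || stats::sd(tm) == 0
  list(r = if (degenerate) NA_real_ else stats::cor(plddt, tm),
       degenerate = degenerate)
}

#' Composite training loss
#'
#' The weighted sum
#' `0.5*FAPE + 0.5*AUX + 0.3*Distance + 0.2*MSA + 0.01*Confidence`
#' aggregating the frame-aligned point error, auxiliary (FAPE + angular),
#' pairwise-distance, masked-MSA and confidence losses. A pure aggregator:
#' the loss terms themselves are produced by a training system outside this
#' package.
#'
#' @param fape,aux,distance,msa,confidence Non-negative finite loss
#'   components.
#' @return The scalar composite loss.
#' @export
composite_loss <- function(fape, aux, distance, msa, confidence) {
  comp <- c(fape = fape, aux = aux, distance = distance, msa = msa,
            confidence = confidence)
  if (any(!is.finite(comp)))
    stop("composite_loss: non-finite component", call. = FALSE)
  if (any(comp < 0))
    stop("composite_loss: negative component: ",
         paste(names(comp)[comp < 0], collapse = ", "), call. = FALSE)
  0.5 * fape + 0.5 * aux + 0.3 * distance + 0.2 * msa + 0.01 * confidence
}
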