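#' Read one protein chain from a PDB or mmCIF file
#'
#' Parses a structure file (via bio3d) and extracts a single chain at the
#' C-alpha level. Residues lacking a C-alpha atom are dropped and counted;
#' alternate locations are resolved to the highest-occupancy conformer, ties
#' broken by the alphabetically first altloc identifier; residues outside the
#' 20 standard amino acids are mapped to `"X"`.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"` or `"mmcif"`.
#' @param chain_policy `"first_protein_chain"` selects the first chain (in
#'   file order) that contains amino-acid C-alpha atoms, skipping e.g. nucleic
#'   acid chains; `"named"` selects the chain given by `chain`.
#' @param chain Chain identifier, required for `chain_policy = "named"`.
#' @param method,resolution,release_date Optional metadata overrides; when
#'   `NULL` they are parsed from the file header where possible.
#'
#' @return A [chain_structure()].
#' @export
read_chain_structure <- function(path,
                                 format = c("pdb", "mmcif"),
                                 chain_policy = c("first_protein_chain", "named"),
                                 chain = NULL,
                                 method = NULL, resolution = NULL,
                                 release_date = NULL) {
  format <- match.arg(format)
  chain_policy <- match.arg(chain_policy)
  if (!file.exists(path))
    stop("read_chain_structure: file not found: ", path, call. = FALSE)

  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("read_chain_structure: parse failure in '",
                             path, "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at$chain[is.na(at$chain)] <- " "

  ca <- at[at$elety == "CA" & at$resid %in% names(AA3_TO_1), , drop = FALSE]
  if (nrow(ca) == 0)
    stop("read_chain_structure: no protein chain in '", path, "'",
         call. = FALSE)

  if (chain_policy == "named") {
    if (is.null(chain))
      stop("read_chain_structure: chain_policy='named' requires `chain`",
           call. = FALSE)
    sel_chain <- chain
    if (!any(ca$chain == sel_chain))
      stop("read_chain_structure: no protein residues in chain '", sel_chain,
           "' of '", path, "'", call. = FALSE)
  } else {
    # first chain, in order of appearance, that carries amino-acid CA atoms
    sel_chain <- unique(at$chain)[unique(at$chain) %in% unique(ca$chain)][1]
  }
  ca <- ca[ca$chain == sel_chain, , drop = FALSE]

  # count residues in this chain that have atoms but no CA
  ch_at <- at[at$chain == sel_chain & at$resid %in% names(AA3_TO_1), ,
              drop = FALSE]
  ins <- if ("insert" %in% names(ch_at)) ch_at$insert else NA
  ins[is.na(ins)] <- ""
  res_keys_all <- unique(paste(ch_at$resno, ins, sep = "|"))
  ins_ca <- if ("insert" %in% names(ca)) ca$insert else NA
  ins_ca[is.na(ins_ca)] <- ""
  ca$res_key <- paste(ca$resno, ins_ca, sep = "|")
  n_dropped <- length(setdiff(res_keys_all, unique(ca$res_key)))

  # altloc resolution: highest occupancy, ties -> alphabetically first alt id
  ca$alt[is.na(ca$alt)] <- ""
  ca$o[is.na(ca$o)] <- 1
  keep <- unlist(lapply(split(seq_len(nrow(ca)), ca$res_key)[
    unique(ca$res_key)], function(ii) {
      sub <- ca[ii, , drop = FALSE]
      ii[order(-sub$o, sub$alt)][1]
    }))
  ca <- ca[sort(keep), , drop = FALSE]

  seq1 <- unname(AA3_TO_1[ca$resid])
  seq1[is.na(seq1)] <- "X"

  meta <- parse_structure_metadata(path, format)
  sid <- sub("\\.(pdb|cif|ent|mmcif)$", "", basename(path), ignore.case = TRUE)

  chain_structure(
    structure_id = sid,
    chain_id = if (sel_chain == " ") "A" else sel_chain,
    sequence = paste(seq1, collapse = ""),
    ca_coords = as.matrix(ca[, c("x", "y", "z")]),
    residue_numbers = ca$resno,
    method = if (!is.null(method)) method else meta$method,
    resolution = if (!is.null(resolution)) resolution else meta$resolution,
    release_date = if (!is.null(release_date)) release_date else meta$release_date,
    n_dropped_ca = n_dropped
  )
}

# Light-weight header scan for experimental metadata. Anything not found is
# reported as absent; filter_chains treats absence conservatively.
parse_structure_metadata <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  method <- "other"; resolution <- NA_real_; release_date <- NA_character_
  if (format == "pdb") {
    exp <- grep("^EXPDTA", lines, value = TRUE)
    if (length(exp)) {
      if (grepl("X-RAY", exp[1])) method <- "xray"
      else if (grepl("ELECTRON MICROSCOPY|CRYO-EM", exp[1])) method <- "em"
      else if (grepl("NMR", exp[1])) method <- "nmr"
    }
    rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(rem2)) {
      m <- regmatches(rem2[1], regexpr("[0-9]+\\.[0-9]+", rem2[1]))
      if (length(m)) resolution <- as.numeric(m)
    }
    hdr <- grep("^HEADER", lines, value = TRUE)
    if (length(hdr) && nchar(hdr[1]) >= 59) {
      d <- trimws(substr(hdr[1], 51, 59))
      dd <- tryCatch(as.Date(d, format = "%d-%b-%y"), error = function(e) NA)
      if (!is.na(dd)) release_date <- format(dd, "%Y-%m-%d")
    }
  } else {
    mline <- grep("_exptl\\.method", lines, value = TRUE)
    if (length(mline)) {
      if (grepl("X-RAY", mline[1], ignore.case = TRUE)) method <- "xray"
      else if (grepl("ELECTRON MICROSCOPY", mline[1], ignore.case = TRUE)) method <- "em"
      else if (grepl("NMR", mline[1], ignore.case = TRUE)) method <- "nmr"
    }
    rline <- grep("_refine\\.ls_d_res_high|_em_3d_reconstruction\\.resolution",
                  lines, value = TRUE)
    if (length(rline)) {
      m <- regmatches(rline[1], regexpr("[0-9]+\\.?[0-9]*\\s*$", rline[1]))
      if (length(m)) resolution <- as.numeric(trimws(m))
    }
    dline <- grep("_pdbx_database_status\\.recvd_initial_deposition_date|_database_PDB_rev\\.date_original",
                  lines, value = TRUE)
    if (length(dline)) {
      m <- regmatches(dline[1], regexpr("[0-9]{4}-[0-9]{2}-[0-9]{2}", dline[1]))
      if (length(m)) release_date <- m
    }
  }
  list(method = method, resolution = resolution, release_date = release_date)
}

#' Write a C-alpha chain (optionally with per-residue B-factors) to PDB
#'
#' Serializes a [chain_structure()] as a C-alpha trace in PDB format via
#' bio3d. Per-residue confidence (plDDT) can be stored in the B-factor column,
#' the de-facto convention for predicted models.
#'
#' @param x A `chain_structure`.
#' @param path Output file path.
#' @param b Optional numeric vector of length L written to the B-factor
#'   column (defaults to 0).
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(x, path, b = NULL) {
  L <- chain_length(x)
  if (is.null(b)) b <- rep(0, L)
  resid3 <- unname(AA1_TO_3[strsplit(x$sequence, "")[[1]]])
  resid3[is.na(resid3)] <- "UNK"
  hdr <- character(0)
  if (x$method == "xray") hdr <- "EXPDTA    X-RAY DIFFRACTION"
  else if (x$method == "em") hdr <- "EXPDTA    ELECTRON MICROSCOPY"
  else if (x$method == "nmr") hdr <- "EXPDTA    SOLUTION NMR"
  if (!is.na(x$resolution))
    hdr <- c(hdr, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                          x$resolution))
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = as.numeric(t(x$ca_coords)),
                   resno = x$residue_numbers, resid = resid3,
                   elety = rep("CA", L), chain = rep(x$chain_id, L),
                   b = b)
  writeLines(c(hdr, readLines(tmp, warn = FALSE)), path)
  unlink(tmp)
  invisible(path)
}

#' Filter a corpus of chains by the standard corpus criteria
#'
#' A chain is kept iff its length is at least `min_len`, its fraction of
#' non-regular (`"X"`) residues is below `max_nonregular_frac`, its method is
#' one of `allowed_methods`, and its resolution is reported and at most
#' `max_resolution`. Absent resolution excludes a chain (conservative; NMR is
#' excluded by method anyway). One decision record is emitted per input.
#'
#' @param chains List of [chain_structure()] objects.
#' @param min_len Minimum chain length (residues), default 50.
#' @param max_nonregular_frac Maximum allowed fraction of `"X"` residues
#'   (strict `<`), default 0.8.
#' @param max_resolution Maximum resolution in Angstrom, default 5.0.
#' @param allowed_methods Character vector of allowed experimental methods.
#'
#' @return A list with `kept` (list of chains) and `decisions` (data.frame
#'   with columns `id`, `kept`, `reasons`; reasons comma-separated among
#'   `too_short`, `too_many_nonregular`, `bad_resolution`, `excluded_method`).
#' @export
filter_chains <- function(chains, min_len = 50, max_nonregular_frac = 0.8,
                          max_resolution = 5.0,
                          allowed_methods = c("xray", "em")) {
  decisions <- lapply(chains, function(ch) {
    reasons <- character(0)
    L <- chain_length(ch)
    if (L < min_len) reasons <- c(reasons, "too_short")
    n_x <- sum(strsplit(ch$sequence, "")[[1]] == "X")
    if (L > 0 && n_x / L >= max_nonregular_frac)
      reasons <- c(reasons, "too_many_nonregular")
    if (!(ch$method %in% allowed_methods))
      reasons <- c(reasons, "excluded_method")
    if (is.na(ch$resolution) || ch$resolution > max_resolution)
      reasons <- c(reasons, "bad_resolution")
    data.frame(id = chain_id(ch), kept = length(reasons) == 0,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  decisions <- do.call(rbind, c(decisions,
                                list(make.row.names = FALSE)))
  if (is.null(decisions))
    decisions <- data.frame(id = character(0), kept = logical(0),
                            reasons = character(0))
  list(kept = chains[decisions$kept], decisions = decisions)
}

#' Write chains to FASTA / read a FASTA file
#'
#' Headers are `structure-id_chain-id`. Round trip is exact:
#' `read_fasta(write_fasta(x))` reproduces ids and sequences.
#'
#' @param chains List of [chain_structure()] objects (or a character vector of
#'   sequences named by id).
#' @param path Output path.
#' @return `write_fasta`: `path` invisibly. `read_fasta`: data.frame with
#'   columns `id` and `sequence`.
#' @export
write_fasta <- function(chains, path) {
  if (is.list(chains) && length(chains) && inherits(chains[[1]], "chain_structure")) {
    seqs <- vapply(chains, function(c) c$sequence, character(1))
    names(seqs) <- vapply(chains, chain_id, character(1))
  } else {
    seqs <- unlist(chains)
    if (length(seqs) == 0) seqs <- character(0)
  }
  if (anyDuplicated(names(seqs)))
    stop("write_fasta: duplicate ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  data.frame(id = names(set), sequence = as.character(set),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the corpus manifest consumed by downstream stages
#'
#' @param chains All input chains (kept or not).
#' @param decisions Decision table from [filter_chains()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_corpus_manifest <- function(chains, decisions, path) {
  rows <- do.call(rbind, lapply(chains, function(ch) {
    data.frame(id = ch$structure_id, chain = ch$chain_id,
               length = chain_length(ch), method = ch$method,
               resolution = ch$resolution, stringsAsFactors = FALSE)
  }))
  rows$kept <- decisions$kept[match(paste0(rows$id, "_", rows$chain),
                                    decisions$id)]
  rows$reasons <- decisions$reasons[match(paste0(rows$id, "_", rows$chain),
                                          decisions$id)]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
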