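#' Kabsch least-RMSD rigid superposition
#'
#' Computes the rigid transform (proper rotation + translation) minimizing the
#' RMSD between two paired point sets, by singular value decomposition of the
#' cross-covariance matrix. Row-vector convention: the transform maps `y` onto
#' `x` as `y %*% rotation + translation`.
#'
#' @param x,y Numeric n x 3 matrices of paired points, n >= 3.
#' @return An object of class `superposition_result` with fields `rotation`
#'   (3 x 3, det +1), `translation` (length-3), `rmsd`, `n_aligned`; the
#'   TM-score fields are `NA` (use [tm_score()]).
#' @export
kabsch_superpose <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("kabsch_superpose: unequal point counts",
                               call. = FALSE)
  if (nrow(x) < 3) stop("kabsch_superpose: need at least 3 point pairs",
                        call. = FALSE)
  fit <- kabsch_fit(x, y)
  if (is.null(fit))
    stop("kabsch_superpose: degenerate (collinear) configuration",
         call. = FALSE)
  new_superposition(fit$R, fit$t, fit$rmsd, n_aligned = nrow(x))
}

# core fit, no validation; returns NULL on degenerate input
kabsch_fit <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  H <- crossprod(yc, xc)
  s <- tryCatch(svd(H), error = function(e) NULL)
  if (is.null(s)) return(NULL)
  # degenerate when two singular values vanish (collinear points)
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-30)) return(NULL)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) return(NULL)
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cx - as.numeric(cy %*% R)
  res <- sweep(yc %*% R, 2, cx - cx) - xc   # = yc%*%R - xc
  list(R = R, t = t, rmsd = sqrt(mean(rowSums(res^2))))
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix (row-vector convention).
#' @param translation Length-3 vector.
#' @return Transformed n x 3 matrix.
#' @export
transform_coords <- function(coords, rotation, translation) {
  sweep(coords %*% rotation, 2, -translation)
}

new_superposition <- function(R, t, rmsd, tm_a = NA_real_, tm_b = NA_real_,
                              n_aligned = NA_integer_) {
  structure(list(
    rotation = R, translation = t, rmsd = rmsd,
    tm_norm_a = tm_a, tm_norm_b = tm_b,
    tm_min = suppressWarnings(min(tm_a, tm_b)),
    tm_max = suppressWarnings(max(tm_a, tm_b)),
    n_aligned = as.integer(n_aligned)
  ), class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf(
    "<superposition_result> rmsd=%.3f  tm_a=%.4f  tm_b=%.4f  n=%d\n",
    x$rmsd, x$tm_norm_a, x$tm_norm_b, x$n_aligned))
  invisible(x)
}

#' TM-score distance scale d0
#'
#' `d0 = 1.24 * (Lnorm - 15)^(1/3) - 1.8`, with `Lnorm - 15` clamped at >= 1
#' before the cube root and the result clamped below at `d0_floor` (degenerate
#' short chains).
#'
#' @param l_norm Normalizing length.
#' @param d0_floor Lower clamp in Angstrom (default 0.5).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_norm, d0_floor = 0.5) {
  pmax(1.24 * pmax(l_norm - 15, 1)^(1/3) - 1.8, d0_floor)
}

#' TM-score with iterative fragment-seeded optimization
#'
#' Computes the TM-score between two chains under a fixed residue
#' correspondence. Superpositions are seeded from contiguous aligned fragments
#' of lengths n, n/2, n/4, ... (>= 4) at half-length offsets; each seed is
#' refined by repeatedly superposing on the residues within `d0` of their
#' partners (growing the cutoff by 0.5 Angstrom whenever fewer than 3 qualify)
#' until the score changes by less than 1e-6 or 20 iterations. The maximum
#' TM found is reported under both length normalizations.
#'
#' @param x,y Full-chain C-alpha coordinate matrices (La x 3, Lb x 3).
#' @param mapping An `alignment_map` pairing residues of `x` and `y`
#'   (1-based); at least 5 pairs.
#' @param normalize_by `"a"`, `"b"` or `"both"` (default): which chain length
#'   normalizes the score.
#' @param d0_floor Lower clamp for d0 (Angstrom).
#' @return A `superposition_result`; `rotation`/`translation` achieve the
#'   best score found and `rmsd` is the least-RMSD over all aligned pairs.
#' @export
tm_score <- function(x, y, mapping, normalize_by = c("both", "a", "b"),
                     d0_floor = 0.5) {
  normalize_by <- match.arg(normalize_by)
  x <- as.matrix(x); y <- as.matrix(y)
  pairs <- mapping$pairs
  if (nrow(pairs) < 5)
    stop("tm_score: need at least 5 aligned pairs", call. = FALSE)
  xs <- x[pairs[, 1], , drop = FALSE]
  ys <- y[pairs[, 2], , drop = FALSE]
  la <- nrow(x); lb <- nrow(y)

  res_a <- if (normalize_by %in% c("a", "both"))
    tm_search(xs, ys, tm_d0(la, d0_floor), la) else NULL
  res_b <- if (normalize_by %in% c("b", "both"))
    tm_search(xs, ys, tm_d0(lb, d0_floor), lb) else NULL

  tm_a <- if (is.null(res_a)) NA_real_ else res_a$tm
  tm_b <- if (is.null(res_b)) NA_real_ else res_b$tm
  best <- if (is.null(res_b) || (!is.null(res_a) && tm_a >= tm_b)) res_a else res_b
  allfit <- kabsch_fit(xs, ys)
  rmsd <- if (is.null(allfit)) NA_real_ else allfit$rmsd
  out <- new_superposition(best$R, best$t, rmsd, tm_a, tm_b,
                           n_aligned = nrow(pairs))
  if (normalize_by != "both") { out$tm_min <- NA_real_; out$tm_max <- NA_real_ }
  out
}

# Fragment-seeded iterative TM maximization for one normalization.
tm_search <- function(xs, ys, d0, l_norm, max_iter = 20, tol = 1e-6) {
  n <- nrow(xs)
  best <- list(tm = -Inf, R = diag(3), t = c(0, 0, 0))
  inv_d0_sq <- 1 / d0^2

  refine <- function(idx) {
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      fit <- kabsch_fit(xs[idx, , drop = FALSE], ys[idx, , drop = FALSE])
      if (is.null(fit)) break
      yt <- sweep(ys %*% fit$R, 2, -fit$t)
      dsq <- rowSums((yt - xs)^2)
      tm <- sum(1 / (1 + dsq * inv_d0_sq)) / l_norm
      if (tm > best$tm) best <<- list(tm = tm, R = fit$R, t = fit$t)
      cut <- d0
      sel <- which(dsq < cut^2)
      while (length(sel) < 3) { cut <- cut + 0.5; sel <- which(dsq < cut^2) }
      if (abs(tm - prev) < tol) break
      prev <- tm
      idx <- sel
    }
  }

  # short chains have rugged score landscapes and cheap refits: seed every
  # 4th fragment length there; halve lengths on longer chains
  if (n <= 60) {
    lens <- unique(c(seq(4, n, by = 4), n))
    stride <- function(l) max(1, l %/% 4)
  } else {
    frag <- n
    lens <- integer(0)
    while (frag >= 4) { lens <- c(lens, frag); frag <- frag %/% 2 }
    stride <- function(l) max(1, l %/% 3)
  }
  for (l in lens) {
    for (o in seq(1, n - l + 1, by = stride(l)))
      refine(o:(o + l - 1))
  }
  # polish: restart once from the inlier set of the best superposition found
  yt <- sweep(ys %*% best$R, 2, -best$t)
  dsq <- rowSums((yt - xs)^2)
  cut <- d0
  sel <- which(dsq < cut^2)
  while (length(sel) < 3) { cut <- cut + 0.5; sel <- which(dsq < cut^2) }
  refine(sel)
  best
}

#' Sequence-guided structural alignment of two chains
#'
#' Aligns the sequences globally, then computes the TM-score on the aligned
#' residue correspondence. Every comparison in the conformational-split
#' pipeline is within a high-identity sequence cluster, where a sequence
#' alignment determines the structural correspondence reliably; this is a
#' deliberate simplification relative to full structure-based alignment of
#' remote homologs.
#'
#' @param a,b [chain_structure()] objects (>= 5 residues each).
#' @param ... Passed to [global_align()].
#' @return List with `alignment` (`alignment_map`) and `superposition`
#'   (`superposition_result`).
#' @export
structural_align <- function(a, b, ...) {
  if (chain_length(a) < 5 || chain_length(b) < 5)
    stop("structural_align: chains must have >= 5 residues", call. = FALSE)
  aln <- global_align(a$sequence, b$sequence, ...)
  if (nrow(aln$pairs) < 5)
    stop("structural_align: fewer than 5 aligned pairs", call. = FALSE)
  sup <- tm_score(a$ca_coords, b$ca_coords, aln)
  list(alignment = aln, superposition = sup)
}

#' Batch pairwise structural scores
#'
#' Scores all unordered pairs in a list of chains and returns a tidy table;
#' pairs failing alignment preconditions are reported with `NA` scores.
#'
#' @param chains List of [chain_structure()] objects.
#' @param path Optional TSV output path.
#' @return data.frame with columns `id_a`, `id_b`, `tm_norm_a`, `tm_norm_b`,
#'   `tm_min`, `tm_max`, `rmsd`, `n_aligned`.
#' @export
pairwise_scores <- function(chains, path = NULL) {
  ids <- vapply(chains, chain_id, character(1))
  n <- length(chains)
  rows <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- tryCatch(structural_align(chains[[i]], chains[[j]])$superposition,
                    error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        id_a = ids[i], id_b = ids[j],
        tm_norm_a = if (is.null(s)) NA else s$tm_norm_a,
        tm_norm_b = if (is.null(s)) NA else s$tm_norm_b,
        tm_min = if (is.null(s)) NA else s$tm_min,
        tm_max = if (is.null(s)) NA else s$tm_max,
        rmsd = if (is.null(s)) NA else s$rmsd,
        n_aligned = if (is.null(s)) NA else s$n_aligned,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_a = character(0), id_b = character(0), tm_norm_a = numeric(0),
               tm_norm_b = numeric(0), tm_min = numeric(0), tm_max = numeric(0),
               rmsd = numeric(0), n_aligned = integer(0))
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
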