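# Independent brute-force oracles. Everything here is deliberately written
# from first principles (own Kabsch, own TM formula, own recursions) so that
# agreement with the package is a genuine cross-check, not a tautology.

# ---- global alignment: exhaustive enumeration (tiny sequences) -------------
# Scoring convention matches the package contract: a gap of length k costs
# gap_open + k * gap_extend (both negative).
oracle_align_score <- function(seq_a, seq_b, submat, gap_open = -11,
                               gap_extend = -1) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  # state: i, j = next positions; g = 0 none / 1 gap-in-a open / 2 gap-in-b
  rec <- function(i, j, g) {
    key <- paste(i, j, g)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b))
      best <- max(best, submat[a[i], b[j]] + rec(i + 1, j + 1, 0))
    if (j <= length(b))   # gap in a: b[j] unmatched
      best <- max(best, (if (g == 1) 0 else gap_open) + gap_extend +
                    rec(i, j + 1, 1))
    if (i <= length(a))   # gap in b: a[i] unmatched
      best <- max(best, (if (g == 2) 0 else gap_open) + gap_extend +
                    rec(i + 1, j, 2))
    memo[[key]] <- best
    best
  }
  rec(1, 1, 0)
}

# ---- own Kabsch (for the TM oracle's internal refits) ----------------------
oracle_kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  H <- t(y - matrix(cy, nrow(y), 3, byrow = TRUE)) %*%
    (x - matrix(cx, nrow(x), 3, byrow = TRUE))
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v))); if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cx - as.numeric(cy %*% R)
  yt <- y %*% R + matrix(t, nrow(y), 3, byrow = TRUE)
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((yt - x)^2))))
}

# ---- rotation grid -----------------------------------------------------
# Fibonacci-sphere axes x angle grid; returns minimal RMSD over the grid
# (translation optimal per rotation via centroid matching).
oracle_grid_rmsd <- function(x, y, n_axes = 400, angle_step_deg = 3) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n_axes) - 1
  z <- 1 - 2 * (k + 0.5) / n_axes
  r <- sqrt(pmax(1 - z^2, 0))
  axes <- cbind(r * cos(golden * k), r * sin(golden * k), z)
  angles <- seq(0, 180, by = angle_step_deg) * pi / 180
  best <- Inf
  for (i in seq_len(n_axes)) {
    u <- axes[i, ]
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
                byrow = TRUE)
    K2 <- K %*% K
    for (th in angles) {
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * K2
      # row-vector convention to match the package: y %*% t(R)
      yt <- yc %*% t(R)
      rmsd <- sqrt(mean(rowSums((yt - xc)^2)))
      if (rmsd < best) best <- rmsd
    }
  }
  best
}

# max displacement of a point at radius `rad` under a rotation error of
# `angle_deg` (bound for grid-resolution tolerance)
grid_rmsd_bound <- function(y, n_axes = 400, angle_step_deg = 3) {
  yc <- sweep(y, 2, colMeans(y))
  rad <- sqrt(max(rowSums(yc^2)))
  # axis resolution of a Fibonacci sphere ~ sqrt(4/n) rad; angle res as given
  ang <- sqrt(4 / n_axes) + angle_step_deg * pi / 180
  2 * rad * sin(ang / 2)
}

# ---- TM-score ----------------------------------------------------------
oracle_tm_d0 <- function(l_norm, d0_floor = 0.5)
  max(1.24 * max(l_norm - 15, 1)^(1/3) - 1.8, d0_floor)

oracle_tm_eval <- function(xs, ys, R, t, d0, l_norm) {
  yt <- ys %*% R + matrix(t, nrow(ys), 3, byrow = TRUE)
  d2 <- rowSums((yt - xs)^2)
  sum(1 / (1 + d2 / d0^2)) / l_norm
}

# exhaustive fragment seeds (every length from 4 to n in steps of 2, every
# offset) each refined by the distance-cutoff iteration, plus a fine
# rotation-grid polish around the best superposition found
oracle_tm <- function(xs, ys, l_norm, d0_floor = 0.5, max_iter = 30) {
  n <- nrow(xs)
  d0 <- oracle_tm_d0(l_norm, d0_floor)
  best <- list(tm = -Inf, R = diag(3), t = c(0, 0, 0))
  refine <- function(idx) {
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      f <- oracle_kabsch(xs[idx, , drop = FALSE], ys[idx, , drop = FALSE])
      tm <- oracle_tm_eval(xs, ys, f$R, f$t, d0, l_norm)
      if (tm > best$tm) best <<- list(tm = tm, R = f$R, t = f$t)
      yt <- ys %*% f$R + matrix(f$t, n, 3, byrow = TRUE)
      d <- sqrt(rowSums((yt - xs)^2))
      cut <- d0
      sel <- which(d < cut)
      while (length(sel) < 3) { cut <- cut + 0.5; sel <- which(d < cut) }
      if (abs(tm - prev) < 1e-7) break
      prev <- tm
      idx <- sel
    }
  }
  for (l in seq(4, n, by = 2)) {
    for (o in seq(1, n - l + 1)) refine(o:(o + l - 1))
  }
  refine(1:n)
  # local rotation polish about the best transform
  axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  axes <- axes / sqrt(rowSums(axes^2))
  center <- colMeans(ys)
  for (rep in 1:2) {
    improved <- FALSE
    for (i in seq_len(nrow(axes))) for (sgn in c(-1, 1))
      for (ang in c(0.5, 1, 2, 4) * pi / 180) {
        u <- axes[i, ]
        K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
                    byrow = TRUE)
        Rp <- diag(3) + sin(sgn * ang) * K + (1 - cos(sgn * ang)) * (K %*% K)
        R2 <- best$R %*% t(Rp)
        t2 <- best$t + center %*% best$R - center %*% R2
        tm <- oracle_tm_eval(xs, ys, R2, as.numeric(t2), d0, l_norm)
        if (tm > best$tm) {
          best <- list(tm = tm, R = R2, t = as.numeric(t2))
          improved <- TRUE
        }
      }
    if (!improved) break
  }
  best$tm
}

# ---- embedding metrics: direct elementwise re-evaluation -------------------
oracle_cosine_per_residue <- function(A, B) {
  acc <- 0
  for (i in seq_len(nrow(A))) {
    num <- sum(A[i, ] * B[i, ])
    acc <- acc + num / (sqrt(sum(A[i, ]^2)) * sqrt(sum(B[i, ]^2)))
  }
  acc / nrow(A)
}

oracle_cosine_frobenius <- function(A, B) {
  a <- as.numeric(A); b <- as.numeric(B)
  (sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))) / nrow(A)
}

oracle_pair_difference <- function(C, D) {
  acc <- 0
  for (k in seq_along(C)) acc <- acc + sqrt((C[k] - D[k])^2)
  acc / length(C)
}

# ---- Hamming nearest-centre scan -------------------------------------------
oracle_nearest_center <- function(seqs, centers) {
  mats <- strsplit(seqs, "")
  vapply(seq_along(seqs), function(r) {
    d <- vapply(centers, function(cc)
      sum(mats[[r]] != mats[[cc]]), numeric(1))
    centers[which.min(d)]
  }, integer(1))
}
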