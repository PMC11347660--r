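#' Build a toy C-alpha chain from a secondary-structure string
#'
#' Generates ideal-geometry C-alpha coordinates for a secondary-structure
#' string over `{H, E, C}`: helices with 1.5 Angstrom rise, 100 degrees per
#' residue and 2.3 Angstrom radius; strands as 3.3 Angstrom-rise zigzags;
#' coil as a self-avoiding walk with 3.8 Angstrom steps. Segments are attached
#' end-to-end with seeded random orientations, rejecting placements that bring
#' non-adjacent residues closer than 3 Angstrom (up to 100 retries each).
#' Deterministic for a fixed seed.
#'
#' @param ss_string Secondary-structure string over `{H, E, C}`, length >= 10.
#' @param seed Integer RNG seed.
#' @param sequence Optional amino-acid sequence (defaults to a seeded random
#'   sequence of matching length).
#' @param structure_id,chain_id Identifiers for the resulting chain.
#' @return A [chain_structure()] (`method = "xray"`, resolution 2.0) with
#'   attribute `"ss"` carrying the generating secondary-structure string.
#' @export
build_toy_chain <- function(ss_string, seed, sequence = NULL,
                            structure_id = "TOY", chain_id = "A") {
  ss <- strsplit(ss_string, "")[[1]]
  if (length(ss) < 10)
    stop("build_toy_chain: need at least 10 residues", call. = FALSE)
  if (!all(ss %in% c("H", "E", "C")))
    stop("build_toy_chain: ss_string must be over {H, E, C}", call. = FALSE)
  set.seed(as.integer(seed))
  coords <- grow_segments(ss)
  if (is.null(sequence))
    sequence <- random_aa_sequence(length(ss))
  out <- chain_structure(structure_id, chain_id, sequence, coords,
                         method = "xray", resolution = 2.0,
                         release_date = "2020-01-01")
  attr(out, "ss") <- ss_string
  out
}

random_aa_sequence <- function(L)
  paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")

# ideal local-frame segment coordinates (first residue at origin, axis +z)
ideal_segment <- function(type, n) {
  if (type == "H") {
    i <- 0:(n - 1)
    ang <- i * 100 * pi / 180
    cbind(2.3 * (cos(ang) - 1), 2.3 * sin(ang), 1.5 * i)
  } else {  # strand zigzag
    i <- 0:(n - 1)
    cbind(0.94 * ((i %% 2) * 2 - 1) - 0.94 * (0 %% 2 * 2 - 1), 0, 3.3 * i)
  }
}

# grow the chain segment by segment with clash rejection
grow_segments <- function(ss) {
  runs <- rle(ss)
  coords <- matrix(numeric(0), ncol = 3)
  dir <- c(0, 0, 1)
  for (k in seq_along(runs$values)) {
    type <- runs$values[k]; n <- runs$lengths[k]
    placed <- FALSE
    for (try in 1:100) {
      if (type == "C") {
        seg <- grow_coil(coords, dir, n)
        if (is.null(seg)) next
        new_coords <- rbind(coords, seg)
      } else {
        local <- ideal_segment(type, n)
        R <- random_rotation()
        seg <- local %*% R
        start <- if (nrow(coords) == 0) c(0, 0, 0) else
          coords[nrow(coords), ] + 3.8 * normalize(jitter_dir(dir))
        seg <- sweep(seg, 2, -start)
        new_coords <- rbind(coords, seg)
        if (has_clash(new_coords, nrow(coords))) next
      }
      coords <- new_coords
      if (nrow(coords) >= 2)
        dir <- normalize(coords[nrow(coords), ] - coords[nrow(coords) - 1, ])
      placed <- TRUE
      break
    }
    if (!placed)
      stop("build_toy_chain: clash rejection failed after 100 retries",
           call. = FALSE)
  }
  coords
}

grow_coil <- function(coords, dir, n) {
  seg <- matrix(NA_real_, n, 3)
  prev <- if (nrow(coords) == 0) c(0, 0, 0) - 3.8 * dir else
    coords[nrow(coords), ]
  cur_dir <- dir
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:50) {
      step <- normalize(cur_dir + 0.8 * stats::rnorm(3))
      cand <- prev + 3.8 * step
      ref <- rbind(coords, seg[seq_len(i - 1), , drop = FALSE])
      if (nrow(ref) > 1) {
        d <- sqrt(rowSums(sweep(ref[-nrow(ref), , drop = FALSE], 2, cand)^2))
        if (any(d < 3.0)) next
      }
      seg[i, ] <- cand
      prev <- cand; cur_dir <- step
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  seg
}

normalize <- function(v) v / sqrt(sum(v^2))

jitter_dir <- function(dir) normalize(dir + 0.5 * stats::rnorm(3))

# uniform random proper rotation from QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

has_clash <- function(coords, n_old, min_dist = 3.0) {
  n <- nrow(coords)
  if (n < 3) return(FALSE)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  d[cbind(1:(n - 1), 2:n)] <- Inf
  d[cbind(2:n, 1:(n - 1))] <- Inf
  any(d < min_dist)
}

#' Rotation matrix from axis and angle (Rodrigues)
#' @param axis Length-3 axis (normalized internally).
#' @param angle_deg Rotation angle in degrees.
#' @return 3 x 3 rotation matrix (row-vector convention: `x %*% R`).
#' @export
rotation_axis_angle <- function(axis, angle_deg) {
  u <- normalize(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t(R)  # row-vector convention
}

#' Apply a hinge rotation to a chain
#'
#' Rotates all residues after `hinge_index` rigidly about `axis` through the
#' hinge C-alpha, leaving both domains internally unchanged. Clashing results
#' are retried with a jittered axis (up to 100 times), then an error is
#' raised.
#'
#' @param chain A [chain_structure()].
#' @param hinge_index Pivot residue; must leave at least 25 residues on each
#'   side.
#' @param axis Rotation axis (3-vector).
#' @param angle_deg Rotation angle in degrees.
#' @return The hinged `chain_structure` (sequence and metadata unchanged).
#' @export
apply_hinge <- function(chain, hinge_index, axis, angle_deg) {
  L <- chain_length(chain)
  if (hinge_index < 25 || hinge_index > L - 25)
    stop("apply_hinge: hinge_index must leave >= 25 residues per side",
         call. = FALSE)
  if (angle_deg == 0) return(chain)
  xyz <- chain$ca_coords
  pivot <- xyz[hinge_index, ]
  cur_axis <- axis
  for (try in 1:100) {
    R <- rotation_axis_angle(cur_axis, angle_deg)
    new <- xyz
    tail_idx <- (hinge_index + 1):L
    new[tail_idx, ] <- sweep(sweep(xyz[tail_idx, , drop = FALSE], 2, pivot) %*%
                               R, 2, -pivot)
    if (!has_clash(new, 0, min_dist = 2.5)) {
      out <- chain
      out$ca_coords <- new
      return(out)
    }
    cur_axis <- normalize(cur_axis + 0.3 * stats::rnorm(3))
  }
  stop("apply_hinge: unresolvable clash after 100 axis retries",
       call. = FALSE)
}

#' Apply a multi-pivot rearrangement to a chain
#'
#' Re-poses the rigid secondary-structure segments by applying small seeded
#' rotations at pivots placed in the coil linkers, so that secondary structure
#' is preserved while no long contiguous block stays rigid. `magnitude`
#' scales the per-pivot rotation angles (degrees ~ 8 x magnitude); the
#' mapping to a TM-score is calibrated by bisection in
#' [make_alternative_conformation()].
#'
#' @param chain A [chain_structure()] (ideally from [build_toy_chain()]).
#' @param magnitude Non-negative deformation scale (Angstrom-scale
#'   displacement of downstream segments per pivot).
#' @param seed Integer RNG seed (axes and raw angles).
#' @return The rearranged `chain_structure`.
#' @export
apply_rearrangement <- function(chain, magnitude, seed) {
  if (magnitude == 0) return(chain)
  set.seed(as.integer(seed))
  L <- chain_length(chain)
  ss <- chain_ss(chain)
  pivots <- coil_pivots(ss)
  if (length(pivots) == 0)
    stop("apply_rearrangement: no coil linkers to pivot on", call. = FALSE)
  raw <- stats::runif(length(pivots), 0.5, 1) *
    sample(c(-1, 1), length(pivots), replace = TRUE)
  deform <- function(axes) {
    xyz <- chain$ca_coords
    for (k in seq_along(pivots)) {
      p <- pivots[k]
      if (p >= L) next
      R <- rotation_axis_angle(axes[k, ], 8 * magnitude * raw[k])
      pivot <- xyz[p, ]
      idx <- (p + 1):L
      xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, pivot) %*% R,
                          2, -pivot)
    }
    xyz
  }
  # magnitude-faithful clash handling: retry with re-drawn axes, same angles
  for (try in 0:100) {
    if (try > 0) set.seed(as.integer(seed) + try)
    xyz <- deform(matrix(stats::rnorm(3 * length(pivots)), ncol = 3))
    if (!has_clash(xyz, 0, min_dist = 2.5)) {
      out <- chain
      out$ca_coords <- xyz
      return(out)
    }
  }
  stop("apply_rearrangement: unresolvable clashes", call. = FALSE)
}

# secondary structure of a chain: the construction-time string when the
# chain came from build_toy_chain (geometry-assignment can blur designed
# linkers), otherwise assigned from geometry
chain_ss <- function(chain) {
  s <- attr(chain, "ss")
  if (!is.null(s)) strsplit(s, "")[[1]] else assign_ss_ca(chain)
}

# centers of internal coil runs
coil_pivots <- function(ss) {
  r <- rle(ss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mid <- floor((starts + ends) / 2)
  keep <- r$values == "C" & starts > 1 & ends < length(ss)
  mid[keep]
}

#' Rebuild a region with the complementary secondary structure (fold switch)
#'
#' Replaces the region's coordinates with ideal geometry of the complementary
#' state (helix becomes strand and vice versa; coil positions inside the
#' region become strand). The downstream part of the chain keeps its internal
#' geometry and is re-anchored as a rigid body as close as possible to its
#' original position (rotation about the new junction), so the structural
#' change is dominated by the switched region itself.
#'
#' @param chain A [chain_structure()].
#' @param region Integer vector of contiguous residue indices, length >= 15.
#' @param seed Integer RNG seed (orientation of the rebuilt region).
#' @return The fold-switched `chain_structure`.
#' @export
apply_fold_switch <- function(chain, region, seed = 1) {
  region <- as.integer(region)
  if (length(region) < 15)
    stop("apply_fold_switch: region must have >= 15 residues", call. = FALSE)
  if (any(diff(region) != 1))
    stop("apply_fold_switch: region must be contiguous", call. = FALSE)
  L <- chain_length(chain)
  if (region[1] < 2 || region[length(region)] > L)
    stop("apply_fold_switch: region out of range (must start >= 2)",
         call. = FALSE)
  set.seed(as.integer(seed))
  ss <- chain_ss(chain)
  comp <- c(H = "E", E = "H", C = "E")
  new_type <- comp[[names(sort(table(ss[region]), decreasing = TRUE))[1]]]
  xyz <- chain$ca_coords
  prev <- xyz[region[1] - 1, ]
  dir <- if (region[1] >= 3)
    normalize(prev - xyz[region[1] - 2, ]) else c(0, 0, 1)
  for (try in 1:100) {
    local <- ideal_segment(new_type, length(region))
    seg <- local %*% random_rotation()
    start <- prev + 3.8 * normalize(jitter_dir(dir))
    seg <- sweep(seg, 2, -start)
    new <- xyz
    new[region, ] <- seg
    if (region[length(region)] < L) {
      tail_idx <- (region[length(region)] + 1):L
      B <- xyz[tail_idx, , drop = FALSE]
      seg_end <- seg[nrow(seg), ]
      u <- B[1, ] - seg_end
      if (sum(u^2) < 1e-9) u <- dir
      q <- seg_end + 3.8 * normalize(u)
      X <- sweep(B, 2, B[1, ])       # downstream body in its internal frame
      Y <- sweep(B, 2, q)            # original positions relative to anchor
      R <- diag(3)
      if (nrow(B) >= 3) {
        s <- svd(crossprod(X, Y))
        dd <- sign(det(s$u %*% t(s$v)))
        if (dd == 0) dd <- 1
        R <- s$u %*% diag(c(1, 1, dd)) %*% t(s$v)
      }
      new[tail_idx, ] <- sweep(X %*% R, 2, -q)
    }
    if (!has_clash(new, 0, min_dist = 2.5)) {
      out <- chain
      out$ca_coords <- new
      if (!is.null(attr(out, "ss"))) {
        s <- strsplit(attr(out, "ss"), "")[[1]]
        s[region] <- new_type
        attr(out, "ss") <- paste(s, collapse = "")
      }
      return(out)
    }
  }
  stop("apply_fold_switch: unresolvable clashes after 100 retries",
       call. = FALSE)
}

#' Mutate a sequence to an exact target identity
#'
#' Substitutes residues at uniformly chosen positions (no indels) so that
#' exactly `round(target_identity * L)` positions remain identical to the
#' input.
#'
#' @param seq Amino-acid string.
#' @param target_identity Fraction in (0, 1].
#' @param seed Integer RNG seed.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, target_identity, seed) {
  if (target_identity <= 0 || target_identity > 1)
    stop("mutate_sequence: target_identity must be in (0, 1]", call. = FALSE)
  L <- nchar(seq)
  n_mut <- L - round(target_identity * L)
  if (n_mut == 0) return(seq)
  set.seed(as.integer(seed))
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(L, n_mut)
  for (p in pos)
    chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
  paste(chars, collapse = "")
}

#' Generate an alternative conformation at a planted aligned-region TM
#'
#' Produces a second conformation of `chain` by the requested change type,
#' calibrated by bisection on the deformation parameter so that the TM-score
#' (minimum normalization) between the two conformations hits `target_tm`
#' within `tol`. Fold switches rebuild the longest secondary-structure run
#' (>= 15 residues) and, when the resulting TM is still above target, add a
#' bisected hinge at a coil linker.
#'
#' @param chain Base conformation from [build_toy_chain()].
#' @param change_type `"hinge"`, `"rearrangement"` or `"fold_switch"`.
#' @param target_tm Planted aligned-region TM (typically in (0.3, 0.8)).
#' @param seed Integer RNG seed.
#' @param tol Calibration tolerance (default 0.03).
#' @return List with `chain` (the new conformation), `achieved_tm`,
#'   `change_type`.
#' @export
make_alternative_conformation <- function(chain,
    change_type = c("hinge", "rearrangement", "fold_switch"),
    target_tm, seed, tol = 0.03) {
  change_type <- match.arg(change_type)
  tm_to_base <- function(alt) {
    tm_score(chain$ca_coords, alt$ca_coords,
             identity_alignment(chain$sequence, alt$sequence))$tm_min
  }
  L <- chain_length(chain)
  set.seed(as.integer(seed))
  if (change_type == "hinge") {
    pivots <- coil_pivots(chain_ss(chain))
    pivots <- pivots[pivots >= 25 & pivots <= L - 25]
    if (length(pivots) == 0) pivots <- floor(L / 2)
    pivot <- pivots[which.min(abs(pivots - L / 2))]
    axis <- stats::rnorm(3)
    make <- function(par) apply_hinge(chain, pivot, axis, par)
    res <- bisect_tm(make, tm_to_base, target_tm, lo = 0, hi = 150, tol = tol)
  } else if (change_type == "rearrangement") {
    make <- function(par) apply_rearrangement(chain, par, seed = seed + 17)
    res <- bisect_tm(make, tm_to_base, target_tm, lo = 0, hi = 12, tol = tol)
  } else {
    # a C-terminal region avoids displacing any downstream body: region
    # length is set from the target (the untouched prefix bounds the TM from
    # above), then a hinge on the retained part tunes the score down
    ssv <- chain_ss(chain)
    region_len <- max(15, min(round(L * (1 - target_tm) * 1.3), L - 30))
    res <- NULL; best <- NULL
    for (attempt in 1:6) {
      region <- (L - region_len + 1):L
      fs <- tryCatch(apply_fold_switch(chain, region,
                                       seed = seed + 29 + attempt),
                     error = function(e) NULL)
      if (!is.null(fs)) {
        tm_fs <- tm_to_base(fs)
        if (is.null(best) ||
            abs(tm_fs - target_tm) < abs(best$achieved_tm - target_tm))
          best <- list(chain = fs, achieved_tm = tm_fs)
        if (abs(tm_fs - target_tm) <= tol) {
          res <- list(chain = fs, achieved_tm = tm_fs)
          break
        }
        if (tm_fs > target_tm) {
          pivots <- coil_pivots(ssv)
          pivots <- pivots[pivots >= 25 &
                             pivots <= min(L - 25, region[1] - 1)]
          if (length(pivots) > 0) {
            pivot <- pivots[which.min(abs(pivots - L / 2))]
            axis <- stats::rnorm(3)
            make <- function(par) apply_hinge(fs, pivot, axis, par)
            r2 <- tryCatch(
              bisect_tm(make, tm_to_base, target_tm, lo = 0, hi = 150,
                        tol = tol), error = function(e) NULL)
            if (!is.null(r2)) {
              if (abs(r2$achieved_tm - target_tm) <
                  abs(best$achieved_tm - target_tm)) best <- r2
              if (abs(r2$achieved_tm - target_tm) <= max(tol, 0.05)) {
                res <- r2
                break
              }
            }
          }
          break  # above target but no tunable pivot: fall back to `best`
        }
        # below target: shrink the switched region and retry
        region_len <- max(15, round(region_len * 0.8))
      }
    }
    if (is.null(res)) {
      if (!is.null(best) &&
          abs(best$achieved_tm - target_tm) <= max(tol, 0.05)) {
        res <- best
      } else {
        stop("make_alternative_conformation: calibration failure for ",
             "fold switch on ", chain_id(chain),
             sprintf(" (best TM %.2f, target %.2f)",
                     if (is.null(best)) NA_real_ else best$achieved_tm,
                     target_tm), call. = FALSE)
      }
    }
  }
  list(chain = res$chain, achieved_tm = res$achieved_tm,
       change_type = change_type)
}

# bisection on a deformation parameter; TM assumed non-increasing in par
bisect_tm <- function(make, tm_fun, target, lo, hi, tol, max_iter = 18) {
  alt_hi <- make(hi)
  tm_hi <- tm_fun(alt_hi)
  if (tm_hi > target) {
    # even the strongest deformation stays above target
    if (abs(tm_hi - target) <= max(tol, 0.05))
      return(list(chain = alt_hi, achieved_tm = tm_hi))
    stop("calibration failure: deformation range cannot reach target TM",
         call. = FALSE)
  }
  best <- list(chain = alt_hi, achieved_tm = tm_hi)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    alt <- make(mid)
    tm <- tm_fun(alt)
    if (abs(tm - target) < abs(best$achieved_tm - target))
      best <- list(chain = alt, achieved_tm = tm)
    if (abs(tm - target) <= tol) break
    if (tm > target) lo <- mid else hi <- mid
  }
  best
}

#' Generator configuration for a synthetic benchmark corpus
#'
#' Defaults describe the study conditions used throughout the package's
#' benchmarks: 50 sequence families of 3 members each, 10% of families given
#' a second conformation with an aligned-region TM drawn from [0.55, 0.75]
#' (a 0.25-0.45 TM gap from self-identity, comfortably beyond the >0.2
#' alternative-conformation threshold), equal mixture of change types,
#' chain lengths 70-120, 0.3 Angstrom coordinate noise, and 95% within-family
#' sequence identity (clustered together at the 90% tier, apart at 30%).
#'
#' @param n_families Number of sequence families.
#' @param members_per_family Members per family in the base conformation.
#' @param fraction_alternative Fraction of families given a second
#'   conformation.
#' @param n_alt_members Members added in the second conformation per
#'   alternative family.
#' @param change_type_mix Named probabilities over hinge, rearrangement,
#'   fold_switch (must sum to 1).
#' @param length_range Chain-length range (min >= 50 to pass corpus filters).
#' @param noise Coordinate noise (Angstrom, per axis) added to each member.
#' @param within_identity Within-family sequence identity of members.
#' @param alt_tm_range Range the planted aligned-region TM is drawn from.
#' @param seed Integer RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_families = 50, members_per_family = 3,
                             fraction_alternative = 0.1, n_alt_members = 2,
                             change_type_mix = c(hinge = 1 / 3,
                                                 rearrangement = 1 / 3,
                                                 fold_switch = 1 / 3),
                             length_range = c(70, 120), noise = 0.3,
                             within_identity = 0.95,
                             alt_tm_range = c(0.55, 0.75), seed = 1) {
  if (abs(sum(change_type_mix) - 1) > 1e-9)
    stop("generator_config: change_type_mix must sum to 1", call. = FALSE)
  if (length_range[1] < 50)
    stop("generator_config: minimum length must be >= 50 (corpus filter)",
         call. = FALSE)
  structure(list(n_families = n_families,
                 members_per_family = members_per_family,
                 fraction_alternative = fraction_alternative,
                 n_alt_members = n_alt_members,
                 change_type_mix = change_type_mix,
                 length_range = length_range, noise = noise,
                 within_identity = within_identity,
                 alt_tm_range = alt_tm_range, seed = as.integer(seed)),
            class = "generator_config")
}

# a two-domain architecture with internal coil linkers, hinge-able at the
# central linker and pivot-able inside each domain
domain_ss_string <- function(L) {
  make_domain <- function(n) {
    out <- character(0)
    types <- c("H", "E")
    t <- 1
    while (n > 0) {
      seg <- min(n, if (types[t] == "H") 16 else 10)
      out <- c(out, strrep(types[t], seg))
      n <- n - seg
      if (n > 0) {
        link <- min(n, 4)
        out <- c(out, strrep("C", link))
        n <- n - link
      }
      t <- 3 - t
    }
    paste(out, collapse = "")
  }
  half <- floor((L - 5) / 2)
  paste0(make_domain(half), strrep("C", 5), make_domain(L - 5 - half))
}

#' Generate a synthetic benchmark corpus with planted ground truth
#'
#' Builds a corpus of C-alpha chains grouped into sequence families: each
#' family has a base fold, members at the configured within-family identity
#' with coordinate noise, and (for alternative families) extra members in a
#' second conformation generated by the configured change type and calibrated
#' to a planted aligned-region TM. Between-family sequences are independent
#' random sequences (expected identity well below the 30% clustering tier).
#' All chains pass the standard corpus filters by construction.
#'
#' @param config A [generator_config()].
#' @return List with `corpus` (list of [chain_structure()]) and `manifest`
#'   (list with `families`, `alternative_families` data.frames and
#'   `rng_seed`).
#' @export
make_benchmark <- function(config = generator_config()) {
  set.seed(config$seed)
  F <- config$n_families
  n_alt <- round(config$fraction_alternative * F)
  alt_families <- if (n_alt > 0) sort(sample(F, n_alt)) else integer(0)
  types <- names(config$change_type_mix)
  alt_types <- if (n_alt > 0)
    sample(types, n_alt, replace = TRUE, prob = config$change_type_mix)
  else character(0)
  targets <- stats::runif(n_alt, config$alt_tm_range[1],
                          config$alt_tm_range[2])
  lengths <- sample(config$length_range[1]:config$length_range[2], F,
                    replace = TRUE)

  corpus <- list()
  fam_rows <- list(); alt_rows <- list()
  for (f in seq_len(F)) {
    fseed <- config$seed + 1000L * f
    base <- build_toy_chain(domain_ss_string(lengths[f]), seed = fseed,
                            structure_id = sprintf("F%03dM1", f))
    member_ids <- character(0)
    add_member <- function(m, conf_chain) {
      set.seed(fseed + 7L * m)
      ch <- conf_chain
      ch$structure_id <- sprintf("F%03dM%d", f, m)
      ch$sequence <- if (m == 1) base$sequence else
        mutate_sequence(base$sequence, config$within_identity,
                        seed = fseed + 7L * m + 1L)
      set.seed(fseed + 7L * m + 2L)
      ch$ca_coords <- conf_chain$ca_coords +
        matrix(stats::rnorm(3 * chain_length(ch), sd = config$noise),
               ncol = 3)
      ch
    }
    for (m in seq_len(config$members_per_family)) {
      ch <- add_member(m, base)
      corpus[[length(corpus) + 1]] <- ch
      member_ids <- c(member_ids, chain_id(ch))
    }
    k <- match(f, alt_families)
    if (!is.na(k)) {
      alt <- make_alternative_conformation(base, alt_types[k],
                                           target_tm = targets[k],
                                           seed = fseed + 500L)
      for (m in seq_len(config$n_alt_members)) {
        ch <- add_member(config$members_per_family + m, alt$chain)
        corpus[[length(corpus) + 1]] <- ch
        member_ids <- c(member_ids, chain_id(ch))
      }
      alt_rows[[length(alt_rows) + 1]] <- data.frame(
        family_id = sprintf("F%03d", f), change_type = alt_types[k],
        planted_aligned_tm = targets[k], achieved_tm = alt$achieved_tm,
        stringsAsFactors = FALSE)
    }
    fam_rows[[length(fam_rows) + 1]] <- data.frame(
      family_id = sprintf("F%03d", f),
      member_ids = I(list(member_ids)),
      planted_identity = config$within_identity,
      is_alternative = !is.na(k), stringsAsFactors = FALSE)
  }
  manifest <- list(
    families = do.call(rbind, fam_rows),
    alternative_families = if (length(alt_rows)) do.call(rbind, alt_rows) else
      data.frame(family_id = character(0), change_type = character(0),
                 planted_aligned_tm = numeric(0), achieved_tm = numeric(0)),
    rng_seed = config$seed)
  list(corpus = corpus, manifest = manifest)
}

#' Generate a synthetic prediction ensemble between two conformations
#'
#' Emulates a conformational-sampling run: `round(mix * n_samples)` samples
#' are noisy copies of `native_b` and the rest of `native_a`. Per-residue
#' confidence follows `plddt_i = 100 * exp(-dev_i / 4) + eps`, where `dev_i`
#' is the residue's deviation from its source native and `eps` is Gaussian
#' reporting noise scaled by `noise`, clipped to [0, 100]; an undistorted
#' residue scores exactly 100.
#'
#' @param native_a,native_b [chain_structure()] objects of equal length.
#' @param n_samples Number of samples.
#' @param mix Fraction of samples drawn from `native_b`, in [0, 1].
#' @param noise Coordinate noise per axis (Angstrom).
#' @param seed Integer RNG seed.
#' @param target_id Ensemble identifier.
#' @return A `prediction_ensemble`; each sample carries attribute `"source"`
#'   (`"a"` or `"b"`).
#' @export
make_synthetic_ensemble <- function(native_a, native_b, n_samples, mix,
                                    noise, seed, target_id = "synthetic") {
  if (chain_length(native_a) != chain_length(native_b))
    stop("make_synthetic_ensemble: natives must share length", call. = FALSE)
  if (mix < 0 || mix > 1)
    stop("make_synthetic_ensemble: mix must be in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  n_b <- round(mix * n_samples)
  L <- chain_length(native_a)
  samples <- lapply(seq_len(n_samples), function(k) {
    src <- if (k <= n_b) native_b else native_a
    disp <- matrix(stats::rnorm(3 * L, sd = noise), ncol = 3)
    ch <- src
    ch$structure_id <- sprintf("%s_s%03d", target_id, k)
    ch$ca_coords <- src$ca_coords + disp
    dev <- sqrt(rowSums(disp^2))
    plddt <- pmin(pmax(100 * exp(-dev / 4) +
                         stats::rnorm(L, sd = 2 * noise), 0), 100)
    out <- list(chain = ch, plddt = plddt)
    attr(out, "source") <- if (k <= n_b) "b" else "a"
    out
  })
  new_prediction_ensemble(target_id, samples)
}

#' Generate synthetic embedding pairs with a planted association
#'
#' Draws per-target pair-embedding differences and TM-like outcomes from a
#' Gaussian copula with Spearman rank correlation `planted_rho` (latent
#' Pearson `2 sin(pi rho / 6)`), and materializes embedding tensors whose
#' [pair_embedding_difference()] equals the drawn difference exactly.
#'
#' @param n_pairs Number of embedding pairs.
#' @param L,d,c Tensor dimensions (single: L x d; pair: L x L x c).
#' @param planted_rho Target Spearman correlation in [-1, 1].
#' @param seed Integer RNG seed.
#' @return List with `pairs` (list of `embedding_pair`), `outcomes`
#'   (TM-like values in (0.4, 1)), `deltas` (the planted differences).
#' @export
make_synthetic_embeddings <- function(n_pairs, L, d, c, planted_rho, seed) {
  if (abs(planted_rho) > 1)
    stop("make_synthetic_embeddings: planted_rho must be in [-1, 1]",
         call. = FALSE)
  set.seed(as.integer(seed))
  r_latent <- 2 * sin(pi * planted_rho / 6)
  z1 <- stats::rnorm(n_pairs)
  z2 <- r_latent * z1 + sqrt(1 - r_latent^2) * stats::rnorm(n_pairs)
  deltas <- exp(0.4 * z1)             # monotone in z1: ranks preserved
  outcomes <- 0.4 + 0.6 * stats::pnorm(z2)
  pairs <- lapply(seq_len(n_pairs), function(k) {
    sa <- matrix(stats::rnorm(L * d), L, d)
    sb <- sa + matrix(stats::rnorm(L * d, sd = 0.1), L, d)
    pa <- array(stats::rnorm(L * L * c), dim = c(L, L, c))
    pb <- pa + deltas[k]
    embedding_pair(sa, sb, pa, pb)
  })
  list(pairs = pairs, outcomes = outcomes, deltas = deltas)
}
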