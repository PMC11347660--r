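test_that("toy chains realize ideal helix and strand geometry", {
  h <- build_toy_chain(strrep("H", 20), seed = 1)
  d13 <- sqrt(rowSums((h$ca_coords[4:20, ] - h$ca_coords[1:17, ])^2))
  expect_true(all(d13 > 4.8 & d13 < 5.6))   # helix i,i+3 signature

  e <- build_toy_chain(strrep("E", 10), seed = 2)
  ee <- sqrt(sum((e$ca_coords[10, ] - e$ca_coords[1, ])^2))
  expect_gt(ee, 0.9 * 3.3 * 9)              # extended end-to-end

  mixed <- build_toy_chain(paste0(strrep("H", 16), strrep("C", 4),
                                  strrep("E", 10)), seed = 3)
  d <- sqrt(rowSums(diff(mixed$ca_coords)^2))
  expect_true(all(d > 3.0 & d < 4.2))       # geometry sanity, base chain
  dm <- as.matrix(dist(mixed$ca_coords))
  dm[abs(row(dm) - col(dm)) <= 1] <- Inf
  expect_gt(min(dm), 2.9)                   # clash-free

  expect_identical(build_toy_chain(strrep("H", 20), seed = 1)$ca_coords,
                   h$ca_coords)             # determinism
  expect_error(build_toy_chain("HHH", seed = 1), "at least 10")
  expect_error(build_toy_chain(strrep("Q", 12), seed = 1), "H, E, C")
})

test_that("hinges leave both domains internally rigid", {
  ch <- build_toy_chain(confsplit:::domain_ss_string(80), seed = 4)
  expect_identical(apply_hinge(ch, 40, c(1, 0, 0), 0)$ca_coords,
                   ch$ca_coords)
  h <- apply_hinge(ch, 40, c(0, 1, 0), 60)
  for (idx in list(1:40, 41:80)) {
    f <- confsplit:::kabsch_fit(ch$ca_coords[idx, ], h$ca_coords[idx, ])
    expect_lt(f$rmsd, 1e-9)
  }
  d <- sqrt(rowSums(diff(h$ca_coords)^2))
  expect_lt(max(d), 10)                    # no chain break at the pivot
  expect_error(apply_hinge(ch, 10, c(1, 0, 0), 30), "25")
})

test_that("hinge sweeps lower tm_min monotonically", {
  ch <- build_toy_chain(confsplit:::domain_ss_string(70), seed = 5)
  aln <- identity_alignment(ch$sequence, ch$sequence)
  tms <- vapply(seq(0, 90, 10), function(ang) {
    h <- apply_hinge(ch, 35, c(0, 0, 1), ang)
    tm_score(ch$ca_coords, h$ca_coords, aln)$tm_min
  }, numeric(1))
  expect_true(all(diff(tms) <= 1e-9))
  expect_equal(tms[1], 1)
})

test_that("rearrangements preserve secondary structure without rigid bodies", {
  ch <- build_toy_chain(confsplit:::domain_ss_string(100), seed = 6)
  expect_identical(apply_rearrangement(ch, 0, seed = 1)$ca_coords,
                   ch$ca_coords)
  r <- apply_rearrangement(ch, 6, seed = 7)
  expect_false(identical(r$ca_coords, ch$ca_coords))
  d <- sqrt(rowSums(diff(r$ca_coords)^2))
  expect_lt(max(d), 10)
  # secondary structure is carried over (segments re-posed rigidly)
  expect_gt(mean(assign_ss_ca(ch) == assign_ss_ca(r)), 0.85)
})

test_that("fold switches convert the region's assigned state", {
  ch <- build_toy_chain(confsplit:::domain_ss_string(100), seed = 8)
  ssv <- strsplit(attr(ch, "ss"), "")[[1]]
  r <- rle(ssv); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  pick <- which(r$values == "H" & r$lengths >= 15 & starts >= 2)[1]
  region <- starts[pick]:ends[pick]
  fs <- apply_fold_switch(ch, region, seed = 9)
  ss_new <- assign_ss_ca(fs)
  expect_gte(mean(ss_new[region] == "E"), 0.8)   # helix rebuilt as strand
  expect_error(apply_fold_switch(ch, region[1:10], seed = 1), ">= 15")
})

test_that("sequence mutation hits exact identity targets", {
  s <- strrep("A", 100)
  expect_equal(mutate_sequence(s, 1.0, 1), s)
  m <- mutate_sequence(s, 0.9, 1)
  expect_equal(sum(strsplit(m, "")[[1]] == "A"), 90L)
  idents <- vapply(1:20, function(i) {
    mm <- mutate_sequence(s, 0.3, i)
    mean(strsplit(mm, "")[[1]] == strsplit(s, "")[[1]])
  }, numeric(1))
  expect_true(all(idents == 0.3))
  expect_error(mutate_sequence(s, 0, 1), "target_identity")
})

test_that("benchmark corpora respect their configuration and filters", {
  cfg0 <- generator_config(n_families = 4, fraction_alternative = 0,
                           seed = 10)
  bm0 <- make_benchmark(cfg0)
  expect_equal(nrow(bm0$manifest$alternative_families), 0L)
  expect_length(bm0$corpus, 4 * 3)

  cfg <- generator_config(n_families = 6, fraction_alternative = 1 / 3,
                          seed = 11)
  bm <- make_benchmark(cfg)
  expect_equal(nrow(bm$manifest$alternative_families), 2L)
  expect_true(all(abs(bm$manifest$alternative_families$achieved_tm -
                        bm$manifest$alternative_families$planted_aligned_tm)
                  <= 0.05))
  expect_true(all(bm$manifest$alternative_families$planted_aligned_tm > 0.3 &
                    bm$manifest$alternative_families$planted_aligned_tm < 0.8))
  # every generated chain passes the corpus filter
  flt <- filter_chains(bm$corpus)
  expect_length(flt$kept, length(bm$corpus))
  # determinism: same config, same corpus
  bm2 <- make_benchmark(cfg)
  expect_identical(lapply(bm$corpus, `[[`, "ca_coords"),
                   lapply(bm2$corpus, `[[`, "ca_coords"))
  expect_identical(bm$manifest, bm2$manifest)
  expect_error(generator_config(length_range = c(40, 80)), ">= 50")
  expect_error(generator_config(change_type_mix = c(hinge = 0.5,
                                                    rearrangement = 0.2,
                                                    fold_switch = 0.2)),
               "sum to 1")
})

test_that("synthetic ensembles honor mix, noise and the confidence map", {
  nat_a <- build_toy_chain(confsplit:::domain_ss_string(60), seed = 12,
                           structure_id = "EA")
  nat_b <- make_alternative_conformation(nat_a, "hinge", 0.6,
                                         seed = 13)$chain
  nat_b$structure_id <- "EB"

  pure_b <- make_synthetic_ensemble(nat_a, nat_b, 3, mix = 1, noise = 0,
                                    seed = 14)
  for (s in pure_b$samples) {
    tm <- structural_align(s$chain, nat_b)$superposition$tm_max
    expect_equal(tm, 1, tolerance = 1e-6)
    expect_equal(s$plddt, rep(100, 60))   # undistorted residues score 100
  }
  mixed <- make_synthetic_ensemble(nat_a, nat_b, 10, mix = 0.5, noise = 0.4,
                                   seed = 15)
  src <- vapply(mixed$samples, attr, character(1), "source")
  expect_equal(sum(src == "b"), 5L)
  expect_true(all(vapply(mixed$samples, function(s)
    all(s$plddt >= 0 & s$plddt <= 100), logical(1))))
  expect_error(make_synthetic_ensemble(nat_a, nat_b, 3, mix = 2, noise = 0,
                                       seed = 1), "mix")
})

test_that("synthetic embeddings have requested shapes and associations", {
  syn <- make_synthetic_embeddings(n_pairs = 5, L = 10, d = 8, c = 4,
                                   planted_rho = 0.5, seed = 16)
  expect_length(syn$pairs, 5L)
  expect_equal(dim(syn$pairs[[1]]$single_a), c(10L, 8L))
  expect_equal(dim(syn$pairs[[1]]$pair_a), c(10L, 10L, 4L))
  expect_equal(vapply(syn$pairs, pair_embedding_difference, numeric(1)),
               syn$deltas, tolerance = 1e-12)

  strong <- make_synthetic_embeddings(150, 4, 3, 2, planted_rho = 1,
                                      seed = 17)
  d <- vapply(strong$pairs, pair_embedding_difference, numeric(1))
  est <- embedding_structure_association(d, strong$outcomes, n_perm = 200)
  expect_gt(est$rho, 0.95)
  expect_error(make_synthetic_embeddings(5, 4, 3, 2, planted_rho = 2,
                                         seed = 1), "planted_rho")
})
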