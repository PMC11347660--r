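mk_seq_cluster <- function(id, members, rep = members[1])
  structure(list(cluster_id = id, representative_id = rep,
                 member_ids = members, identity_threshold = 0.9,
                 coverage_threshold = 0.8), class = "sequence_cluster")

mk_struct_cluster <- function(id, members, rep = members[1])
  structure(list(cluster_id = id, parent_sequence_cluster_id = "p",
                 representative_id = rep, member_ids = members,
                 tm_threshold = 0.8), class = "structural_cluster")

test_that("candidate detection finds 90% clusters spanning structures", {
  s90 <- list(mk_seq_cluster("s1", c("a", "b")),
              mk_seq_cluster("s2", c("c", "d", "e")))
  # all in one structural cluster each -> no candidates
  sc <- list(mk_struct_cluster("t1", c("a", "b")),
             mk_struct_cluster("t2", c("c", "d", "e")))
  expect_equal(nrow(detect_candidate_clusters(s90, sc)), 0L)

  # one 90% cluster spanning three structural clusters -> one candidate
  sc3 <- list(mk_struct_cluster("t1", c("a", "b")),
              mk_struct_cluster("t2", "c"), mk_struct_cluster("t3", "d"),
              mk_struct_cluster("t4", "e"))
  cand <- detect_candidate_clusters(s90, sc3)
  expect_equal(cand$seq90_cluster_id, "s2")
  expect_setequal(cand$struct_cluster_ids[[1]], c("t2", "t3", "t4"))

  # unassigned structure -> error naming it
  sc_bad <- list(mk_struct_cluster("t1", c("a", "b")),
                 mk_struct_cluster("t2", c("c", "d")))
  expect_error(detect_candidate_clusters(s90, sc_bad), "e")
})

test_that("degenerate identical pair scores TM 1 and is not alternative", {
  ch <- toy_chain(55, seed = 40, id = "DG")
  p <- score_conformer_pair(ch, ch)
  expect_equal(p$tm_aligned_region, 1)
  expect_false(p$is_alternative)
  expect_equal(p$overlap_fraction, 1)
})

test_that("a planted hinge pair is alternative; a terminal tail is not", {
  base <- build_toy_chain(confsplit:::domain_ss_string(90), seed = 41,
                          structure_id = "HG")
  alt <- make_alternative_conformation(base, "hinge", target_tm = 0.65,
                                       seed = 42)
  b <- alt$chain; b$structure_id <- "HG2"
  p <- score_conformer_pair(base, b)
  expect_true(p$is_alternative)
  expect_lt(abs(p$tm_aligned_region - 0.65), 0.06)

  # same fold plus a 15-residue disordered terminus: alignment excludes it
  long <- build_toy_chain(paste0(attr(base, "ss"), strrep("C", 15)),
                          seed = 43, structure_id = "TL")
  core <- subset_chain(long, 1:90)
  core$structure_id <- "TLCORE"
  p2 <- score_conformer_pair(core, long)
  expect_gt(p2$tm_aligned_region, 0.9)
  expect_false(p2$is_alternative)
})

test_that("representative selection follows (overlap, TM difference)", {
  p1 <- fake_pair("a1", "b1", overlap_fraction = 0.95, tm = 0.70)
  p2 <- fake_pair("a2", "b2", overlap_fraction = 0.80, tm = 0.55)
  expect_equal(select_representatives(list(p1, p2))[[1]]$id_a, "a1")

  p3 <- fake_pair("a3", "b3", overlap_fraction = 0.9, tm = 0.70)
  p4 <- fake_pair("a4", "b4", overlap_fraction = 0.9, tm = 0.60)
  expect_equal(select_representatives(list(p3, p4))[[1]]$id_a, "a4")

  expect_equal(select_representatives(list(p1))[[1]]$id_a, "a1")
  # one representative per structural-cluster pair
  p5 <- fake_pair("a5", "b5", 0.9, 0.5, sc_a = "sc1", sc_b = "sc3")
  sel <- select_representatives(list(p3, p4, p5))
  expect_length(sel, 2L)
})

test_that("curation rejects terminal-only, broken and low-overlap pairs", {
  base <- toy_chain(55, seed = 44, id = "CU")
  # terminal-only deviation: swing the last 12 residues
  b <- base; b$structure_id <- "CU2"
  R <- rotation_axis_angle(c(0, 1, 0), 140)
  pivot <- b$ca_coords[43, ]
  idx <- 44:55
  b$ca_coords[idx, ] <- sweep(sweep(b$ca_coords[idx, ], 2, pivot) %*% R,
                              2, -pivot)
  p <- score_conformer_pair(base, b)
  expect_true(p$is_alternative)   # full-length TM drops below 0.8
  chains <- list(base, b)
  names(chains) <- vapply(chains, chain_id, character(1))
  kept <- automated_curation(list(p), chains)
  expect_length(kept, 0L)
  expect_equal(attr(kept, "rejected")$rule, "terminal_only")

  # chain break: translate the second half far away
  br <- base; br$structure_id <- "CU3"
  br$ca_coords[30:55, ] <- br$ca_coords[30:55, ] +
    matrix(c(15, 0, 0), 26, 3, byrow = TRUE)
  p_br <- score_conformer_pair(base, br)
  expect_true(p_br$is_alternative)
  chains2 <- list(base, br)
  names(chains2) <- vapply(chains2, chain_id, character(1))
  kept2 <- automated_curation(list(p_br), chains2)
  expect_length(kept2, 0L)
  expect_equal(attr(kept2, "rejected")$rule, "chain_break")

  # genuine full-length hinge is retained
  hull <- build_toy_chain(confsplit:::domain_ss_string(90), seed = 45,
                          structure_id = "CU4")
  alt <- make_alternative_conformation(hull, "hinge", 0.6, seed = 46)$chain
  alt$structure_id <- "CU5"
  p_ok <- score_conformer_pair(hull, alt)
  chains3 <- list(hull, alt)
  names(chains3) <- vapply(chains3, chain_id, character(1))
  kept3 <- automated_curation(list(p_ok), chains3)
  expect_length(kept3, 1L)
})

test_that("splits assign every cluster once and isolate alternatives", {
  ids <- sprintf("c%03d", 1:100)
  m <- make_split(ids, list(), seed = 1, val_fraction = 0.05)
  tab <- table(factor(m$assignment, levels = c("train", "val", "test")))
  expect_equal(unname(tab["val"]), 5)
  expect_equal(unname(tab["train"]), 95)
  expect_equal(unname(tab["test"]), 0)

  # one alternative set of three clusters: exactly 1 train-side, 2 test
  pairs <- list(fake_pair("x", "y", 1, 0.6, sc_a = "c001", sc_b = "c002"),
                fake_pair("x", "z", 1, 0.6, sc_a = "c002", sc_b = "c003"))
  m2 <- make_split(ids, pairs, seed = 7)
  set_assign <- m2$assignment[c("c001", "c002", "c003")]
  expect_equal(sum(set_assign == "test"), 2)
  expect_equal(sum(set_assign %in% c("train", "val")), 1)
  expect_length(m2$alternative_sets, 1L)

  # determinism and seed variability
  expect_identical(make_split(ids, pairs, seed = 7), m2)
  picks <- vapply(1:10, function(s) {
    mm <- make_split(ids, pairs, seed = s)
    names(which(mm$assignment[c("c001", "c002", "c003")] != "test"))
  }, character(1))
  expect_gt(length(unique(picks)), 1L)

  expect_error(make_split(ids, list(), seed = 1, val_fraction = 0.6),
               "val_fraction")
  bad <- list(fake_pair("x", "y", 1, 0.6, sc_a = "c001", sc_b = "zzz"))
  expect_error(make_split(ids, bad, seed = 1), "unknown structural cluster")
})

test_that("verify_split passes sound manifests and flags corrupted ones", {
  ids <- sprintf("c%03d", 1:40)
  pairs <- list(fake_pair("x", "y", 1, 0.55, sc_a = "c001", sc_b = "c002"))
  m <- make_split(ids, pairs, seed = 3)
  rep <- verify_split(m, ids, pairs)
  expect_true(rep$ok)
  expect_equal(sum(rep$counts), 40)

  m_bad <- m
  m_bad$assignment[c("c001", "c002")] <- "train"
  rep_bad <- verify_split(m_bad, ids, pairs)
  expect_false(rep_bad$ok)
  expect_match(paste(rep_bad$violations, collapse = "; "), "c001")
})

test_that("split manifests serialize with their sidecar", {
  ids <- sprintf("c%03d", 1:10)
  m <- make_split(ids, list(), seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_split_manifest(m, f)
  df <- utils::read.delim(f)
  expect_equal(nrow(df), 10L)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$seed, 5L)
})
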