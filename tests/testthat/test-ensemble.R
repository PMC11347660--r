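test_that("sampling schedules enumerate the documented job counts", {
  s <- build_schedule("msa_clustering")
  expect_equal(nrow(s$jobs), 104L)                  # 8 sizes x 13 samples
  expect_equal(sort(unique(s$jobs$cluster_size)),
               c(16, 32, 64, 128, 256, 512, 1024, 5120))
  expect_equal(anyDuplicated(s$jobs$seed), 0L)

  d <- build_schedule("dropout")
  expect_equal(nrow(d$jobs), 100L)
  expect_equal(anyDuplicated(d$jobs$seed), 0L)

  small <- build_schedule("msa_clustering", cluster_sizes = 16,
                          samples_per_size = 5)
  expect_equal(nrow(small$jobs), 5L)
  expect_error(build_schedule("msa_clustering", cluster_sizes = integer(0)),
               "empty")
})

test_that("MSA subsampling keeps the query and matches a Hamming scan", {
  set.seed(50)
  q <- paste(sample(c("A", "C", "D", "E"), 30, TRUE), collapse = "")
  seqs <- c(q, vapply(1:19, function(i)
    mutate_sequence(q, runif(1, 0.5, 0.95), seed = i), character(1)))
  msa <- data.frame(id = sprintf("r%02d", 1:20), sequence = seqs)

  all_in <- msa_cluster_sample(msa, n_clusters = 50, seed = 1)
  expect_equal(all_in$sequence, msa$sequence)

  only_q <- msa_cluster_sample(msa, n_clusters = 1, seed = 1)
  expect_equal(nrow(only_q), 1L)
  expect_equal(only_q$sequence, q)

  sub1 <- msa_cluster_sample(msa, n_clusters = 5, seed = 9)
  sub2 <- msa_cluster_sample(msa, n_clusters = 5, seed = 9)
  expect_identical(sub1, sub2)
  expect_true(q %in% sub1$sequence)
  centers <- match(sub1$sequence, msa$sequence)
  assign <- attr(sub1, "assignment")
  expect_equal(unname(assign), unname(oracle_nearest_center(seqs, centers)))
  expect_error(msa_cluster_sample(msa, 0, 1), "n_clusters")
})

test_that("A3M records read with insertions and match columns strip", {
  f <- withr::local_tempfile(fileext = ".a3m")
  writeLines(c(">query", "ACDEF", ">hit1", "ACaDEF", ">hit2", "AC-EF"), f)
  msa <- read_a3m(f)
  expect_equal(nrow(msa), 3L)
  expect_equal(msa$id, c("query", "hit1", "hit2"))
  stripped <- confsplit:::a3m_match_columns(msa$sequence)
  expect_equal(nchar(stripped), rep(5L, 3))
})

test_that("best-of-N evaluation finds exact copies and is order-invariant", {
  natA <- build_toy_chain(confsplit:::domain_ss_string(70), seed = 60,
                          structure_id = "NA1")
  natB <- make_alternative_conformation(natA, "hinge", 0.6, seed = 61)$chain
  natB$structure_id <- "NB1"
  samples <- list(
    list(chain = natB, plddt = rep(90, 70)),
    list(chain = natA, plddt = rep(80, 70)))
  ens <- confsplit:::new_prediction_ensemble("t1", samples)
  rec <- best_sample_scores(ens, natA, natB)
  expect_equal(rec$tm_best_test, 1)
  expect_equal(rec$tm_best_train, 1)
  expect_lt(abs(rec$native_delta_tm - 0.6), 0.06)
  expect_equal(rec$mean_plddt_best_test, 90)

  ens_rev <- confsplit:::new_prediction_ensemble("t1", rev(samples))
  rec_rev <- best_sample_scores(ens_rev, natA, natB)
  expect_equal(rec_rev$tm_best_test, rec$tm_best_test)
  expect_equal(rec_rev$tm_best_train, rec$tm_best_train)

  # random coils resemble neither native
  coils <- lapply(1:2, function(i)
    list(chain = random_coords_chain(70, seed = 70 + i),
         plddt = rep(50, 70)))
  for (i in 1:2) coils[[i]]$chain$sequence <- natA$sequence
  rec_c <- best_sample_scores(
    confsplit:::new_prediction_ensemble("t2", coils), natA, natB)
  expect_lt(rec_c$tm_best_test, 0.4)
  expect_lt(rec_c$tm_best_train, 0.4)
})

test_that("success counts use strict thresholds and shrink as they rise", {
  df <- data.frame(tm_best_train = c(0.9, 0.85, 0.7),
                   tm_best_test = c(0.85, 0.85, 0.75))
  s <- success_table(df)
  expect_equal(unname(s), c(2L, 2L, 2L, 3L))
  df_bound <- data.frame(tm_best_train = rep(0.8, 4),
                         tm_best_test = rep(0.8, 4))
  expect_equal(unname(success_table(df_bound)), c(0L, 0L, 0L, 4L))
  s_low <- success_table(df, threshold = 0.5)
  expect_true(all(s_low[1:3] >= s[1:3]))
})

test_that("sample outcome fractions label by threshold and dominance", {
  all_test <- data.frame(tm_train = c(0.5, 0.6), tm_test = c(0.99, 0.95))
  expect_equal(unname(sample_outcome_fractions(all_test)), c(1, 0, 0))
  none <- data.frame(tm_train = c(0.5, 0.6), tm_test = c(0.4, 0.7))
  expect_equal(unname(sample_outcome_fractions(none)), c(0, 0, 1))
  set.seed(51)
  n <- 600
  lab <- sample(c("test", "train", "neither"), n, TRUE,
                prob = c(0.4, 0.4, 0.2))
  tm_test <- ifelse(lab == "test", runif(n, 0.85, 1), runif(n, 0.3, 0.75))
  tm_train <- ifelse(lab == "train", runif(n, 0.85, 1), runif(n, 0.3, 0.75))
  fr <- sample_outcome_fractions(data.frame(tm_train, tm_test))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_lt(abs(fr["frac_test"] - 0.4), 0.05)
  expect_lt(abs(fr["frac_train"] - 0.4), 0.05)
})

test_that("conformational changes classify by constructed type", {
  mk_pair_chains <- function(type, seed) {
    base <- build_toy_chain(confsplit:::domain_ss_string(100), seed = seed,
                            structure_id = "CA1")
    alt <- make_alternative_conformation(base, type, 0.62, seed = seed + 1)
    b <- alt$chain; b$structure_id <- "CB1"
    list(a = base, b = b, pair = score_conformer_pair(base, b))
  }
  h <- mk_pair_chains("hinge", 80)
  expect_equal(classify_conformational_change(h$pair, h$a, h$b), "hinge")
  r <- mk_pair_chains("rearrangement", 82)
  expect_equal(classify_conformational_change(r$pair, r$a, r$b),
               "rearrangement")
  f <- mk_pair_chains("fold_switch", 84)
  expect_equal(classify_conformational_change(f$pair, f$a, f$b),
               "fold_switch")
  # short chains cannot be typed
  short_pair <- fake_pair("x", "y", 1, 0.6)
  sa <- toy_chain(45, seed = 86, id = "SH1")
  sb <- sa; sb$structure_id <- "SH2"
  expect_equal(classify_conformational_change(short_pair, sa, sb),
               "unassigned")
  not_alt <- fake_pair("x", "y", 1, 0.95)
  expect_error(classify_conformational_change(not_alt, sa, sb),
               "not an alternative")
})

test_that("accuracy-vs-change curve tracks a perfect line and degenerates", {
  df <- data.frame(target_id = sprintf("t%d", 1:20),
                   tm_best_train = 0.9,
                   tm_best_test = 1 - seq(0.2, 0.58, 0.02),
                   native_delta_tm = seq(0.2, 0.58, 0.02),
                   mean_plddt_best_test = 80, change_type = "hinge")
  out <- accuracy_vs_change_curve(df)
  expect_equal(out$pearson_r, -1, tolerance = 1e-12)
  expect_false(out$degenerate)
  expect_true(all(out$curve$n >= 1))

  df$tm_best_test <- 0.8
  out2 <- accuracy_vs_change_curve(df)
  expect_true(out2$degenerate)
  expect_true(is.na(out2$pearson_r))
})

test_that("confidence-accuracy correlation is Pearson with degeneracy flag", {
  x <- seq(1, 10)
  expect_equal(plddt_tm_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(plddt_tm_correlation(x, -x)$r, -1)
  flat <- plddt_tm_correlation(rep(5, 10), x)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$r))
  expect_error(plddt_tm_correlation(1:2, 1:2), "at least 3")
})

test_that("the composite loss reproduces its printed weights", {
  expect_equal(composite_loss(0, 0, 0, 0, 0), 0)
  expect_equal(composite_loss(1, 1, 1, 1, 1), 1.51)
  expect_equal(composite_loss(2, 0, 0, 0, 0), 1.0)
  expect_equal(composite_loss(0, 0, 0, 0, 100), 1.0)
  expect_error(composite_loss(-1, 0, 0, 0, 0), "negative")
  expect_error(composite_loss(Inf, 0, 0, 0, 0), "non-finite")
})

test_that("prediction ensembles round trip through model PDB files", {
  nat <- build_toy_chain(confsplit:::domain_ss_string(60), seed = 90,
                         structure_id = "ENS")
  ens <- make_synthetic_ensemble(nat, nat, n_samples = 3, mix = 0,
                                 noise = 0.2, seed = 91)
  dir <- withr::local_tempdir()
  for (k in seq_along(ens$samples))
    write_chain_pdb(ens$samples[[k]]$chain,
                    file.path(dir, sprintf("model_%02d.pdb", k)),
                    b = ens$samples[[k]]$plddt)
  back <- read_prediction_ensemble(dir, "ENS")
  expect_length(back$samples, 3L)
  expect_equal(back$samples[[1]]$plddt, ens$samples[[1]]$plddt,
               tolerance = 0.01)
  expect_equal(back$samples[[2]]$chain$ca_coords,
               ens$samples[[2]]$chain$ca_coords, tolerance = 1e-3,
               ignore_attr = TRUE)
})
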