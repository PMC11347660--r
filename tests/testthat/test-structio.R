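test_that("a minimal PDB fixture parses to the verbatim CA coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  coords <- rbind(c(1.5, 2.25, 3), c(5, 6, 7), c(8, 9.125, 10))
  write_minimal_pdb(f, coords)
  ch <- read_chain_structure(f, "pdb")
  expect_equal(chain_length(ch), 3L)
  expect_equal(unname(ch$ca_coords), coords)
  expect_equal(ch$sequence, "AGM")
  expect_equal(ch$residue_numbers, 1:3)
  expect_equal(ch$method, "xray")
  expect_equal(ch$resolution, 2.0)
})

test_that("first_protein_chain skips a leading nucleic-acid chain", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_nucleic_first_pdb(f)
  ch <- read_chain_structure(f, "pdb", chain_policy = "first_protein_chain")
  expect_equal(ch$chain_id, "P")
  expect_equal(ch$sequence, "GGGGGG")
})

test_that("altlocs resolve to highest occupancy, ties alphabetically", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_altloc_pdb(f, occ_a = 0.4, occ_b = 0.6)
  ch <- read_chain_structure(f, "pdb")
  expect_equal(ch$ca_coords[1, 1], 2)   # altloc B, occ 0.6
  write_altloc_pdb(f, occ_a = 0.5, occ_b = 0.5)
  ch <- read_chain_structure(f, "pdb")
  expect_equal(ch$ca_coords[1, 1], 1)   # tie -> alphabetically first (A)
})

test_that("parse errors carry file context; absent files are errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(read_chain_structure(f, "pdb"), "not found")
  writeLines(c("EXPDTA    X-RAY DIFFRACTION",
               pdb_atom_line(1, " P  ", " ", " DA", "N", 1, 0, 0, 0), "END"),
             f)
  expect_error(read_chain_structure(f, "pdb"), "no protein chain")
})

test_that("filter boundaries match the corpus criteria exactly", {
  mk <- function(L, n_x = 0, method = "xray", res = 2.0) {
    seqs <- c(rep("A", L - n_x), rep("X", n_x))
    chain_structure(paste0("c", L, method, n_x), "A",
                    paste(seqs, collapse = ""),
                    cbind(3.8 * seq_len(L), 0, 0), method = method,
                    resolution = res)
  }
  chains <- list(
    short = mk(49), nonreg = mk(100, n_x = 85), nmr = mk(200, method = "nmr"),
    badres = mk(100, res = 5.5), ok = mk(50), ok_at_limit = mk(100, res = 5.0),
    nores = mk(100, res = NA))
  out <- filter_chains(chains)
  d <- out$decisions
  expect_equal(nrow(d), length(chains))          # decisions exhaustive
  expect_equal(d$reasons[1], "too_short")
  expect_equal(d$reasons[2], "too_many_nonregular")
  expect_match(d$reasons[3], "excluded_method")
  expect_equal(d$reasons[4], "bad_resolution")
  expect_true(d$kept[5])                          # exactly 50 residues kept
  expect_true(d$kept[6])                          # resolution at 5.0 kept
  expect_equal(d$reasons[7], "bad_resolution")    # absent resolution excluded
  # idempotence: filtering the kept set removes nothing
  again <- filter_chains(out$kept)
  expect_equal(length(again$kept), length(out$kept))
  # partition: each input appears exactly once
  expect_setequal(d$id, vapply(chains, chain_id, character(1)))
})

test_that("FASTA round trip is exact, duplicates are rejected", {
  f <- withr::local_tempfile(fileext = ".fasta")
  chains <- list(toy_chain(55, 1, "AAA"), toy_chain(60, 2, "BBB"))
  write_fasta(chains, f)
  rec <- read_fasta(f)
  expect_equal(rec$id, c("AAA_A", "BBB_A"))
  expect_equal(rec$sequence, vapply(chains, `[[`, character(1), "sequence"))

  write_fasta(list(), f)
  expect_equal(nrow(read_fasta(f)), 0L)

  set.seed(42)
  seqs <- vapply(1:200, function(i)
    paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                   "R","S","T","V","W","Y"), sample(50:200, 1), TRUE),
          collapse = ""), character(1))
  names(seqs) <- sprintf("s%04d", 1:200)
  write_fasta(seqs, f)
  rec <- read_fasta(f)
  expect_identical(rec$sequence, unname(seqs))
  expect_identical(rec$id, names(seqs))

  dup <- seqs[c(1, 1, 2)]
  expect_error(write_fasta(dup, f), "duplicate")
})

test_that("PDB write/read round trip preserves sequence and coordinates", {
  ch <- build_toy_chain(paste0(strrep("H", 20), strrep("C", 5),
                               strrep("E", 30)), seed = 3,
                        structure_id = "RT")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_chain_pdb(ch, f)
  back <- read_chain_structure(f, "pdb")
  expect_equal(back$sequence, ch$sequence)
  expect_equal(back$residue_numbers, ch$residue_numbers)
  expect_lt(max(abs(back$ca_coords - ch$ca_coords)), 1e-3)
  expect_equal(back$method, "xray")
  expect_equal(back$resolution, 2.0)
})

test_that("mmCIF chains parse with metadata", {
  # hand-written minimal mmCIF with one protein chain
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "_exptl.method 'X-RAY DIFFRACTION'",
    "_refine.ls_d_res_high 1.80",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 4.500 5.000 6.000 1.00 0.00 ? 2 GLY A CA 1",
    "ATOM 3 C CA . MET A 1 3 ? 8.000 8.500 9.000 1.00 0.00 ? 3 MET A CA 1",
    "#"), f)
  ch <- read_chain_structure(f, "mmcif")
  expect_equal(ch$sequence, "AGM")
  expect_equal(unname(ch$ca_coords[2, ]), c(4.5, 5, 6))
  expect_equal(ch$method, "xray")
  expect_equal(ch$resolution, 1.8)
})
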