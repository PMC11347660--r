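# PDB fixture construction (fixed-column ATOM records built by hand)

pdb_atom_line <- function(serial, name, alt, resname, chain, resno,
                          x, y, z, occ = 1, b = 0) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, alt, resname, chain, resno, x, y, z, occ, b)
}

write_minimal_pdb <- function(path, coords = rbind(c(1.5, 2.25, 3), c(5, 6, 7),
                                                   c(8, 9.125, 10)),
                              resnames = c("ALA", "GLY", "MET"),
                              chain = "A", header = TRUE) {
  lines <- c(
    if (header) c("HEADER    TEST PROTEIN                            01-JAN-20   XXXX",
                  "EXPDTA    X-RAY DIFFRACTION",
                  "REMARK   2 RESOLUTION.    2.00 ANGSTROMS."),
    vapply(seq_len(nrow(coords)), function(i)
      pdb_atom_line(i, " CA ", " ", resnames[i], chain, i,
                    coords[i, 1], coords[i, 2], coords[i, 3]),
      character(1)),
    "END")
  writeLines(lines, path)
  path
}

# a file whose first chain is a nucleic acid, second a protein
write_nucleic_first_pdb <- function(path) {
  lines <- c(
    "EXPDTA    X-RAY DIFFRACTION",
    pdb_atom_line(1, " P  ", " ", " DA", "N", 1, 0, 0, 0),
    pdb_atom_line(2, " C1'", " ", " DA", "N", 1, 1, 1, 1),
    pdb_atom_line(3, " P  ", " ", " DT", "N", 2, 2, 2, 2),
    vapply(1:6, function(i)
      pdb_atom_line(3 + i, " CA ", " ", "GLY", "P", i,
                    i * 3.8, 0, 0), character(1)),
    "END")
  writeLines(lines, path)
  path
}

# one residue with two altlocs (A occ 0.4 at x=1, B occ 0.6 at x=2)
write_altloc_pdb <- function(path, occ_a = 0.4, occ_b = 0.6) {
  lines <- c(
    "EXPDTA    X-RAY DIFFRACTION",
    pdb_atom_line(1, " CA ", "A", "ALA", "A", 1, 1, 0, 0, occ = occ_a),
    pdb_atom_line(2, " CA ", "B", "ALA", "A", 1, 2, 0, 0, occ = occ_b),
    pdb_atom_line(3, " CA ", " ", "GLY", "A", 2, 5, 0, 0),
    pdb_atom_line(4, " CA ", " ", "MET", "A", 3, 9, 0, 0),
    "END")
  writeLines(lines, path)
  path
}

# quick chain constructors
toy_chain <- function(L = 60, seed = 1, id = "TOY")
  build_toy_chain(strrep("H", L), seed = seed, structure_id = id)

random_coords_chain <- function(L = 10, seed = 1, id = "RND") {
  set.seed(seed)
  chain_structure(id, "A",
                  paste(sample(c("A", "C", "D", "E", "F", "G"), L, TRUE),
                        collapse = ""),
                  matrix(rnorm(L * 3, sd = 5), ncol = 3),
                  method = "xray", resolution = 2.0)
}

# planted families detected by a pipeline run, read off the members of the
# structural clusters in each alternative set (cluster ids carry the 30%
# representative's name, which may belong to a different family when two
# families merge at the broad tier)
detected_families <- function(run) {
  sort(unique(unlist(lapply(run$manifest$alternative_sets, function(s) {
    members <- unlist(lapply(run$struct_clusters[
      vapply(run$struct_clusters, function(c) c$cluster_id %in% s,
             logical(1))], `[[`, "member_ids"))
    unique(sub("^(F[0-9]+)M.*$", "\\1", members))
  }))))
}

# a fabricated conformer_pair record (for selection/curation logic tests)
fake_pair <- function(id_a, id_b, overlap_fraction, tm, seq90 = "s90",
                      sc_a = "sc1", sc_b = "sc2", alt_threshold = 0.8) {
  structure(list(
    id_a = id_a, id_b = id_b, seq90_cluster_id = seq90,
    struct_cluster_a = sc_a, struct_cluster_b = sc_b,
    overlap_length = 100L, overlap_fraction = overlap_fraction,
    tm_aligned_region = tm, is_alternative = tm < alt_threshold,
    change_type = "unassigned", alt_threshold = alt_threshold),
    class = "conformer_pair")
}
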