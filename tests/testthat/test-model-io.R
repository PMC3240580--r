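test_that("PDB reading round-trips coordinates at format precision", {
  # handwritten 3-atom fixture
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104  22.050   3.001  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      12.560  22.100   3.125  1.00 11.00           C",
    "ATOM      3  C   ALA A   1      13.100  23.450   2.750  1.00 12.00           C",
    "END")
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, p)
  m <- read_structure(p)
  expect_equal(n_atoms(m), 3L)
  expect_identical(coords(m),
                   matrix(c(11.104, 22.050, 3.001,
                            12.560, 22.100, 3.125,
                            13.100, 23.450, 2.750),
                          ncol = 3L, byrow = TRUE,
                          dimnames = list(NULL, c("x", "y", "z"))))
  expect_equal(m$atoms$bfactor, c(10, 11, 12))

  # write then re-read an arbitrary model: identical atom list, coordinates
  # preserved to 3 decimals
  h <- make_ideal_helix(8)
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h, p2)
  h2 <- read_structure(p2)
  expect_equal(h2$atoms$name, h$atoms$name)
  expect_equal(h2$atoms$resid, h$atoms$resid)
  expect_equal(coords(h2), round(coords(h), 3), ignore_attr = TRUE)
})

test_that("malformed and duplicate PDB records are rejected with context", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104  22.050   3.001  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      12.560  abcdef   3.125  1.00 11.00           C"),
    p)
  expect_error(read_structure(p), "line 2")
  writeLines("ATOM      1  N   ALA A", p)
  expect_error(read_structure(p), "truncated")
  # duplicate atom identity
  at <- make_ideal_helix(2)$atoms
  at$resid <- 1L  # collapses residues -> duplicate (chain, resid, name)? no:
  at$name <- "N"  # force identical names
  expect_error(structure_model(at), "duplicate")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       1.000   0.000   0.000  0.40 10.00           N",
    "ATOM      2  N  BALA A   1       2.000   0.000   0.000  0.60 10.00           N",
    "ATOM      3  CA  ALA A   1       3.000   0.000   0.000  0.00 10.00           C"),
    p)
  m <- read_structure(p)
  expect_equal(n_atoms(m), 2L)
  expect_equal(m$atoms$x[m$atoms$name == "N"], 2.0)
  # zero-occupancy atoms are kept (disordered tails are physically present)
  expect_true("CA" %in% m$atoms$name)
})

test_that("a written nucleosome model reads back with 147 base-paired nucleotides per strand", {
  toy <- toy_fixture()
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$model, p)
  m <- read_structure(p)
  bp <- count_basepairs(m, c("I", "J"))
  expect_equal(unname(bp$per_strand), c(147L, 147L))
  expect_equal(bp$n_pairs, 147L)
})

test_that("trajectory dialects read and write consistently", {
  sm <- subset_model(toy_fixture()$model, 1:40)
  tr <- make_harmonic_trajectory(sm, 10, sigma = 0.2, dt = 1, seed = 5)
  expect_equal(tr$times, as.numeric(0:9))

  # single-frame multi-model PDB equals the structure
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sm, p1)
  tr1 <- read_trajectory(p1, sm)
  expect_equal(n_frames(tr1), 1L)
  expect_equal(tr1$frames[[1L]], round(coords(sm), 3), ignore_attr = TRUE)

  # 10-frame round trips: PDB at format precision, table near-exactly
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, p2)
  tr2 <- read_trajectory(p2, sm)
  expect_equal(n_frames(tr2), 10L)
  expect_equal(tr2$frames[[7L]], round(tr$frames[[7L]], 3), ignore_attr = TRUE)

  p3 <- withr::local_tempfile(fileext = ".txt")
  write_trajectory(tr, p3, format = "table")
  tr3 <- read_trajectory(p3, sm)
  expect_equal(tr3$times, tr$times)
  expect_equal(tr3$frames[[3L]], tr$frames[[3L]], tolerance = 1e-7,
               ignore_attr = TRUE)

  # frame with a missing atom is rejected, citing the frame
  tab <- utils::read.table(p3, header = TRUE)
  tab <- tab[-(n_atoms(sm) + 1L), ]  # drop first atom of frame 2
  p4 <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(tab, p4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_trajectory(p4, sm), "frame 2")
})

test_that("tail truncation removes exactly the specified residues in both copies", {
  toy <- toy_fixture()
  m <- toy$model; topo <- toy$topology

  tr <- apply_truncation(m, topo, truncation_spec(H2A = list(n = c(1, 11), c = c(118, 128))))
  for (ch in c("C", "G")) {  # the two H2A copies
    res <- unique(tr$atoms$resid[tr$atoms$chain == ch])
    expect_false(any(res %in% c(1:11, 118:128)))
    expect_true(all(c(12:117, 129) %in% res))
  }
  # all other chains untouched, order preserved
  others <- setdiff(unique(m$atoms$chain), c("C", "G"))
  expect_identical(tr$atoms[tr$atoms$chain %in% others, ],
                   m$atoms[m$atoms$chain %in% others, ],
                   ignore_attr = TRUE)

  # identity and idempotence
  expect_identical(apply_truncation(m, topo, truncation_spec()), m)
  full <- apply_truncation(m, topo)
  expect_identical(apply_truncation(full, topo,
                                    truncation_spec(H4 = list(n = c(1, 17)))),
                   apply_truncation(m, topo))

  # range past the chain end errors, listing the missing residues
  expect_error(apply_truncation(m, topo, truncation_spec(H4 = list(n = c(1, 200)))),
               "absent residues")
})

test_that("SHL segmentation partitions the duplex symmetrically about the dyad", {
  topo <- toy_fixture()$topology
  seg <- segment_dna_by_shl(topo)
  expect_equal(nrow(seg), 14L)
  # union covers all base pairs, pairwise disjoint
  covered <- unlist(Map(seq, seg$start_bp, seg$end_bp))
  expect_equal(sort(covered), 1:147)
  expect_equal(anyDuplicated(covered), 0L)
  # retrievable segment labels around the dyad
  expect_true("SHL[0,+1]" %in% seg$label)
  # dyad-to-SHL+1.5 helper range
  rng <- dna_segment_range(topo, 0, 1.5)
  expect_equal(unname(rng), c(74, 90))

  # 21-bp toy duplex with two turns: brute-force partition by boundary list
  t2 <- nucleosome_topology(
    histone_assignments = data.frame(chain = "A", histone = "H3", copy = 1L),
    tail_ranges = list(H3 = list(n = c(1, 2))),
    domain_ranges = data.frame(chain = "A", domain = "alpha1", start = 3, end = 5),
    dna_chains = c("I", "J"), dyad_bp = 11L, shl_boundaries = 10L,
    n_bp = 21L, bp_per_turn = 10.5)
  s2 <- segment_dna_by_shl(t2)
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$start_bp, c(1L, 11L))
  expect_equal(s2$end_bp, c(10L, 21L))
})

test_that("topology config files round-trip", {
  topo <- toy_fixture()$topology
  p <- withr::local_tempfile(fileext = ".yaml")
  write_topology(topo, p)
  t2 <- read_topology(p)
  expect_equal(t2$shl_boundaries, topo$shl_boundaries)
  expect_equal(t2$dyad_bp, topo$dyad_bp)
  expect_equal(t2$histone_assignments, topo$histone_assignments)
  expect_equal(segment_dna_by_shl(t2), segment_dna_by_shl(topo))
})
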