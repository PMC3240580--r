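test_that("ideal peptide generator reproduces the requested torsions exactly", {
  h <- make_ideal_helix(10, -57, -47)
  at <- h$atoms
  g <- function(rid, nm) {
    r <- at[at$resid == rid & at$name == nm, ]
    c(r$x, r$y, r$z)
  }
  for (i in 3:8) {
    expect_equal(torsion(g(i - 1, "C"), g(i, "N"), g(i, "CA"), g(i, "C")),
                 -57, tolerance = 1e-6)
    expect_equal(torsion(g(i, "N"), g(i, "CA"), g(i, "C"), g(i + 1, "N")),
                 -47, tolerance = 1e-6)
    expect_equal(abs(torsion(g(i, "CA"), g(i, "C"), g(i + 1, "N"), g(i + 1, "CA"))),
                 180, tolerance = 1e-6)
  }
  expect_error(make_ideal_helix(1), "at least 2")
})

test_that("the duplex generator produces a valid antiparallel pairing", {
  seqs <- c("DA", "DG", "DT", "DC", "DA", "DA", "DT", "DG")
  d <- make_bdna_duplex(seqs)
  a <- d$atoms
  n <- length(seqs)
  comp <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")
  for (i in seq_len(n)) {
    rn_i <- a$resname[a$chain == "I" & a$resid == i][1]
    rn_j <- a$resname[a$chain == "J" & a$resid == n + 1 - i][1]
    expect_equal(rn_i, seqs[i])
    expect_equal(rn_j, unname(comp[seqs[i]]))
    # paired C1' atoms sit at the canonical cross-pair separation
    c1i <- a[a$chain == "I" & a$resid == i & a$name == "C1'", c("x", "y", "z")]
    c1j <- a[a$chain == "J" & a$resid == n + 1 - i & a$name == "C1'", c("x", "y", "z")]
    expect_equal(sqrt(sum((c1i - c1j)^2)), 10.7, tolerance = 0.05)
  }
  # 5'-terminal phosphates omitted on both strands
  expect_false(any(a$name == "P" & a$chain == "I" & a$resid == 1))
  expect_false(any(a$name == "P" & a$chain == "J" & a$resid == 1))
  expect_error(make_bdna_duplex(c("DA", "XX")), "bases")
})

test_that("the toy nucleosome carries the full annotation set", {
  toy <- toy_fixture()
  m <- toy$model; topo <- toy$topology
  expect_equal(nrow(segment_dna_by_shl(topo)), 14L)
  # 2 x 146 phosphates: no 5'-terminal P on either strand
  expect_equal(sum(m$atoms$name == "P" & m$atoms$chain %in% c("I", "J")), 292L)
  expect_equal(length(histone_chains(topo)), 8L)
  dr <- topo$domain_ranges
  dock <- dr[dr$domain == "docking", ]
  expect_equal(nrow(dock), 2L)  # one docking domain per H2A copy
  expect_equal(unique(dock$start), 100)
  expect_equal(unique(dock$end), 119)
  # docking-domain range lies within H2A
  for (ch in dock$chain)
    expect_true(all(100:119 %in% m$atoms$resid[m$atoms$chain == ch]))
  expect_error(make_toy_nucleosome(turns = 0), "positive")
})

test_that("harmonic trajectories are seeded, deterministic and independent across atoms", {
  sm <- subset_model(toy_fixture()$model, 1:30)
  t1 <- make_harmonic_trajectory(sm, 5, sigma = 0.3, seed = 9)
  t2 <- make_harmonic_trajectory(sm, 5, sigma = 0.3, seed = 9)
  expect_identical(t1$frames, t2$frames)  # bit-identical under a fixed seed
  t3 <- make_harmonic_trajectory(sm, 5, sigma = 0.3, seed = 10)
  expect_false(identical(t1$frames, t3$frames))

  # sigma = 0: the reference repeated; rmsd identically zero
  tz <- make_harmonic_trajectory(sm, 4, sigma = 0, seed = 1)
  rs <- rmsd_series(tz, sm, select_all())
  expect_equal(rs$rmsd, rep(0, 4), tolerance = 1e-10)
  expect_error(make_harmonic_trajectory(sm, 4, sigma = -0.1), "sigma")

  # per-selection scales and empirical independence between selections
  tr <- make_harmonic_trajectory(
    sm, 1000, sigma = 0.2,
    sigma_by = list(list(sel = select_atoms(resid = 1), sigma = 0.6)),
    seed = 12)
  disp <- function(i) vapply(tr$frames, function(f) f[i, 1L] - coords(sm)[i, 1L], 1)
  expect_equal(sd(disp(1L)), 0.6, tolerance = 0.1)
  expect_equal(sd(disp(20L)), 0.2, tolerance = 0.05)
  expect_lt(abs(cor(disp(1L), disp(20L))), 0.05)
})

test_that("injected destabilization raises R_T only for the target domain", {
  toy <- toy_fixture()
  topo <- toy$topology
  # protein backbone subset keeps the fixture light without changing the
  # selections' semantics
  keep <- resolve_selection(select_backbone(histone_chains(topo)), toy$model)
  sm <- subset_model(toy$model, keep)
  dom <- select_domain(topo, "G", "alpha3")
  nf <- 200
  tri <- make_harmonic_trajectory(sm, nf, sigma = 0.3, seed = 61)
  trt <- make_harmonic_trajectory(
    sm, nf, sigma = 0.3, seed = 62,
    destabilization = list(sel = dom, profile = seq(0, 6, length.out = nf),
                           direction = c(1, 0.5, 0)))
  # superpose on the stable part of the core: a domain known to move would
  # otherwise drag the global fit and bleed RMSD into every selection
  core <- select_histone_core(topo)
  fit_sel <- selection(function(a)
    core$predicate(a) & !(a$chain == "G" & a$resid %in% 80:97),
    "core minus perturbed domain")
  doms <- topo$domain_ranges
  sels <- lapply(seq_len(nrow(doms)), function(i)
    select_domain(topo, doms$chain[i], doms$domain[i]))
  names(sels) <- paste0(doms$chain, ":", doms$domain)
  ri <- nuctraj:::rmsd_multi(tri, sm, fit_sel, sels)
  rt <- nuctraj:::rmsd_multi(trt, sm, fit_sel, sels)
  z <- vapply(names(sels), function(nm) {
    op <- order_parameter_RT(
      structure(data.frame(time = trt$times, rmsd = rt[[nm]]),
                class = c("RMSDSeries", "data.frame")),
      structure(data.frame(time = tri$times, rmsd = ri[[nm]]),
                class = c("RMSDSeries", "data.frame")))
    c(op$RT, (op$RT - 1) / op$se)
  }, numeric(2L))
  # the injected domain is strongly destabilized ...
  expect_gt(z[1L, "G:alpha3"], 1)
  expect_gt(z[2L, "G:alpha3"], 10)
  # ... and untouched domains sit at R_T ~ 1: most within 2 SE, none with
  # anything resembling a destabilization signal (4 SE guards the
  # 27-domain family-wise rate), and none shifted by more than 5% in the
  # ratio itself
  untouched <- setdiff(colnames(z), "G:alpha3")
  expect_gt(mean(abs(z[2L, untouched]) < 2), 0.75)
  expect_lt(max(abs(z[2L, untouched])), 4)
  expect_lt(max(abs(z[1L, untouched] - 1)), 0.05)
})
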