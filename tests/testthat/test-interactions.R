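test_that("hydrogen-bond detection honours both geometric cutoffs", {
  crit <- hbond_criteria(3.5, 150)
  mk <- function(da) tiny_model(c("N", "H", "O"),
                                c(0, 0, 0, 1, 0, 0, da, 0, 0),
                                resid = c(1, 1, 2))
  hb <- detect_hbonds(mk(2.9), select_atoms(resid = 1), select_atoms(resid = 2), crit)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$dist, 2.9)
  expect_equal(hb$angle, 180)
  expect_equal(nrow(detect_hbonds(mk(3.6), select_atoms(resid = 1),
                                  select_atoms(resid = 2), crit)), 0L)
  # bent geometry below the angle cutoff
  bent <- tiny_model(c("N", "H", "O"), c(0, 0, 0, 1, 0, 0, 1, 2.2, 0),
                     resid = c(1, 1, 2))
  expect_equal(nrow(detect_hbonds(bent, select_atoms(resid = 1),
                                  select_atoms(resid = 2), crit)), 0L)
  # apolar selections give an empty result, not an error
  apolar <- tiny_model(c("C1", "C2"), c(0, 0, 0, 3, 0, 0), resid = c(1, 2))
  expect_equal(nrow(detect_hbonds(apolar, select_atoms(resid = 1),
                                  select_atoms(resid = 2), crit)), 0L)
  expect_error(hbond_criteria(-1), "positive")
  expect_error(hbond_criteria(3.5, 190), "angle")
})

test_that("hydrogen-bond detection equals the exhaustive oracle on random instances", {
  crit <- hbond_criteria(3.5, 120)
  for (s in 1:3) {
    set.seed(200 + s)
    # 8 donors with hydrogens, 6 acceptors, random packing
    nd <- 8L; na <- 6L
    dpos <- matrix(runif(nd * 3, 0, 8), ncol = 3L)
    hdir <- matrix(rnorm(nd * 3), ncol = 3L)
    hdir <- hdir / sqrt(rowSums(hdir^2))
    hpos <- dpos + hdir
    apos <- matrix(runif(na * 3, 0, 8), ncol = 3L)
    atoms <- data.frame(
      serial = seq_len(2 * nd + na),
      name = c(rep("N", nd), rep("HN", nd), rep("O", na)),
      element = c(rep("N", nd), rep("H", nd), rep("O", na)),
      resname = "X",
      resid = c(seq_len(nd), seq_len(nd), nd + seq_len(na)),
      chain = "Z",
      x = c(dpos[, 1], hpos[, 1], apos[, 1]),
      y = c(dpos[, 2], hpos[, 2], apos[, 2]),
      z = c(dpos[, 3], hpos[, 3], apos[, 3]),
      occupancy = 1, bfactor = 0)
    m <- structure_model(atoms)
    got <- detect_hbonds(m, select_atoms(resid = seq_len(nd)),
                         select_atoms(resid = nd + seq_len(na)), crit)
    want <- oracle_hbonds(coords(m), donors = seq_len(nd),
                          hydro = as.list(nd + seq_len(nd)),
                          acceptors = 2 * nd + seq_len(na),
                          dist_cut = 3.5, ang_cut = 120)
    got_pairs <- unique(got[, c("donor", "acceptor")])
    expect_equal(nrow(got_pairs), nrow(want))
    if (nrow(want)) {
      o1 <- got_pairs[order(got_pairs$donor, got_pairs$acceptor), ]
      o2 <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(unname(as.matrix(o1)), unname(o2))
    }
  }
})

test_that("hydrogen-bond counts track constructed bond breaking", {
  bonded <- c(0, 0, 0, 1, 0, 0, 2.9, 0, 0)
  broken <- c(0, 0, 0, 1, 0, 0, 6.0, 0, 0)
  m <- tiny_model(c("N", "H", "O"), bonded, resid = c(1, 1, 2))
  fr <- function(v) matrix(v, ncol = 3L, byrow = TRUE)
  tr <- trajectory(m, c(replicate(4, fr(bonded), simplify = FALSE),
                        replicate(6, fr(broken), simplify = FALSE)))
  cnt <- hbond_count_series(tr, select_atoms(resid = 1), select_atoms(resid = 2))
  expect_equal(cnt$count, c(rep(1L, 4), rep(0L, 6)))
  expect_equal(mean(cnt$count), 0.4)  # two-state mixture fraction
})

test_that("minimum-distance series is exact", {
  m <- tiny_model(c("A1", "B1"), c(0, 0, 0, 3, 4, 0), resid = c(1, 2))
  tr <- trajectory(m, list(coords(m)))
  md <- min_distance_series(tr, select_atoms(resid = 1), select_atoms(resid = 2))
  expect_equal(md$dist, 5)
  # selections sharing an atom: zero
  md0 <- min_distance_series(tr, select_all(), select_atoms(resid = 2))
  expect_equal(md0$dist, 0)
  expect_error(min_distance_series(tr, select_atoms(chain = "nope"),
                                   select_all()), "empty")
  # random configurations vs the exhaustive oracle
  for (s in 1:3) {
    set.seed(300 + s)
    xa <- matrix(runif(30, 0, 10), ncol = 3L)
    xb <- matrix(runif(24, 0, 10), ncol = 3L)
    mm <- tiny_model(paste0("C", 1:18),
                     as.vector(t(rbind(xa, xb))),
                     resid = c(rep(1L, 10), rep(2L, 8)))
    trr <- trajectory(mm, list(coords(mm)))
    got <- min_distance_series(trr, select_atoms(resid = 1), select_atoms(resid = 2))
    expect_equal(got$dist, oracle_min_dist(xa, xb), tolerance = 1e-12)
  }
})

test_that("detachment classification uses mean + SD with a strict 'greater than'", {
  mk <- function(v) structure(data.frame(time = seq_along(v), dist = v),
                              class = c("ContactSeries", "data.frame"))
  ref <- mk(rep(3, 10))                    # mean 3, SD 0
  expect_true(all(detachment_classify(mk(rep(3, 5)), ref)$states == "in_contact"))
  expect_true(all(detachment_classify(mk(rep(3.5, 5)), ref)$states == "detached"))
  expect_error(detachment_classify(mk(1), mk(3)), "at least 2")

  # Gaussian reference, shifted test: detached fraction matches the normal
  # tail probability within Monte-Carlo error
  set.seed(17)
  mu <- 5; s <- 0.3; delta <- 0.4; n <- 4000
  refg <- mk(rnorm(n, mu, s))
  test <- mk(rnorm(n, mu + delta, s))
  call <- detachment_classify(test, refg)
  p_closed <- 1 - pnorm((call$threshold - (mu + delta)) / s)
  mc_err <- 4 * sqrt(p_closed * (1 - p_closed) / n)
  expect_equal(call$fraction_detached, p_closed, tolerance = mc_err / p_closed)

  # monotonicity: raising every test distance never un-detaches a frame
  raised <- detachment_classify(mk(test$dist + 0.3), refg)
  expect_false(any(call$states == "detached" & raised$states == "in_contact"))
})

test_that("contact maps flag residue pairs at the closest-atom distance", {
  m <- tiny_model(c("A1", "A2", "B1", "B2"),
                  c(0, 0, 0, 1.2, 0.8, 0, 3.7, 0, 0.5, 10, 2, 0),
                  resid = c(1, 1, 2, 2))
  cm <- contact_map(m, select_atoms(resid = 1), select_atoms(resid = 2))
  expect_equal(unname(cm$distance[1, 1]), sqrt(2.5^2 + 0.8^2 + 0.5^2))
  expect_true(cm$close[1, 1])
  far <- tiny_model(c("A1", "B1"), c(0, 0, 0, 9, 0, 0), resid = c(1, 2))
  cmf <- contact_map(far, select_atoms(resid = 1), select_atoms(resid = 2))
  expect_false(any(cmf$close))
  expect_error(contact_map(m, select_all(), select_atoms(resid = 2)), "overlap")

  # docking-domain style fixture vs exhaustive per-pair oracle
  toy <- toy_fixture()
  dock <- select_domain(toy$topology, "G", "docking", backbone_only = FALSE)
  near <- select_atoms(chain = "I", resid = 60:75)
  cmap <- contact_map(toy$model, dock, near)
  a <- toy$model$atoms
  xyz <- coords(toy$model)
  for (probe in list(c(1, 1), c(5, 8), c(20, 16))) {
    ra <- strsplit(cmap$residues_a[probe[1]], " ")[[1]]
    rb <- strsplit(cmap$residues_b[probe[2]], " ")[[1]]
    ia <- which(a$chain == ra[1] & a$resid == as.integer(ra[2]) &
                  seq_len(nrow(a)) %in% resolve_selection(dock, toy$model))
    ib <- which(a$chain == rb[1] & a$resid == as.integer(rb[2]))
    expect_equal(unname(cmap$distance[probe[1], probe[2]]),
                 oracle_min_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE]),
                 tolerance = 1e-12)
  }

  # trajectory-average mode on a static trajectory equals the single frame
  tr <- trajectory(m, replicate(3, coords(m), simplify = FALSE))
  cm2 <- contact_map(tr, select_atoms(resid = 1), select_atoms(resid = 2))
  expect_equal(cm2$distance, cm$distance, tolerance = 1e-9)
})

test_that("nonbonded energies reproduce closed forms and the pairwise oracle", {
  # two neutral LJ particles at the minimum: energy = -epsilon
  pars <- nonbonded_params(data.frame(chain = "Z", resid = 1:2,
                                      name = c("C1", "C2"), charge = 0,
                                      epsilon = 0.25, rmin_half = 1.9))
  m <- tiny_model(c("C1", "C2"), c(0, 0, 0, 3.8, 0, 0), resid = c(1, 2))
  e <- interaction_energy(m, select_atoms(resid = 1), select_atoms(resid = 2), pars)
  expect_equal(e$total, -0.25, tolerance = 1e-12)

  # two unit charges at 10 A: the Coulomb constant scale
  pars_q <- nonbonded_params(data.frame(chain = "Z", resid = 1:2,
                                        name = c("C1", "C2"), charge = 1,
                                        epsilon = 0, rmin_half = 1))
  m10 <- tiny_model(c("C1", "C2"), c(0, 0, 0, 10, 0, 0), resid = c(1, 2))
  e10 <- interaction_energy(m10, select_atoms(resid = 1), select_atoms(resid = 2), pars_q)
  expect_equal(e10$elec, 332.0636 / 10, tolerance = 1e-9)

  # random groups vs the exhaustive pairwise oracle
  set.seed(41)
  n1 <- 5L; n2 <- 5L
  xyz <- matrix(runif((n1 + n2) * 3, 0, 6), ncol = 3L)
  pr <- data.frame(chain = "Z", resid = rep(1:2, c(n1, n2)),
                   name = paste0("C", seq_len(n1 + n2)),
                   charge = runif(n1 + n2, -1, 1),
                   epsilon = runif(n1 + n2, 0.05, 0.3),
                   rmin_half = runif(n1 + n2, 1.2, 2.1))
  mm <- tiny_model(pr$name, as.vector(t(xyz)), resid = pr$resid)
  ee <- interaction_energy(mm, select_atoms(resid = 1), select_atoms(resid = 2),
                           nonbonded_params(pr))
  want <- oracle_energy(xyz[1:n1, ], xyz[n1 + 1:n2, ],
                        pr$charge[1:n1], pr$charge[n1 + 1:n2],
                        pr$epsilon[1:n1], pr$epsilon[n1 + 1:n2],
                        pr$rmin_half[1:n1], pr$rmin_half[n1 + 1:n2])
  expect_equal(ee$elec, unname(want["elec"]), tolerance = 1e-9)
  expect_equal(ee$vdw, unname(want["vdw"]), tolerance = 1e-9)

  # switching: unity inside r_on, zero beyond r_off
  sw <- list(r_on = 8, r_off = 9)
  e_in <- interaction_energy(m10 <- tiny_model(c("C1", "C2"), c(0, 0, 0, 7, 0, 0),
                                               resid = c(1, 2)),
                             select_atoms(resid = 1), select_atoms(resid = 2),
                             pars_q, switching = sw)
  expect_equal(e_in$elec, 332.0636 / 7, tolerance = 1e-9)
  e_out <- interaction_energy(tiny_model(c("C1", "C2"), c(0, 0, 0, 9.5, 0, 0),
                                         resid = c(1, 2)),
                              select_atoms(resid = 1), select_atoms(resid = 2),
                              pars_q, switching = sw)
  expect_equal(e_out$elec, 0)

  # missing parameters are reported by atom
  expect_error(interaction_energy(tiny_model(c("ZZ", "C2"), c(0, 0, 0, 1, 0, 0),
                                             resid = c(1, 2)),
                                  select_atoms(resid = 1), select_atoms(resid = 2),
                                  pars_q),
               "missing nonbonded parameters")
})

test_that("the smoothed potential matches the erf closed form and is linear", {
  m1 <- tiny_model("C1", c(0, 0, 0))
  g <- potential_map(m1, charges = 1, spacing = 1, beta = 0.25, margin = 6)
  expect_equal(grid_value_at(g, c(4, 0, 0)),
               14.399645 * nuctraj:::erf(0.25 * 4) / 4, tolerance = 1e-9)
  # all charges zero: a zero grid
  g0 <- potential_map(m1, charges = 0, spacing = 1, beta = 0.25, margin = 3)
  expect_equal(max(abs(g0$values)), 0)
  # two charges: superposition of single-charge grids
  m2 <- tiny_model(c("C1", "C2"), c(0, 0, 0, 2, 0, 0))
  g2 <- potential_map(m2, charges = c(0.7, -0.4), spacing = 1, beta = 0.25,
                      margin = 4)
  ga <- potential_map(m2, charges = c(0.7, 0), spacing = 1, beta = 0.25,
                      margin = 4)
  gb <- potential_map(m2, charges = c(0, -0.4), spacing = 1, beta = 0.25,
                      margin = 4)
  expect_equal(g2$values, ga$values + gb$values, tolerance = 1e-12)
  # beta -> Inf approaches the bare Coulomb potential
  gi <- potential_map(m1, charges = 1, spacing = 1, beta = 2, margin = 6)
  r <- 4  # beta * r = 8 > 6
  expect_equal(grid_value_at(gi, c(r, 0, 0)), 14.399645 / r, tolerance = 1e-6)
  expect_error(potential_map(m1, charges = 1, spacing = 0), "spacing")
})

test_that("potential grids are written as parseable OpenDX scalar fields", {
  m <- tiny_model(c("C1", "C2"), c(0, 0, 0, 3, 1, 2))
  g <- potential_map(m, charges = c(1, -1), spacing = 2, margin = 3)
  p <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, p)
  lines <- readLines(p)
  expect_match(lines[1], sprintf("counts %d %d %d", g$dims[1], g$dims[2], g$dims[3]))
  data_start <- grep("data follows", lines) + 1L
  data_end <- grep("attribute", lines)[1L] - 1L
  vals <- as.numeric(unlist(strsplit(trimws(lines[data_start:data_end]), "\\s+")))
  expect_equal(length(vals), prod(g$dims))
  # z-fastest ordering: first value is the grid origin corner
  expect_equal(vals[1L], g$values[1, 1, 1], tolerance = 1e-5)
  expect_equal(vals[2L], g$values[1, 1, 2], tolerance = 1e-5)
})
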