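# NeRF placement: position atom D bonded to C with length r, angle
# B-C-D = theta, torsion A-B-C-D = chi (degrees)
place_atom <- function(A, B, C, r, theta, chi) {
  th <- deg2rad(180 - theta)
  ch <- deg2rad(chi)
  d_local <- r * c(cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  bc <- vunit(C - B)
  n <- vunit(vcross(B - A, bc))
  m <- cbind(bc, vcross(n, bc), n)
  C + as.vector(m %*% d_local)
}

PEPTIDE_GEOM <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
  a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.5,
  omega = 180
)

#' Ideal poly-alanine backbone helix
#'
#' Builds an `n_res`-residue poly-alanine backbone (N, CA, C, O) with every
#' phi/psi torsion set exactly to the requested values and omega = 180
#' degrees, using standard peptide bond lengths and angles. `(-57, -47)`
#' gives an ideal alpha helix; `(180, 180)` a fully extended chain.
#'
#' @param n_res number of residues (>= 2)
#' @param phi,psi backbone torsions, degrees
#' @param chain chain id
#' @param resid_start first residue number
#' @return a `StructureModel`
#' @export
make_ideal_helix <- function(n_res, phi = -57, psi = -47, chain = "A",
                             resid_start = 1L) {
  if (n_res < 2L) stopf("need at least 2 residues")
  g <- PEPTIDE_GEOM
  N <- list(); CA <- list(); C <- list()
  N[[1L]] <- c(0, 0, 0)
  CA[[1L]] <- c(g$b_NCA, 0, 0)
  ang <- deg2rad(180 - g$a_NCAC)
  C[[1L]] <- CA[[1L]] + g$b_CAC * c(cos(ang), sin(ang), 0)
  for (i in 2:n_res) {
    N[[i]] <- place_atom(N[[i - 1L]], CA[[i - 1L]], C[[i - 1L]],
                         g$b_CN, g$a_CACN, psi)
    CA[[i]] <- place_atom(CA[[i - 1L]], C[[i - 1L]], N[[i]],
                          g$b_NCA, g$a_CNCA, g$omega)
    C[[i]] <- place_atom(C[[i - 1L]], N[[i]], CA[[i]],
                         g$b_CAC, g$a_NCAC, phi)
  }
  O <- vector("list", n_res)
  for (i in seq_len(n_res))
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]], g$b_CO, g$a_CACO,
                         wrap180(psi + 180))
  xyz <- do.call(rbind, lapply(seq_len(n_res), function(i)
    rbind(N[[i]], CA[[i]], C[[i]], O[[i]])))
  structure_model(data.frame(
    serial = seq_len(4L * n_res),
    name = rep(c("N", "CA", "C", "O"), n_res),
    element = rep(c("N", "C", "C", "O"), n_res),
    resname = "ALA",
    resid = rep(resid_start + seq_len(n_res) - 1L, each = 4L),
    chain = chain,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occupancy = 1, bfactor = 0, stringsAsFactors = FALSE))
}

dna_complement <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")

element_from_name <- function(name) {
  e <- substr(gsub("[0-9']", "", name), 1L, 1L)
  ifelse(e == "", "C", e)
}

# build a blunt duplex from per-base-pair frames (R = orientation columns,
# o = origin); strand II runs antiparallel with residue j pairing n+1-j
duplex_from_frames <- function(frames, sequence, chains = c("I", "J"),
                               serial_start = 1L) {
  n <- length(sequence)
  stopifnot(length(frames) == n)
  flip <- diag(c(1, -1, -1))
  place <- function(base, R, o, drop_p) {
    g <- std_base_geometry[[base]]
    if (drop_p) g <- g[!g$name %in% c("P", "OP1", "OP2"), , drop = FALSE]
    xyz <- as.matrix(g[, c("x", "y", "z")]) %*% t(R)
    xyz <- sweep(xyz, 2L, o, "+")
    list(name = g$name, xyz = xyz)
  }
  rows <- list()
  serial <- serial_start - 1L
  emit <- function(ats, base, resid, chain) {
    na <- length(ats$name)
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial + seq_len(na), name = ats$name,
      element = element_from_name(ats$name),
      resname = base, resid = resid, chain = chain,
      x = ats$xyz[, 1L], y = ats$xyz[, 2L], z = ats$xyz[, 3L],
      occupancy = 1, bfactor = 0, stringsAsFactors = FALSE)
    serial <<- serial + na
  }
  for (k in seq_len(n)) {
    f <- frames[[k]]
    emit(place(sequence[k], f$R, f$o, drop_p = (k == 1L)),
         sequence[k], k, chains[1L])
  }
  for (j in seq_len(n)) {
    k <- n + 1L - j  # paired strand-I position
    f <- frames[[k]]
    base <- dna_complement[[sequence[k]]]
    emit(place(base, f$R %*% flip, f$o, drop_p = (j == 1L)),
         base, j, chains[2L])
  }
  structure_model(do.call(rbind, rows))
}

#' Ideal straight B-DNA duplex
#'
#' Fibre-model duplex with uniform step geometry: every base pair is the
#' embedded standard-reference-frame geometry, advanced by `rise` along and
#' rotated by `twist` about the global z axis. All interior backbone
#' dihedrals are constant along the sequence by construction, and
#' [step_parameters()] recovers `twist`/`rise` exactly. 5'-terminal
#' phosphates are omitted (as in nucleic-acid crystal structures).
#'
#' @param sequence character vector of bases (`"DA"`-style or `"A"`-style)
#' @param twist helical twist per step, degrees
#' @param rise rise per step, A
#' @param chains the two chain ids
#' @return a `StructureModel`
#' @export
make_bdna_duplex <- function(sequence, twist = 36, rise = 3.38,
                             chains = c("I", "J")) {
  sequence <- normalize_base_resname(sequence)
  if (anyNA(sequence)) stopf("sequence must be A/T/G/C bases")
  n <- length(sequence)
  frames <- lapply(seq_len(n), function(k) {
    list(R = rotation_about(c(0, 0, 1), (k - 1L) * twist),
         o = c(0, 0, (k - 1L) * rise))
  })
  duplex_from_frames(frames, sequence, chains)
}

toy_histone_lengths <- c(H3 = 135L, H4 = 102L, H2A = 129L, H2B = 125L)

toy_domain_table <- function(chain, histone) {
  dom <- switch(histone,
    H3 = list(alphaN = c(44, 57), alpha1 = c(63, 77), alpha2 = c(85, 114),
              alpha3 = c(120, 131)),
    H4 = list(alpha1 = c(30, 41), alpha2 = c(49, 76), alpha3 = c(82, 89)),
    H2A = list(alpha1 = c(26, 37), alpha2 = c(46, 73), alpha3 = c(80, 97),
               docking = c(100, 119)),
    H2B = list(alpha1 = c(37, 49), alpha2 = c(57, 84), alpha3 = c(90, 102)))
  do.call(rbind, lapply(names(dom), function(d)
    data.frame(chain = chain, domain = d, start = dom[[d]][1L],
               end = dom[[d]][2L], stringsAsFactors = FALSE)))
}

#' Nucleosome-like toy system
#'
#' A desk-scale geometric emulation of the nucleosome core particle: a
#' 147-bp duplex bent onto a left-handed superhelical path (configurable
#' radius, pitch and number of wraps) with the helical register rotating at
#' one turn per `bp_per_turn` base pairs, plus eight ideal-helix
#' pseudo-histone chains (A-H: H3/H4/H2A/H2B copies 1 and 2) whose residue
#' numbering carries the real tail, helix-domain and docking-domain ranges
#' so that selections exercise the same code paths as a crystal-structure
#' model. The accompanying topology records chain assignments, tails,
#' domains, the dyad and the SHL segment boundaries (one per helical turn,
#' 14 segments for 147 bp).
#'
#' The pseudo-histones are geometric stand-ins with no sequence realism;
#' analyses that depend only on annotations, fluctuations and relative
#' geometry are meaningful on this system, force-field-level realism is
#' not.
#'
#' @param n_bp duplex length, base pairs
#' @param radius,pitch superhelix radius and pitch per wrap, A
#' @param turns number of superhelical wraps (> 0)
#' @param bp_per_turn DNA helical repeat, bp
#' @param sequence optional explicit base sequence (length `n_bp`)
#' @param seed seed for the random sequence
#' @return list with elements `model` (a `StructureModel`) and `topology`
#'   (a `NucleosomeTopology`)
#' @export
make_toy_nucleosome <- function(n_bp = 147L, radius = 41.9, pitch = 25.9,
                                turns = 1.67, bp_per_turn = 10.5,
                                sequence = NULL, seed = 101L) {
  if (turns <= 0) stopf("superhelix turns must be positive")
  if (is.null(sequence)) {
    sequence <- with_seed(seed,
      sample(c("DA", "DT", "DG", "DC"), n_bp, replace = TRUE))
  } else sequence <- normalize_base_resname(sequence)
  # superhelical path, centred; z axis = superhelix axis
  th <- 2 * pi * turns * (seq_len(n_bp) - 1L) / (n_bp - 1L) - pi * turns
  path <- cbind(radius * cos(th), radius * sin(th), pitch * th / (2 * pi))
  frames <- vector("list", n_bp)
  for (k in seq_len(n_bp)) {
    tangent <- vunit(c(-radius * sin(th[k]), radius * cos(th[k]), pitch / (2 * pi)))
    inward <- c(-cos(th[k]), -sin(th[k]), 0)
    inward <- vunit(inward - sum(inward * tangent) * tangent)
    binorm <- vcross(tangent, inward)
    w <- deg2rad(360 / bp_per_turn * (k - 1L))
    x_axis <- cos(w) * inward + sin(w) * binorm
    z_axis <- tangent
    y_axis <- vcross(z_axis, x_axis)
    frames[[k]] <- list(R = cbind(x_axis, y_axis, z_axis), o = path[k, ])
  }
  dna <- duplex_from_frames(frames, sequence, chains = c("I", "J"))
  chain_ids <- c("A", "B", "C", "D", "E", "F", "G", "H")
  histones <- rep(c("H3", "H4", "H2A", "H2B"), 2L)
  copies <- rep(1:2, each = 4L)
  models <- list(dna)
  serial <- max(dna$atoms$serial)
  for (i in seq_along(chain_ids)) {
    h <- make_ideal_helix(toy_histone_lengths[[histones[i]]],
                          chain = chain_ids[i])
    phi <- 2 * pi * (i - 1L) / 8
    R <- rotation_about(c(0, 0, 1), rad2deg(phi)) %*%
      rotation_about(c(0, 1, 0), 30 * (-1)^i)
    xyz <- coords(h) %*% t(R)
    xyz <- sweep(xyz, 2L, c(18 * cos(phi), 18 * sin(phi), 3 * (i - 4.5)), "+")
    coords(h) <- xyz
    h$atoms$serial <- h$atoms$serial + serial
    serial <- max(h$atoms$serial)
    models[[length(models) + 1L]] <- h
  }
  model <- structure_model(do.call(rbind, lapply(models, `[[`, "atoms")))
  dyad <- as.integer(ceiling(n_bp / 2))
  n_seg_side <- floor((n_bp / bp_per_turn) / 2)
  bnd <- floor(dyad + bp_per_turn * seq(-n_seg_side + 1L, n_seg_side - 1L))
  bnd <- bnd[bnd >= 1L & bnd < n_bp]
  topo <- nucleosome_topology(
    histone_assignments = data.frame(chain = chain_ids, histone = histones,
                                     copy = copies, stringsAsFactors = FALSE),
    tail_ranges = list(H3 = list(n = c(1, 26)), H4 = list(n = c(1, 17)),
                       H2A = list(n = c(1, 11), c = c(118, 129)),
                       H2B = list(n = c(1, 20))),
    domain_ranges = do.call(rbind, lapply(seq_along(chain_ids), function(i)
      toy_domain_table(chain_ids[i], histones[i]))),
    dna_chains = c("I", "J"),
    dyad_bp = dyad,
    shl_boundaries = bnd,
    n_bp = n_bp,
    bp_per_turn = bp_per_turn
  )
  list(model = model, topology = topo)
}

#' Stationary harmonic synthetic trajectory
#'
#' Frames are the reference coordinates plus independent Gaussian noise of
#' per-coordinate standard deviation `sigma` (A) — a stationary stand-in
#' for an equilibrated MD trajectory whose fluctuation statistics are known
#' in closed form (per-atom `B = 8 pi^2 sigma^2`). `sigma_by` assigns
#' different fluctuation scales to selections (later entries win);
#' `destabilization` rigidly displaces a target selection by a per-frame
#' profile along a direction, emulating the progressive loss of a domain's
#' native position. Output is bit-reproducible for a given seed.
#'
#' @param ref reference `StructureModel`
#' @param n_frames number of frames
#' @param sigma baseline per-coordinate fluctuation, A (>= 0)
#' @param sigma_by optional list of `list(sel = Selection, sigma = )`
#' @param destabilization optional `list(sel = Selection, profile = numeric
#'   n_frames (A), direction = 3-vector)`
#' @param dt frame spacing, ns
#' @param seed RNG seed
#' @return a [trajectory()]
#' @export
make_harmonic_trajectory <- function(ref, n_frames, sigma = 0.5,
                                     sigma_by = NULL, destabilization = NULL,
                                     dt = 0.1, seed = 1L) {
  na <- n_atoms(ref)
  sig <- rep(sigma, na)
  for (entry in sigma_by %||% list())
    sig[resolve_selection(entry$sel, ref)] <- entry$sigma
  if (any(sig < 0)) stopf("fluctuation scale sigma must be >= 0")
  dest_idx <- NULL
  if (!is.null(destabilization)) {
    dest_idx <- resolve_selection(destabilization$sel, ref)
    prof <- destabilization$profile
    if (length(prof) != n_frames)
      stopf("destabilization profile must have one value per frame")
    dir <- vunit(destabilization$direction %||% c(1, 0, 0))
  }
  base <- coords(ref)
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      fr <- base + matrix(stats::rnorm(na * 3L, sd = rep(sig, 3L)), ncol = 3L)
      if (!is.null(dest_idx))
        fr[dest_idx, ] <- sweep(fr[dest_idx, , drop = FALSE], 2L,
                                prof[f] * dir, "+")
      fr
    })
  })
  trajectory(ref, frames, times = dt * (seq_len(n_frames) - 1L))
}
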