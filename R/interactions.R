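#' Hydrogen-bond geometric criteria
#'
#' Defaults: donor-acceptor distance <= 3.5 A and donor-H...acceptor angle
#' >= 150 degrees (configurable; simulation-analysis tools differ and the
#' choice is deliberately explicit).
#'
#' @param dist_cutoff donor-acceptor heavy-atom distance cutoff, A (> 0)
#' @param angle_cutoff D-H...A angle cutoff, degrees in `(0, 180]`
#' @export
hbond_criteria <- function(dist_cutoff = 3.5, angle_cutoff = 150) {
  if (dist_cutoff <= 0) stopf("distance cutoff must be positive")
  if (angle_cutoff <= 0 || angle_cutoff > 180)
    stopf("angle cutoff must lie in (0, 180]")
  structure(list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "HBondCriteria")
}

# hydrogens covalently attached to each donor: element H within 1.25 A
attached_hydrogens <- function(model, donor_idx) {
  a <- model$atoms
  h_idx <- which(a$element == "H" | grepl("^H", a$name))
  if (!length(h_idx)) return(stats::setNames(rep(list(integer()), length(donor_idx)),
                                             donor_idx))
  xyz <- coords(model)
  d2 <- cross_dist2(xyz[donor_idx, , drop = FALSE], xyz[h_idx, , drop = FALSE])
  lapply(seq_along(donor_idx), function(k) h_idx[d2[k, ] < 1.25^2])
}

#' Detect hydrogen bonds in one frame
#'
#' Returns all and only (donor, H, acceptor) triplets whose donor-acceptor
#' distance and D-H...A angle meet the criteria. Donor candidates are N/O
#' atoms of `donors` carrying at least one attached hydrogen; acceptor
#' candidates are N/O atoms of `acceptors`. Selections without polar atoms
#' give an empty result, not an error.
#'
#' @param model a `StructureModel`
#' @param donors,acceptors selections (or atom index vectors)
#' @param crit a [hbond_criteria()]
#' @return data.frame `donor`, `h`, `acceptor` (atom indices), `dist` (A),
#'   `angle` (degrees)
#' @export
detect_hbonds <- function(model, donors, acceptors, crit = hbond_criteria()) {
  a <- model$atoms
  xyz <- coords(model)
  d_idx <- resolve_selection(donors, model)
  a_idx <- resolve_selection(acceptors, model)
  d_idx <- d_idx[a$element[d_idx] %in% c("N", "O")]
  a_idx <- a_idx[a$element[a_idx] %in% c("N", "O")]
  empty <- data.frame(donor = integer(), h = integer(), acceptor = integer(),
                      dist = numeric(), angle = numeric())
  if (!length(d_idx) || !length(a_idx)) return(empty)
  hs <- attached_hydrogens(model, d_idx)
  keep_donor <- lengths(hs) > 0L
  d_idx <- d_idx[keep_donor]; hs <- hs[keep_donor]
  if (!length(d_idx)) return(empty)
  d2 <- cross_dist2(xyz[d_idx, , drop = FALSE], xyz[a_idx, , drop = FALSE])
  out <- list()
  for (k in seq_along(d_idx)) {
    cand <- which(d2[k, ] <= crit$dist_cutoff^2)
    for (m in cand) {
      di <- d_idx[k]; ai <- a_idx[m]
      if (di == ai) next
      for (hi in hs[[k]]) {
        ang <- vangle(xyz[di, ] - xyz[hi, ], xyz[ai, ] - xyz[hi, ])
        if (ang >= crit$angle_cutoff) {
          out[[length(out) + 1L]] <- data.frame(
            donor = di, h = hi, acceptor = ai,
            dist = sqrt(d2[k, m]), angle = ang)
          break  # one bond per donor-acceptor pair
        }
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Per-frame hydrogen-bond counts between two groups
#'
#' Counts bonds with the donor in one group and the acceptor in the other
#' (both directions), per frame.
#'
#' @param traj a `Trajectory`
#' @param groupA,groupB selections
#' @param crit a [hbond_criteria()]
#' @return data.frame `time`, `count`
#' @export
hbond_count_series <- function(traj, groupA, groupB, crit = hbond_criteria()) {
  counts <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- model_frame(traj, f)
    nrow(detect_hbonds(m, groupA, groupB, crit)) +
      nrow(detect_hbonds(m, groupB, groupA, crit))
  }, 1L)
  data.frame(time = traj$times, count = counts)
}

#' Minimum interatomic distance time series between two selections
#'
#' Exact pairwise minimum per frame, with the closest atom pair recorded.
#'
#' @param traj a `Trajectory`
#' @param selA,selB non-empty selections
#' @return object of class `ContactSeries`: data.frame `time`, `dist` (A),
#'   `atom_a`, `atom_b` (atom indices)
#' @export
min_distance_series <- function(traj, selA, selB) {
  ia <- resolve_selection(selA, traj$topology)
  ib <- resolve_selection(selB, traj$topology)
  if (!length(ia) || !length(ib)) stopf("empty selection")
  nf <- n_frames(traj)
  out <- data.frame(time = traj$times, dist = NA_real_,
                    atom_a = NA_integer_, atom_b = NA_integer_)
  for (f in seq_len(nf)) {
    xyz <- traj$frames[[f]]
    d2 <- cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    w <- arrayInd(which.min(d2), dim(d2))
    out$dist[f] <- sqrt(max(0, d2[w]))
    out$atom_a[f] <- ia[w[1L]]
    out$atom_b[f] <- ib[w[2L]]
  }
  class(out) <- c("ContactSeries", "data.frame")
  out
}

#' Classify frames as in-contact or detached
#'
#' The threshold is the reference (intact-trajectory) mean minimum distance
#' plus one reference standard deviation; a frame is `detached` when its
#' minimum distance strictly exceeds the threshold ("greater than"), and
#' `in_contact` at or below it.
#'
#' @param test `ContactSeries` to classify
#' @param reference `ContactSeries` from the intact trajectory (>= 2
#'   frames, so the SD is defined)
#' @return object of class `DetachmentCall`: `threshold`, `ref_mean`,
#'   `ref_sd`, `states` (per frame), `fraction_detached`
#' @export
detachment_classify <- function(test, reference) {
  if (nrow(reference) < 2L)
    stopf("reference series needs at least 2 frames for a standard deviation")
  m <- mean(reference$dist); s <- stats::sd(reference$dist)
  thr <- m + s
  states <- ifelse(test$dist > thr, "detached", "in_contact")
  obj <- list(threshold = thr, ref_mean = m, ref_sd = s,
              time = test$time, states = states,
              fraction_detached = mean(states == "detached"))
  class(obj) <- "DetachmentCall"
  obj
}

#' @export
print.DetachmentCall <- function(x, ...) {
  cat(sprintf("DetachmentCall: threshold %.3f A (ref %.3f + %.3f), %.1f%% detached\n",
              x$threshold, x$ref_mean, x$ref_sd, 100 * x$fraction_detached))
  invisible(x)
}

#' Residue-pair interface contact map
#'
#' For every residue pair (one from each group) the distance between the
#' two closest atoms of the pair — equivalently the sum of each atom's
#' distance to their midpoint — with pairs at or below the cutoff flagged
#' as close contacts (3 A by default, the distance below which interface
#' residues are regarded to be in close contact). On a trajectory the map
#' is computed on the frame-averaged structure after superposing every
#' frame onto the first.
#'
#' @param x a `StructureModel` or `Trajectory`
#' @param groupA,groupB disjoint selections
#' @param cutoff close-contact cutoff, A
#' @param fit_sel alignment selection for the trajectory-average mode
#' @return object of class `ContactMap`: `distance` (matrix, A), `close`
#'   (logical mask), `residues_a`, `residues_b`
#' @export
contact_map <- function(x, groupA, groupB, cutoff = 3, fit_sel = select_all()) {
  if (inherits(x, "Trajectory")) {
    ref <- x$frames[[1L]]
    fit_idx <- resolve_selection(fit_sel, x$topology)
    acc <- matrix(0, nrow(ref), 3L)
    for (f in seq_len(n_frames(x))) {
      fr <- x$frames[[f]]
      fit <- kabsch_fit(fr[fit_idx, , drop = FALSE], ref[fit_idx, , drop = FALSE])
      acc <- acc + apply_superposition(fr, fit)
    }
    model <- x$topology
    coords(model) <- acc / n_frames(x)
  } else model <- x
  ia <- resolve_selection(groupA, model)
  ib <- resolve_selection(groupB, model)
  if (length(intersect(ia, ib)))
    stopf("contact-map groups overlap (%d shared atoms)", length(intersect(ia, ib)))
  a <- model$atoms
  key_a <- unique(paste(a$chain[ia], a$resid[ia]))
  key_b <- unique(paste(a$chain[ib], a$resid[ib]))
  xyz <- coords(model)
  d2 <- cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  res_a <- paste(a$chain[ia], a$resid[ia])
  res_b <- paste(a$chain[ib], a$resid[ib])
  dist <- matrix(NA_real_, length(key_a), length(key_b),
                 dimnames = list(key_a, key_b))
  for (i in seq_along(key_a)) {
    rows <- res_a == key_a[i]
    for (j in seq_along(key_b)) {
      dist[i, j] <- sqrt(max(0, min(d2[rows, res_b == key_b[j]])))
    }
  }
  obj <- list(distance = dist, close = dist <= cutoff, cutoff = cutoff,
              residues_a = key_a, residues_b = key_b)
  class(obj) <- "ContactMap"
  obj
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap: %d x %d residue pairs, %d close contacts (<= %.2f A)\n",
              nrow(x$distance), ncol(x$distance), sum(x$close), x$cutoff))
  invisible(x)
}

COULOMB_CONST <- 332.0636  # kcal A / (mol e^2)

#' Per-atom nonbonded parameters
#'
#' @param atoms data.frame with `chain`, `resid`, `name` identifying atoms,
#'   plus `charge` (e), `epsilon` (kcal/mol, LJ well depth) and `rmin_half`
#'   (A, half the LJ minimum-energy distance; combined additively across a
#'   pair, with geometric-mean well depths)
#' @export
nonbonded_params <- function(atoms) {
  need <- c("chain", "resid", "name", "charge", "epsilon", "rmin_half")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("parameter table lacks columns: %s", paste(miss, collapse = ", "))
  if (any(!is.finite(atoms$charge)) || any(!is.finite(atoms$epsilon)) ||
      any(atoms$rmin_half <= 0))
    stopf("nonbonded parameters must be finite with positive radii")
  structure(atoms, class = c("NonbondedParams", "data.frame"))
}

match_params <- function(model, idx, params) {
  a <- model$atoms
  key <- paste(a$chain[idx], a$resid[idx], a$name[idx])
  pk <- paste(params$chain, params$resid, params$name)
  m <- match(key, pk)
  if (anyNA(m))
    stopf("missing nonbonded parameters for atom(s): %s",
          paste(utils::head(key[is.na(m)], 3L), collapse = "; "))
  params[m, , drop = FALSE]
}

# CHARMM-style switching function on r in [r_on, r_off]
switch_factor <- function(r, switching) {
  if (is.null(switching)) return(rep(1, length(r)))
  ron2 <- switching$r_on^2; roff2 <- switching$r_off^2
  r2 <- r^2
  s <- (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) / (roff2 - ron2)^3
  ifelse(r2 <= ron2, 1, ifelse(r2 >= roff2, 0, s))
}

#' Pairwise nonbonded interaction energy between two groups
#'
#' Sum over cross-group atom pairs of the 12-6 Lennard-Jones term
#' `eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` plus the Coulomb term
#' `332.0636 q_i q_j / r` (kcal/mol), optionally modulated by a smooth
#' switching function between stated radii (as applied in the underlying
#' simulations). Computed per frame on a trajectory.
#'
#' @param x a `StructureModel` or `Trajectory`
#' @param groupA,groupB selections
#' @param params a [nonbonded_params()] table covering all atoms of both
#'   groups
#' @param switching `NULL` (no truncation) or `list(r_on=, r_off=)` in A
#' @return data.frame `time`, `elec`, `vdw`, `total` (kcal/mol); a single
#'   row with `time = 0` for a `StructureModel`
#' @export
interaction_energy <- function(x, groupA, groupB, params, switching = NULL) {
  if (inherits(x, "Trajectory")) {
    topo <- x$topology; frames <- x$frames; times <- x$times
  } else {
    topo <- x; frames <- list(coords(x)); times <- 0
  }
  ia <- resolve_selection(groupA, topo)
  ib <- resolve_selection(groupB, topo)
  if (!length(ia) || !length(ib)) stopf("empty selection")
  pa <- match_params(topo, ia, params)
  pb <- match_params(topo, ib, params)
  qq <- outer(pa$charge, pb$charge) * COULOMB_CONST
  eps <- sqrt(outer(pa$epsilon, pb$epsilon))
  rmin <- outer(pa$rmin_half, pb$rmin_half, "+")
  out <- data.frame(time = times, elec = NA_real_, vdw = NA_real_)
  for (f in seq_along(frames)) {
    xyz <- frames[[f]]
    r <- sqrt(pmax(cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE]), 1e-12))
    sw <- switch_factor(r, switching)
    s6 <- (rmin / r)^6
    out$elec[f] <- sum(qq / r * sw)
    out$vdw[f] <- sum(eps * (s6^2 - 2 * s6) * sw)
  }
  out$total <- out$elec + out$vdw
  out
}
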