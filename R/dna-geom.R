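#' Torsion angle of four points
#'
#' IUPAC-signed dihedral in degrees, in `(-180, 180]`: looking from `p2` to
#' `p3`, clockwise rotation of the far bond relative to the near bond is
#' positive.
#'
#' @param p1,p2,p3,p4 3-vectors (A)
#' @return angle in degrees
#' @export
torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stopf("collinear points: torsion undefined")
  ang <- rad2deg(atan2(vnorm(b2) * sum(b1 * n2), sum(n1 * n2)))
  wrap180(ang)
}

DNA_BACKBONE_TORSIONS <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")

#' DNA backbone dihedrals for one strand
#'
#' Computes alpha (O3'-P-O5'-C5'), beta (P-O5'-C5'-C4'), gamma
#' (O5'-C5'-C4'-C3'), delta (C5'-C4'-C3'-O3'), epsilon (C4'-C3'-O3'-P) and
#' zeta (C3'-O3'-P-O5') per nucleotide, degrees in `(-180, 180]`.
#' Dihedrals whose neighbouring atoms are absent (chain termini, missing
#' names) are `NA`, not zero.
#'
#' @param model a `StructureModel`
#' @param chain DNA chain id
#' @return data.frame `resid`, `alpha` .. `zeta`
#' @export
backbone_dihedrals <- function(model, chain) {
  a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  if (!nrow(a)) stopf("no atoms in chain %s", chain)
  resids <- unique(a$resid)
  get <- function(rid, nm) {
    m <- a[a$resid == rid & a$name == nm, , drop = FALSE]
    if (nrow(m)) c(m$x[1L], m$y[1L], m$z[1L]) else NULL
  }
  tors <- function(ps) {
    if (any(vapply(ps, is.null, TRUE))) return(NA_real_)
    torsion(ps[[1L]], ps[[2L]], ps[[3L]], ps[[4L]])
  }
  out <- data.frame(resid = resids)
  for (nm in DNA_BACKBONE_TORSIONS) out[[nm]] <- NA_real_
  for (k in seq_along(resids)) {
    rid <- resids[k]
    prev <- if (k > 1L) resids[k - 1L] else NULL
    nxt <- if (k < length(resids)) resids[k + 1L] else NULL
    P <- get(rid, "P"); O5 <- get(rid, "O5'"); C5 <- get(rid, "C5'")
    C4 <- get(rid, "C4'"); C3 <- get(rid, "C3'"); O3 <- get(rid, "O3'")
    O3p <- if (!is.null(prev)) get(prev, "O3'") else NULL
    Pn <- if (!is.null(nxt)) get(nxt, "P") else NULL
    O5n <- if (!is.null(nxt)) get(nxt, "O5'") else NULL
    out$alpha[k] <- tors(list(O3p, P, O5, C5))
    out$beta[k] <- tors(list(P, O5, C5, C4))
    out$gamma[k] <- tors(list(O5, C5, C4, C3))
    out$delta[k] <- tors(list(C5, C4, C3, O3))
    out$epsilon[k] <- tors(list(C4, C3, O3, Pn))
    out$zeta[k] <- tors(list(C3, O3, Pn, O5n))
  }
  out
}

#' BI/BII backbone substate classification
#'
#' B-DNA backbone substates from the epsilon-zeta torsion difference
#' (wrapped to `(-180, 180]`): BI when `eps - zeta < 0` (strictly), BII
#' otherwise; `undefined` where either torsion is missing.
#'
#' @param dihedrals data.frame from [backbone_dihedrals()] (needs columns
#'   `epsilon`, `zeta`)
#' @return data.frame `resid`, `eps_zeta` (degrees), `state`
#' @export
classify_bi_bii <- function(dihedrals) {
  ez <- wrap180(dihedrals$epsilon - dihedrals$zeta)
  state <- ifelse(is.na(ez), "undefined", ifelse(ez < 0, "BI", "BII"))
  data.frame(resid = dihedrals$resid, eps_zeta = ez, state = state,
             stringsAsFactors = FALSE)
}

# ---- base-pair reference frames ------------------------------------------

normalize_base_resname <- function(x) {
  map <- c(A = "DA", DA = "DA", ADE = "DA",
           T = "DT", DT = "DT", THY = "DT",
           G = "DG", DG = "DG", GUA = "DG",
           C = "DC", DC = "DC", CYT = "DC")
  unname(map[x])
}

# orientation (columns = frame axes) and origin of one base, by
# least-squares fit of the standard-reference-frame ring coordinates onto
# the observed ring atoms
base_frame <- function(model, chain, resid) {
  a <- model$atoms[model$atoms$chain == chain & model$atoms$resid == resid, , drop = FALSE]
  if (!nrow(a)) return(NULL)
  res <- normalize_base_resname(a$resname[1L])
  if (is.na(res)) return(NULL)
  ring <- base_ring_atoms[[res]]
  std <- std_base_geometry[[res]]
  obs <- a[match(ring, a$name), c("x", "y", "z")]
  if (anyNA(obs)) return(NULL)
  stdm <- as.matrix(std[match(ring, std$name), c("x", "y", "z")])
  fit <- kabsch_fit(stdm, as.matrix(obs))
  list(R = fit$rotation, origin = fit$translation, fit_rmsd = fit$rmsd)
}

rot2quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- (i %% 3L) + 1L; k <- (j %% 3L) + 1L
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

quat2rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

mid_rotation <- function(R1, R2) {
  q1 <- rot2quat(R1); q2 <- rot2quat(R2)
  if (sum(q1 * q2) < 0) q2 <- -q2
  q <- q1 + q2
  quat2rot(q / sqrt(sum(q^2)))
}

# base-pair frame: average of the strand-I base frame and the strand-II
# base frame flipped 180 degrees about its x axis (so that an ideal
# Watson-Crick pair gives coincident frames)
basepair_frame <- function(model, chains, res_i, res_j) {
  f1 <- base_frame(model, chains[1L], res_i)
  f2 <- base_frame(model, chains[2L], res_j)
  if (is.null(f1) || is.null(f2)) return(NULL)
  flip <- diag(c(1, -1, -1))
  R2f <- f2$R %*% flip
  list(R = mid_rotation(f1$R, R2f), origin = (f1$origin + f2$origin) / 2)
}

#' Default blunt-duplex base-pairing map
#'
#' Position `i` on strand I pairs with `n + 1 - i` on strand II. Supply an
#' explicit map to [step_parameters()] / [groove_widths()] for non-standard
#' pairing (the nucleosome trajectory work noted one non-Watson-Crick
#' pairing, so pairing is never inferred silently from geometry).
#'
#' @param n_bp number of base pairs
#' @return data.frame `bp`, `res_i`, `res_j`
#' @export
basepair_map <- function(n_bp) {
  data.frame(bp = seq_len(n_bp), res_i = seq_len(n_bp),
             res_j = n_bp + 1L - seq_len(n_bp))
}

# CEHS/mid-step decomposition of the transform between two base-pair frames
step_from_frames <- function(R1, o1, R2, o2) {
  z1 <- R1[, 3L]; z2 <- R2[, 3L]
  gamma <- vangle(z1, z2)
  if (gamma < 1e-7) {
    R1p <- R1; R2p <- R2
    hinge <- NULL
  } else {
    hinge <- vunit(vcross(z1, z2))
    R1p <- rotation_about(hinge, +gamma / 2) %*% R1
    R2p <- rotation_about(hinge, -gamma / 2) %*% R2
  }
  zc <- R1p[, 3L]
  x1 <- R1p[, 1L]; x2 <- R2p[, 1L]
  twist <- rad2deg(atan2(sum(vcross(x1, x2) * zc), sum(x1 * x2)))
  Rm <- mid_rotation(R1p, R2p)
  if (is.null(hinge)) {
    roll <- 0; tilt <- 0
  } else {
    ym <- Rm[, 2L]
    phi <- atan2(sum(vcross(hinge, ym) * zc), sum(hinge * ym))
    roll <- gamma * cos(phi)
    tilt <- gamma * sin(phi)
  }
  d <- as.vector(crossprod(Rm, o2 - o1))
  c(shift = d[1L], slide = d[2L], rise = d[3L],
    tilt = tilt, roll = roll, twist = twist)
}

#' Base-pair step parameters
#'
#' Base-pair reference frames are obtained by least-squares fit of embedded
#' standard-reference-frame base geometries to the observed ring atoms
#' (strand II flipped about its x axis), averaged across the pair; step
#' parameters (shift, slide, rise / tilt, roll, twist) follow from the
#' mid-step frame decomposition of consecutive pair frames. Pairs whose
#' base cannot be fit (modified/unknown residue, missing ring atoms) are
#' skipped and flagged in the `skipped` attribute.
#'
#' @param model a `StructureModel`
#' @param chains the two DNA chain ids (strand I first)
#' @param pairing data.frame from [basepair_map()] or a custom map
#' @return data.frame `step` (between `bp` and `bp+1`), `shift`, `slide`,
#'   `rise` (A), `tilt`, `roll`, `twist` (degrees); attribute `frames` holds
#'   the per-pair origin/orientation list
#' @export
step_parameters <- function(model, chains, pairing = NULL) {
  if (is.null(pairing)) {
    n <- length(unique(model$atoms$resid[model$atoms$chain == chains[1L]]))
    pairing <- basepair_map(n)
  }
  frames <- vector("list", nrow(pairing))
  for (k in seq_len(nrow(pairing)))
    frames[[k]] <- basepair_frame(model, chains, pairing$res_i[k], pairing$res_j[k])
  skipped <- which(vapply(frames, is.null, TRUE))
  steps <- list()
  for (k in seq_len(nrow(pairing) - 1L)) {
    f1 <- frames[[k]]; f2 <- frames[[k + 1L]]
    if (is.null(f1) || is.null(f2)) next
    steps[[length(steps) + 1L]] <-
      c(step = pairing$bp[k], step_from_frames(f1$R, f1$origin, f2$R, f2$origin))
  }
  out <- as.data.frame(do.call(rbind, steps))
  attr(out, "frames") <- frames
  attr(out, "skipped") <- skipped
  out
}

# ---- groove widths --------------------------------------------------------

# cross-strand offsets (in base-pair steps, on the strand-I position scale)
# at which the phosphate-phosphate separation across the minor and major
# grooves is measured; the spline refinement then finds the local closest
# approach around these offsets
GROOVE_MINOR_OFFSET <- -3
GROOVE_MAJOR_OFFSET <- 3
GROOVE_WINDOW <- 1.5

phosphate_spline <- function(model, chain, positions) {
  a <- model$atoms[model$atoms$chain == chain & model$atoms$name == "P", , drop = FALSE]
  if (nrow(a) < 4L) return(NULL)
  a <- a[order(match(a$resid, unique(model$atoms$resid[model$atoms$chain == chain]))), , drop = FALSE]
  u <- positions(a$resid)
  ord <- order(u)
  u <- u[ord]; a <- a[ord, , drop = FALSE]
  fx <- stats::splinefun(u, a$x, method = "natural")
  fy <- stats::splinefun(u, a$y, method = "natural")
  fz <- stats::splinefun(u, a$z, method = "natural")
  list(f = function(t) cbind(fx(t), fy(t), fz(t)), range = range(u))
}

#' Groove widths by the refined phosphate-spline construction
#'
#' Minor and major groove widths per base-pair step as cross-strand P-P
#' distances in the El Hassan-Calladine sense: cubic splines are threaded
#' through each strand's phosphorus atoms, and at each step level the
#' closest approach between the strand-I spline and the strand-II spline is
#' found within a window around the canonical minor-groove (offset -3
#' steps) and major-groove (offset +3 steps) crossings. Widths are
#' undefined (`NA`) near the termini where fewer than two phosphates flank
#' the window on either side.
#'
#' @param model a `StructureModel`
#' @param chains the two DNA chain ids (strand I first)
#' @param pairing pairing map (default [basepair_map()])
#' @return data.frame `step`, `minor`, `major` (A, P-P centre distances)
#' @export
groove_widths <- function(model, chains, pairing = NULL) {
  n <- length(unique(model$atoms$resid[model$atoms$chain == chains[1L]]))
  if (is.null(pairing)) pairing <- basepair_map(n)
  # strand-I phosphate at residue i sits at bp position i (5' side);
  # strand-II residue j maps to bp position n + 1 - j
  pos_i <- function(res) res
  jmap <- stats::setNames(pairing$bp, pairing$res_j)
  pos_j <- function(res) unname(jmap[as.character(res)])
  s1 <- phosphate_spline(model, chains[1L], pos_i)
  s2 <- phosphate_spline(model, chains[2L], pos_j)
  steps <- seq_len(n - 1L)
  out <- data.frame(step = steps, minor = NA_real_, major = NA_real_)
  if (is.null(s1) || is.null(s2)) return(out)
  closest <- function(t0, offset) {
    w <- GROOVE_WINDOW
    lo1 <- t0 - w; hi1 <- t0 + w
    lo2 <- t0 + offset - w; hi2 <- t0 + offset + w
    # require two flanking phosphates inside each strand's fitted range
    if (lo1 < s1$range[1L] + 1 || hi1 > s1$range[2L] - 1) return(NA_real_)
    if (lo2 < s2$range[1L] + 1 || hi2 > s2$range[2L] - 1) return(NA_real_)
    obj <- function(p) sqrt(sum((s1$f(p[1L]) - s2$f(p[2L]))^2))
    # multi-start within the window: the cross-strand distance surface can
    # hold two shallow local minima
    starts <- expand.grid(u = c(lo1 + 0.01, t0, hi1 - 0.01),
                          v = c(lo2 + 0.01, t0 + offset, hi2 - 0.01))
    min(apply(starts, 1L, function(p0)
      stats::optim(as.numeric(p0), obj, method = "L-BFGS-B",
                   lower = c(lo1, lo2), upper = c(hi1, hi2),
                   control = list(factr = 10))$value))
  }
  for (m in steps) {
    t0 <- m + 0.5
    out$minor[m] <- closest(t0, GROOVE_MINOR_OFFSET)
    out$major[m] <- closest(t0, GROOVE_MAJOR_OFFSET)
  }
  out
}
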