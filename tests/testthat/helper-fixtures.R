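# shared fixtures (built in code, cached per session) and independent
# brute-force oracles used across the suite

.fixture_cache <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(.fixture_cache$toy))
    .fixture_cache$toy <- make_toy_nucleosome()
  .fixture_cache$toy
}

# minimal atom-table constructor for hand-made geometries
tiny_model <- function(names, xyz, elements = NULL, resid = NULL,
                       chain = "Z", resname = "XXX") {
  n <- length(names)
  xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
  structure_model(data.frame(
    serial = seq_len(n), name = names,
    element = elements %||% toupper(substr(gsub("[0-9']", "", names), 1, 1)),
    resname = resname, resid = resid %||% seq_len(n), chain = chain,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occupancy = 1, bfactor = 0, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent oracles --------------------------------------------------

# exhaustive O(n*m) minimum distance
oracle_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# exhaustive hydrogen-bond triplets over explicit donor/H/acceptor lists
oracle_hbonds <- function(xyz, donors, hydro, acceptors, dist_cut, ang_cut) {
  hits <- list()
  for (k in seq_along(donors)) {
    d <- donors[k]
    for (a in acceptors) {
      if (a == d) next
      r <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (r > dist_cut) next
      for (h in hydro[[k]]) {
        v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= ang_cut) {
          hits[[length(hits) + 1L]] <- c(d, a)
          break
        }
      }
    }
  }
  if (!length(hits)) return(matrix(integer(), ncol = 2L))
  unique(do.call(rbind, hits))
}

# exhaustive pairwise LJ + Coulomb
oracle_energy <- function(xa, xb, qa, qb, ea, eb, ra, rb) {
  elec <- 0; vdw <- 0
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    r <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    elec <- elec + 332.0636 * qa[i] * qb[j] / r
    rm <- ra[i] + rb[j]; eps <- sqrt(ea[i] * eb[j])
    vdw <- vdw + eps * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  c(elec = elec, vdw = vdw)
}

# minimum RMSD by direct minimisation over rotations (Euler angles,
# multi-start Nelder-Mead refined with BFGS) -- independent of the SVD path
oracle_min_rmsd <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2L, cm); Y <- sweep(reference, 2L, cr)
  rotmat <- function(a) {
    Rz1 <- nuctraj:::rotation_about(c(0, 0, 1), a[1L] * 180 / pi)
    Ry <- nuctraj:::rotation_about(c(0, 1, 0), a[2L] * 180 / pi)
    Rz2 <- nuctraj:::rotation_about(c(0, 0, 1), a[3L] * 180 / pi)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(a) sqrt(mean(rowSums((X %*% t(rotmat(a)) - Y)^2)))
  best <- Inf
  set.seed(99)
  starts <- rbind(expand.grid(a = c(0, pi / 2, pi, 3 * pi / 2),
                              b = c(0, pi / 2, pi),
                              g = c(0, pi / 2, pi, 3 * pi / 2)))
  for (s in seq_len(nrow(starts))) {
    r0 <- optim(as.numeric(starts[s, ]), obj, method = "Nelder-Mead",
                control = list(maxit = 500))
    r1 <- optim(r0$par, obj, method = "BFGS",
                control = list(maxit = 200, reltol = 1e-14))
    best <- min(best, r1$value)
  }
  best
}

# torsion via the two-plane acos construction with explicit sign from the
# scalar triple product (distinct from the atan2 path)
oracle_torsion <- function(p1, p2, p3, p4) {
  x <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                        a[3] * b[1] - a[1] * b[3],
                        a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- x(b1, b2); n2 <- x(b2, b3)
  ca <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, ca))) * 180 / pi
  if (sum(x(n1, n2) * b2) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}
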