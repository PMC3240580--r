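#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic model of the backbone NH...O=C hydrogen bond:
#' `E = q1*q2*(1/rON + 1/rCH - 1/rOH - 1/rCN) * 332` kcal/mol with
#' `q1*q2 = 0.42 * 0.20`. A bond is declared when `E < -0.5` kcal/mol.
#' If any of the four distances falls below 0.5 A (overlapping atoms) the
#' energy is capped at the conventional minimum of -9.9 kcal/mol and the
#' result carries attribute `capped = TRUE`.
#'
#' @param N,H donor backbone nitrogen and amide hydrogen positions
#'   (3-vectors, A)
#' @param C,O acceptor backbone carbonyl carbon and oxygen positions
#' @return energy in kcal/mol (attribute `capped` flags the overlap cap)
#' @export
ks_hbond_energy <- function(N, H, C, O) {
  rON <- vnorm(O - N); rCH <- vnorm(C - H)
  rOH <- vnorm(O - H); rCN <- vnorm(C - N)
  if (min(rON, rCH, rOH, rCN) < 0.5)
    return(structure(-9.9, capped = TRUE))
  e <- 0.42 * 0.20 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  structure(max(e, -9.9), capped = FALSE)
}

KS_HBOND_CUTOFF <- -0.5  # kcal/mol

# build the per-chain residue backbone table; amide H is reconstructed
# 1.00 A from N along the preceding C=O direction (pointing away from O)
# when the structure carries no hydrogens
residue_backbone <- function(model, chains = NULL) {
  a <- model$atoms
  if (is.null(chains)) {
    has_ca <- unique(a$chain[a$name == "CA"])
    chains <- has_ca
  }
  rows <- list()
  for (ch in chains) {
    ca <- a[a$chain == ch, , drop = FALSE]
    resids <- unique(ca$resid)
    get <- function(rid, nm) {
      m <- ca[ca$resid == rid & ca$name == nm, , drop = FALSE]
      if (nrow(m)) c(m$x[1L], m$y[1L], m$z[1L]) else NULL
    }
    prevC <- NULL; prevO <- NULL
    for (rid in resids) {
      N <- get(rid, "N"); CA <- get(rid, "CA"); C <- get(rid, "C"); O <- get(rid, "O")
      H <- get(rid, "H")
      resname <- ca$resname[ca$resid == rid][1L]
      complete <- !is.null(N) && !is.null(CA) && !is.null(C) && !is.null(O)
      # chain continuity: peptide bond C(i-1)-N(i) about 1.33 A
      linked <- !is.null(prevC) && !is.null(N) && vnorm(N - prevC) < 2.5
      if (is.null(H) && complete && linked && resname != "PRO") {
        H <- N + vunit(prevC - prevO)  # 1.00 A from N, anti to C=O
      }
      rows[[length(rows) + 1L]] <- list(chain = ch, resid = rid,
                                        resname = resname,
                                        N = N, CA = CA, C = C, O = O, H = H,
                                        complete = complete, linked = linked)
      prevC <- C; prevO <- O
    }
  }
  rows
}

# HB[i, j] is TRUE when the carbonyl of residue i accepts a hydrogen bond
# from the amide of residue j
ks_hbond_matrix <- function(res) {
  n <- length(res)
  HB <- matrix(FALSE, n, n)
  if (n < 2L) return(HB)
  CAs <- t(vapply(res, function(r) r$CA %||% c(NA_real_, NA_real_, NA_real_), numeric(3L)))
  ok_acc <- vapply(res, function(r) !is.null(r$C) && !is.null(r$O), logical(1L))
  ok_don <- vapply(res, function(r) !is.null(r$N) && !is.null(r$H), logical(1L))
  d2 <- cross_dist2(CAs, CAs)
  for (i in which(ok_acc)) {
    cand <- which(ok_don & d2[i, ] < 81 & seq_len(n) != i)  # 9 A CA-CA screen
    for (j in cand) {
      e <- ks_hbond_energy(res[[j]]$N, res[[j]]$H, res[[i]]$C, res[[i]]$O)
      if (e < KS_HBOND_CUTOFF) HB[i, j] <- TRUE
    }
  }
  HB
}

#' Assign secondary structure to one frame
#'
#' Kabsch-Sander pattern assignment from backbone hydrogen bonds: helices
#' from consecutive n-turns (H: n->n+4, G: n->n+3, I: n->n+5), extended
#' strand from parallel/antiparallel bridge patterns (isolated bridges are
#' folded into E), hydrogen-bonded turns T, and bends S (CA-trace kink
#' > 70 degrees). Codes are resolved with the deterministic priority
#' H > E > G > I > T > S; everything else, and any residue lacking backbone
#' atoms, is coil (`"C"`). Hydrogens are reconstructed when absent.
#'
#' @param model a `StructureModel` (one frame)
#' @param chains protein chains to assign (default: all chains with CA
#'   atoms)
#' @return data.frame `chain`, `resid`, `code` in residue order
#' @export
assign_ss <- function(model, chains = NULL) {
  res <- residue_backbone(model, chains)
  n <- length(res)
  code <- rep("C", n)
  if (n == 0L) return(data.frame(chain = character(), resid = integer(),
                                 code = character(), stringsAsFactors = FALSE))
  HB <- ks_hbond_matrix(res)
  ch <- vapply(res, `[[`, "", "chain")
  same_chain_span <- function(i, j) {
    ch[i] == ch[j] && all(vapply(res[seq(min(i, j), max(i, j))], `[[`, TRUE, "linked")[-1L])
  }
  # n-turns: turn_n[i] when CO(i) accepts from NH(i+n) within one chain
  turn <- list()
  for (nn in 3:5) {
    t_n <- rep(FALSE, n)
    if (n > nn) for (i in seq_len(n - nn)) {
      if (HB[i, i + nn] && same_chain_span(i, i + nn)) t_n[i] <- TRUE
    }
    turn[[as.character(nn)]] <- t_n
  }
  # helices: two consecutive n-turns
  helixH <- rep(FALSE, n); helixG <- rep(FALSE, n); helixI <- rep(FALSE, n)
  if (n >= 5L) for (i in 2:(n - 1L)) {
    if (i + 3L <= n && turn[["4"]][i - 1L] && turn[["4"]][i]) helixH[i:(i + 3L)] <- TRUE
    if (i + 2L <= n && turn[["3"]][i - 1L] && turn[["3"]][i]) helixG[i:(i + 2L)] <- TRUE
    if (i + 4L <= n && turn[["5"]][i - 1L] && turn[["5"]][i]) helixI[i:(i + 4L)] <- TRUE
  }
  # bridges -> strand
  strand <- rep(FALSE, n)
  if (n >= 3L) for (i in 2:(n - 1L)) {
    for (j in seq_len(n)) {
      if (j < 2L || j + 1L > n) next
      if (ch[i] == ch[j] && abs(i - j) < 3L) next
      par <- (HB[i - 1L, j] && HB[j, i + 1L]) || (HB[j - 1L, i] && HB[i, j + 1L])
      anti <- (HB[i, j] && HB[j, i]) || (HB[i - 1L, j + 1L] && HB[j - 1L, i + 1L])
      if (par || anti) { strand[i] <- TRUE; strand[j] <- TRUE }
    }
  }
  # hydrogen-bonded turns
  turnT <- rep(FALSE, n)
  for (nn in 3:5) {
    for (i in which(turn[[as.character(nn)]])) {
      span <- seq(i + 1L, i + nn - 1L)
      turnT[span[span <= n]] <- TRUE
    }
  }
  # bends
  bendS <- rep(FALSE, n)
  if (n >= 5L) for (i in 3:(n - 2L)) {
    if (!same_chain_span(i - 2L, i + 2L)) next
    r <- res[[i]]
    if (is.null(r$CA) || is.null(res[[i - 2L]]$CA) || is.null(res[[i + 2L]]$CA)) next
    u <- r$CA - res[[i - 2L]]$CA
    v <- res[[i + 2L]]$CA - r$CA
    if (vnorm(u) < 1e-6 || vnorm(v) < 1e-6) next
    if (vangle(u, v) > 70) bendS[i] <- TRUE
  }
  code[bendS] <- "S"
  code[turnT] <- "T"
  code[helixI] <- "I"
  code[helixG] <- "G"
  code[strand] <- "E"
  code[helixH] <- "H"
  incomplete <- !vapply(res, `[[`, TRUE, "complete")
  code[incomplete] <- "C"
  data.frame(chain = ch,
             resid = vapply(res, `[[`, 0L, "resid"),
             code = code, stringsAsFactors = FALSE)
}

#' Secondary structure over a trajectory
#'
#' @param traj a `Trajectory`
#' @param chains protein chains (default: all with CA atoms)
#' @return data.frame in long format: `chain`, `resid`, `frame`, `code`
#' @export
ss_trajectory <- function(traj, chains = NULL) {
  out <- lapply(seq_len(n_frames(traj)), function(f) {
    ss <- assign_ss(model_frame(traj, f), chains)
    ss$frame <- f
    ss
  })
  do.call(rbind, out)
}

#' Per-residue alpha-helix propensity
#'
#' Fraction of frames in which each residue carries code `H`.
#'
#' @param traj a `Trajectory`
#' @param chains protein chains (default: all with CA atoms)
#' @return data.frame `chain`, `resid`, `propensity` (in `[0, 1]`)
#' @export
helix_propensity <- function(traj, chains = NULL) {
  long <- ss_trajectory(traj, chains)
  agg <- stats::aggregate(list(propensity = long$code == "H"),
                          by = list(chain = long$chain, resid = long$resid),
                          FUN = mean)
  agg[order(agg$chain, agg$resid), , drop = FALSE]
}
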