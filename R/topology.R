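#' Nucleosome topology: histone copies, tails, domains and DNA SHLs
#'
#' Describes the anatomy of a nucleosome model: which chain is which histone
#' copy, where the disordered tails are, named structural domains (helices,
#' the H2A docking domain), the DNA duplex chains, the dyad base pair and
#' the superhelix-location (SHL) segment boundaries.
#'
#' @param histone_assignments data.frame with columns `chain`, `histone`
#'   (one of H3, H4, H2A, H2B) and `copy` (1 or 2)
#' @param tail_ranges named list per histone type, each a list with `n`
#'   (N-terminal residue range `c(from, to)`) and optional `c` (C-terminal
#'   range)
#' @param domain_ranges data.frame with columns `chain`, `domain`, `start`,
#'   `end` (residue numbers, closed intervals)
#' @param dna_chains the two DNA chain ids, 5'-3' strand I first
#' @param dyad_bp 1-based index (from the 5' end of strand I) of the dyad
#'   base pair
#' @param shl_boundaries strictly increasing interior base-pair boundary
#'   indices separating one-turn SHL segments
#' @param n_bp number of base pairs in the duplex
#' @param bp_per_turn helical repeat used to map SHL values to base pairs
#' @return an object of class `NucleosomeTopology`
#' @export
nucleosome_topology <- function(histone_assignments, tail_ranges,
                                domain_ranges, dna_chains, dyad_bp,
                                shl_boundaries, n_bp, bp_per_turn = 10.5) {
  stopifnot(all(c("chain", "histone", "copy") %in% names(histone_assignments)))
  if (!all(histone_assignments$histone %in% c("H3", "H4", "H2A", "H2B")))
    stopf("histone types must be H3, H4, H2A or H2B")
  if (length(dna_chains) != 2L) stopf("dna_chains must name two chains")
  shl_boundaries <- as.integer(shl_boundaries)
  if (is.unsorted(shl_boundaries, strictly = TRUE))
    stopf("SHL boundaries must be strictly increasing")
  if (any(shl_boundaries < 1L) || any(shl_boundaries >= n_bp))
    stopf("SHL boundaries must lie within 1..n_bp-1")
  # tail and core must be disjoint: tails are ranges at the chain ends
  for (h in names(tail_ranges)) {
    tr <- tail_ranges[[h]]
    if (!is.null(tr$n) && !is.null(tr$c) && tr$n[2L] >= tr$c[1L])
      stopf("tail ranges for %s overlap", h)
  }
  obj <- list(histone_assignments = histone_assignments,
              tail_ranges = tail_ranges,
              domain_ranges = domain_ranges,
              dna_chains = dna_chains,
              dyad_bp = as.integer(dyad_bp),
              shl_boundaries = shl_boundaries,
              n_bp = as.integer(n_bp),
              bp_per_turn = bp_per_turn)
  class(obj) <- "NucleosomeTopology"
  obj
}

#' @export
print.NucleosomeTopology <- function(x, ...) {
  cat(sprintf("NucleosomeTopology: %d histone chains, DNA %s/%s, %d bp, dyad at bp %d, %d SHL segments\n",
              nrow(x$histone_assignments), x$dna_chains[1L], x$dna_chains[2L],
              x$n_bp, x$dyad_bp, length(x$shl_boundaries) + 1L))
  invisible(x)
}

#' Chain ids assigned to histones
#' @param topo a `NucleosomeTopology`
#' @param histone,copy optional filters (histone type, copy number)
#' @return character vector of chain ids in assignment order
#' @export
histone_chains <- function(topo, histone = NULL, copy = NULL) {
  ha <- topo$histone_assignments
  if (!is.null(histone)) ha <- ha[ha$histone %in% histone, , drop = FALSE]
  if (!is.null(copy)) ha <- ha[ha$copy %in% copy, , drop = FALSE]
  ha$chain
}

tail_residues <- function(topo, histone) {
  tr <- topo$tail_ranges[[histone]]
  if (is.null(tr)) return(integer())
  out <- integer()
  if (!is.null(tr$n)) out <- c(out, seq(tr$n[1L], tr$n[2L]))
  if (!is.null(tr$c)) out <- c(out, seq(tr$c[1L], tr$c[2L]))
  out
}

#' Histone-core backbone selection (tails excluded)
#'
#' Default fit selection for trajectory superposition: backbone N, CA, C, O
#' of histone chains excluding the tail residue ranges.
#'
#' @param topo a `NucleosomeTopology`
#' @param histone,copy optional restriction to one histone type / copy
#' @export
select_histone_core <- function(topo, histone = NULL, copy = NULL) {
  ha <- topo$histone_assignments
  if (!is.null(histone)) ha <- ha[ha$histone %in% histone, , drop = FALSE]
  if (!is.null(copy)) ha <- ha[ha$copy %in% copy, , drop = FALSE]
  tails <- lapply(seq_len(nrow(ha)), function(i) tail_residues(topo, ha$histone[i]))
  chains <- ha$chain
  label <- sprintf("core backbone %s", paste(sprintf("%s(%d)=%s", ha$histone, ha$copy, ha$chain), collapse = " "))
  selection(function(a) {
    keep <- rep(FALSE, nrow(a))
    for (i in seq_along(chains)) {
      keep <- keep | (a$chain == chains[i] &
                        a$name %in% protein_backbone_names &
                        !(a$resid %in% tails[[i]]))
    }
    keep
  }, label = label)
}

#' Selection for a named domain of a histone chain
#' @param topo a `NucleosomeTopology`
#' @param chain chain id
#' @param domain domain name as listed in `topo$domain_ranges`
#' @param backbone_only restrict to backbone atoms (default TRUE)
#' @export
select_domain <- function(topo, chain, domain, backbone_only = TRUE) {
  dr <- topo$domain_ranges
  row <- dr[dr$chain == chain & dr$domain == domain, , drop = FALSE]
  if (nrow(row) != 1L) stopf("domain '%s' not defined for chain %s", domain, chain)
  select_atoms(chain = chain, resid = seq(row$start, row$end),
               name = if (backbone_only) protein_backbone_names else NULL,
               label = sprintf("%s %s (%d-%d)", chain, domain, row$start, row$end))
}

#' Selection for the DNA duplex or a base-pair range of it
#' @param topo a `NucleosomeTopology`
#' @param bp_range optional `c(from, to)` base-pair range (strand I index)
#' @param backbone_only restrict to the phosphate backbone (P, O5', C5',
#'   C4', C3', O3')
#' @export
select_dna <- function(topo, bp_range = NULL, backbone_only = FALSE) {
  chains <- topo$dna_chains
  n <- topo$n_bp
  bb <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
  label <- if (is.null(bp_range)) "DNA duplex"
           else sprintf("DNA bp %d-%d", bp_range[1L], bp_range[2L])
  force(bp_range)
  selection(function(a) {
    keep_i <- a$chain == chains[1L]
    keep_j <- a$chain == chains[2L]
    if (!is.null(bp_range)) {
      rng <- seq(bp_range[1L], bp_range[2L])
      keep_i <- keep_i & a$resid %in% rng
      keep_j <- keep_j & a$resid %in% (n + 1L - rng)
    }
    keep <- keep_i | keep_j
    if (backbone_only) keep <- keep & a$name %in% bb
    keep
  }, label = label)
}

# ---- truncation -----------------------------------------------------------

#' Histone tail truncation specification
#'
#' Defaults follow the trypsin-accessible clip sites used in tail-truncation
#' simulation work: N-terminal residues 1-26 (H3), 1-17 (H4), 1-11 (H2A),
#' 1-20 (H2B), and additionally C-terminal residues 118-128 for H2A.
#'
#' @param ... per-histone lists with elements `n` and optionally `c`, each a
#'   `c(from, to)` residue range, e.g. `H3 = list(n = c(1, 26))`
#' @export
truncation_spec <- function(...) {
  spec <- list(...)
  if (!length(spec)) return(structure(list(), class = "TruncationSpec"))
  if (!all(names(spec) %in% c("H3", "H4", "H2A", "H2B")))
    stopf("truncation spec keys must be histone types")
  for (h in names(spec)) {
    entry <- spec[[h]]
    for (side in intersect(c("n", "c"), names(entry))) {
      r <- entry[[side]]
      if (length(r) != 2L || r[1L] > r[2L]) stopf("bad range for %s$%s", h, side)
    }
  }
  structure(spec, class = "TruncationSpec")
}

#' @rdname truncation_spec
#' @export
default_truncation_spec <- function() {
  truncation_spec(
    H3 = list(n = c(1, 26)),
    H4 = list(n = c(1, 17)),
    H2A = list(n = c(1, 11), c = c(118, 128)),
    H2B = list(n = c(1, 20))
  )
}

#' Remove histone tail residues from a model
#'
#' Removes exactly the specified residue ranges from both copies of each
#' listed histone; all other atoms are untouched and atom order is
#' preserved. A partially absent range is an error listing the missing
#' residues (a numbering mismatch must not truncate silently); a range that
#' is absent in its entirety is treated as already truncated, which makes
#' the operation idempotent.
#'
#' @param model a `StructureModel`
#' @param topo a `NucleosomeTopology`
#' @param spec a [truncation_spec()]; the empty spec returns the model
#'   unchanged
#' @return the truncated `StructureModel`
#' @export
apply_truncation <- function(model, topo, spec = default_truncation_spec()) {
  stopifnot(inherits(spec, "TruncationSpec"))
  if (!length(spec)) return(model)
  a <- model$atoms
  drop <- rep(FALSE, nrow(a))
  for (h in names(spec)) {
    chains <- histone_chains(topo, histone = h)
    if (!length(chains)) stopf("no chains assigned to histone %s", h)
    resids <- integer()
    entry <- spec[[h]]
    if (!is.null(entry$n)) resids <- c(resids, seq(entry$n[1L], entry$n[2L]))
    if (!is.null(entry$c)) resids <- c(resids, seq(entry$c[1L], entry$c[2L]))
    for (ch in chains) {
      present <- unique(a$resid[a$chain == ch])
      missing <- setdiff(resids, present)
      # a range that is entirely absent is treated as already truncated
      # (making truncation idempotent); a partially absent range is a
      # numbering mismatch and an error
      if (length(missing) && length(missing) < length(resids))
        stopf("truncation range for %s chain %s names absent residues: %s",
              h, ch, paste(missing, collapse = ", "))
      drop <- drop | (a$chain == ch & a$resid %in% resids)
    }
  }
  structure_model(a[!drop, , drop = FALSE])
}

# ---- SHL segmentation -----------------------------------------------------

#' Segment nucleosomal DNA by superhelix location
#'
#' Splits the duplex into consecutive, non-overlapping one-turn segments at
#' the topology's SHL boundaries: the segments partition base pairs
#' `1..n_bp`, are symmetric about the dyad, and are labelled by the SHL
#' interval they span (e.g. `"SHL[0,+1]"`). A 147-bp nucleosomal duplex
#' segmented at every helical turn yields 14 segments.
#'
#' @param topo a `NucleosomeTopology`
#' @return data.frame with columns `label`, `start_bp`, `end_bp`
#' @export
segment_dna_by_shl <- function(topo) {
  b <- topo$shl_boundaries
  n <- topo$n_bp
  if (!length(b)) stopf("topology has no SHL boundaries")
  starts <- c(1L, b + 1L)
  ends <- c(b, n)
  if (any(starts > ends)) stopf("SHL boundaries do not cover the duplex")
  # SHL value at segment midpoints, relative to the dyad
  k <- length(starts)
  shl_lo <- round((starts - 0.5 - topo$dyad_bp) / topo$bp_per_turn)
  shl_hi <- shl_lo + 1L
  lab <- sprintf("SHL[%+d,%+d]", shl_lo, shl_hi)
  lab[shl_lo == 0L] <- sprintf("SHL[0,%+d]", shl_hi[shl_lo == 0L])
  lab[shl_hi == 0L] <- sprintf("SHL[%+d,0]", shl_lo[shl_hi == 0L])
  data.frame(label = lab, start_bp = starts, end_bp = ends,
             stringsAsFactors = FALSE)
}

#' Base-pair range between two superhelix locations
#'
#' Maps an SHL interval (in helical turns from the dyad, SHL 0) to a closed
#' base-pair range on strand I; e.g. `dna_segment_range(topo, 0, 1.5)` is
#' the segment between the dyad and SHL +1.5.
#'
#' @param topo a `NucleosomeTopology`
#' @param from,to SHL values (turns from the dyad; negative = 5' side)
#' @export
dna_segment_range <- function(topo, from, to) {
  if (from > to) { tmp <- from; from <- to; to <- tmp }
  lo <- max(1L, as.integer(round(topo$dyad_bp + from * topo$bp_per_turn)))
  hi <- min(topo$n_bp, as.integer(round(topo$dyad_bp + to * topo$bp_per_turn)))
  c(start_bp = lo, end_bp = hi)
}

#' Write SHL segments as TSV
#' @param topo a `NucleosomeTopology`
#' @param path output path
#' @export
write_shl_segments <- function(topo, path) {
  utils::write.table(segment_dna_by_shl(topo), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- topology config file -------------------------------------------------

#' Read or write a topology as a YAML config
#' @param path YAML file path
#' @export
read_topology <- function(path) {
  y <- yaml::read_yaml(path)
  nucleosome_topology(
    histone_assignments = do.call(rbind, lapply(y$histones, function(h)
      data.frame(chain = h$chain, histone = h$histone, copy = h$copy,
                 stringsAsFactors = FALSE))),
    tail_ranges = y$tails,
    domain_ranges = do.call(rbind, lapply(y$domains, function(d)
      data.frame(chain = d$chain, domain = d$domain, start = d$start,
                 end = d$end, stringsAsFactors = FALSE))),
    dna_chains = unlist(y$dna_chains),
    dyad_bp = y$dyad_bp,
    shl_boundaries = unlist(y$shl_boundaries),
    n_bp = y$n_bp,
    bp_per_turn = y$bp_per_turn %||% 10.5
  )
}

#' @rdname read_topology
#' @param topo a `NucleosomeTopology`
#' @export
write_topology <- function(topo, path) {
  ha <- topo$histone_assignments
  dr <- topo$domain_ranges
  y <- list(
    histones = lapply(seq_len(nrow(ha)), function(i)
      list(chain = ha$chain[i], histone = ha$histone[i], copy = ha$copy[i])),
    tails = topo$tail_ranges,
    domains = lapply(seq_len(nrow(dr)), function(i)
      list(chain = dr$chain[i], domain = dr$domain[i],
           start = dr$start[i], end = dr$end[i])),
    dna_chains = as.list(topo$dna_chains),
    dyad_bp = topo$dyad_bp,
    shl_boundaries = as.list(topo$shl_boundaries),
    n_bp = topo$n_bp,
    bp_per_turn = topo$bp_per_turn
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
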