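#' Structure model: atoms, residues, chains with coordinates
#'
#' A `StructureModel` is the package's in-memory representation of a PDB
#' model: an ordered atom table plus the ordered list of chain identifiers.
#' Atom order always matches file order; all downstream selections resolve
#' to deterministic, ordered atom index vectors on this table.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z`, `occupancy`, `bfactor`.
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(atoms) {
  need <- c("serial", "name", "element", "resname", "resid", "chain",
            "x", "y", "z", "occupancy", "bfactor")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atom table lacks columns: %s", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stopf("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    stopf("duplicate atom identity (chain, resid, name): %s",
          paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))], collapse = "; "))
  rownames(atoms) <- NULL
  obj <- list(atoms = atoms, chains = unique(atoms$chain))
  class(obj) <- "StructureModel"
  obj
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel: %d atoms, %d chains (%s), %d residues\n",
              nrow(x$atoms), length(x$chains), paste(x$chains, collapse = ","),
              nrow(unique(x$atoms[, c("chain", "resid")]))))
  invisible(x)
}

#' Number of atoms in a model
#' @param model a `StructureModel`
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Extract or replace the coordinate matrix of a model
#'
#' @param model a `StructureModel`
#' @return `coords()`: an `n_atoms x 3` matrix in Angstrom, file order.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' @rdname coords
#' @param value replacement `n_atoms x 3` coordinate matrix
#' @export
`coords<-` <- function(model, value) {
  value <- as.matrix(value)
  if (!identical(dim(value), c(n_atoms(model), 3L)) &&
      !(nrow(value) == n_atoms(model) && ncol(value) == 3L))
    stopf("replacement coordinates must be %d x 3", n_atoms(model))
  model$atoms$x <- value[, 1L]
  model$atoms$y <- value[, 2L]
  model$atoms$z <- value[, 3L]
  model
}

# sanity scan of ATOM/HETATM records before delegating to the parser, so a
# malformed record is reported with its line number
check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stopf("malformed PDB record at line %d (truncated): '%s'", i, ln)
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1L], fld[2L])))
      if (is.na(v))
        stopf("malformed PDB record at line %d (bad coordinate field): '%s'", i, ln)
    }
  }
  invisible(length(idx))
}

# convert a bio3d atom table (already altloc-resolved) to our atom table
bio3d_to_atoms <- function(at) {
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) el <- NA_character_
  el <- ifelse(is.na(el) | el == "", toupper(substr(gsub("[0-9']", "", at$elety), 1, 1)), trimws(el))
  data.frame(
    serial = at$eleno,
    name = at$elety,
    element = el,
    resname = at$resid,
    resid = at$resno,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE
  )
}

# keep the highest-occupancy conformer per (chain, resid, insert, name);
# zero-occupancy atoms are kept (nucleosome tails have occupancy zero in the
# crystal yet are physically present)
resolve_altloc <- function(at) {
  alt <- at$alt
  if (is.null(alt)) return(at)
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  key <- paste(at$chain, at$resno, at$insert %||% "", at$elety)
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(seq_len(nrow(at)))
  keep <- !logical(nrow(at))
  for (k in unique(key[duplicated(key)])) {
    rows <- which(key == k)
    best <- rows[which.max(occ[rows])]
    keep[setdiff(rows, best)] <- FALSE
  }
  at[keep, , drop = FALSE]
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (delegating to [bio3d::read.pdb()]), resolves
#' alternate locations by keeping the highest-occupancy conformer, and
#' returns atoms in file order. Malformed records are reported with their
#' line number; duplicate atom identities after altloc resolution are an
#' error.
#'
#' @param path path to a PDB file
#' @param hetatm keep HETATM records (default `TRUE`)
#' @return a [structure_model()] object
#' @export
read_structure <- function(path, hetatm = TRUE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  check_pdb_records(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (!hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- resolve_altloc(at)
  structure_model(bio3d_to_atoms(at))
}

#' Write a structure to a PDB file
#'
#' Coordinates are written at the PDB format's precision (3 decimals, A).
#'
#' @param model a `StructureModel`
#' @param path output path
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords(model))),
    type = rep("ATOM", nrow(a)),
    resno = a$resid, resid = a$resname,
    eleno = a$serial, elety = a$name,
    chain = a$chain, o = a$occupancy, b = a$bfactor,
    elesy = a$element
  )
  invisible(path)
}

#' Subset a model by atom indices (order preserved)
#' @param model a `StructureModel`
#' @param idx integer atom indices (1-based, in desired order)
#' @export
subset_model <- function(model, idx) {
  structure_model(model$atoms[idx, , drop = FALSE])
}

#' Count base-paired nucleotides per DNA strand
#'
#' Reports, for each of the two DNA chains, the number of nucleotide
#' residues, and the number of residue pairs under the given pairing
#' (default: position i on the first strand pairs with position n+1-i on
#' the second). Used to confirm that an ingested nucleosome core particle
#' carries 147 base-paired nucleotides per strand.
#'
#' @param model a `StructureModel`
#' @param dna_chains character vector of the two DNA chain ids
#' @return list with `per_strand` named counts and `n_pairs`
#' @export
count_basepairs <- function(model, dna_chains) {
  if (length(dna_chains) != 2L) stopf("need exactly two DNA chain ids")
  nt <- lapply(dna_chains, function(ch) {
    a <- model$atoms[model$atoms$chain == ch, , drop = FALSE]
    a <- a[grepl("^D?[ATGCU]$|^D[ATGC]$", a$resname), , drop = FALSE]
    unique(a$resid)
  })
  n <- vapply(nt, length, 1L)
  names(n) <- dna_chains
  list(per_strand = n, n_pairs = min(n))
}
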