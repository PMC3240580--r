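# conversion of 1 e/A Coulomb potential (Gaussian units, vacuum) to Volts:
# e / (4 pi eps0 * 1 A)
VOLT_PER_E_PER_ANGSTROM <- 14.399645

#' Smoothed long-range electrostatic potential grid
#'
#' Each point charge `q` (in e) contributes `q * erf(beta * r) / r` to the
#' potential — the long-range (reciprocal-space-equivalent) component of an
#' Ewald decomposition with smoothing factor `beta`, evaluated by direct
#' summation on a regular grid and converted to Volts assuming vacuum
#' permittivity. As `beta -> Inf` the kernel approaches the bare Coulomb
#' potential. Defaults mirror the smoothed-potential maps used for
#' nucleosome electrostatics: 1 A grid resolution and `beta = 0.25` 1/A.
#'
#' @param model a `StructureModel` (one frame)
#' @param charges numeric vector of per-atom charges (e), length
#'   `n_atoms`, or a [nonbonded_params()] table
#' @param spacing grid spacing, A (> 0)
#' @param beta Ewald smoothing factor, 1/A (> 0)
#' @param margin grid padding beyond the bounding box, A
#' @param sel selection of source atoms (default: all)
#' @return object of class `PotentialGrid`: `origin`, `spacing`, `dims`,
#'   `values` (3d array, Volts), `beta`
#' @export
potential_map <- function(model, charges, spacing = 1, beta = 0.25,
                          margin = 5, sel = select_all()) {
  if (spacing <= 0) stopf("grid spacing must be positive")
  if (beta <= 0) stopf("Ewald factor must be positive")
  idx <- resolve_selection(sel, model)
  if (inherits(charges, "NonbondedParams"))
    charges <- match_params(model, seq_len(n_atoms(model)), charges)$charge
  if (length(charges) != n_atoms(model))
    stopf("need one charge per atom (%d != %d)", length(charges), n_atoms(model))
  xyz <- coords(model)[idx, , drop = FALSE]
  q <- charges[idx]
  lo <- apply(xyz, 2L, min) - margin
  hi <- apply(xyz, 2L, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  gx <- lo[1L] + (seq_len(dims[1L]) - 1L) * spacing
  gy <- lo[2L] + (seq_len(dims[2L]) - 1L) * spacing
  gz <- lo[3L] + (seq_len(dims[3L]) - 1L) * spacing
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  vals <- numeric(nrow(grid))
  nz <- which(q != 0)
  for (k in nz) {
    r <- sqrt(rowSums(sweep(grid, 2L, xyz[k, ])^2))
    contrib <- ifelse(r < 1e-9, 2 * beta / sqrt(pi), erf(beta * r) / r)
    vals <- vals + q[k] * contrib
  }
  obj <- list(origin = lo, spacing = spacing, dims = dims,
              values = array(vals * VOLT_PER_E_PER_ANGSTROM, dim = dims),
              beta = beta)
  class(obj) <- "PotentialGrid"
  obj
}

#' @export
print.PotentialGrid <- function(x, ...) {
  cat(sprintf("PotentialGrid: %d x %d x %d points, %.2f A spacing, beta %.3g 1/A, range [%.3g, %.3g] V\n",
              x$dims[1L], x$dims[2L], x$dims[3L], x$spacing, x$beta,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Interpolate (nearest-node) grid value at a point
#' @param grid a `PotentialGrid`
#' @param point 3-vector, A
#' @export
grid_value_at <- function(grid, point) {
  ijk <- round((point - grid$origin) / grid$spacing) + 1
  ijk <- pmin(pmax(ijk, 1), grid$dims)
  grid$values[ijk[1L], ijk[2L], ijk[3L]]
}

#' Write a potential grid in OpenDX scalar-field format
#' @param grid a `PotentialGrid`
#' @param path output path
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1L], d[2L], d[3L]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1L], grid$origin[2L], grid$origin[3L]),
    sprintf("delta %.6f 0 0", grid$spacing),
    sprintf("delta 0 %.6f 0", grid$spacing),
    sprintf("delta 0 0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1L], d[2L], d[3L]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(d))
  ), con)
  # DX order: z fastest
  v <- aperm(grid$values, c(3L, 2L, 1L))
  vals <- as.vector(v)
  pad <- (-length(vals)) %% 3L
  if (pad) vals <- c(vals, rep(NA_real_, pad))
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "potential (V)" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
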