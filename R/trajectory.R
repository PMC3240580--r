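#' Trajectory: ordered frames over a fixed topology
#'
#' @param topology a `StructureModel` defining atom identities and order
#' @param frames list of `n_atoms x 3` coordinate matrices, Angstrom
#' @param times frame times in ns, strictly increasing; default `0, 1, ...`
#' @return an object of class `Trajectory`
#' @export
trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "StructureModel"))
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || nrow(f) != na || ncol(f) != 3L)
      stopf("frame %d has %s atoms; topology has %d", i,
            if (is.matrix(f)) nrow(f) else "malformed", na)
  }
  times <- times %||% as.numeric(seq_along(frames) - 1L)
  if (length(times) != length(frames))
    stopf("times length (%d) != number of frames (%d)", length(times), length(frames))
  if (length(times) > 1L && any(diff(times) <= 0))
    stopf("frame times must be strictly increasing")
  obj <- list(topology = topology, frames = frames, times = as.numeric(times))
  class(obj) <- "Trajectory"
  obj
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.3g..%.3g ns\n",
              n_frames(x), n_atoms(x$topology),
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame as a StructureModel
#' @param traj a `Trajectory`
#' @param i frame index
#' @export
model_frame <- function(traj, i) {
  m <- traj$topology
  coords(m) <- traj$frames[[i]]
  m
}

#' Read a trajectory
#'
#' Two on-disk dialects are supported:
#' * multi-model PDB (`MODEL`/`ENDMDL` blocks), and
#' * a plain-text per-frame coordinate table with a header line
#'   `frame time x y z` and `n_atoms` rows per frame in topology atom order.
#'
#' @param path file path (`.pdb` or coordinate table)
#' @param topology `StructureModel` the frames must match; required for the
#'   table dialect, and used for consistency checking for PDB
#' @param times optional frame times (ns) overriding file content
#' @param format `"auto"`, `"pdb"` or `"table"`
#' @return a [trajectory()]
#' @export
read_trajectory <- function(path, topology, times = NULL, format = "auto") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "table"
  if (format == "pdb") {
    check_pdb_records(path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    na_file <- ncol(xyz) / 3L
    if (!missing(topology) && !is.null(topology)) {
      if (na_file != n_atoms(topology))
        stopf("frame 1 has %d atoms; topology has %d", na_file, n_atoms(topology))
    } else {
      topology <- structure_model(bio3d_to_atoms(resolve_altloc(pdb$atom)))
    }
    frames <- lapply(seq_len(nrow(xyz)), function(i)
      matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  } else {
    tab <- utils::read.table(path, header = TRUE)
    need <- c("frame", "time", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stopf("coordinate table must have columns: %s", paste(need, collapse = ", "))
    na <- n_atoms(topology)
    ids <- unique(tab$frame)
    frames <- vector("list", length(ids))
    ftimes <- numeric(length(ids))
    for (k in seq_along(ids)) {
      rows <- tab[tab$frame == ids[k], , drop = FALSE]
      if (nrow(rows) != na)
        stopf("frame %d has %d atoms; topology has %d", k, nrow(rows), na)
      frames[[k]] <- as.matrix(rows[, c("x", "y", "z")])
      ftimes[k] <- rows$time[1L]
    }
    if (is.null(times)) times <- ftimes
  }
  trajectory(topology, frames, times = times)
}

#' Write a trajectory
#'
#' @param traj a `Trajectory`
#' @param path output path
#' @param format `"pdb"` (multi-model) or `"table"` (plain-text table, see
#'   [read_trajectory()])
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "table")) {
  format <- match.arg(format)
  if (format == "pdb") {
    a <- traj$topology$atoms
    xyz <- do.call(rbind, lapply(traj$frames, function(f) as.vector(t(f))))
    bio3d::write.pdb(
      file = path, xyz = xyz,
      type = rep("ATOM", nrow(a)),
      resno = a$resid, resid = a$resname,
      eleno = a$serial, elety = a$name,
      chain = a$chain, o = a$occupancy, b = a$bfactor,
      elesy = a$element
    )
  } else {
    na <- n_atoms(traj$topology)
    tab <- data.frame(
      frame = rep(seq_len(n_frames(traj)), each = na),
      time = rep(traj$times, each = na),
      x = unlist(lapply(traj$frames, function(f) f[, 1L])),
      y = unlist(lapply(traj$frames, function(f) f[, 2L])),
      z = unlist(lapply(traj$frames, function(f) f[, 3L]))
    )
    utils::write.table(format(tab, digits = 10), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Restrict a trajectory to a window of frames
#' @param traj a `Trajectory`
#' @param window integer frame indices (contiguous)
#' @export
trajectory_window <- function(traj, window) {
  trajectory(traj$topology, traj$frames[window], times = traj$times[window])
}
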