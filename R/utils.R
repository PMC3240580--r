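# internal geometry / misc helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  a / n
}

# angle between two vectors, degrees in [0, 180]
vangle <- function(a, b) {
  ca <- sum(vunit(a) * vunit(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap degrees into (-180, 180]
wrap180 <- function(x) {
  y <- ((x + 180) %% 360) - 180
  ifelse(y == -180, 180, y)
}

# rotation matrix about an arbitrary unit axis, angle in degrees
rotation_about <- function(axis, angle_deg) {
  u <- vunit(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

# error function in terms of the normal CDF
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# run code with a private, restored RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# pairwise squared distances between rows of two matrices
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A * A)
  b2 <- rowSums(B * B)
  outer(a2, b2, "+") - 2 * tcrossprod(A, B)
}
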