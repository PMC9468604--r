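#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired point sets, suppressing reflections. The returned transform maps
#' `coords_a` onto `coords_b`: `coords_a %*% rotation + translation`.
#'
#' Point sets with fewer than three points, or collinear sets, do not pin
#' down the rotation uniquely (rotation about the common axis is free); the
#' minimized RMSD is still well defined and is returned with a warning.
#'
#' @param coords_a,coords_b numeric matrices (n x 3), equal row counts, in
#'   Angstrom.
#' @return list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3) and `rmsd` (Angstrom).
#' @export
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' kabsch_superpose(a, a)$rmsd  # 0
kabsch_superpose <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b)) abort("point sets must have equal sizes")
  if (ncol(a) != 3 || ncol(b) != 3) abort("coordinates must be n x 3")
  n <- nrow(a)
  if (n < 2) abort("insufficient points: superposition needs at least 2")
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  h <- crossprod(a0, b0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  degenerate <- n < 3 || s$d[2] < 1e-10 * max(s$d[1], 1e-300)
  if (degenerate) {
    warn("degenerate point set (collinear or < 3 points): rotation not unique; reflection suppressed")
  }
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rot <- t(rot) # so that a %*% rotation maps onto b
  fitted <- a0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  list(
    rotation = rot,
    translation = as.numeric(cb - ca %*% rot),
    rmsd = rmsd
  )
}

rmsd_of <- function(a, b) kabsch_superpose(a, b)$rmsd
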