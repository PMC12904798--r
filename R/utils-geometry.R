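#' Rigid-body superposition (Kabsch algorithm)
#'
#' Computes the rotation and translation minimising the RMSD between two
#' paired coordinate sets, via singular value decomposition with a
#' determinant correction that excludes reflections.
#'
#' @param x,y numeric matrices (n x 3); `y` is superposed onto `x`.
#' @return list with `R` (3x3 rotation), `t` (translation), `rmsd`, and
#'   `transform(m)` applying the fit to an arbitrary n x 3 matrix.
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' th <- 0.7; rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' fit <- kabsch(x, x %*% t(rot))
#' stopifnot(fit$rmsd < 1e-8)
#' @export
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3, ncol(y) == 3, nrow(x) >= 1)
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2, cx)
  y0 <- sweep(y, 2, cy)
  s <- svd(crossprod(y0, x0))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  yr <- y0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((yr - x0)^2)))
  trans <- function(m) sweep(sweep(m, 2, cy) %*% t(rot), 2, cx, `+`)
  list(R = rot, t = cx - as.numeric(rot %*% cy), rmsd = rmsd, transform = trans)
}

#' Root-mean-square deviation of paired coordinates without superposition
#' @param x,y n x 3 matrices.
#' @return RMSD in the input units.
#' @export
rmsd_nofit <- function(x, y) {
  stopifnot(nrow(x) == nrow(y))
  sqrt(mean(rowSums((x - y)^2)))
}

# All pairwise Euclidean distances between rows of a and rows of b.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  k <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

# Enumerate all permutations of seq_len(n) as a matrix (n! rows). n <= 9.
all_permutations <- function(n) {
  stopifnot(n >= 0, n <= 9)
  if (n == 0) return(matrix(integer(), 1, 0))
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }
  do.call(rbind, out)
}

# Enumerate injective assignments of k items into n slots: rows are
# choose(n,k)*k! orderings (as columns of target indices).
all_injections <- function(k, n) {
  stopifnot(k <= n)
  if (k == 0) return(matrix(integer(), 1, 0))
  combs <- utils::combn(n, k)
  perms <- all_permutations(k)
  out <- vector("list", ncol(combs))
  for (i in seq_len(ncol(combs))) {
    cc <- combs[, i]
    out[[i]] <- matrix(cc[perms], nrow(perms))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
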