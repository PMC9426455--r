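#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' point sets in 1:1 correspondence (implied by row order), via SVD of the
#' cross-covariance matrix with the usual determinant correction so that no
#' reflection is ever returned.
#'
#' The returned transform maps `points_b` onto `points_a`:
#' `transformed_b = points_b %*% rotation + translation` (row vectors).
#'
#' @param points_a,points_b n x 3 numeric matrices, n >= 3, equal n.
#' @return A `superposition_result`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom), `n` (number of pairs) and
#'   `degenerate` (TRUE when the points are collinear or coincident, in
#'   which case the minimiser is still returned but is not unique).
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' kabsch(a, a)$rmsd  # 0
#' @export
kabsch <- function(points_a, points_b) {
  A <- as.matrix(points_a)
  B <- as.matrix(points_b)
  if (ncol(A) != 3 || ncol(B) != 3) stop("point sets must be n x 3")
  if (nrow(A) != nrow(B)) stop("point sets differ in length")
  if (nrow(A) < 3) stop("need at least 3 corresponded points")
  if (any(!is.finite(A)) || any(!is.finite(B))) stop("non-finite coordinates")
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  H <- crossprod(B0, A0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  # degenerate when centered sets span < 2 dimensions
  degenerate <- {
    sa <- svd(A0, nu = 0, nv = 0)$d
    sb <- svd(B0, nu = 0, nv = 0)$d
    (sa[2] <= 1e-9 * max(sa[1], 1)) || (sb[2] <= 1e-9 * max(sb[1], 1))
  }
  diff <- A0 - B0 %*% R
  rmsd <- sqrt(max(sum(diff^2) / nrow(A), 0))
  structure(
    list(rotation = R, translation = as.numeric(ca - cb %*% R),
         rmsd = rmsd, n = nrow(A), degenerate = degenerate),
    class = "superposition_result"
  )
}

#' @export
print.superposition_result <- function(x, ...) {
  cat("<superposition_result> rmsd =", format(x$rmsd, digits = 6),
      "A over", x$n, "pairs",
      if (isTRUE(x$degenerate)) "(degenerate point set)" else "", "\n")
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param fit A `superposition_result`.
#' @param xyz n x 3 coordinate matrix (the "B" frame of [kabsch()]).
#' @return Transformed n x 3 matrix in the "A" frame.
#' @export
apply_transform <- function(fit, xyz) {
  sweep(as.matrix(xyz) %*% fit$rotation, 2, fit$translation, "+")
}
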