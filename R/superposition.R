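#' Optimal rigid superposition of paired point sets
#'
#' Least-squares (Kabsch) superposition: finds the proper rotation and
#' translation minimizing the RMSD between `moving` (transformed) and
#' `fixed`.  The SVD reflection branch is corrected so the returned rotation
#' always has determinant +1; degenerate configurations (all points
#' collinear or coincident), for which the optimal rotation is not unique,
#' raise an error rather than returning an arbitrary frame.
#'
#' The transform acts on row-vector coordinates as
#' `transformed = coords %*% t(rotation) + translation` (see
#' [apply_transform()]).
#'
#' @param moving,fixed Numeric matrices (n x 3) of paired coordinates in
#'   identical row order; n >= 3.
#'
#' @return An object of class `superposition_result`: a list with elements
#'   `transform` (list of `rotation`, a 3x3 proper-orthogonal matrix, and
#'   `translation`, a length-3 vector), `rmsd` (Angstrom) and `n_points`.
#' @export
#' @examples
#' set.seed(1)
#' p <- matrix(rnorm(30), ncol = 3)
#' kabsch_superpose(p + 5, p)$rmsd  # pure translation is removed exactly
kabsch_superpose <- function(moving, fixed) {
  moving <- as_coord_matrix(moving, "moving")
  fixed <- as_coord_matrix(fixed, "fixed")
  if (nrow(moving) != nrow(fixed)) {
    abort("point sets differ in length", class = "fpair_validation_error")
  }
  n <- nrow(moving)
  if (n < 3) {
    abort("superposition requires at least 3 paired points",
          class = "fpair_validation_error")
  }

  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  p <- sweep(moving, 2, cm)
  q <- sweep(fixed, 2, cf)

  h <- crossprod(p, q)                       # 3x3 covariance
  s <- svd(h)
  if (s$d[2] <= max(s$d[1] * 1e-8, 1e-12)) {
    abort("degenerate geometry: points are collinear or coincident",
          class = "fpair_degenerate_error")
  }
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(cf - rot %*% cm)

  delta <- p %*% t(rot) - q
  rmsd <- sqrt(mean(rowSums(delta^2)))

  structure(
    list(transform = list(rotation = rot, translation = trans),
         rmsd = rmsd, n_points = n),
    class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat("<superposition_result> rmsd =", format(x$rmsd, digits = 6),
      "A over", x$n_points, "points\n")
  invisible(x)
}

#' RMSD between paired points without fitting
#'
#' Root-mean-square deviation over paired points with no superposition
#' applied — used where the fitting frame and the measurement set differ.
#'
#' @param a,b Numeric matrices (n x 3), identical row order, n >= 1.
#' @return RMSD in Angstrom.
#' @export
#' @examples
#' rmsd_no_fit(matrix(0, 1, 3), matrix(c(2, 0, 0), 1, 3))  # 2
rmsd_no_fit <- function(a, b) {
  a <- as_coord_matrix(a, "a")
  b <- as_coord_matrix(b, "b")
  if (nrow(a) != nrow(b)) {
    abort("point sets differ in length", class = "fpair_validation_error")
  }
  if (nrow(a) == 0) {
    abort("empty point sets", class = "fpair_validation_error")
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Apply a rigid transform to coordinates
#'
#' @param coords Numeric matrix (n x 3) of row-vector coordinates.
#' @param transform A transform as returned in
#'   `kabsch_superpose()$transform`: list with `rotation` and `translation`.
#' @return Transformed coordinate matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords <- as_coord_matrix(coords, "coords")
  sweep(coords %*% t(transform$rotation), 2, transform$translation, "+")
}

as_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) {
    abort(paste0(what, " must be an n x 3 coordinate matrix"),
          class = "fpair_validation_error")
  }
  if (nrow(x) > 0 && !all(is.finite(x))) {
    abort(paste0(what, " contains non-finite coordinates"),
          class = "fpair_validation_error")
  }
  storage.mode(x) <- "double"
  x
}

# Rotation matrix about a (not necessarily unit) axis by angle in degrees.
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  k <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

# Rotation by a given angle (degrees) about an isotropically random axis.
random_rotation <- function(angle_deg) {
  axis <- rnorm(3)
  while (sum(axis^2) < 1e-12) axis <- rnorm(3)
  rotation_about_axis(axis, angle_deg)
}
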