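#' Root-mean-square deviation between two coordinate sets
#'
#' Plain coordinate RMSD with no fitting; both matrices must have identical
#' atom correspondence.
#'
#' @param a,b n x 3 coordinate matrices (Angstrom).
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in shape")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD of
#' `mobile[fit_selection, ]` onto `reference[fit_selection, ]` and applies it
#' to ALL mobile atoms. Reflections are excluded (determinant forced to +1).
#'
#' @param mobile_coords,reference_coords n x 3 matrices with identical atom
#'   correspondence.
#' @param fit_selection 1-based indices of the atoms used for the fit
#'   (default: all atoms).
#' @return list with `coords` (transformed mobile set), `rmsd` (Angstrom,
#'   over the fit atoms), `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% R + t`).
#' @export
superpose <- function(mobile_coords, reference_coords, fit_selection = NULL) {
  mobile_coords <- as.matrix(mobile_coords)
  reference_coords <- as.matrix(reference_coords)
  if (is.null(fit_selection)) fit_selection <- seq_len(nrow(mobile_coords))
  fit_selection <- as.integer(fit_selection)
  if (length(fit_selection) < 3L) {
    stop("superposition needs at least 3 fit atoms, got ", length(fit_selection))
  }
  m <- mobile_coords[fit_selection, , drop = FALSE]
  r <- reference_coords[fit_selection, , drop = FALSE]
  if (nrow(m) != nrow(r)) stop("fit sets differ in atom count")
  mc <- colMeans(m)
  rc <- colMeans(r)
  m0 <- sweep(m, 2, mc)
  r0 <- sweep(r, 2, rc)
  # collinearity check: rank of the centered fit set
  sv_fit <- svd(m0)$d
  if (sv_fit[2] < 1e-8 * max(sv_fit[1], 1e-12)) {
    warning("fit atoms are (nearly) collinear; rotation about the axis is underdetermined")
  }
  h <- t(m0) %*% r0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot <- t(rot)  # so that row-vector convention x %*% rot applies
  trans <- rc - mc %*% rot
  out <- sweep(mobile_coords %*% rot, 2, -as.numeric(trans))
  fitted <- out[fit_selection, , drop = FALSE]
  list(coords = out,
       rmsd = coord_rmsd(fitted, r),
       rotation = rot,
       translation = as.numeric(trans))
}

# Rotation matrix (row-vector convention) taking unit vector `a` to `b` by
# the minimal rotation about a x b (Rodrigues). Stable for a == -b.
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s2 <- sum(v^2)
  if (s2 < 1e-16) {
    if (c_ > 0) return(diag(3))
    # 180 degrees: rotate about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(t(2 * outer(ax, ax) - diag(3)))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  rot <- diag(3) + vx + vx %*% vx * ((1 - c_) / s2)
  t(rot)
}
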