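#' Rigid 3D transform
#'
#' A rotation (Euler angles, radians) about a fixed centre followed by a
#' translation: \code{T(p) = R (p - c) + c + t} with
#' \code{R = Rz(rz) Ry(ry) Rx(rx)}.
#'
#' @param rotation length-3 numeric, Euler angles (rx, ry, rz) in radians.
#' @param translation length-3 numeric, mm.
#' @param center length-3 numeric, rotation centre in mm.
#' @return a \code{rigid_transform} object.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0),
                            translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3,
            length(center) == 3)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot (deg): %s | trans (mm): %s | centre: %s\n",
    paste(signif(x$rotation * 180 / pi, 4), collapse = ", "),
    paste(signif(x$translation, 4), collapse = ", "),
    paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

# Euler angles (rx, ry, rz) from R = Rz Ry Rx; valid away from gimbal lock,
# which cannot occur for the small patient-repositioning angles handled here.
euler_from_matrix <- function(R) {
  ry <- asin(-R[3, 1])
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  c(rx, ry, rz)
}

#' Apply a rigid transform to points
#'
#' @param transform a \code{\link{rigid_transform}}.
#' @param points n x 3 matrix (or length-3 vector) of physical mm points.
#' @return n x 3 matrix of mapped points.
#' @export
transform_points <- function(transform, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  R <- rotation_matrix(transform$rotation)
  t(R %*% (t(p) - transform$center) + transform$center +
      transform$translation)
}

#' Invert a rigid transform
#'
#' @param transform a \code{\link{rigid_transform}}.
#' @return the inverse \code{rigid_transform} (same centre).
#' @export
transform_inverse <- function(transform) {
  R <- rotation_matrix(transform$rotation)
  Rinv <- t(R)
  rigid_transform(rotation = euler_from_matrix(Rinv),
                  translation = as.numeric(-Rinv %*% transform$translation),
                  center = transform$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{b} first, then
#' \code{a} (i.e. \code{T(p) = a(b(p))}), expressed about \code{a}'s
#' centre.
#'
#' @param a,b \code{rigid_transform} objects.
#' @return a \code{rigid_transform}.
#' @export
transform_compose <- function(a, b) {
  Ra <- rotation_matrix(a$rotation)
  Rb <- rotation_matrix(b$rotation)
  R <- Ra %*% Rb
  # a(b(p)) = R p + [Ra (Rb'...)]: expand both affine forms
  ta <- -Ra %*% a$center + a$center + a$translation
  tb <- -Rb %*% b$center + b$center + b$translation
  t_full <- as.numeric(Ra %*% tb + ta)       # full affine offset of T
  c0 <- a$center
  rigid_transform(rotation = euler_from_matrix(R),
                  translation = as.numeric(t_full - c0 + R %*% c0),
                  center = c0)
}
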