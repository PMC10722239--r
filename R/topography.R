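#' Medoid of a terminal point set
#'
#' The member point minimizing the sum of Euclidean distances to all members;
#' ties are broken by lowest index. The medoid (unlike the centroid) is an
#' actual observed target location even when the terminals fall in separated
#' termination domains.
#'
#' @param points Non-empty n x 3 matrix of terminal points (um).
#' @return Length-3 numeric vector (a member of \code{points}).
#' @export
terminal_medoid <- function(points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3L) else as.matrix(points)
  if (!nrow(p)) stop("empty point set has no medoid", call. = FALSE)
  if (nrow(p) == 1L) return(as.numeric(p[1L, ]))
  s <- rowSums(as.matrix(dist(p)))
  as.numeric(p[which.min(s), ])
}

#' Polar decomposition of a linear map
#'
#' Factors \code{A = R S} with \code{R} the closest proper rotation
#' (reflections corrected through the SVD determinant fix) and \code{S}
#' symmetric.
#'
#' @param A 3 x 3 matrix.
#' @return List with \code{R} (rotation, det +1) and \code{S} (symmetric
#'   stretch).
#' @export
polar_decompose <- function(A) {
  sv <- svd(A)
  C <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% C %*% t(sv$v)
  list(R = R, S = sv$v %*% C %*% diag(sv$d) %*% t(sv$v))
}

.axis_rot <- function(axis, theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  R <- diag(3)
  idx <- setdiff(1:3, axis)
  R[idx[1L], idx[1L]] <- c_; R[idx[2L], idx[2L]] <- c_
  if (axis == 2L) { R[idx[1L], idx[2L]] <- s_; R[idx[2L], idx[1L]] <- -s_ }
  else { R[idx[1L], idx[2L]] <- -s_; R[idx[2L], idx[1L]] <- s_ }
  R
}

.parse_order <- function(order) {
  ax <- match(strsplit(tolower(order), "")[[1L]], c("x", "y", "z"))
  if (length(ax) != 3L || anyNA(ax) || length(unique(ax)) != 3L)
    stop("convention must name three distinct axes, e.g. 'xyz'", call. = FALSE)
  ax
}

#' Compose a rotation from Euler angles
#'
#' @param angles_deg Three angles in degrees, one per axis of \code{order}.
#' @param order Axis order, e.g. \code{"xyz"} (Tait-Bryan, distinct axes).
#' @param intrinsic If FALSE (default), angles are extrinsic (applied about
#'   the fixed world axes in the given order); if TRUE, intrinsic.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_from_euler <- function(angles_deg, order = "xyz", intrinsic = FALSE) {
  ax <- .parse_order(order)
  th <- angles_deg * pi / 180
  mats <- Map(.axis_rot, ax, th)
  if (intrinsic) Reduce(`%*%`, mats)          # R = R1 R2 R3
  else Reduce(`%*%`, rev(mats))               # R = R3 R2 R1
}

#' Extract Euler angles from a rotation matrix
#'
#' Inverse of \code{\link{rotation_from_euler}} for any Tait-Bryan axis
#' order. Near gimbal lock the third angle is set to zero and the result is
#' flagged with the \code{"gimbal_lock"} attribute.
#'
#' @param R Proper 3 x 3 rotation matrix.
#' @param order Axis order, e.g. \code{"xyz"}.
#' @param intrinsic Extrinsic (default) or intrinsic convention.
#' @return Numeric vector of three angles in degrees.
#' @export
euler_from_rotation <- function(R, order = "xyz", intrinsic = FALSE) {
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6 || det(R) < 0)
    stop("input is not a proper rotation matrix", call. = FALSE)
  if (!intrinsic) {
    # extrinsic i-j-k == intrinsic k-j-i with angles reversed
    ang <- euler_from_rotation(R, order = paste(rev(strsplit(order, "")[[1L]]),
                                                collapse = ""),
                               intrinsic = TRUE)
    out <- rev(as.numeric(ang))
    attributes(out) <- attributes(ang)["gimbal_lock"]
    names(out) <- NULL
    attr(out, "gimbal_lock") <- attr(ang, "gimbal_lock")
    return(out)
  }
  ax <- .parse_order(order)
  i <- ax[1L]; j <- ax[2L]; k <- ax[3L]
  eps <- if (((i %% 3L) + 1L) == j) 1 else -1   # permutation parity
  s2 <- eps * R[i, k]
  lock <- abs(s2) > 1 - 1e-9
  th2 <- asin(pmin(1, pmax(-1, s2)))
  if (!lock) {
    th1 <- atan2(-eps * R[j, k], R[k, k])
    th3 <- atan2(-eps * R[i, j], R[i, i])
  } else {
    th3 <- 0
    th1 <- atan2(eps * R[j, i], R[j, j])
  }
  out <- c(th1, th2, th3) * 180 / pi
  attr(out, "gimbal_lock") <- lock
  out
}

#' Least-squares soma-to-terminal topography fit
#'
#' Fits the affine map from soma positions to the medoids of each neuron's
#' axonal terminals by ordinary least squares (homogeneous augmentation),
#' extracts the rotation from the 3 x 3 linear part by polar decomposition
#' and reports its Euler angles. The default fit unit is 10-um voxels.
#'
#' @param somata n x 3 soma positions (PIR um), n >= 4 and not degenerate.
#' @param medoids n x 3 terminal medoids (PIR um).
#' @param unit \code{"voxel"} (coordinates divided by \code{voxel_size_um})
#'   or \code{"um"}; the MSE is reported in the squared fit unit.
#' @param voxel_size_um Voxel edge used when \code{unit = "voxel"}.
#' @param order,intrinsic Euler convention (see
#'   \code{\link{euler_from_rotation}}).
#' @return An object of class \code{topography_fit}: \code{linear} (3 x 3),
#'   \code{translation}, \code{rotation}, \code{stretch},
#'   \code{euler_deg}, \code{mse}, \code{unit}, \code{medoids}.
#' @export
fit_topography <- function(somata, medoids, unit = c("voxel", "um"),
                           voxel_size_um = 10, order = "xyz",
                           intrinsic = FALSE) {
  unit <- match.arg(unit)
  S <- as.matrix(somata); M <- as.matrix(medoids)
  stopifnot(ncol(S) == 3L, ncol(M) == 3L, nrow(S) == nrow(M))
  if (nrow(S) < 4L)
    stop("fit error: at least 4 soma/medoid pairs are required", call. = FALSE)
  scl <- if (unit == "voxel") voxel_size_um else 1
  S <- S / scl; M <- M / scl
  X <- cbind(1, S)
  qx <- qr(X)
  if (qx$rank < 4L)
    stop("fit error: rank-deficient soma configuration (coplanar/collinear)",
         call. = FALSE)
  B <- qr.coef(qx, M)                 # 4 x 3: intercept + linear rows
  A <- t(B[2:4, , drop = FALSE])      # medoid ~ A %*% soma + t
  translation <- as.numeric(B[1L, ])
  pd <- polar_decompose(A)
  res <- M - X %*% B
  structure(list(linear = A, translation = translation,
                 rotation = pd$R, stretch = pd$S,
                 euler_deg = euler_from_rotation(pd$R, order = order,
                                                 intrinsic = intrinsic),
                 euler_order = order, euler_intrinsic = intrinsic,
                 mse = mean(rowSums(res^2)),
                 unit = unit, voxel_size_um = voxel_size_um,
                 n = nrow(S), medoids = M * scl),
            class = "topography_fit")
}

#' @export
print.topography_fit <- function(x, ...) {
  cat(sprintf("<topography_fit> n = %d (%s units)\n", x$n, x$unit))
  cat(sprintf("  Euler %s angles (deg): %.1f, %.1f, %.1f%s\n",
              toupper(x$euler_order), x$euler_deg[1L], x$euler_deg[2L],
              x$euler_deg[3L],
              if (isTRUE(attr(x$euler_deg, "gimbal_lock"))) " [gimbal lock]"
              else ""))
  cat(sprintf("  fit MSE: %.4g (squared %s)\n", x$mse,
              if (x$unit == "voxel") sprintf("%g-um voxels", x$voxel_size_um)
              else "um"))
  invisible(x)
}

#' Export a topography fit as JSON
#'
#' @param fit A \code{topography_fit}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_topography <- function(fit, path) {
  jsonlite::write_json(list(
    linear = fit$linear, translation = fit$translation,
    rotation = fit$rotation, euler_deg = as.numeric(fit$euler_deg),
    euler_order = fit$euler_order, euler_intrinsic = fit$euler_intrinsic,
    mse = fit$mse, unit = fit$unit, voxel_size_um = fit$voxel_size_um,
    n = fit$n), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
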