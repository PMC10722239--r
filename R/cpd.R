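#' Configuration for rotation-only rigid CPD
#'
#' @param max_iter EM iteration cap (default 60).
#' @param tol Absolute change in the negative log-likelihood below which the
#'   EM stops (default 0.001).
#' @param w Uniform-outlier weight in [0, 1) (default 0).
#' @param max_points Optional subsample cap per cloud; larger clouds are
#'   subsampled without replacement, reproducibly via \code{seed}.
#' @param seed Seed for subsampling.
#' @param soft_mse If TRUE, the reported MSE weights squared distances by the
#'   posterior responsibilities instead of hard argmax correspondences.
#' @return An object of class \code{cpd_config}.
#' @export
cpd_config <- function(max_iter = 60, tol = 0.001, w = 0, max_points = NULL,
                       seed = 0L, soft_mse = FALSE) {
  stopifnot(max_iter >= 1, tol > 0, w >= 0, w < 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol, w = w,
                 max_points = max_points, seed = as.integer(seed),
                 soft_mse = soft_mse),
            class = "cpd_config")
}

.check_cloud <- function(p, what) {
  p <- as.matrix(p)
  if (ncol(p) != 3L || nrow(p) < 3L)
    stop("alignment error: ", what, " cloud needs at least 3 points in 3-D",
         call. = FALSE)
  if (!all(is.finite(p))) stop("alignment error: non-finite coordinates in ",
                               what, " cloud", call. = FALSE)
  sv <- svd(sweep(p, 2L, colMeans(p)), nu = 0, nv = 0)$d
  if (sum(sv > max(sv) * 1e-9) < 2L)
    stop("alignment error: ", what, " cloud is degenerate (rank < 2)",
         call. = FALSE)
  p
}

.maybe_subsample <- function(p, cfg) {
  if (is.null(cfg$max_points) || nrow(p) <= cfg$max_points) return(p)
  idx <- with_seed(cfg$seed, sample.int(nrow(p), cfg$max_points))
  p[sort(idx), , drop = FALSE]
}

#' CPD E-step responsibilities
#'
#' Posterior probability that each moving-cloud point (Gaussian mixture
#' centroid, after applying \code{rotation}) generated each reference point,
#' including the uniform outlier component weighted by \code{w}.
#'
#' @param moving M x 3 moving cloud (mixture centroids).
#' @param reference N x 3 reference cloud (data).
#' @param sigma2 Gaussian variance (um^2).
#' @param rotation 3 x 3 rotation applied to the moving cloud.
#' @param w Outlier weight in [0, 1).
#' @return M x N matrix of responsibilities; columns sum to at most 1
#'   (exactly 1 when \code{w = 0}).
#' @export
cpd_estep <- function(moving, reference, sigma2, rotation = diag(3), w = 0) {
  stopifnot(sigma2 > 0)
  .cpd_estep_core(as.matrix(reference),
                  as.matrix(moving) %*% t(rotation), sigma2, w)
}

#' Rotation-only rigid CPD registration
#'
#' Registers a soma-centered moving point cloud to a soma-centered reference
#' cloud by expectation-maximization over a Gaussian mixture whose centroids
#' are the moving points, with scale fixed at 1 and translation fixed at 0.
#' The M-step obtains the rotation from the SVD of the posterior-weighted
#' cross-covariance with a determinant correction (proper rotations only);
#' the variance follows the standard rigid update. Iteration stops when the
#' absolute change of the negative log-likelihood falls below \code{tol} or
#' after \code{max_iter} iterations.
#'
#' @param moving M x 3 soma-centered cloud to be rotated.
#' @param reference N x 3 soma-centered cloud to register against.
#' @param cfg A \code{\link{cpd_config}}.
#' @return An object of class \code{cpd_result}: \code{rotation} (3 x 3,
#'   det +1), \code{sigma2}, \code{n_iter}, \code{converged_by},
#'   \code{nll} (objective trace), \code{correspondence} (per moving point,
#'   the argmax-responsibility reference index) and \code{mse} (mean squared
#'   distance between rotated moving points and their correspondents, um^2).
#' @export
cpd_rigid_rotation <- function(moving, reference, cfg = cpd_config()) {
  X <- .check_cloud(reference, "reference")
  Y <- .check_cloud(moving, "moving")
  X <- .maybe_subsample(X, cfg)
  Y <- .maybe_subsample(Y, cfg)
  res <- .cpd_core(X, Y, cfg$max_iter, cfg$tol, cfg$w)
  if (cfg$soft_mse) {
    P <- .cpd_estep_core(X, Y %*% t(res$rotation), res$sigma2, cfg$w)
    Yr <- Y %*% t(res$rotation)
    d2 <- outer(rowSums(Yr^2), rowSums(X^2), "+") - 2 * Yr %*% t(X)
    res$mse <- sum(P * pmax(d2, 0)) / sum(P)
  }
  structure(list(rotation = res$rotation, sigma2 = res$sigma2,
                 n_iter = res$n_iter, converged_by = res$converged_by,
                 nll = res$nll, correspondence = res$correspondence,
                 mse = res$mse, n_moving = nrow(Y), n_reference = nrow(X)),
            class = "cpd_result")
}

#' @export
print.cpd_result <- function(x, ...) {
  cat(sprintf("<cpd_result> %d x %d points, %d iteration(s) (%s), mse %.4g um^2\n",
              x$n_moving, x$n_reference, x$n_iter, x$converged_by, x$mse))
  invisible(x)
}

#' Geodesic angle between two rotations, in degrees
#'
#' @param R1,R2 3 x 3 rotation matrices.
#' @return The rotation angle of \code{R1 t(R2)} in degrees.
#' @export
rotation_angle_deg <- function(R1, R2 = diag(3)) {
  tr <- sum(diag(R1 %*% t(R2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Morphological dissimilarity of two neurons
#'
#' Both topological minors are re-centered on their somata and the second
#' neuron's axonal point cloud is registered to the first by rotation-only
#' CPD; the dissimilarity is the resulting registration MSE in um^2.
#'
#' @param a,b \code{topological_minor} objects.
#' @param cfg A \code{\link{cpd_config}}.
#' @return The registration mean squared error (um^2).
#' @export
pair_dissimilarity <- function(a, b, cfg = cpd_config()) {
  cpd_rigid_rotation(minor_points(b, center_soma = TRUE),
                     minor_points(a, center_soma = TRUE), cfg)$mse
}

#' All-pairs CPD dissimilarity matrix
#'
#' @param minors List of \code{topological_minor} objects (n >= 2).
#' @param cfg A \code{\link{cpd_config}}.
#' @param symmetrize If TRUE (default), the matrix is averaged with its
#'   transpose; the diagonal is zero either way.
#' @param verbose Log progress with \code{message()}.
#' @return n x n numeric matrix of um^2 dissimilarities with neuron ids as
#'   dimnames. Pair failures are imputed as the matrix maximum with a
#'   warning.
#' @export
dissimilarity_matrix <- function(minors, cfg = cpd_config(),
                                 symmetrize = TRUE, verbose = FALSE) {
  n <- length(minors)
  stopifnot(n >= 2L)
  ids <- vapply(minors, `[[`, character(1), "neuron_id")
  clouds <- lapply(minors, minor_points, center_soma = TRUE)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  failed <- 0L
  for (i in seq_len(n)) {
    if (verbose) message(sprintf("dissimilarity row %d/%d", i, n))
    for (j in seq_len(n)) {
      if (i == j) next
      D[i, j] <- tryCatch(
        cpd_rigid_rotation(clouds[[j]], clouds[[i]], cfg)$mse,
        error = function(e) { failed <<- failed + 1L; NA_real_ })
    }
  }
  if (failed > 0L) {
    warning(sprintf("%d pair registration(s) failed; imputed as matrix maximum",
                    failed), call. = FALSE)
    D[is.na(D)] <- max(D, na.rm = TRUE)
  }
  if (symmetrize) D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' Nearest morphology in a collection
#'
#' Selects the collection neuron minimizing the CPD registration MSE to the
#' query (the collection neuron is registered to the query); ties are broken
#' by collection order.
#'
#' @param query A \code{topological_minor}.
#' @param collection Non-empty list of \code{topological_minor} objects.
#' @param cfg A \code{\link{cpd_config}}.
#' @return List with \code{neuron_id}, \code{mse} and \code{index}.
#' @export
nearest_neuron <- function(query, collection, cfg = cpd_config()) {
  stopifnot(length(collection) >= 1L)
  mses <- vapply(collection, function(cand)
    pair_dissimilarity(query, cand, cfg), numeric(1))
  i <- which.min(mses)
  list(neuron_id = collection[[i]]$neuron_id, mse = mses[i], index = i)
}

#' Write a dissimilarity matrix as TSV with an id header row/column
#'
#' @param D Square matrix with dimnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_dissimilarity <- function(D, path) {
  write.table(cbind(neuron_id = rownames(D), as.data.frame(D)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
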