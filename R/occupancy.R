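#' Build sparse source/target occupancy maps
#'
#' Encodes, per neuronal type, the voxels containing somata (source) and the
#' voxels containing axonal terminal points (target) on the 10-um reference
#' grid. Stored sparsely as 0-based voxel-index matrices; the dense
#' equivalent of the two binary 4-D arrays is reconstructed on demand.
#'
#' @param somata n x 3 matrix of soma positions (PIR um).
#' @param minors List of \code{topological_minor} objects (same order).
#' @param type_labels Integer/character type per neuron.
#' @param voxel_size_um Voxel edge length.
#' @param grid_dims Grid dimensions in voxels (defaults to the 10-um
#'   reference template, 1320 x 800 x 1140).
#' @param palette Optional named list/vector of RGB colors per type.
#' @return An object of class \code{occupancy_map} with per-type sparse
#'   \code{source} and \code{target} voxel lists; out-of-grid points are
#'   dropped and counted in the \code{dropped} field.
#' @export
build_occupancy <- function(somata, minors, type_labels, voxel_size_um = 10,
                            grid_dims = c(1320, 800, 1140), palette = NULL) {
  n <- nrow(somata)
  stopifnot(length(minors) == n, length(type_labels) == n)
  types <- sort(unique(as.character(type_labels)))
  if (is.null(palette)) {
    palette <- grDevices::hcl.colors(max(3L, length(types)), "Dark 3")[
      seq_along(types)]
    names(palette) <- types
  }
  inb <- function(v) v[, 1L] >= 0L & v[, 1L] < grid_dims[1L] &
    v[, 2L] >= 0L & v[, 2L] < grid_dims[2L] &
    v[, 3L] >= 0L & v[, 3L] < grid_dims[3L]
  dropped <- 0L
  src <- tgt <- setNames(vector("list", length(types)), types)
  for (ty in types) {
    idx <- which(as.character(type_labels) == ty)
    sv <- um_to_voxel(somata[idx, , drop = FALSE], voxel_size_um)
    ok <- inb(sv); dropped <- dropped + sum(!ok)
    src[[ty]] <- unique(sv[ok, , drop = FALSE])
    tp <- do.call(rbind, lapply(minors[idx], `[[`, "terminal_points"))
    tv <- um_to_voxel(tp, voxel_size_um)
    ok <- inb(tv); dropped <- dropped + sum(!ok)
    tgt[[ty]] <- unique(tv[ok, , drop = FALSE])
  }
  structure(list(voxel_size_um = voxel_size_um, grid_dims = grid_dims,
                 source = src, target = tgt, palette = palette,
                 dropped = dropped),
            class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %d type(s) on %d x %d x %d grid @ %g um (%d point(s) dropped)\n",
              length(x$source), x$grid_dims[1L], x$grid_dims[2L],
              x$grid_dims[3L], x$voxel_size_um, x$dropped))
  invisible(x)
}

#' Densify one type of an occupancy map
#'
#' @param map An \code{occupancy_map}.
#' @param which \code{"source"} or \code{"target"}.
#' @param type Type name.
#' @return Logical 3-D array on the map grid.
#' @export
occupancy_dense <- function(map, which = c("target", "source"), type) {
  which <- match.arg(which)
  v <- map[[which]][[as.character(type)]]
  arr <- array(FALSE, dim = map$grid_dims)
  if (nrow(v)) arr[v + 1L] <- TRUE
  arr
}

#' Sparsify a dense occupancy array
#'
#' @param arr Logical 3-D array.
#' @return Integer matrix of 0-based voxel indices.
#' @export
occupancy_sparse <- function(arr) {
  idx <- which(arr, arr.ind = TRUE)
  v <- idx - 1L
  storage.mode(v) <- "integer"
  unname(v[order(v[, 1L], v[, 2L], v[, 3L]), , drop = FALSE])
}

# Maximum projection of one type's voxel list along one grid axis; returns a
# logical matrix over the two remaining axes.
.project_voxels <- function(v, grid_dims, axis) {
  keep <- setdiff(1:3, axis)
  m <- matrix(FALSE, grid_dims[keep[1L]], grid_dims[keep[2L]])
  if (nrow(v)) m[v[, keep, drop = FALSE] + 1L] <- TRUE
  m
}

#' Maximum projection plots of an occupancy map
#'
#' Writes three PNG images — coronal (projected along the anterior-posterior
#' axis), sagittal (left-right) and horizontal (superior-inferior) — with
#' each type's voxels in its palette color, optionally over a grayscale
#' background volume.
#'
#' @param map An \code{occupancy_map}.
#' @param out_dir Output directory.
#' @param which \code{"source"} (somata) or \code{"target"} (terminals).
#' @param background Optional numeric 3-D array on the map grid.
#' @return Named list of the written file paths (and, invisibly accessible,
#'   the per-plane per-type projection matrices in the \code{"projections"}
#'   attribute).
#' @export
max_projection_plots <- function(map, out_dir, which = c("source", "target"),
                                 background = NULL) {
  which <- match.arg(which)
  if (!any(vapply(map[[which]], nrow, integer(1)) > 0))
    stop("occupancy map has no ", which, " voxels", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  planes <- c(coronal = 1L, sagittal = 3L, horizontal = 2L)
  paths <- list(); projections <- list()
  for (pn in names(planes)) {
    ax <- planes[[pn]]
    keep <- setdiff(1:3, ax)
    dims2 <- map$grid_dims[keep]
    img <- array(0, dim = c(dims2, 3L))
    if (!is.null(background)) {
      bg <- apply(background, keep, max)
      bg <- bg / max(bg, 1e-12)
      for (ch in 1:3) img[, , ch] <- 0.6 * bg
    }
    projections[[pn]] <- list()
    for (ty in names(map[[which]])) {
      pr <- .project_voxels(map[[which]][[ty]], map$grid_dims, ax)
      projections[[pn]][[ty]] <- pr
      rgb <- grDevices::col2rgb(map$palette[[ty]]) / 255
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[pr] <- rgb[ch]
        img[, , ch] <- plane
      }
    }
    # image rows run along the second kept axis for display
    path <- file.path(out_dir, sprintf("%s_%s.png", which, pn))
    png::writePNG(aperm(img, c(2L, 1L, 3L)), path)
    paths[[pn]] <- path
  }
  structure(paths, projections = projections)
}
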