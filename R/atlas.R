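#' Construct a labeled atlas volume
#'
#' A 3-D integer label grid in PIR orientation with a label map assigning each
#' nonzero label an area acronym and (for cortical labels) a layer name.
#'
#' @param labels 3-D integer array of region labels (0 = background).
#' @param voxel_size_um Voxel edge length in micrometers.
#' @param label_map data.frame with columns \code{label}, \code{area},
#'   \code{layer} (\code{NA} for non-layered structures).
#' @return An object of class \code{atlas_volume}. Per-area voxel coordinates
#'   used by \code{\link{border_distance}} are cached lazily.
#' @export
atlas_volume <- function(labels, voxel_size_um = 10, label_map) {
  stopifnot(length(dim(labels)) == 3L, voxel_size_um > 0)
  storage.mode(labels) <- "integer"
  label_map <- as.data.frame(label_map, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "area", "layer") %in% names(label_map)))
  used <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(used, label_map$label)
  if (length(missing))
    stop("labels present in grid but absent from label_map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(labels = labels,
                 voxel_size_um = voxel_size_um,
                 orientation = "PIR",
                 label_map = label_map,
                 area_groups = split(label_map$label, label_map$area),
                 cache = new.env(parent = emptyenv())),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<atlas_volume> %d x %d x %d voxels @ %g um, %d labels, %d areas\n",
              d[1L], d[2L], d[3L], x$voxel_size_um, nrow(x$label_map),
              length(x$area_groups)))
  invisible(x)
}

#' Look up the atlas area/layer at 3-D points
#'
#' Points are mapped to voxels with the floor convention (0-based, half-open
#' ownership, corner origin); out-of-bounds points and zero labels return the
#' background value (\code{NA} area and layer).
#'
#' @param a An \code{\link{atlas_volume}}.
#' @param p Length-3 vector or n x 3 matrix of PIR micrometers.
#' @return data.frame with one row per point: \code{area}, \code{layer},
#'   \code{label} (0 for background).
#' @export
label_at <- function(a, p) {
  v <- um_to_voxel(p, a$voxel_size_um) + 1L   # to 1-based grid indices
  d <- dim(a$labels)
  ok <- v[, 1L] >= 1L & v[, 1L] <= d[1L] &
        v[, 2L] >= 1L & v[, 2L] <= d[2L] &
        v[, 3L] >= 1L & v[, 3L] <= d[3L]
  lab <- integer(nrow(v))
  if (any(ok)) lab[ok] <- a$labels[v[ok, , drop = FALSE]]
  i <- match(lab, a$label_map$label)
  data.frame(area = a$label_map$area[i],
             layer = a$label_map$layer[i],
             label = lab,
             stringsAsFactors = FALSE)
}

# Cached voxel-center coordinates (um) of all voxels carrying any label of an
# area.
.area_voxel_um <- function(a, area) {
  key <- paste0("area:", area)
  if (!is.null(a$cache[[key]])) return(a$cache[[key]])
  labs <- a$area_groups[[area]]
  if (is.null(labs))
    stop("configuration error: unknown area acronym '", area, "'", call. = FALSE)
  idx <- which(array(a$labels %in% labs, dim = dim(a$labels)), arr.ind = TRUE)
  coords <- (idx - 0.5) * a$voxel_size_um
  a$cache[[key]] <- coords
  coords
}

#' Euclidean distance from points to the nearest voxel of an area
#'
#' Returns 0 for points whose own voxel carries a label of the target area;
#' otherwise the distance to the nearest voxel center carrying any label of
#' the area (across layers). Used for the center/border focality rule.
#'
#' @param a An \code{\link{atlas_volume}}.
#' @param p Length-3 vector or n x 3 matrix of PIR micrometers.
#' @param target_area Area acronym present in the atlas.
#' @return Numeric vector of distances in micrometers.
#' @export
border_distance <- function(a, p, target_area) {
  coords <- .area_voxel_um(a, target_area)
  pm <- if (is.null(dim(p))) matrix(p, ncol = 3L) else as.matrix(p)
  inside <- label_at(a, pm)$area %in% target_area
  out <- numeric(nrow(pm))
  todo <- which(!inside)
  if (length(todo)) {
    c2 <- rowSums(coords^2)
    chunk <- max(1L, floor(2e6 / nrow(coords)))
    for (s in split(todo, ceiling(seq_along(todo) / chunk))) {
      q <- pm[s, , drop = FALSE]
      # ||q - c||^2 = |q|^2 + |c|^2 - 2 q.c, minimized over voxel centers
      cross <- coords %*% t(q)                       # V x k
      d2 <- sweep(-2 * cross, 1L, c2, "+")
      out[s] <- sqrt(pmax(0, apply(d2, 2L, min) + rowSums(q^2)))
    }
  }
  out
}

#' Build a toy labeled volume for testing and synthesis
#'
#' Constructs a labeled grid containing a subcortical nucleus ellipsoid and a
#' cortical slab partitioned into areas along the left-right axis and into
#' layers (L1, L2/3, L4, L5, L6a, L6b) along the depth (superior-inferior)
#' axis. The slab occupies the full anterior-posterior and left-right extent
#' from the top of the volume down to the summed layer thickness.
#'
#' @param dims_um Volume extents in micrometers (PIR axes).
#' @param voxel_size_um Voxel edge length in micrometers.
#' @param areas Area acronyms, in spatial order along the left-right axis.
#' @param layers Named vector of layer thicknesses in micrometers, in order
#'   from the pial surface.
#' @param nucleus List with \code{name}, \code{center} (um), \code{radii}
#'   (um) of the nucleus ellipsoid.
#' @param barrels If > 0, the named area \code{barrel_area} is subdivided
#'   along the anterior-posterior axis into this many barrel strips labeled
#'   \code{b1, b2, ...} (all layers), for barrel-level censuses.
#' @param barrel_area Area to subdivide when \code{barrels > 0}.
#' @return An \code{\link{atlas_volume}}.
#' @export
build_toy_atlas <- function(dims_um = c(2000, 2000, 3000),
                            voxel_size_um = 10,
                            areas = c("SSp-m", "SSs", "SSp-ll", "SSp-ul",
                                      "SSp-n", "SSp-bfd"),
                            layers = c("L1" = 100, "L2/3" = 300, "L4" = 200,
                                       "L5" = 300, "L6a" = 250, "L6b" = 50),
                            nucleus = list(name = "VPM",
                                           center = c(400, 1600, 2700),
                                           radii = c(180, 300, 180)),
                            barrels = 0, barrel_area = "SSp-bfd") {
  stopifnot(all(dims_um > 0), voxel_size_um > 0, length(areas) >= 1,
            all(layers > 0))
  d <- as.integer(round(dims_um / voxel_size_um))
  labels <- array(0L, dim = d)

  n_areas <- length(areas)
  n_layers <- length(layers)
  layer_top_um <- cumsum(c(0, layers))
  cortex_vox <- ceiling(sum(layers) / voxel_size_um)
  if (cortex_vox > d[2L])
    stop("construction error: cortical slab thicker than the volume", call. = FALSE)

  # cortex: label = (area_index - 1) * n_layers + layer_index
  yc_um <- (seq_len(cortex_vox) - 0.5) * voxel_size_um
  layer_idx <- findInterval(yc_um, layer_top_um, rightmost.closed = TRUE)
  layer_idx[layer_idx > n_layers] <- n_layers
  zc_um <- (seq_len(d[3L]) - 0.5) * voxel_size_um
  area_idx <- pmin(n_areas, 1L + floor(zc_um / (dims_um[3L] / n_areas)))
  lab_yz <- outer(layer_idx, (area_idx - 1L) * n_layers, "+")  # y x z
  for (x in seq_len(d[1L])) labels[x, seq_len(cortex_vox), ] <- lab_yz

  label_map <- data.frame(
    label = seq_len(n_areas * n_layers),
    area = rep(areas, each = n_layers),
    layer = rep(names(layers), n_areas),
    stringsAsFactors = FALSE)

  # optional barrel subdivision of one area (all its layers), along AP
  if (barrels > 0) {
    az <- which(areas == barrel_area)
    if (!length(az)) stop("barrel_area not in areas", call. = FALSE)
    zmask <- area_idx == az
    xc_um <- (seq_len(d[1L]) - 0.5) * voxel_size_um
    b_idx <- pmin(barrels, 1L + floor(xc_um / (dims_um[1L] / barrels)))
    base <- n_areas * n_layers
    for (x in seq_len(d[1L])) {
      blab <- base + (b_idx[x] - 1L) * n_layers
      labels[x, seq_len(cortex_vox), zmask] <-
        blab + rep(layer_idx, sum(zmask))
    }
    label_map <- label_map[label_map$area != barrel_area, , drop = FALSE]
    label_map <- rbind(label_map, data.frame(
      label = base + as.vector(outer(seq_len(n_layers),
                                     (seq_len(barrels) - 1L) * n_layers, "+")),
      area = rep(paste0("b", seq_len(barrels)), each = n_layers),
      layer = rep(names(layers), barrels),
      stringsAsFactors = FALSE))
  }

  # nucleus ellipsoid
  nuc_label <- max(label_map$label) + 1L
  cx <- ((seq_len(d[1L]) - 0.5) * voxel_size_um - nucleus$center[1L]) / nucleus$radii[1L]
  cy <- ((seq_len(d[2L]) - 0.5) * voxel_size_um - nucleus$center[2L]) / nucleus$radii[2L]
  cz <- ((seq_len(d[3L]) - 0.5) * voxel_size_um - nucleus$center[3L]) / nucleus$radii[3L]
  xr <- which(abs(cx) <= 1); yr <- which(abs(cy) <= 1); zr <- which(abs(cz) <= 1)
  if (!length(xr) || !length(yr) || !length(zr))
    stop("generation error: nucleus ellipsoid has zero volume", call. = FALSE)
  sub <- outer(cx[xr]^2, outer(cy[yr]^2, cz[zr]^2, "+"), "+") <= 1
  cur <- labels[xr, yr, zr]
  if (any(cur[sub] != 0L))
    stop("construction error: nucleus overlaps the cortical slab", call. = FALSE)
  cur[sub] <- nuc_label
  labels[xr, yr, zr] <- cur
  label_map <- rbind(label_map,
                     data.frame(label = nuc_label, area = nucleus$name,
                                layer = NA_character_,
                                stringsAsFactors = FALSE))

  atlas_volume(labels, voxel_size_um, label_map)
}

#' Write an atlas volume as NIfTI plus a JSON label-map sidecar
#'
#' @param a An \code{\link{atlas_volume}}.
#' @param path Output path for the NIfTI file (\code{.nii} or
#'   \code{.nii.gz}); the sidecar is written next to it with extension
#'   \code{.labels.json}.
#' @return \code{path}, invisibly.
#' @export
write_atlas <- function(a, path) {
  img <- RNifti::asNifti(a$labels,
                         pixdim = rep(a$voxel_size_um / 1000, 3L))
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  jsonlite::write_json(list(voxel_size_um = a$voxel_size_um,
                            orientation = "PIR",
                            label_map = a$label_map),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an atlas volume written by \code{\link{write_atlas}}
#'
#' Real annotation volumes with integer labels are drop-in compatible as long
#' as a label-map sidecar is provided.
#'
#' @param path Path to the NIfTI label volume.
#' @return An \code{\link{atlas_volume}}.
#' @export
read_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".labels.json", path)
  if (!file.exists(side))
    stop("label-map sidecar not found: ", side, call. = FALSE)
  meta <- jsonlite::fromJSON(side)
  atlas_volume(array(as.integer(img), dim = dim(img)),
               voxel_size_um = meta$voxel_size_um,
               label_map = meta$label_map)
}
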