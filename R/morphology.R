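#' Coordinate space description for a morphology source
#'
#' Describes the axis orientation, the unit of the stored coordinates and the
#' template extents of the space a morphology was reconstructed in. The
#' canonical analysis space is PIR (anterior-to-posterior,
#' superior-to-inferior, left-to-right, origin at the anterior-superior-left
#' corner) in micrometers; MouseLight-style sources are LIP.
#'
#' @param orientation Three-letter axis code, \code{"PIR"} or \code{"LIP"}.
#' @param unit_um Micrometers per coordinate unit of the source (> 0).
#' @param extents_um Template extents in micrometers along the PIR axes;
#'   the third entry (left-right, 11,400 um for the 10-um reference template)
#'   is the reflection extent used when converting LIP sources.
#' @return An object of class \code{space_spec}.
#' @export
space_spec <- function(orientation = "PIR", unit_um = 1,
                       extents_um = c(13200, 8000, 11400)) {
  orientation <- toupper(as.character(orientation))
  if (nchar(orientation) != 3L)
    stop("orientation must be a 3-letter axis code", call. = FALSE)
  if (!is.numeric(unit_um) || length(unit_um) != 1L || unit_um <= 0)
    stop("unit_um must be a positive number", call. = FALSE)
  if (length(extents_um) != 3L || any(extents_um <= 0))
    stop("extents_um must be 3 positive numbers", call. = FALSE)
  structure(list(orientation = orientation, unit_um = unit_um,
                 extents_um = as.numeric(extents_um)),
            class = "space_spec")
}

.structure_levels <- c("soma", "axon", "dendrite")

.swc_code_to_structure <- function(code) {
  out <- rep(NA_character_, length(code))
  out[code == 1] <- "soma"
  out[code == 2] <- "axon"
  out[code %in% c(3, 4)] <- "dendrite"
  unknown <- is.na(out)
  if (any(unknown)) {
    warning(sprintf("%d point(s) with SWC structure code outside 1-4 mapped to dendrite",
                    sum(unknown)), call. = FALSE)
    out[unknown] <- "dendrite"
  }
  out
}

.structure_to_swc_code <- function(structure) {
  c(soma = 1L, axon = 2L, dendrite = 3L)[structure]
}

#' Construct a neuron morphology
#'
#' A reconstructed neuron held as paired point/line arrays: an ordered matrix
#' of 3-D coordinates and, per point, a structure label and the index of its
#' parent point. Exactly one point is the root (parent 0); the parent relation
#' must form a tree in which every parent precedes its children.
#'
#' @param neuron_id Identifier string.
#' @param points Numeric n x 3 matrix of coordinates.
#' @param structure Character vector of per-point labels in
#'   \code{c("soma", "axon", "dendrite")}.
#' @param parent Integer vector of 1-based parent indices; 0 marks the root.
#' @param source_db One of \code{"mouselight"}, \code{"braintell"},
#'   \code{"synthetic"}, \code{"other"}.
#' @param space A \code{\link{space_spec}} describing the coordinates.
#' @param radius Optional per-point radius (SWC column 6), preserved on
#'   round-trips but unused by the analysis.
#' @return An object of class \code{neuron_morphology} with a
#'   \code{soma_index} field (first soma-labeled point).
#' @export
neuron_morphology <- function(neuron_id, points, structure, parent,
                              source_db = "other", space = space_spec(),
                              radius = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (ncol(points) != 3L) stop("points must be n x 3", call. = FALSE)
  if (!all(is.finite(points))) stop("all coordinates must be finite", call. = FALSE)
  structure <- as.character(structure)
  parent <- as.integer(parent)
  if (length(structure) != n || length(parent) != n)
    stop("structure and parent must have one entry per point", call. = FALSE)
  if (!all(structure %in% .structure_levels))
    stop("structure labels must be soma/axon/dendrite", call. = FALSE)
  if (sum(parent == 0L) != 1L)
    stop("structural error: exactly one root (parent 0) is required", call. = FALSE)
  if (any(parent < 0L | parent > n))
    stop("structural error: dangling parent reference", call. = FALSE)
  if (!any(structure == "soma"))
    stop("at least one soma-labeled point is required", call. = FALSE)
  source_db <- match.arg(source_db,
                         c("mouselight", "braintell", "synthetic", "other"))
  if (is.null(radius)) radius <- rep(1, n)

  # Enforce parent-before-child order (reorders topologically if needed;
  # detects cycles).
  if (any(parent >= seq_len(n))) {
    ord <- .topo_order(parent)
    inv <- integer(n)
    inv[ord] <- seq_len(n)
    points <- points[ord, , drop = FALSE]
    structure <- structure[ord]
    radius <- radius[ord]
    parent <- ifelse(parent[ord] == 0L, 0L, inv[parent[ord]])
  }

  structure(list(neuron_id = as.character(neuron_id),
                 source_db = source_db,
                 points = points,
                 structure = structure,
                 parent = parent,
                 radius = as.numeric(radius),
                 soma_index = which(structure == "soma")[1L],
                 space = space),
            class = "neuron_morphology")
}

# Topological order of a parent array (children after parents); errors on
# cycles.
.topo_order <- function(parent) {
  n <- length(parent)
  children <- split(seq_len(n), factor(parent, levels = 0:n))
  ord <- integer(0)
  frontier <- children[["0"]]
  while (length(frontier)) {
    ord <- c(ord, frontier)
    frontier <- unlist(children[as.character(frontier)], use.names = FALSE)
  }
  if (length(ord) != n)
    stop("structural error: parent relation contains a cycle or unreachable points",
         call. = FALSE)
  ord
}

#' @export
print.neuron_morphology <- function(x, ...) {
  cat(sprintf("<neuron_morphology> %s [%s]\n", x$neuron_id, x$source_db))
  cat(sprintf("  %d points (%d soma, %d axon, %d dendrite), space %s @ %g um/unit\n",
              nrow(x$points), sum(x$structure == "soma"),
              sum(x$structure == "axon"), sum(x$structure == "dendrite"),
              x$space$orientation, x$space$unit_um))
  invisible(x)
}

#' Read a morphology from an SWC file
#'
#' Parses the standard 7-column SWC records (id, type, x, y, z, radius,
#' parent). Structure codes map 1 to soma, 2 to axon, 3/4 to dendrite; other
#' codes map to dendrite with a warning. Coordinates are left in the source
#' space; unit/orientation conversion is a separate step
#' (\code{\link{to_ccf_pir}}).
#'
#' @param path Path to an SWC file.
#' @param space A \code{\link{space_spec}} for the source coordinates.
#' @param neuron_id Identifier; defaults to the file name without extension.
#' @param source_db Source database tag.
#' @return A \code{\link{neuron_morphology}}.
#' @export
read_swc <- function(path, space = space_spec(), neuron_id = NULL,
                     source_db = "other") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("parse error: no SWC records in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop(sprintf("parse error at line %d: expected 7 SWC columns, found %d",
                 lineno[which(nf != 7L)[1L]], nf[nf != 7L][1L]), call. = FALSE)
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
  if (anyNA(m))
    stop(sprintf("parse error at line %d: non-numeric SWC field",
                 lineno[which(rowSums(is.na(m)) > 0)[1L]]), call. = FALSE)
  ids <- m[, 1L]
  if (anyDuplicated(ids))
    stop("structural error: duplicate SWC sample ids", call. = FALSE)
  par_raw <- m[, 7L]
  if (sum(par_raw == -1) > 1L)
    stop("structural error: multiple roots in SWC file", call. = FALSE)
  if (sum(par_raw == -1) == 0L)
    stop("structural error: no root (parent -1) in SWC file", call. = FALSE)
  pos <- match(par_raw, ids)
  bad <- par_raw != -1 & is.na(pos)
  if (any(bad))
    stop(sprintf("structural error: parent id %g not defined", par_raw[bad][1L]),
         call. = FALSE)
  parent <- ifelse(par_raw == -1, 0L, pos)
  if (is.null(neuron_id)) neuron_id <- sub("\\.[sS][wW][cC]$", "", basename(path))
  neuron_morphology(neuron_id = neuron_id,
                    points = m[, 3:5, drop = FALSE],
                    structure = .swc_code_to_structure(m[, 2L]),
                    parent = as.integer(parent),
                    source_db = source_db, space = space,
                    radius = m[, 6L])
}

#' Write a morphology to an SWC file
#'
#' @param m A \code{\link{neuron_morphology}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_swc <- function(m, path) {
  rec <- data.frame(id = seq_len(nrow(m$points)),
                    type = .structure_to_swc_code(m$structure),
                    x = m$points[, 1L], y = m$points[, 2L], z = m$points[, 3L],
                    radius = m$radius,
                    parent = ifelse(m$parent == 0L, -1L, m$parent))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# SWC written by axonmap; id %s; space %s unit_um %g",
                     m$neuron_id, m$space$orientation, m$space$unit_um), con)
  write.table(format(rec, trim = TRUE, scientific = FALSE), con,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a morphology from the portal-style JSON dialect
#'
#' The dialect is an object with keys \code{"id"}, \code{"space"}
#' (\code{orientation}, \code{unit_um}, \code{extents_um}), \code{"points"}
#' (array of [x, y, z]) and \code{"lines"} (array of
#' [structure_code, point_index, parent_index]) where point indices are
#' 0-based and the root parent is -1.
#'
#' @param path Path to a JSON morphology file.
#' @param source_db Source database tag.
#' @return A \code{\link{neuron_morphology}}; space metadata is taken from the
#'   file header.
#' @export
read_json_morphology <- function(path, source_db = "other") {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj$points) || is.null(obj$lines))
    stop("format error: JSON morphology requires 'points' and 'lines' keys",
         call. = FALSE)
  pts <- as.matrix(obj$points)
  ln <- as.matrix(obj$lines)
  if (ncol(ln) != 3L)
    stop("format error: each line record must be [structure_code, point_index, parent_index]",
         call. = FALSE)
  n <- nrow(pts)
  if (nrow(ln) != n)
    stop("structural error: point and line arrays differ in length", call. = FALSE)
  pt_idx <- as.integer(ln[, 2L])
  par_idx <- as.integer(ln[, 3L])
  if (any(pt_idx < 0L | pt_idx >= n) ||
      any(par_idx != -1L & (par_idx < 0L | par_idx >= n)))
    stop("structural error: line array references a point index outside the point array",
         call. = FALSE)
  if (anyDuplicated(pt_idx))
    stop("structural error: duplicate point_index in line array", call. = FALSE)
  sp <- if (!is.null(obj$space))
    space_spec(obj$space$orientation, obj$space$unit_um, obj$space$extents_um)
  else space_spec()
  ord <- order(pt_idx)
  parent01 <- par_idx[ord]
  neuron_morphology(neuron_id = if (!is.null(obj$id)) obj$id else "json",
                    points = pts[ord, , drop = FALSE],
                    structure = .swc_code_to_structure(as.numeric(ln[ord, 1L])),
                    parent = ifelse(parent01 == -1L, 0L, parent01 + 1L),
                    source_db = source_db, space = sp)
}

#' Write a morphology in the portal-style JSON dialect
#'
#' @param m A \code{\link{neuron_morphology}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_json_morphology <- function(m, path) {
  n <- nrow(m$points)
  obj <- list(
    id = m$neuron_id,
    space = list(orientation = m$space$orientation,
                 unit_um = m$space$unit_um,
                 extents_um = m$space$extents_um),
    points = unname(m$points),
    lines = cbind(.structure_to_swc_code(m$structure),
                  seq_len(n) - 1L,
                  ifelse(m$parent == 0L, -1L, m$parent - 1L)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Normalize a morphology to micrometers in PIR orientation
#'
#' Converts coordinates to micrometers in the canonical PIR orientation.
#' For LIP sources the first and third coordinates are swapped and the new
#' third (left-right) coordinate is reflected as \code{extent_LR - value};
#' PIR sources are only rescaled. Idempotent on already-normalized input.
#'
#' @param m A \code{\link{neuron_morphology}}.
#' @param space Optional \code{\link{space_spec}} overriding \code{m$space}.
#' @return The morphology with PIR micrometer coordinates and an updated
#'   space field.
#' @export
to_ccf_pir <- function(m, space = NULL) {
  sp <- if (is.null(space)) m$space else space
  p <- m$points * sp$unit_um
  if (sp$orientation == "PIR") {
    # unit rescale only
  } else if (sp$orientation == "LIP") {
    p <- p[, c(3L, 2L, 1L), drop = FALSE]
    p[, 3L] <- sp$extents_um[3L] - p[, 3L]
  } else {
    stop("configuration error: unknown orientation code '", sp$orientation,
         "' (supported: PIR, LIP)", call. = FALSE)
  }
  m$points <- p
  m$space <- space_spec("PIR", 1, sp$extents_um)
  m
}

#' Convert PIR micrometer points to 0-based voxel indices
#'
#' Uses the floor convention with half-open voxel ownership and a corner
#' origin.
#'
#' @param points_um n x 3 matrix (or length-3 vector) of PIR micrometers.
#' @param voxel_size_um Voxel edge length in micrometers.
#' @return Integer n x 3 matrix of 0-based voxel indices.
#' @export
um_to_voxel <- function(points_um, voxel_size_um = 10) {
  p <- if (is.null(dim(points_um))) matrix(points_um, ncol = 3L)
       else as.matrix(points_um)
  v <- floor(p / voxel_size_um)
  storage.mode(v) <- "integer"
  v
}
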