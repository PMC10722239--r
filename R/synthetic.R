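#' Default parameters of the synthetic population generator
#'
#' The generator emulates a first-order thalamic nucleus projecting
#' topographically to a parcellated, layered cortical slab: somata are
#' sampled inside the nucleus ellipsoid; a neuron's primary target is
#' determined by pushing its soma through a fixed rotation-plus-stretch map;
#' motif order is sampled from the published order distribution with
#' secondary areas chosen adjacent along the topographic axis (so the two
#' extreme areas never co-occur); branch count, terminal spread and radial
#' distance all increase monotonically with the soma's depth parameter.
#'
#' @return Named list of generator defaults.
#' @export
synthetic_defaults <- function() {
  list(
    rotation_deg = c(-60, 0, -120),   # generator soma-to-terminal rotation
    euler_order = "xyz", euler_intrinsic = FALSE,
    scale = c(0.5, 5.35, 0.5),        # stretch: spreads the rotated somata
                                      # across the whole 6-area axis
    base_um = c(1000, 600, 1500),     # cortical anchor of the map
    motif_order_probs = c(0.26, 0.53, 0.17, 0.015),
    noise_um = 10,                    # terminal jitter (~1 atlas voxel of
                                      # registration error)
    seg_um = 25,                      # polyline sampling step
    spread_um = c(40, 150),           # primary terminal fan radius, d = 0..1
    branch_rise_um = c(80, 430),      # primary fan-cone height, d = 0..1
                                      # (branch length grows with depth)
    secondary_spread_um = 40,
    secondary_rise_um = 100,
    n_secondary = c(11, 9, 7, 5),     # terminal branches per secondary area
    soma_fill = 0.9,                  # fraction of nucleus radii used
    dendrite_stub = TRUE)
}

.interp_segment <- function(from, to, seg_um) {
  len <- sqrt(sum((to - from)^2))
  k <- max(1L, ceiling(len / seg_um))
  tt <- seq_len(k) / k
  outer(tt, to - from) + rep(from, each = k)
}

# Symmetric terminal fan in the (AP, depth) plane around `center`:
# one central terminal plus (n-1)/2 antipodal pairs. Confining the fan to
# the plane orthogonal to the area axis keeps intended motifs geometrically
# exact in the noiseless limit; the central point is the exact medoid of the
# noiseless fan.
.fan_offsets <- function(n, spread, phase) {
  stopifnot(n %% 2L == 1L)
  P <- (n - 1L) %/% 2L
  if (P == 0L) return(matrix(0, 1L, 3L))
  r <- spread * (0.4 + 0.6 * seq_len(P) / P)
  th <- phase + 2 * pi * seq_len(P) / P
  off <- cbind(r * cos(th), r * sin(th), 0)
  rbind(c(0, 0, 0), off, -off)
}

# Grow one neuron. Returns a neuron_morphology plus its ground-truth row.
.grow_neuron <- function(id, soma, depth, primary_center, sec_centers,
                         n_primary, par) {
  pts <- list(); structure <- character(0); parent <- integer(0)
  add <- function(p, str, par_idx) {
    pts[[length(pts) + 1L]] <<- p
    structure[length(structure) + 1L] <<- str
    parent[length(parent) + 1L] <<- par_idx
    length(structure)
  }
  i_soma <- add(soma, "soma", 0L)
  if (isTRUE(par$dendrite_stub)) {
    i <- i_soma
    for (step in 1:3) i <- add(soma + c(0, 25 * step, 20 * step), "dendrite", i)
  }
  b0 <- c(primary_center[1L], primary_center[2L] + 200, primary_center[3L])
  chain <- function(from_idx, from_pt, to_pt) {
    seg <- .interp_segment(from_pt, to_pt, par$seg_um)
    i <- from_idx
    for (r in seq_len(nrow(seg))) i <- add(seg[r, ], "axon", i)
    i
  }
  i_b0 <- chain(i_soma, soma, b0)
  centers <- c(list(primary_center), sec_centers)
  n_term <- c(n_primary, par$n_secondary[seq_along(sec_centers)])
  spreads <- c(par$spread_um[1L] + diff(par$spread_um) * depth,
               rep(par$secondary_spread_um, length(sec_centers)))
  rises <- c(par$branch_rise_um[1L] + diff(par$branch_rise_um) * depth,
             rep(par$secondary_rise_um, length(sec_centers)))
  for (ci in seq_along(centers)) {
    cen <- centers[[ci]]
    i_b <- chain(i_b0, b0, cen + c(0, rises[ci], 0))
    off <- .fan_offsets(n_term[ci], spreads[ci], phase = runif(1, 0, 2 * pi))
    for (ti in seq_len(nrow(off))) {
      tpt <- cen + off[ti, ]
      seg <- .interp_segment(cen + c(0, rises[ci], 0), tpt, par$seg_um)
      if (par$noise_um > 0)
        seg <- sweep(seg, 2L, rnorm(3, sd = par$noise_um), "+")
      i <- i_b
      for (r in seq_len(nrow(seg))) i <- add(seg[r, ], "axon", i)
    }
  }
  neuron_morphology(neuron_id = id,
                    points = do.call(rbind, pts),
                    structure = structure, parent = parent,
                    source_db = "synthetic",
                    space = space_spec("PIR", 1))
}

#' Generate a topographically organized synthetic population
#'
#' Builds a toy atlas and \code{n} branching axonal morphologies whose
#' primary cortical target follows the soma position through a known
#' rotation, with motif orders drawn from a configurable distribution and
#' depth-dependent morphometrics. Fully reproducible from \code{seed}.
#'
#' @param n Number of neurons (>= 1).
#' @param params Named list overriding \code{\link{synthetic_defaults}}.
#' @param seed Integer seed driving all randomness.
#' @param atlas Optional pre-built toy atlas (defaults to
#'   \code{\link{build_toy_atlas}()}).
#' @param dir Optional output directory; when given, SWC files, the NIfTI
#'   atlas and a ground-truth manifest JSON are written there.
#' @return List with \code{morphologies} (list of
#'   \code{\link{neuron_morphology}}), \code{atlas} and \code{truth} (class
#'   \code{synthetic_truth}: generator parameters plus a per-neuron
#'   data.frame with soma, depth, intended motif and terminal counts).
#' @export
generate_population <- function(n, params = list(), seed = 1L, atlas = NULL,
                                dir = NULL) {
  stopifnot(n >= 1)
  par <- utils::modifyList(synthetic_defaults(), params)
  if (is.null(atlas)) atlas <- build_toy_atlas()
  areas <- unique(atlas$label_map$area)
  areas <- areas[!is.na(atlas$label_map$layer[match(areas, atlas$label_map$area)])]
  dims_um <- dim(atlas$labels) * atlas$voxel_size_um
  n_areas <- length(areas)
  area_width <- dims_um[3L] / n_areas
  z_center <- function(idx) (idx - 0.5) * area_width

  nuc_area <- setdiff(unique(atlas$label_map$area), areas)[1L]
  # nucleus geometry from the toy-atlas defaults unless overridden
  mu <- if (!is.null(par$nucleus_center)) par$nucleus_center else c(400, 1600, 2700)
  radii <- if (!is.null(par$nucleus_radii)) par$nucleus_radii else c(180, 300, 180)

  Rstar <- rotation_from_euler(par$rotation_deg, par$euler_order,
                               par$euler_intrinsic)
  A <- Rstar %*% diag(par$scale)

  probs <- c(par$motif_order_probs, max(0, 1 - sum(par$motif_order_probs)))

  morphs <- vector("list", n)
  rows <- vector("list", n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      # soma inside the (shrunken) nucleus ellipsoid, with the depth
      # parameter uniform so the population covers the whole topographic
      # axis; the transverse position is uniform in the cross-section disc
      depth <- runif(1)
      u2 <- 2 * depth - 1
      rdisc <- sqrt(max(0, 1 - u2^2))
      repeat {
        uu <- runif(2, -1, 1)
        if (sum(uu^2) <= 1) break
      }
      sprime <- c(uu[1L] * rdisc, u2, uu[2L] * rdisc) * radii * par$soma_fill
      soma <- mu + sprime

      cen <- par$base_um + as.numeric(A %*% sprime)
      prim_idx <- min(n_areas, max(1L, 1L + floor(cen[3L] / area_width)))
      prim <- areas[prim_idx]

      k <- sample.int(length(probs), 1L, prob = probs)
      sec_idx <- integer(0)
      if (k > 1L) {
        cand <- setdiff(seq_len(n_areas), prim_idx)
        ord <- order(abs(cand - prim_idx), runif(length(cand)))
        sec_idx <- cand[ord][seq_len(min(k - 1L, length(cand)))]
      }
      sec_centers <- lapply(sec_idx, function(j)
        c(cen[1L], cen[2L], z_center(j)))
      # the primary arbor keeps the clear majority of terminal branches,
      # whatever the motif order (odd count: symmetric fan + center)
      n_sec_total <- sum(par$n_secondary[seq_along(sec_idx)])
      base <- max(17L, n_sec_total + 5L)
      if (base %% 2L == 0L) base <- base + 1L
      n_primary <- base + 2L * round(3 * depth)

      id <- sprintf("syn%03d", i)
      morphs[[i]] <- .grow_neuron(id, soma, depth, cen, sec_centers,
                                  n_primary, par)
      rows[[i]] <- data.frame(
        neuron_id = id, depth = depth,
        soma_x = soma[1L], soma_y = soma[2L], soma_z = soma[3L],
        primary = prim,
        motif = paste(c(prim, areas[sec_idx]), collapse = " - "),
        order = k, n_primary = n_primary,
        primary_center_x = cen[1L], primary_center_y = cen[2L],
        primary_center_z = cen[3L],
        stringsAsFactors = FALSE)
    }
  })

  truth <- structure(list(
    seed = seed, rotation_deg = par$rotation_deg,
    euler_order = par$euler_order, euler_intrinsic = par$euler_intrinsic,
    scale = par$scale, base_um = par$base_um, nucleus_center = mu,
    nucleus_area = nuc_area, areas = areas,
    motif_order_probs = par$motif_order_probs, noise_um = par$noise_um,
    neurons = do.call(rbind, rows)), class = "synthetic_truth")

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (m in morphs) write_swc(m, file.path(dir, paste0(m$neuron_id, ".swc")))
    write_atlas(atlas, file.path(dir, "atlas.nii.gz"))
    jsonlite::write_json(unclass(truth), file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(morphologies = morphs, atlas = atlas, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d neurons, rotation (%g, %g, %g) deg, noise %g um\n",
              nrow(x$neurons), x$rotation_deg[1L], x$rotation_deg[2L],
              x$rotation_deg[3L], x$noise_um))
  invisible(x)
}

#' Generate a morphology pair for registration tests
#'
#' The second morphology is derived from the first by the named transform:
#' \code{"identical"} copies it, \code{"rotated"} rotates all points about
#' the soma around one PIR axis, \code{"noisy"} adds independent isotropic
#' Gaussian jitter to every point.
#'
#' @param kind One of \code{"identical"}, \code{"rotated"}, \code{"noisy"}.
#' @param params List: \code{angle_deg} (default 25), \code{axis} (default 2,
#'   the superior-inferior axis), \code{sigma_um} (default 5), plus any
#'   \code{\link{generate_population}} overrides for the base neuron.
#' @param seed Integer seed.
#' @return List with morphologies \code{a} and \code{b} and the transform
#'   parameters.
#' @export
make_fixture_pair <- function(kind = c("identical", "rotated", "noisy"),
                              params = list(), seed = 1L) {
  kind <- match.arg(kind)
  angle_deg <- if (!is.null(params$angle_deg)) params$angle_deg else 25
  axis <- if (!is.null(params$axis)) params$axis else 2L
  sigma_um <- if (!is.null(params$sigma_um)) params$sigma_um else 5
  gen_par <- params[setdiff(names(params), c("angle_deg", "axis", "sigma_um"))]
  if (is.null(gen_par$noise_um)) gen_par$noise_um <- 0
  if (is.null(gen_par$motif_order_probs))
    gen_par$motif_order_probs <- c(0, 0, 1, 0)   # trifurcating: richer cloud
  a <- generate_population(1L, params = gen_par, seed = seed)$morphologies[[1L]]
  b <- a
  b$neuron_id <- paste0(a$neuron_id, "_b")
  if (kind == "rotated") {
    R <- .axis_rot(as.integer(axis), angle_deg * pi / 180)
    soma <- a$points[a$soma_index, ]
    b$points <- sweep(sweep(a$points, 2L, soma) %*% t(R), 2L, soma, "+")
  } else if (kind == "noisy") {
    b$points <- a$points + with_seed(seed + 1L,
      matrix(rnorm(length(a$points), sd = sigma_um), nrow(a$points), 3L))
  }
  list(a = a, b = b,
       params = list(kind = kind, angle_deg = angle_deg, axis = axis,
                     sigma_um = sigma_um))
}
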