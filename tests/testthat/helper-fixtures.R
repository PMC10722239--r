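# Shared fixtures built in code.

with_seed <- get("with_seed", asNamespace("axonmap"))

# minimal 3-point SWC: soma at origin, two axon points stacked in z
swc3_lines <- c(
  "# minimal chain",
  "1 1 0 0 0 5 -1",
  "2 2 0 0 100 1 1",
  "3 2 0 0 200 1 2")

write_swc3 <- function(path = tempfile(fileext = ".swc"), lines = swc3_lines) {
  writeLines(lines, path)
  path
}

# Y-shaped axon: soma -> trunk -> two leaves
y_tree <- function() {
  neuron_morphology(
    "ytree",
    points = rbind(c(0, 0, 0), c(0, 0, 100), c(-50, 0, 200), c(50, 0, 200)),
    structure = c("soma", "axon", "axon", "axon"),
    parent = c(0L, 1L, 2L, 2L))
}

# unbranched axonal chain of n points after the soma, step um apart in z
chain_tree <- function(n = 10, step = 30) {
  pts <- cbind(0, 0, seq(0, n * step, by = step))
  neuron_morphology("chain", pts,
                    structure = c("soma", rep("axon", n)),
                    parent = c(0L, seq_len(n)))
}

# random axonal tree with arbitrary branching, soma root
random_tree <- function(n = 200, seed = 1) {
  with_seed <- get("with_seed", asNamespace("axonmap"))
  with_seed(seed, {
    parent <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
    pts <- matrix(rnorm(n * 3, sd = 100), n, 3)
    pts[1L, ] <- 0
    neuron_morphology("rand", pts,
                      structure = c("soma", rep("axon", n - 1L)),
                      parent = parent)
  })
}

# two-area slab atlas: area A occupies z < split_um, area B the rest; single
# layer; used for border-distance geometry
two_area_atlas <- function(dims_vox = c(30, 30, 40), voxel = 10,
                           split_um = 200) {
  labels <- array(1L, dim = dims_vox)
  zc <- (seq_len(dims_vox[3]) - 0.5) * voxel
  labels[, , zc >= split_um] <- 2L
  atlas_volume(labels, voxel,
               data.frame(label = 1:2, area = c("A", "B"),
                          layer = c("L4", "L4")))
}

# minimal projection-profile stub from terminal counts (+ equal lengths)
make_profile <- function(counts, areas = names(counts), id = "p",
                         lengths = NULL) {
  if (is.null(lengths)) lengths <- counts * 10
  al <- setNames(numeric(length(areas) + 1L), c(areas, "other"))
  al[names(lengths)] <- lengths
  ac <- setNames(integer(length(areas) + 1L), c(areas, "other"))
  ac[names(counts)] <- as.integer(counts)
  p <- structure(list(neuron_id = id, areas = areas, area_length_um = al,
                      area_layer = data.frame(area = character(0),
                                              layer = character(0),
                                              length_um = numeric(0)),
                      area_terminal_count = ac,
                      terminals = NULL, dominant_target = NA_character_),
                 class = "projection_profile")
  p$dominant_target <- dominant_target(p)
  p
}

# minimal topological-minor stub carrying only terminal points
minor_stub <- function(terminal_points, id = "stub") {
  structure(list(neuron_id = id, soma_point = c(0, 0, 0),
                 branch_nodes = matrix(numeric(0), 0, 3),
                 terminal_branches = list(),
                 branch_lengths = numeric(0),
                 terminal_points = terminal_points,
                 branch_node_terminals = list(),
                 n_points_full = nrow(terminal_points),
                 n_points_minor = nrow(terminal_points)),
            class = "topological_minor")
}

# Kabsch / orthogonal-Procrustes rotation with known correspondences
kabsch <- function(moving, reference) {
  A <- t(reference) %*% moving
  sv <- svd(A)
  C <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  sv$u %*% C %*% t(sv$v)
}
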