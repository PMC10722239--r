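#' Reduce a morphology to its topological minor
#'
#' Keeps only the soma, the axonal branch nodes (points with two or more
#' axonal children) and the terminal branches: for every axonal leaf the path
#' is backtracked until a branch node (or the soma/axon root) is reached, so
#' path lengths along terminal branches are preserved exactly. Dendrites are
#' excluded.
#'
#' @param m A \code{\link{neuron_morphology}} (at least one axonal point).
#' @return An object of class \code{topological_minor} with fields
#'   \code{soma_point}, \code{branch_nodes} (b x 3), \code{terminal_branches}
#'   (list of point matrices, each running from its branch node, or the
#'   branch origin, to the terminal point), \code{branch_lengths},
#'   \code{terminal_points}, \code{branch_node_terminals} (terminal indices
#'   descending from each branch node), \code{n_points_full} and
#'   \code{n_points_minor}.
#' @export
extract_topological_minor <- function(m) {
  stopifnot(inherits(m, "neuron_morphology"))
  n <- nrow(m$points)
  is_axon <- m$structure == "axon"
  if (!any(is_axon))
    stop("empty-minor error: morphology has no axonal points", call. = FALSE)

  # children counts over axon-to-axon edges
  par <- m$parent
  axon_children <- integer(n)
  edge <- which(is_axon & par > 0L)
  tab <- table(par[edge][is_axon[par[edge]]])
  axon_children[as.integer(names(tab))] <- as.integer(tab)

  terminals <- which(is_axon & axon_children == 0L)
  branch_nodes <- which(is_axon & axon_children >= 2L)
  is_branch <- logical(n)
  is_branch[branch_nodes] <- TRUE

  soma_point <- m$points[m$soma_index, ]

  # Backtrack each terminal to the nearest branch node (or out of the axon).
  branches <- vector("list", length(terminals))
  branch_node_of <- integer(length(terminals))  # 0 = rooted at soma/axon root
  ancestors <- vector("list", length(terminals))
  for (k in seq_along(terminals)) {
    path <- terminals[k]
    i <- par[terminals[k]]
    while (i > 0L && is_axon[i] && !is_branch[i]) {
      path <- c(path, i)
      i <- par[i]
    }
    if (i > 0L && is_axon[i]) {            # stopped at a branch node
      path <- c(path, i)
      branch_node_of[k] <- i
    } else {                               # reached soma/dendrite/root
      path <- c(path, if (i > 0L) i else integer(0))
      branch_node_of[k] <- 0L
    }
    branches[[k]] <- rev(path)
    # full ancestor branch-node set (for branching-width morphometrics)
    anc <- integer(0)
    j <- terminals[k]
    while (j > 0L) {
      if (is_branch[j]) anc <- c(anc, j)
      j <- par[j]
    }
    ancestors[[k]] <- anc
  }

  branch_mats <- lapply(branches, function(idx) m$points[idx, , drop = FALSE])
  branch_lengths <- vapply(branch_mats, function(p) {
    if (nrow(p) < 2L) return(0)
    sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1))

  bnt <- lapply(branch_nodes, function(b)
    which(vapply(ancestors, function(a) b %in% a, logical(1))))
  names(bnt) <- as.character(branch_nodes)

  minor_idx <- unique(c(m$soma_index, branch_nodes, unlist(branches)))
  structure(list(
    neuron_id = m$neuron_id,
    soma_point = as.numeric(soma_point),
    branch_nodes = m$points[branch_nodes, , drop = FALSE],
    branch_node_index = branch_nodes,
    terminal_branches = branch_mats,
    branch_lengths = branch_lengths,
    terminal_points = m$points[terminals, , drop = FALSE],
    terminal_index = terminals,
    branch_node_terminals = bnt,
    n_points_full = n,
    n_points_minor = length(minor_idx)),
    class = "topological_minor")
}

#' @export
print.topological_minor <- function(x, ...) {
  cat(sprintf("<topological_minor> %s: %d branch nodes, %d terminal branches, %d/%d points\n",
              x$neuron_id, nrow(x$branch_nodes), length(x$terminal_branches),
              x$n_points_minor, x$n_points_full))
  invisible(x)
}

#' Axonal point cloud of a topological minor
#'
#' All unique axonal points of the minor (branch nodes plus terminal-branch
#' polyline points; the soma is excluded). This is the cloud used by the CPD
#' dissimilarity.
#'
#' @param t A \code{topological_minor}.
#' @param center_soma If TRUE, subtract the soma position so the cloud is
#'   soma-centered at the origin.
#' @return A numeric n x 3 matrix.
#' @export
minor_points <- function(t, center_soma = FALSE) {
  p <- unique(rbind(t$branch_nodes, do.call(rbind, t$terminal_branches)))
  if (center_soma) p <- sweep(p, 2L, t$soma_point)
  unname(p)
}

#' Morphometrics of a topological minor
#'
#' Computes the measures used by the gradient analysis: number of branch
#' points, mean radial distance (mean Euclidean soma-to-terminal distance),
#' mean branching width (per branch node, the maximum pairwise distance among
#' the terminal points descending from it; averaged over branch nodes — a
#' rotation-invariant reading of the pictured horizontal-extent bar), total
#' terminal-branch path length and terminal count. Duplicate terminal points
#' (zero-length final segments) are deduplicated before averaging.
#'
#' @param t A \code{topological_minor}.
#' @return A one-row data.frame with columns \code{neuron_id},
#'   \code{n_branch_points}, \code{mean_radial_distance},
#'   \code{mean_branch_width}, \code{total_terminal_length},
#'   \code{n_terminals}.
#' @export
morphometrics <- function(t) {
  stopifnot(inherits(t, "topological_minor"))
  term <- unique(t$terminal_points)
  radial <- sqrt(rowSums(sweep(term, 2L, t$soma_point)^2))
  widths <- vapply(t$branch_node_terminals, function(idx) {
    pts <- unique(t$terminal_points[idx, , drop = FALSE])
    if (nrow(pts) < 2L) return(0)
    max(dist(pts))
  }, numeric(1))
  data.frame(neuron_id = t$neuron_id,
             n_branch_points = nrow(t$branch_nodes),
             mean_radial_distance = mean(radial),
             mean_branch_width = if (length(widths)) mean(widths) else 0,
             total_terminal_length = sum(t$branch_lengths),
             n_terminals = length(t$terminal_branches),
             stringsAsFactors = FALSE)
}

#' Morphometric table for a set of minors
#'
#' @param minors List of \code{topological_minor} objects.
#' @param path Optional TSV output path (one row per neuron).
#' @return A data.frame of per-neuron morphometrics.
#' @export
morphometric_table <- function(minors, path = NULL) {
  tab <- do.call(rbind, lapply(minors, morphometrics))
  rownames(tab) <- NULL
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
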