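#' Embed a dissimilarity matrix in two dimensions with t-SNE
#'
#' Runs exact t-SNE in precomputed-distance mode on a symmetric,
#' zero-diagonal dissimilarity matrix. Bit-reproducible for a fixed seed.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal and neuron ids
#'   as dimnames.
#' @param perplexity t-SNE perplexity; must be smaller than the number of
#'   neurons.
#' @param seed Seed for the random initialization.
#' @param max_iter Gradient-descent iterations.
#' @return n x 2 coordinate matrix with the input rownames.
#' @export
embed_tsne <- function(D, perplexity = 30, seed = 0L, max_iter = 1000L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D))))
    stop("D must be a symmetric square matrix", call. = FALSE)
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal", call. = FALSE)
  if (perplexity >= n)
    stop("parameter error: perplexity must be smaller than the number of neurons",
         call. = FALSE)
  Y <- .tsne_embed(D, perplexity, seed, max_iter = max_iter)
  rownames(Y) <- rownames(D)
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}

#' Geodesic gradient index on a 2-D embedding
#'
#' Builds a k-nearest-neighbor graph on the embedding coordinates with
#' Euclidean edge weights (k grown until the graph is connected), computes
#' the shortest-path distance of every neuron from the root point, and
#' normalizes by the maximum so indices lie in [0, 1] with the root at 0.
#'
#' @param coords n x 2 embedding with neuron ids as rownames.
#' @param root_id Neuron id of the root point.
#' @param k Initial neighbor count.
#' @return Named numeric vector of gradient indices in [0, 1]; the
#'   \code{"k"} attribute records the neighbor count actually used.
#' @export
gradient_index <- function(coords, root_id, k = 10) {
  n <- nrow(coords)
  if (n < 2L) stop("gradient index undefined for fewer than 2 neurons",
                   call. = FALSE)
  ids <- rownames(coords)
  if (!root_id %in% ids) stop("root_id not among neurons", call. = FALSE)
  dm <- as.matrix(dist(coords))
  k <- min(max(1L, as.integer(k)), n - 1L)
  repeat {
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- order(dm[i, ])[2:(k + 1L)]
      cbind(i, nb)
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::E(g)$weight <- dm[edges]
    g <- igraph::simplify(g, edge.attr.comb = "first")
    if (igraph::components(g)$no == 1L || k >= n - 1L) break
    k <- k + 1L
  }
  d <- as.numeric(igraph::distances(g, v = match(root_id, ids)))
  idx <- d / max(d)
  names(idx) <- ids
  attr(idx, "k") <- k
  idx
}

#' Select the gradient root neuron
#'
#' Among neurons whose dominant projection target is the barrel cortex, the
#' one with the most dorsal soma (smallest superior-inferior coordinate);
#' depth ties are broken by the lexicographically smaller id. If no neuron
#' is barrel-dominant, falls back (with a warning) to the embedding point
#' farthest from the embedding centroid.
#'
#' @param coords n x 2 embedding with ids as rownames.
#' @param profiles List of \code{projection_profile} objects (same neurons).
#' @param somata n x 3 matrix of soma positions in PIR micrometers.
#' @param barrel_area Dominant-target acronym defining the root pool.
#' @return A neuron id.
#' @export
select_root <- function(coords, profiles, somata, barrel_area = "SSp-bfd") {
  ids <- rownames(coords)
  dom <- vapply(profiles, function(p) as.character(p$dominant_target),
                character(1))
  pool <- which(dom %in% barrel_area)
  if (!length(pool)) {
    warning("no ", barrel_area,
            "-dominant neuron; falling back to the extremal embedding point",
            call. = FALSE)
    cen <- colMeans(coords)
    return(ids[which.max(rowSums(sweep(coords, 2L, cen)^2))])
  }
  depth <- somata[pool, 2L]
  cand <- pool[depth == min(depth)]
  ids[cand[order(ids[cand])][1L]]
}

#' Partition the embedding into morphological types
#'
#' Agglomerative (Ward) clustering of the 2-D embedding cut at k clusters;
#' labels are renumbered so the mean gradient index increases with the label.
#'
#' @param coords n x 2 embedding.
#' @param k Number of clusters.
#' @param gradient Optional gradient indices used to order the labels.
#' @param linkage \code{hclust} linkage method.
#' @return Integer labels 1..k, named by neuron id.
#' @export
cluster_types <- function(coords, k = 3, gradient = NULL,
                          linkage = "ward.D2") {
  n <- nrow(coords)
  if (n < k) stop("parameter error: fewer neurons than clusters", call. = FALSE)
  lab <- cutree(hclust(dist(coords), method = linkage), k = k)
  if (!is.null(gradient)) {
    mg <- vapply(seq_len(k), function(cl) mean(gradient[lab == cl]),
                 numeric(1))
    lab <- match(lab, order(mg))
  }
  names(lab) <- rownames(coords)
  lab
}

#' Spearman correlation of the gradient with a morphometric
#'
#' @param indices Gradient indices.
#' @param values Morphometric values, same length and order.
#' @return List with \code{r}, \code{p} and \code{constant} (TRUE when the
#'   correlation is undefined because an input is constant).
#' @export
correlate_gradient <- function(indices, values) {
  stopifnot(length(indices) == length(values), length(indices) >= 3L)
  if (stats::sd(values) == 0 || stats::sd(indices) == 0) {
    warning("constant input; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, constant = TRUE))
  }
  ct <- suppressWarnings(cor.test(indices, values, method = "spearman",
                                  exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, constant = FALSE)
}

#' Fit soma coordinates to the morphological gradient
#'
#' Ordinary least squares of the gradient index on the superior-inferior and
#' left-right soma coordinates (with intercept); the MSE is the mean squared
#' residual of the unitless 0-1 gradient.
#'
#' @param somata n x 2 matrix (superior-inferior, left-right) in micrometers.
#' @param indices Gradient indices.
#' @return List with \code{coefficients}, \code{mse} and the \code{lm} fit;
#'   a rank-deficient design sets \code{degenerate = TRUE}.
#' @export
fit_soma_to_gradient <- function(somata, indices) {
  stopifnot(nrow(somata) == length(indices), nrow(somata) >= 3L)
  df <- data.frame(g = indices, si = somata[, 1L], lr = somata[, 2L])
  fit <- lm(g ~ si + lr, data = df)
  list(coefficients = stats::coef(fit),
       mse = mean(resid(fit)^2),
       degenerate = fit$rank < 3L,
       fit = fit)
}

#' Order projection motifs along the gradient
#'
#' @param profiles List of \code{projection_profile} objects.
#' @param indices Gradient indices named by neuron id (or in profile order).
#' @param min_terminal_branches Motif threshold.
#' @return data.frame of motifs with member count and mean gradient index,
#'   sorted by ascending mean gradient.
#' @export
motifs_along_gradient <- function(profiles, indices,
                                  min_terminal_branches = 5) {
  keys <- vapply(profiles, function(p)
    .motif_key(extract_motif(p, min_terminal_branches)), character(1))
  ids <- vapply(profiles, `[[`, character(1), "neuron_id")
  g <- if (!is.null(names(indices))) indices[ids] else indices
  agg <- stats::aggregate(list(mean_gradient = g), by = list(motif = keys),
                          FUN = mean)
  agg$n <- as.integer(table(keys)[agg$motif])
  agg[order(agg$mean_gradient), c("motif", "n", "mean_gradient")]
}
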