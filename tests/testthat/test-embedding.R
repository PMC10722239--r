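# small dissimilarity matrix with two well-separated groups
two_cluster_D <- function(n1 = 8, n2 = 8, gap = 100, seed = 1) {
  with_seed <- get("with_seed", asNamespace("axonmap"))
  x <- with_seed(seed, c(rnorm(n1, 0, 1), rnorm(n2, gap, 1)))
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("n", seq_len(n1 + n2)),
                      paste0("n", seq_len(n1 + n2)))
  D
}

test_that("t-SNE embedding is deterministic for a fixed seed", {
  D <- two_cluster_D()
  c1 <- embed_tsne(D, perplexity = 5, seed = 3)
  c2 <- embed_tsne(D, perplexity = 5, seed = 3)
  expect_identical(c1, c2)
  expect_equal(rownames(c1), rownames(D))
})

test_that("t-SNE separates well-separated clusters (positive silhouette)", {
  D <- two_cluster_D()
  co <- embed_tsne(D, perplexity = 5, seed = 0)
  g <- rep(1:2, each = 8)
  de <- as.matrix(dist(co))
  sil <- vapply(1:16, function(i) {
    a <- mean(de[i, g == g[i]][-which(which(g == g[i]) == i)])
    b <- mean(de[i, g != g[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("four mutually equidistant items embed near-symmetrically", {
  # in 2-D the symmetric optimum is a square: four equal sides, two equal
  # diagonals, ratio sqrt(2); every distance is then within 25% of the mean
  D <- matrix(1, 4, 4) - diag(4)
  dimnames(D) <- list(letters[1:4], letters[1:4])
  co <- embed_tsne(D, perplexity = 2, seed = 1, max_iter = 2000)
  d <- sort(as.numeric(dist(co)))
  sides <- d[1:4]; diags <- d[5:6]
  expect_lt(diff(range(sides)) / mean(sides), 0.05)
  expect_lt(diff(range(diags)) / mean(diags), 0.05)
  expect_equal(mean(diags) / mean(sides), sqrt(2), tolerance = 0.05)
  expect_lt(max(abs(d - mean(d))) / mean(d), 0.25 * 1.1)
})

test_that("perplexity must be below the number of neurons", {
  D <- two_cluster_D(3, 3)
  expect_error(embed_tsne(D, perplexity = 6), "parameter error")
  expect_error(embed_tsne(D[, 1:5], perplexity = 2), "symmetric")
})

test_that("gradient indices on a line equal the normalized positions", {
  co <- cbind(0:9, rep(0, 10))
  rownames(co) <- paste0("n", 1:10)
  g <- gradient_index(co, "n1", k = 2)
  expect_equal(as.numeric(g), (0:9) / 9)
  expect_equal(unname(g["n1"]), 0)
})

test_that("gradient indices equal an all-pairs shortest-path oracle", {
  with_seed <- get("with_seed", asNamespace("axonmap"))
  co <- with_seed(5, matrix(rnorm(40), 20, 2))
  rownames(co) <- paste0("n", 1:20)
  g <- gradient_index(co, "n3", k = 4)
  k <- attr(g, "k")
  # oracle: rebuild the same graph and run Dijkstra from scratch
  dm <- as.matrix(dist(co))
  adj <- matrix(FALSE, 20, 20)
  for (i in 1:20) adj[i, order(dm[i, ])[2:(k + 1)]] <- TRUE
  adj <- adj | t(adj)
  w <- ifelse(adj, dm, Inf)
  dist0 <- rep(Inf, 20); dist0[3] <- 0; done <- rep(FALSE, 20)
  for (step in 1:20) {
    u <- which.min(replace(dist0, done, Inf)); done[u] <- TRUE
    dist0 <- pmin(dist0, dist0[u] + w[u, ])
  }
  expect_equal(as.numeric(g), dist0 / max(dist0), tolerance = 1e-9)
})

test_that("the root is the most dorsal barrel-dominant neuron", {
  co <- cbind(1:4, 1:4); rownames(co) <- c("a", "b", "c", "d")
  profs <- list(make_profile(c("SSp-bfd" = 9), id = "a"),
                make_profile(c("SSp-bfd" = 9), id = "b"),
                make_profile(c("SSp-m" = 9), id = "c"),
                make_profile(c("SSp-m" = 9), id = "d"))
  som <- rbind(c(0, 500, 0), c(0, 300, 0), c(0, 100, 0), c(0, 900, 0))
  expect_equal(select_root(co, profs, som), "b")   # smallest SI among bfd
  # depth tie broken by lexicographically smaller id
  som[1, 2] <- 300
  expect_equal(select_root(co, profs, som), "a")
  # no barrel-dominant neuron: extremal fallback with a warning
  profs2 <- profs[c(3, 4, 3, 4)]
  expect_warning(r <- select_root(co, profs2, som), "extremal")
  expect_true(r %in% rownames(co))
  # single neuron
  expect_equal(select_root(co[1, , drop = FALSE], profs[1],
                           som[1, , drop = FALSE]), "a")
})

test_that("morphological types recover separated blobs and order by gradient", {
  with_seed <- get("with_seed", asNamespace("axonmap"))
  co <- with_seed(4, rbind(matrix(rnorm(20, 0, .3), 10),
                           matrix(rnorm(20, 10, .3), 10),
                           matrix(rnorm(20, 20, .3), 10)))
  rownames(co) <- paste0("n", 1:30)
  g <- seq(0, 1, length.out = 30)
  lab <- cluster_types(co, k = 3, gradient = g)
  expect_equal(unname(lab), rep(1:3, each = 10))
  mg <- tapply(g, lab, mean)
  expect_true(all(diff(mg) > 0))
  expect_equal(unname(cluster_types(co, k = 1)), rep(1L, 30))
  expect_error(cluster_types(co[1:2, ], k = 3), "parameter error")
})

test_that("gradient correlation handles monotone, reversed and constant input", {
  g <- seq(0, 1, length.out = 20)
  expect_equal(correlate_gradient(g, g^3 + 2)$r, 1)
  expect_equal(correlate_gradient(g, rev(g))$r, -1)
  expect_warning(out <- correlate_gradient(g, rep(2, 20)), "constant")
  expect_true(out$constant)
})

test_that("the soma-to-gradient fit matches the normal equations", {
  with_seed <- get("with_seed", asNamespace("axonmap"))
  som <- with_seed(8, matrix(runif(40, 0, 1000), 20, 2))
  g <- 0.2 + 0.0005 * som[, 1] - 0.0002 * som[, 2]
  fit <- fit_soma_to_gradient(som, g)
  expect_lt(fit$mse, 1e-20)
  gn <- g + with_seed(9, rnorm(20, 0, 0.05))
  fit <- fit_soma_to_gradient(som, gn)
  X <- cbind(1, som)
  beta <- solve(t(X) %*% X, t(X) %*% gn)
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-9)
  # permuted indices: mse near the variance of the indices
  gp <- with_seed(10, sample(gn))
  expect_gt(fit_soma_to_gradient(som, gp)$mse,
            0.3 * mean((gp - mean(gp))^2))
})

test_that("motifs are ordered by their mean gradient index", {
  profs <- list(make_profile(c(A = 9), id = "1"),
                make_profile(c(A = 9), id = "2"),
                make_profile(c(A = 9, B = 6), id = "3"),
                make_profile(c(A = 9, B = 6), id = "4"),
                make_profile(c(B = 9), id = "5"))
  idx <- c("1" = 0.1, "2" = 0.2, "3" = 0.8, "4" = 0.6, "5" = 0.4)
  out <- motifs_along_gradient(profs, idx)
  expect_equal(out$motif, c("A", "B", "A - B"))
  expect_equal(out$mean_gradient, c(0.15, 0.4, 0.7))
  one <- motifs_along_gradient(profs[1], idx[1])
  expect_equal(nrow(one), 1L)
})
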