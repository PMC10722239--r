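cloud_fixture <- function(n = 120, seed = 1) {
  with_seed <- get("with_seed", asNamespace("axonmap"))
  with_seed(seed, {
    p <- matrix(rnorm(n * 3, sd = 150), n, 3)
    p %*% diag(c(1, 0.6, 0.3)) + rep(c(50, -30, 20), each = n)
  })
}

test_that("self-alignment returns the identity and near-zero MSE", {
  X <- cloud_fixture()
  res <- cpd_rigid_rotation(X, X)
  expect_lt(rotation_angle_deg(res$rotation), 0.01)
  expect_lt(res$mse, 1e-6)
  expect_equal(res$correspondence, seq_len(nrow(X)))
})

test_that("a known rotation is recovered and matches the Kabsch oracle", {
  X <- cloud_fixture(200, seed = 5)
  Rtrue <- rotation_from_euler(c(0, 25, 0))     # 25 deg about the SI axis
  Y <- X %*% t(Rtrue)                           # moving = rotated reference
  res <- cpd_rigid_rotation(Y, X)
  # CPD maps moving back onto the reference: expect the inverse rotation
  expect_lt(rotation_angle_deg(res$rotation, t(Rtrue)), 1)
  expect_lt(res$mse, 1)
  # closed-form orthogonal Procrustes with known correspondences
  Rk <- kabsch(Y, X)
  expect_lt(rotation_angle_deg(res$rotation, Rk), 1)
})

test_that("E-step responsibilities equal hand-enumerated Gaussian posteriors", {
  X <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 12, 0))
  Y <- rbind(c(1, 1, 0), c(9, -1, 2), c(0, 10, 3), c(4, 4, 4))
  for (w in c(0, 0.3)) {
    s2 <- 20
    P <- cpd_estep(Y, X, sigma2 = s2, w = w)
    M <- nrow(Y); N <- nrow(X)
    for (n in seq_len(N)) {
      g <- vapply(seq_len(M), function(m)
        exp(-sum((X[n, ] - Y[m, ])^2) / (2 * s2)), numeric(1))
      c0 <- (2 * pi * s2)^1.5 * (w / (1 - w)) * M / N
      for (m in seq_len(M))
        expect_equal(P[m, n], g[m] / (sum(g) + c0), tolerance = 1e-10)
    }
  }
})

test_that("the EM objective is non-increasing and rotations stay proper", {
  X <- cloud_fixture(80, seed = 3)
  Y <- cloud_fixture(90, seed = 4)
  res <- cpd_rigid_rotation(Y, X)
  expect_true(all(diff(res$nll) <= 1e-6))
  expect_equal(t(res$rotation) %*% res$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(res$rotation), 1, tolerance = 1e-8)
})

test_that("degenerate clouds are rejected", {
  expect_error(cpd_rigid_rotation(rbind(c(1, 1, 1)), cloud_fixture()),
               "at least 3 points")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(cpd_rigid_rotation(line, cloud_fixture()), "rank < 2")
})

test_that("dissimilarity is invariant to rotation and point order", {
  fp <- make_fixture_pair("identical", seed = 6)
  a <- extract_topological_minor(fp$a)
  expect_lt(pair_dissimilarity(a, a), 1e-6)

  fr <- make_fixture_pair("rotated", params = list(angle_deg = 25), seed = 6)
  b <- extract_topological_minor(fr$b)
  expect_lt(pair_dissimilarity(extract_topological_minor(fr$a), b), 1)

  # relabeling the point order leaves the dissimilarity unchanged
  a2 <- a
  perm <- with_seed(2, sample(nrow(minor_points(a))))
  # permute branch list order (the cloud is the union of branch points)
  a2$terminal_branches <- rev(a2$terminal_branches)
  expect_equal(pair_dissimilarity(a, a2), pair_dissimilarity(a, a),
               tolerance = 1e-6)
})

test_that("isotropic jitter produces the expected noise floor", {
  for (sn in c(2, 8)) {
    fp <- make_fixture_pair("noisy", params = list(sigma_um = sn), seed = 11)
    d <- pair_dissimilarity(extract_topological_minor(fp$a),
                            extract_topological_minor(fp$b))
    expect_gt(d, 3 * sn^2 / 2)
    expect_lt(d, 2 * 3 * sn^2)
  }
})

test_that("the dissimilarity matrix is symmetric with a zero diagonal", {
  pop <- generate_population(5, seed = 19)
  minors <- lapply(pop$morphologies, extract_topological_minor)
  minors <- c(minors, minors[1])                # duplicated neuron
  D <- dissimilarity_matrix(minors)
  expect_equal(D, t(D), tolerance = 1e-9)
  expect_equal(diag(D), setNames(rep(0, 6),
                                 vapply(minors, `[[`, "", "neuron_id")))
  expect_lt(D[1, 6], 1e-6)                      # duplicate pair ~ 0
  # entries equal independent pair calls after symmetrization
  d12 <- pair_dissimilarity(minors[[1]], minors[[2]])
  d21 <- pair_dissimilarity(minors[[2]], minors[[1]])
  expect_equal(D[1, 2], (d12 + d21) / 2, tolerance = 1e-9)
})

test_that("nearest-neuron search equals the brute-force minimum", {
  pop <- generate_population(6, seed = 23)
  minors <- lapply(pop$morphologies, extract_topological_minor)
  q <- minors[[1]]
  # a rotated copy of the query must win with ~0 MSE
  rot <- q
  R <- rotation_from_euler(c(0, 40, 0))
  shift <- function(p) sweep(sweep(p, 2, q$soma_point) %*% t(R), 2,
                             q$soma_point, "+")
  rot$branch_nodes <- shift(rot$branch_nodes)
  rot$terminal_branches <- lapply(rot$terminal_branches, shift)
  rot$terminal_points <- shift(rot$terminal_points)
  rot$neuron_id <- "rotcopy"
  coll <- c(minors[-1], list(rot))
  hit <- nearest_neuron(q, coll)
  expect_equal(hit$neuron_id, "rotcopy")
  expect_lt(hit$mse, 1)
  mses <- vapply(coll, function(cand) pair_dissimilarity(q, cand), numeric(1))
  expect_equal(hit$index, which.min(mses))
  # singleton collection returns the query itself
  self <- nearest_neuron(q, list(q))
  expect_equal(self$neuron_id, q$neuron_id)
  expect_lt(self$mse, 1e-6)
})

test_that("subsampling caps the pairwise cost deterministically", {
  X <- cloud_fixture(300, seed = 9)
  cfg <- cpd_config(max_points = 100, seed = 7)
  r1 <- cpd_rigid_rotation(X, X, cfg)
  r2 <- cpd_rigid_rotation(X, X, cfg)
  expect_equal(r1$n_moving, 100L)
  expect_identical(r1$mse, r2$mse)
})
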