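test_that("a minimal SWC chain parses into the expected point/line arrays", {
  m <- read_swc(write_swc3())
  expect_equal(nrow(m$points), 3L)
  expect_equal(m$soma_index, 1L)
  expect_equal(m$structure, c("soma", "axon", "axon"))
  expect_equal(m$parent, c(0L, 1L, 2L))
  expect_equal(m$points[, 3L], c(0, 100, 200))
})

test_that("SWC write/read round trip reproduces the record set", {
  m <- random_tree(60, seed = 4)
  p <- tempfile(fileext = ".swc")
  write_swc(m, p)
  m2 <- read_swc(p, neuron_id = m$neuron_id)
  expect_equal(m2$points, m$points, tolerance = 1e-8)
  expect_equal(m2$structure, m$structure)
  expect_equal(m2$parent, m$parent)
})

test_that("malformed and structurally invalid SWC files are rejected", {
  p <- write_swc3(lines = c("1 1 0 0 0 5", "2 2 0 0 1 1 1"))
  expect_error(read_swc(p), "line 1")
  p <- write_swc3(lines = c("1 1 0 0 0 5 -1", "2 1 0 0 9 5 -1"))
  expect_error(read_swc(p), "multiple roots")
  p <- write_swc3(lines = c("1 1 0 0 0 5 -1", "2 2 0 0 9 1 99"))
  expect_error(read_swc(p), "parent id")
  expect_warning(
    read_swc(write_swc3(lines = c("1 1 0 0 0 5 -1", "2 7 0 0 9 1 1"))),
    "mapped to dendrite")
})

test_that("JSON dialect round trips and matches the SWC reading", {
  m <- read_swc(write_swc3())
  pj <- tempfile(fileext = ".json")
  write_json_morphology(m, pj)
  mj <- read_json_morphology(pj)
  expect_equal(mj$points, m$points)
  expect_equal(mj$structure, m$structure)
  expect_equal(mj$parent, m$parent)

  # arbitrary tree round trip
  m <- random_tree(40, seed = 2)
  write_json_morphology(m, pj)
  mj <- read_json_morphology(pj)
  expect_equal(mj$points, m$points, tolerance = 1e-12)
  expect_equal(mj$parent, m$parent)
})

test_that("JSON dialect errors on missing keys and bad indices", {
  pj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "x", points = list(c(0, 0, 0))), pj,
                       auto_unbox = TRUE)
  expect_error(read_json_morphology(pj), "format error")
  jsonlite::write_json(
    list(id = "x",
         points = rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
         lines = rbind(c(1, 0, -1), c(2, 1, 0), c(2, 99, 1))),
    pj, auto_unbox = TRUE)
  expect_error(read_json_morphology(pj), "structural error")
})

test_that("LIP sources are swapped and reflected into PIR micrometers", {
  m <- neuron_morphology("lip", rbind(c(100, 200, 300), c(0, 0, 0)),
                         c("soma", "axon"), c(0L, 1L),
                         space = space_spec("LIP", 1))
  m2 <- to_ccf_pir(m)
  expect_equal(m2$points[1L, ], c(300, 200, 11400 - 100))
  expect_equal(m2$space$orientation, "PIR")

  # PIR input at 1 um is unchanged, and the conversion is idempotent
  mp <- neuron_morphology("pir", rbind(c(300, 200, 11300), c(0, 0, 0)),
                          c("soma", "axon"), c(0L, 1L),
                          space = space_spec("PIR", 1))
  expect_equal(to_ccf_pir(mp)$points, mp$points)
  expect_equal(to_ccf_pir(to_ccf_pir(m))$points, m2$points)

  expect_error(to_ccf_pir(m, space_spec("RAS", 1)), "configuration error")
})

test_that("micrometer points map to 10-um voxel indices by flooring", {
  expect_equal(um_to_voxel(c(300, 200, 11300), 10)[1, ], c(30L, 20L, 1130L))
  expect_equal(um_to_voxel(c(9.99, 10, 0), 10)[1, ], c(0L, 1L, 0L))
})

test_that("orientation normalization preserves pairwise distances", {
  m <- random_tree(50, seed = 6)
  m$space <- space_spec("LIP", 2)   # 2 um per unit
  m2 <- to_ccf_pir(m)
  d1 <- dist(m$points) * 2
  d2 <- dist(m2$points)
  expect_equal(as.numeric(d2), as.numeric(d1), tolerance = 1e-9)
})

test_that("morphology validation enforces the tree invariants", {
  expect_error(
    neuron_morphology("x", rbind(c(0, 0, 0), c(1, 1, 1)),
                      c("soma", "axon"), c(0L, 0L)),
    "exactly one root")
  expect_error(
    neuron_morphology("x", rbind(c(0, 0, 0), c(1, 1, 1)),
                      c("soma", "axon"), c(0L, 5L)),
    "dangling parent")
  expect_error(
    neuron_morphology("x", rbind(c(0, 0, 0), c(1, 1, 1)),
                      c("axon", "axon"), c(0L, 1L)),
    "soma")
  # parent-after-child order is repaired, not rejected
  m <- neuron_morphology("x", rbind(c(0, 0, 100), c(0, 0, 0)),
                         c("axon", "soma"), c(2L, 0L))
  expect_true(all(m$parent < seq_len(2L)))
})
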