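test_that("terminal branches accrue their full path length to the area of their endpoint", {
  a <- two_area_atlas(split_um = 200)
  # two branches of 120 um each ending in area A (z < 200)
  m <- neuron_morphology(
    "n1",
    points = rbind(c(150, 150, 350), c(150, 150, 250),
                   c(150, 150, 130), c(150, 150 + 89.4427191, 170)),
    structure = c("soma", "axon", "axon", "axon"),
    parent = c(0L, 1L, 2L, 2L))
  t <- extract_topological_minor(m)
  p <- projection_profile(t, a, c("A", "B"))
  expect_equal(unname(p$area_length_um["A"]), 240)
  expect_equal(unname(p$area_terminal_count["A"]), 2L)
  expect_equal(p$area_layer$length_um[p$area_layer$area == "A"], 240)
  expect_equal(p$dominant_target, "A", ignore_attr = TRUE)
})

test_that("branches ending outside configured areas accrue to other", {
  a <- two_area_atlas(split_um = 200)
  m <- chain_tree(5, step = 30)                 # ends at z=150 inside A
  m$points <- m$points + rep(c(150, 150, 0), each = nrow(m$points))
  t <- extract_topological_minor(m)
  p <- projection_profile(t, a, areas = "B")    # A not configured
  expect_equal(unname(p$area_length_um["other"]), 150)
  expect_equal(unname(p$area_length_um["B"]), 0)
  expect_true(is.na(dominant_target(p)))
})

test_that("profile totals conserve terminal-branch path length", {
  pop <- generate_population(6, seed = 31)
  for (i in seq_along(pop$morphologies)) {
    t <- extract_topological_minor(pop$morphologies[[i]])
    p <- projection_profile(t, pop$atlas, pop$truth$areas)
    expect_equal(sum(p$area_length_um), sum(t$branch_lengths),
                 tolerance = 1e-9)
    expect_equal(sum(p$area_terminal_count), length(t$terminal_branches))
  }
})

test_that("dominant target is the argmax with canonical tie-breaking", {
  p <- make_profile(c("SSp-m" = 10, "SSs" = 5),
                    lengths = c("SSp-m" = 300, "SSs" = 100))
  expect_equal(dominant_target(p), "SSp-m", ignore_attr = TRUE)
  expect_false(attr(dominant_target(p), "tie"))
  p <- make_profile(c("SSp-m" = 10, "SSs" = 10),
                    lengths = c("SSp-m" = 100, "SSs" = 100))
  expect_equal(dominant_target(p), "SSp-m", ignore_attr = TRUE)  # canonical order
  expect_true(attr(dominant_target(p), "tie"))
  # random profiles vs brute-force max scan
  for (s in 1:20) {
    len <- with_seed(s, setNames(runif(4, 1, 100), c("w", "x", "y", "z")))
    p <- make_profile(setNames(rep(5, 4), names(len)), lengths = len)
    expect_equal(dominant_target(p), names(which.max(len)),
                 ignore_attr = TRUE)
  }
})

test_that("motif extraction applies the terminal-branch threshold", {
  p <- make_profile(c(A = 20, B = 7, C = 4))
  expect_equal(extract_motif(p), c("A", "B"))
  expect_equal(extract_motif(make_profile(c(A = 5))), "A")
  expect_equal(extract_motif(make_profile(c(A = 4))), character(0))
  # determinism under permuted input
  p1 <- make_profile(c(A = 9, B = 12, C = 6))
  p2 <- make_profile(c(C = 6, A = 9, B = 12))
  expect_equal(extract_motif(p1), extract_motif(p2))
  # monotonicity: raising the threshold never grows the motif
  for (thr in 1:10)
    expect_true(all(extract_motif(p1, thr + 1) %in% extract_motif(p1, thr)))
})

test_that("order classes map motif size per the published scheme", {
  expect_equal(classify_order(character(0)), "subthreshold")
  expect_equal(classify_order("A"), "monofocal")
  expect_equal(classify_order(c("A", "B")), "bifurcating")
  expect_equal(classify_order(c("A", "B", "C")), "trifurcating")
  expect_equal(classify_order(c("A", "B", "C", "D")), "quadrifurcating")
  expect_equal(classify_order(letters[1:5]), "higher")
})

test_that("focality applies the four-terminal 200-um border rule", {
  a <- two_area_atlas(dims_vox = c(30, 30, 80), split_um = 300)
  # terminals in B at chosen distances beyond the A border (z = 295 center)
  mk <- function(dists) minor_stub(cbind(155, 155, 295 + dists))
  expect_equal(classify_focality(mk(c(250, 260, 300, 270)), a, c("A", "B")),
               "center")
  expect_equal(classify_focality(mk(c(250, 260, 300)), a, c("A", "B")),
               "border")
  expect_equal(classify_focality(mk(c(250, 150, 300, 120)), a, c("A", "B")),
               "border")
  expect_equal(classify_focality(mk(c(250, 260, 300, 270)), a, "A"),
               "not_applicable")
})

test_that("focality labels agree with a brute-force distance check", {
  a <- two_area_atlas(dims_vox = c(30, 30, 80), split_um = 300)
  for (s in 1:10) {
    pts <- with_seed(s, cbind(runif(6, 50, 250), runif(6, 50, 250),
                              runif(6, 310, 700)))
    t <- minor_stub(pts)
    deep <- border_distance(a, pts, "A") > 200
    inB <- label_at(a, pts)$area %in% "B"
    want <- if (sum(deep & inB) >= 4) "center" else "border"
    expect_equal(classify_focality(t, a, c("A", "B")), want)
  }
})

test_that("the census counts unique motifs, classes and fractions", {
  profs <- list(make_profile(c(A = 6), id = "1"),
                make_profile(c(A = 6), id = "2"),
                make_profile(c(A = 9, B = 6), id = "3"),
                make_profile(c(B = 6), id = "4"),
                make_profile(c(A = 9, B = 6), id = "5"))
  cen <- motif_census(profs)
  expect_equal(cen$n, 5L)
  tab <- cen$table
  expect_equal(tab$n[tab$motif == "A"], 2L)
  expect_equal(tab$n[tab$motif == "A - B"], 2L)
  expect_equal(tab$n[tab$motif == "B"], 1L)
  oc <- cen$order_counts
  expect_equal(oc$fraction[oc$order_class == "monofocal"], 0.6)
  expect_equal(oc$fraction[oc$order_class == "bifurcating"], 0.4)
  expect_equal(sum(tab$n), 5L)                    # conservation
  expect_equal(nrow(motif_census(list())$table), 0L)
})

test_that("motif significance follows the exact binomial with Bonferroni", {
  # n = 100, p_A = p_B = 0.5, joint count at expectation -> p ~ 1
  mk_census <- function(joint) {
    nA_only <- 50 - joint; nB_only <- 50 - joint
    profs <- c(
      replicate(joint, make_profile(c(A = 9, B = 6)), simplify = FALSE),
      replicate(nA_only, make_profile(c(A = 9)), simplify = FALSE),
      replicate(nB_only, make_profile(c(B = 9)), simplify = FALSE),
      replicate(100 - joint - nA_only - nB_only,
                make_profile(c(C = 9)), simplify = FALSE))
    motif_census(profs)
  }
  s25 <- motif_significance(mk_census(25), 100)
  expect_gt(s25$p_value[s25$motif == "A - B"], 0.9)
  expect_false(s25$significant[s25$motif == "A - B"])
  s50 <- motif_significance(mk_census(50), 100)
  expect_lt(s50$p_value[s50$motif == "A - B"], 0.001)
  # with a single motif tested, Bonferroni leaves p unchanged
  expect_equal(s50$p_adj, pmin(1, s50$p_value * nrow(s50)))
  expect_equal(s25$p_value[s25$motif == "A - B"],
               binom.test(25, 100, 0.25)$p.value)
})

test_that("layer distributions sum correctly and pick preferred layers", {
  p1 <- make_profile(c("SSp-bfd" = 9))
  p1$area_layer <- data.frame(area = "SSp-bfd", layer = c("L4", "L2/3"),
                              length_um = c(240, 60))
  p1$area_length_um["SSp-bfd"] <- 300
  out <- layer_distribution(list(p1), "SSp-bfd")
  expect_equal(out$totals["SSp-bfd", "L4"], 240)
  expect_equal(out$preferred$layer[out$preferred$rank == 1], "L4")

  # 3-neuron fixture vs hand-computed histogram
  p2 <- make_profile(c("SSp-bfd" = 6, "SSs" = 5))
  p2$area_layer <- data.frame(area = c("SSp-bfd", "SSs"),
                              layer = c("L4", "L5"),
                              length_um = c(100, 80))
  p3 <- make_profile(c("SSp-bfd" = 6))
  p3$area_layer <- data.frame(area = "SSp-bfd", layer = "L2/3",
                              length_um = 50)
  out <- layer_distribution(list(p1, p2, p3), c("SSp-bfd", "SSs"))
  expect_equal(out$totals["SSp-bfd", "L4"], 340)
  expect_equal(out$totals["SSp-bfd", "L2/3"], 110)
  expect_equal(out$totals["SSs", "L5"], 80)
  expect_equal(sum(out$totals), 240 + 60 + 100 + 80 + 50)
})

test_that("the barrel census partitions neurons into the four groups", {
  atlas <- build_toy_atlas(barrels = 4)
  pop <- generate_population(25, seed = 17)
  minors <- lapply(pop$morphologies, extract_topological_minor)
  area_profiles <- lapply(minors, projection_profile, a = pop$atlas,
                          areas = pop$truth$areas)
  barrel_profiles <- lapply(minors, projection_profile, a = atlas,
                            areas = paste0("b", 1:4))
  bc <- barrel_census(area_profiles, barrel_profiles)
  expect_equal(bc$monofocal_single + bc$monofocal_multi +
                 bc$multifocal_single + bc$multifocal_multi, bc$total)
  expect_true(all(bc$total >= 0))
})
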