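test_that("thinning reduces a filled bar to a single 1-px path", {
  bar <- matrix(FALSE, 20, 110)
  bar[8:12, 5:104] <- TRUE
  sk <- skeletonize(bar)
  # independent thinning oracles give 97 px (98 for medial-axis variants)
  # for a 5 x 100 bar: ends erode toward the inscribed-disk centre
  expect_gte(sum(sk), 94)
  expect_lte(sum(sk), 100)
  g <- build_graph(sk)
  expect_identical(nrow(g$branch_points), 0L)
  expect_identical(nrow(g$end_points), 2L)
  expect_length(g$edges, 1L)
  expect_identical(oracle_component_count(sk), 1L)
})

test_that("thinning handles empty, minimal and multi-component masks", {
  empty <- matrix(FALSE, 10, 10)
  expect_identical(skeletonize(empty), empty)
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_identical(skeletonize(one), one)
  # component count is preserved on random blobs
  set.seed(21)
  for (i in 1:5) {
    img <- matrix(runif(48 * 48), 48, 48)
    blob <- mean_blur(img, 3) > 0.52
    sk <- skeletonize(blob)
    expect_identical(oracle_component_count(sk), oracle_component_count(blob))
    # 1-px wide: non-junction pixels have at most 2 neighbours
    deg <- oracle_degree_map(sk)
    expect_true(all(deg[sk] <= 2 | deg[sk] >= 3))
  }
})

test_that("a T-shaped skeleton yields 1 branch point, 3 end points, 3 edges", {
  g <- build_graph(t_mask())
  expect_identical(nrow(g$branch_points), 1L)
  expect_identical(nrow(g$end_points), 3L)
  expect_length(g$edges, 3L)
  expect_true(all(vapply(g$edges, `[[`, logical(1), "spur")))
  # the 20-px stem measures 20 and the 30-px crossbar splits into two
  # edges that, with the junction, cover its 30 pixels
  lens <- sort(vapply(g$edges, `[[`, integer(1), "length"))
  expect_identical(lens, c(14L, 15L, 20L))
  # edge pixels plus junction-cluster pixels partition the skeleton
  covered <- sum(vapply(g$edges, function(e) length(e$del), integer(1))) +
    sum(vapply(g$branch_clusters, nrow, integer(1)))
  expect_identical(as.integer(covered), g$n_pixels)
})

test_that("a straight line is one edge whose length is its pixel count", {
  line <- matrix(FALSE, 10, 60)
  line[5, 6:55] <- TRUE
  g <- build_graph(line)
  expect_identical(nrow(g$branch_points), 0L)
  expect_identical(nrow(g$end_points), 2L)
  expect_length(g$edges, 1L)
  expect_identical(g$edges[[1]]$length, 50L)
})

test_that("a pure cycle is stored as one closed edge", {
  # diamond ring: |dr| + |dc| == 6 is a clean 8-connected cycle
  ring <- matrix(FALSE, 15, 15)
  for (i in 1:15) for (j in 1:15) {
    if (abs(i - 8) + abs(j - 8) == 6) ring[i, j] <- TRUE
  }
  g <- build_graph(ring)
  expect_identical(nrow(g$end_points), 0L)
  expect_identical(nrow(g$branch_points), 0L)
  expect_length(g$edges, 1L)
  expect_true(g$edges[[1]]$closed)
  expect_identical(g$edges[[1]]$length, as.integer(sum(ring)))
})

test_that("spur trimming follows the strict-< rule and the identity at 0", {
  tm <- t_mask(stem_rows = 11:13)  # 3-px spur below the crossbar
  trimmed <- trim_spurs(build_graph(tm), 5L)
  crossbar <- matrix(FALSE, 40, 50); crossbar[10, 10:39] <- TRUE
  expect_identical(trimmed, crossbar)
  # strict <: a 3-px spur survives trim_factor 3
  expect_identical(trim_spurs(build_graph(tm), 3L), tm != 0)
  expect_identical(trim_spurs(build_graph(tm), 0L), tm != 0)
})

test_that("trimming matches the pruning oracle, idempotent and monotone", {
  for (seed in 1:15) {
    sk <- random_skeleton(48L, 48L, n_seg = 8L, seed = seed)
    for (k in c(3L, 6L)) {
      mine <- trim_spurs(build_graph(sk), k)
      expect_identical(mine, oracle_trim(sk, k))
      expect_identical(trim_spurs(build_graph(mine), k), mine)
    }
    t3 <- trim_spurs(build_graph(sk), 3L)
    t6 <- trim_spurs(build_graph(sk), 6L)
    expect_true(all(t3 >= t6))  # larger trim factors remove supersets
  }
})

test_that("auto trim factor uses mode + 1 with ties toward smaller", {
  backbone <- function(runs) {
    m <- matrix(FALSE, 30, 60)
    m[15, 3:58] <- TRUE
    cols <- c(10, 20, 30, 40)
    for (i in seq_along(runs)) m[16:(15 + runs[i]), cols[i]] <- TRUE
    m
  }
  # a vertical run of k pixels below the backbone is a spur of length k
  g <- build_graph(backbone(c(2, 2, 2, 7)))   # spur lengths {2,2,2,7}
  expect_identical(auto_trim_factor(g, 1L, trigger_fraction = 0.05), 3L)
  # trigger not met: the user's value passes through
  expect_identical(auto_trim_factor(g, 1L, trigger_fraction = 0.99), 1L)
  # tie in the mode breaks toward the smaller length
  g2 <- build_graph(backbone(c(2, 2, 5, 5)))  # spur lengths {2,2,5,5}
  expect_identical(auto_trim_factor(g2, 1L, trigger_fraction = 0.05), 3L)
  # no spurs at all: user's trim factor
  line <- matrix(FALSE, 10, 40); line[5, 5:35] <- TRUE
  expect_identical(auto_trim_factor(build_graph(line), 7L), 7L)
})

test_that("commissural removal deletes rungs, spares rails and spurs", {
  lad <- ladder_mask(110L, c(20L, 30L), rung_rows = seq(15, 95, by = 20))
  g <- build_graph(lad)
  out <- remove_commissural(g, keep_length = 15)
  # rails untouched: every rail pixel survives
  expect_true(all(out[, 20]))
  expect_true(all(out[, 30]))
  # rung interiors gone
  expect_false(any(out[seq(15, 95, by = 20), 23:27]))
  # keep_length 0 is the identity
  expect_identical(remove_commissural(build_graph(lad), 0), lad != 0)
  # spans above keep_length are retained
  wide <- ladder_mask(110L, c(20L, 40L), rung_rows = seq(15, 95, by = 25))
  kept <- remove_commissural(build_graph(wide), keep_length = 15)
  expect_identical(kept, wide != 0)
  # spur edges are never removed by this operation
  spurred <- lad
  spurred[50, 15:19] <- TRUE  # 5-px spur off the left rail
  out2 <- remove_commissural(build_graph(spurred), keep_length = 15)
  expect_true(all(out2[50, 15:19]))
})

test_that("graph + thinning recover the arc length of clean networks", {
  for (topo in c("parallel", "reticulate")) {
    spec <- vein_spec(topo, image_height = 400L, image_width = 400L,
                      n_primaries = 3L, rail_spacing_px = 110,
                      waviness_amplitude_px = 5,
                      commissural_spacing_px = 130,
                      stroke_width_px = 5L, noise_sd = 0,
                      illumination_gradient = 0, seed = 1L)
    gen <- generate_veins(spec)
    mask <- gen$image < (spec$background_level + spec$vein_level) / 2
    g <- build_graph(skeletonize(mask))
    total <- sum(vapply(g$edges, `[[`, numeric(1), "length")) +
      sum(vapply(g$branch_clusters, nrow, integer(1)))
    arc_px <- gen$ground_truth_length_um / spec$pixel_length_um
    expect_lt(abs(total - arc_px) / arc_px, 0.05)
  }
})
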