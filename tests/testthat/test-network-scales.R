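test_that("Strahler orders follow the confluence rule on hand-built networks", {
  # two order-1 tributaries joining -> order 2 downstream
  y <- make_y_net()
  ords <- setNames(y$segments$strahler, y$segments$id)
  expect_equal(unname(ords[c("s2", "s3")]), c(1L, 1L))
  expect_equal(unname(ords[["s1"]]), 2L)
  # a chain stays order 1 (single inflow never increments)
  ch <- make_chain_net()
  expect_true(all(ch$segments$strahler == 1L))
  # order-1 joining order-2 -> still order 2: Y with one arm extended
  seg <- data.frame(id = c("s1", "s2", "s3", "s4", "s5"),
                    downstream_id = c(NA, "s1", "s1", "s2", "s2"),
                    length_m = rep(500, 5), stringsAsFactors = FALSE)
  seg$polyline <- list(rbind(c(0, 0), c(0, 500)),
                       rbind(c(0, 500), c(-354, 854))[, , drop = FALSE],
                       rbind(c(0, 500), c(354, 854)),
                       rbind(c(-354, 854), c(-354, 1354)),
                       rbind(c(-354, 854), c(-708, 1208)))
  # fix polyline lengths to match 500 exactly
  seg$polyline <- lapply(seq_len(5), function(i) {
    pl <- seg$polyline[[i]]
    d <- pl[2, ] - pl[1, ]
    rbind(pl[1, ], pl[1, ] + d / sqrt(sum(d^2)) * 500)
  })
  net <- compute_strahler(river_network(seg))
  ords <- setNames(net$segments$strahler, net$segments$id)
  expect_equal(unname(ords[["s2"]]), 2L)  # s4 + s5 (both order 1)
  expect_equal(unname(ords[["s1"]]), 2L)  # order 2 joined by order 1 (s3)
  # perfect binary tree with 64 headwaters -> outlet order 7
  bal <- make_balanced_net(7)
  expect_equal(bal$segments$strahler[1], 7L)
})

test_that("Strahler orders match the recursive oracle on random trees", {
  for (s in 1:12) {
    net <- random_net(seed = 100 + s)
    expect_equal(net$segments$strahler, strahler_oracle(net))
  }
})

test_that("cycles are rejected with the offending chain named", {
  seg <- data.frame(id = c("a", "b", "c"),
                    downstream_id = c("c", "a", "b"),
                    length_m = rep(100, 3), stringsAsFactors = FALSE)
  seg$polyline <- lapply(1:3, function(i) rbind(c(0, 0), c(0, 100)))
  expect_error(river_network(seg), "cycle")
})

test_that("width model and buffer half-width follow the stated rule", {
  expect_equal(buffer_halfwidth(1, c(`1` = 2)), 101)
  expect_equal(buffer_halfwidth(5, c(`5` = 40)), 520)
  expect_equal(buffer_halfwidth(11, c(`11` = 800)), 1500)
  # constant functional model
  expect_equal(predicted_width(3, function(o) 10), 10)
  # default table is non-decreasing over its domain
  w <- predicted_width(1:11)
  expect_true(all(diff(w) >= 0))
  expect_true(all(diff(buffer_halfwidth(1:11)) > 0))
  expect_error(predicted_width(12), "not defined")
})

test_that("upstream reach walks the channel and branches at confluences", {
  # single long segment, site at the downstream end
  ch <- make_chain_net(lengths = 5000)
  r <- upstream_reach(ch, site_position("a", "s1", 0), 1000)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$from_m, r$to_m), c(0, 1000))
  # site at a confluence of two 600-m headwaters, 1000-m budget covers both
  y <- make_y_net(len1 = 1000, len2 = 600, len3 = 600)
  r2 <- upstream_reach(y, site_position("a", "s1", 800), 1000)
  r2 <- r2[order(r2$segment_id), ]
  expect_equal(r2$segment_id, c("s1", "s2", "s3"))
  expect_equal(r2$to_m - r2$from_m, c(200, 600, 600))
})

test_that("upstream reach matches the distance-walk oracle on random trees", {
  set.seed(77)
  for (s in 1:10) {
    net <- random_net(seed = 200 + s)
    seg <- net$segments
    i <- sample(nrow(seg), 1)
    site <- site_position("x", seg$id[i], runif(1, 0, seg$length_m[i]))
    r <- upstream_reach(net, site, 1e4)
    r <- r[order(r$segment_id), ]
    o <- reach_oracle(net, site, 1e4)
    expect_equal(r$segment_id, o$segment_id)
    expect_equal(r$from_m, o$from_m, tolerance = 1e-9)
    expect_equal(r$to_m, o$to_m, tolerance = 1e-9)
  }
})

test_that("reach sets are nested and buffer areas non-decreasing across scales", {
  study <- get_shared_study()
  net <- study$network
  set.seed(9)
  for (k in 1:4) {
    i <- sample(nrow(net$segments), 1)
    site <- site_position("x", net$segments$id[i],
                          runif(1, 0, net$segments$length_m[i]))
    r1 <- upstream_reach(net, site, 1e3)
    r10 <- upstream_reach(net, site, 1e4)
    r100 <- upstream_reach(net, site, 1e5)
    tot <- function(r) sum(r$to_m - r$from_m)
    expect_lte(tot(r1), tot(r10))
    expect_lte(tot(r10), tot(r100))
    # nesting: every 1-km portion lies inside a 10-km portion
    for (p in seq_len(nrow(r1))) {
      m <- r10[r10$segment_id == r1$segment_id[p], ]
      expect_true(any(m$from_m <= r1$from_m[p] + 1e-9 &
                      m$to_m >= r1$to_m[p] - 1e-9))
    }
    areas <- vapply(upstream_scales(net, site)[c("1km", "10km", "100km")],
                    function(sp) sp$area_km2, 0)
    expect_true(all(diff(areas) >= -1e-9))
  }
})

test_that("corridor polygons have the exact rectangle area on straight portions", {
  # straight 1000-m order-1 segment, width 2 m -> area 1000 x 2*101
  ch <- make_chain_net(lengths = 1000)
  r <- upstream_reach(ch, site_position("a", "s1", 0), 1000)
  bp <- reach_buffer_polygon(ch, r, width_model = c(`1` = 2))
  expect_equal(bp$area_m2, 1000 * 2 * 101)
  # two disjoint parallel portions add exactly
  seg <- data.frame(id = c("s1", "s2", "s3"),
                    downstream_id = c(NA, "s1", "s1"),
                    length_m = c(10000, 1000, 1000), stringsAsFactors = FALSE)
  seg$polyline <- list(rbind(c(0, 0), c(0, 10000)),
                       rbind(c(0, 10000), c(-400, 10000), c(-400, 10600)),
                       rbind(c(0, 10000), c(400, 10000), c(400, 10600)))
  seg$length_m[2:3] <- 1000
  net <- compute_strahler(river_network(seg))
  reach <- data.frame(segment_id = c("s2", "s3"),
                      from_m = c(500, 500), to_m = c(1000, 1000))
  bp2 <- reach_buffer_polygon(net, reach, width_model = c(`1` = 2, `2` = 4))
  # portions are 500-m straight pieces far apart: two 500 x 202 rectangles
  expect_equal(bp2$area_m2, 2 * 500 * 202)
})

test_that("corridor area at a confluence matches the rasterization oracle within 1%", {
  y <- make_y_net(len1 = 400, len2 = 500, len3 = 500)
  site <- site_position("a", "s1", 0)
  r <- upstream_reach(y, site, 900)
  wm <- default_width_model()
  bp <- reach_buffer_polygon(y, r, wm)
  oracle <- corridor_raster_oracle(y, r, wm, cell = 2)
  expect_equal(bp$area_m2, oracle, tolerance = 0.01)
})

test_that("full upstream polygons are additive unions of drainage tiles", {
  ch <- make_chain_net(lengths = c(1000, 1000, 1000))
  # site at the outlet end -> all 3 drainage polygons
  fp <- full_upstream_polygon(ch, site_position("a", "s1", 0))
  per_seg <- vapply(ch$drainage, ps_union_area, 0)
  expect_equal(fp$area_m2, sum(per_seg))
  # site at a headwater top -> that segment only
  fp2 <- full_upstream_polygon(ch, site_position("b", "s3", 900))
  expect_equal(fp2$area_m2, per_seg[["s3"]])
  # random tree interior site: union area equals the sum of member areas
  net <- random_net(seed = 321, n_headwaters = 10)
  i <- sample(nrow(net$segments), 1)
  site <- site_position("c", net$segments$id[i], 10)
  idx <- riverpa:::upstream_segment_indices(net, site)
  ids <- net$segments$id[idx]
  fp3 <- full_upstream_polygon(net, site)
  expect_equal(fp3$area_m2, sum(vapply(net$drainage[ids], ps_union_area, 0)),
               tolerance = 1e-9)
  # missing drainage -> configuration error
  expect_error(full_upstream_polygon(make_y_net(), site_position("d", "s1", 0)),
               "drainage")
})

test_that("pixel areas converge to exact areas as the pixel shrinks", {
  sq <- scale_polygon("x", "full", polyset(list(rect_piece(0, 0, 1000, 1000))))
  expect_equal(area_km2(sq, "exact"), 1)
  expect_equal(area_km2(sq, "pixel", 90), 1, tolerance = 0.02)
  expect_equal(area_km2(polyset(), "exact"), 0)
  tri <- polyset(list(cbind(c(0, 1500, 400), c(0, 300, 1200))))
  exact <- area_km2(tri, "exact")
  errs <- vapply(c(90, 30, 10), function(px)
    abs(area_km2(tri, "pixel", px) - exact), 0)
  expect_true(all(diff(errs) <= 1e-6))
  expect_lt(errs[3] / exact, 0.01)
})
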