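test_that("cross-section generation is reproducible and well-formed", {
  a <- generate_cross_sections(25, 18, seed = 7)
  b <- generate_cross_sections(25, 18, seed = 7)
  expect_identical(a$polygons, b$polygons)
  expect_length(a$polygons, 25)
  # polygons are simple convex CCW shapes with positive area inside the box
  areas <- vapply(a$polygons, myowalk:::polygon_area, numeric(1))
  expect_true(all(areas > 0))
  expect_lt(sum(areas), a$Lx * a$Ly)
  for (p in a$polygons) {
    expect_gte(min(p), -1e-9)
    expect_gte(myowalk:::shoelace(p), 0)
  }
  # pairwise non-overlap
  expect_false(myowalk:::has_overlaps(a))
  # single cell: one polygon with an extracellular frame around it
  one <- generate_cross_sections(1, 10, jitter = 0, seed = 1)
  expect_length(one$polygons, 1)
  expect_gt(ecv(one), 0)
  expect_true(all(one$polygons[[1]][, 1] > 0 &
                    one$polygons[[1]][, 1] < one$Lx))
})

test_that("raw packing ECV agrees with the polygon-area oracle", {
  cs <- generate_cross_sections(100, 18, seed = 2)
  # area-sum oracle recomputed independently via the shoelace formula
  gap <- cs$Lx * cs$Ly - sum(vapply(cs$polygons, function(p) {
    n <- nrow(p)
    abs(sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])) / 2
  }, numeric(1)))
  expect_lt(abs(ecv(cs) - gap / (cs$Lx * cs$Ly)), 0.05)
})

test_that("ECV morphing reaches the protocol targets and errors when infeasible", {
  cs <- packed_cross_sections(60)
  for (tgt in c(0.4182, 0.2469, 0.188)) {
    m <- morph_ecv(cs, tgt)
    expect_lt(abs(ecv(m) - tgt), 1e-3)
    expect_false(myowalk:::has_overlaps(m))
  }
  # target equal to the current ECV: unchanged within tolerance
  same <- morph_ecv(cs, ecv(cs))
  expect_lt(abs(ecv(same) - ecv(cs)), 1e-3)
  # growing far beyond the packing must fail (cells would merge)
  expect_error(morph_ecv(cs, 0.002), "infeasible|overlap|merge")
})

test_that("locate resolves compartments and respects periodicity", {
  s <- square_cell_substrate()
  res <- locate(s, rbind(c(1, 1, 5),      # centroid, mid-extrusion
                         c(1.9, 1.9, 5),  # gap between cells
                         c(1 + 2 * 7, 1 + 2 * 3, 5 + 10 * 4)))  # periodic image
  expect_equal(res$compartment, c("ICS", "ECS", "ICS"))
  expect_equal(res$cell_id[1], 1L)
  expect_true(is.na(res$cell_id[2]))

  # Monte Carlo occupancy matches the analytic ECV (cell area 1 in box 4)
  set.seed(5)
  n <- 20000
  pts <- cbind(runif(n, -50, 50), runif(n, -50, 50), runif(n, -50, 50))
  fr <- mean(locate(s, pts)$compartment == "ECS")
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(fr - 0.75), 3 * se)
})

test_that("helix-angle rotation advances per block row and conserves ECV", {
  cs <- packed_cross_sections(30, 0.2469)
  blk <- tissue_block(cs)
  s <- build_substrate(blk, ha_rate = 10, half_shift = FALSE)
  # a point one block row deeper, rotated by ha_rate * Ly about Y, lands in
  # the same compartment as its row-0 counterpart
  theta <- 10 * pi / 180 / 1000 * cs$Ly
  R <- matrix(c(cos(theta), 0, sin(theta), 0, 1, 0,
                -sin(theta), 0, cos(theta)), 3, 3, byrow = TRUE)
  set.seed(8)
  p0 <- cbind(runif(200, 0, cs$Lx), runif(200, 0, cs$Ly), runif(200, 0, 100))
  p1 <- t(R %*% t(p0))
  p1[, 2] <- p0[, 2] + cs$Ly
  l0 <- locate(s, p0)
  l1 <- locate(s, p1)
  expect_gt(mean((l0$compartment == l1$compartment) &
                   (is.na(l0$cell_id) | l0$cell_id == l1$cell_id)), 0.99)

  # ECV is invariant to the rotation rate (MC, 3 binomial SDs)
  set.seed(9)
  n <- 30000
  pts <- cbind(runif(n, -1000, 1000), runif(n, -1000, 1000),
               runif(n, -1000, 1000))
  f0 <- mean(locate(build_substrate(blk, ha_rate = 0), pts)$compartment == "ECS")
  f10 <- mean(locate(s, pts)$compartment == "ECS")
  se <- sqrt(f0 * (1 - f0) / n)
  expect_lt(abs(f10 - f0), 3 * sqrt(2) * se)
})

test_that("segment intersection matches the analytic ray-plane oracle", {
  s <- square_cell_substrate(icd_depth = 2)
  # wall x = 1.5 crossed from outside at t = (1.6 - 1.5) / 0.3
  h <- intersect_segment(s, c(1.6, 1.0, 5), c(1.3, 1.1, 5))
  expect_equal(h$t, 1 / 3, tolerance = 1e-9)
  expect_equal(h$x, 1.5, tolerance = 1e-9)
  expect_equal(abs(c(h$nx, h$ny, h$nz)), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(h$kind, "sarcolemma")
  expect_equal(h$from, "ECS")
  expect_equal(h$to, "ICS")
  expect_equal(h$dx, 0.1, tolerance = 1e-9)

  # no membrane on a path inside one compartment
  expect_null(intersect_segment(s, c(0.9, 0.9, 5), c(1.1, 1.1, 5)))

  # crossing a wall within icd_depth of the cap is an ICD interaction
  h2 <- intersect_segment(s, c(1.6, 1.0, 1.2), c(1.3, 1.0, 1.2))
  expect_equal(h2$kind, "ICD")
  # an end-cap crossing inside the cell is ICD with an axial normal
  h3 <- intersect_segment(s, c(1, 1, 9.5), c(1, 1, 10.5))
  expect_equal(h3$kind, "ICD")
  expect_equal(abs(h3$nz), 1, tolerance = 1e-12)
  expect_equal(h3$z, 10, tolerance = 1e-9)
})

test_that("locate and intersect_segment are mutually consistent", {
  s <- packed_substrate(30)
  set.seed(11)
  n <- 2000
  p0 <- cbind(runif(n, -200, 200), runif(n, -200, 200), runif(n, -200, 200))
  d <- matrix(runif(3 * n, -2, 2), ncol = 3)
  crossing_free <- vapply(seq_len(n), function(i) {
    is.null(intersect_segment(s, p0[i, ], p0[i, ] + d[i, ]))
  }, logical(1))
  a <- locate(s, p0[crossing_free, , drop = FALSE])
  b <- locate(s, p0[crossing_free, , drop = FALSE] +
                d[crossing_free, , drop = FALSE])
  agree <- a$compartment == b$compartment &
    (is.na(a$cell_id) | a$cell_id == b$cell_id)
  expect_gt(sum(crossing_free), 500)
  expect_gte(mean(agree), 0.999)
})

test_that("substrate text format round-trips", {
  cs <- packed_cross_sections(12)
  blk <- tissue_block(cs, Lz = 127, icd_depth = 2)
  f <- tempfile(fileext = ".txt")
  write_substrate(blk, f)
  blk2 <- read_substrate(f)
  expect_equal(blk2$Lz, 127)
  expect_equal(blk2$icd_depth, 2)
  expect_equal(blk2$cross_sections$Lx, cs$Lx)
  expect_equal(length(blk2$cross_sections$polygons), length(cs$polygons))
  for (i in seq_along(cs$polygons)) {
    expect_equal(blk2$cross_sections$polygons[[i]], cs$polygons[[i]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  unlink(f)
})
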