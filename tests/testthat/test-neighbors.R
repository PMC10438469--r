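square_lattice <- function(n = 7) {
  g <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
  m <- cbind(g$x, g$y, 0)
  rownames(m) <- sprintf("p%02d_%02d", g$x, g$y)
  m
}

tri_lattice <- function(n = 7) {
  g <- expand.grid(i = seq_len(n) - 1, j = seq_len(n) - 1)
  m <- cbind(g$i + g$j / 2, g$j * sqrt(3) / 2, 0)
  rownames(m) <- sprintf("h%02d_%02d", g$i, g$j)
  m
}

test_that("the neighbor score matches the analytic cases", {
  expect_equal(neighbor_score(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0)), 1)
  # unit equilateral triangle
  expect_equal(neighbor_score(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)), 2)
  # distant third cell, unit pair separation
  expect_equal(neighbor_score(c(0, 0, 0), c(1, 0, 0), c(0.5, 100, 0)),
               2 * sqrt(100^2 + 0.25))
  expect_error(neighbor_score(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0)), "coincide")
})

test_that("the neighbor score is at least 1 for random triples", {
  set.seed(13)
  for (i in 1:200) {
    pts <- matrix(stats::rnorm(9), 3)
    if (all(pts[1, ] == pts[2, ])) next
    expect_gte(neighbor_score(pts[1, ], pts[2, ], pts[3, ]), 1)
  }
})

test_that("square-lattice adjacency follows the enumerated scores", {
  pos <- square_lattice(7)
  # axis-adjacent pair: best blocker gives 1 + sqrt(2) > 2
  expect_true(pair_is_neighbor("p03_03", "p04_03", pos))
  # diagonal pair: the shared corner cell gives 2/sqrt(2) < 2
  expect_false(pair_is_neighbor("p03_03", "p04_04", pos))
  # two-step pair: the cell in between gives exactly 1
  expect_false(pair_is_neighbor("p02_03", "p04_03", pos))
  g <- neighbor_graph(pos)
  deg <- graph_degrees(g)
  interior <- rownames(pos)[pos[, 1] >= 2 & pos[, 1] <= 4 & pos[, 2] >= 2 & pos[, 2] <= 4]
  expect_true(all(deg[interior] == 4L))
})

test_that("ideal triangular-lattice pairs sit exactly at the strict cutoff", {
  # the two shared neighbors of an adjacent pair form equilateral triangles,
  # so the min-over-S score is exactly 2 and the strict rule (> 2) excludes
  # the pair; this is the knife-edge case of the cutoff
  pos <- tri_lattice(7)
  a <- "h03_03"; b <- "h04_03"
  ia <- match(a, rownames(pos)); ib <- match(b, rownames(pos))
  others <- pos[-c(ia, ib), , drop = FALSE]
  sc <- min(neighbor_score(pos[ia, ], pos[ib, ], others))
  expect_equal(sc, 2, tolerance = 1e-9)
  expect_false(pair_is_neighbor(a, b, pos))
})

test_that("two cells alone in a frame are neighbors (vacuous blocking set)", {
  pos <- matrix(c(0, 0, 0, 3, 0, 0), 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  expect_true(pair_is_neighbor("a", "b", pos))
  g1 <- neighbor_graph(pos[1, , drop = FALSE])
  expect_equal(nrow(g1$edges), 0L)
})

test_that("the neighbor graph is symmetric and order-independent", {
  set.seed(19)
  pos <- matrix(stats::runif(90, 0, 30), ncol = 3)
  rownames(pos) <- sprintf("c%02d", 1:30)
  g <- neighbor_graph(pos)
  expect_true(all(g$edges$a < g$edges$b))
  expect_false(any(g$edges$a == g$edges$b))
  g2 <- neighbor_graph(pos[sample(30), ])
  norm <- function(e) e[order(e$a, e$b), c("a", "b")]
  expect_equal(norm(g2$edges), norm(g$edges), ignore_attr = TRUE)
  # every edge passes the pairwise test from both endpoints
  for (k in seq_len(min(10, nrow(g$edges)))) {
    expect_true(pair_is_neighbor(g$edges$a[k], g$edges$b[k], pos) ||
                  pair_is_neighbor(g$edges$b[k], g$edges$a[k], pos))
  }
})

static_forest <- function(pos, n_frames = 60L) {
  pts <- do.call(rbind, lapply(0:(n_frames - 1L), function(f) {
    data.frame(track_id = rownames(pos), frame = f,
               x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }))
  lineage_forest(pts)
}

test_that("static neighbor pairs persist fully at every horizon", {
  pos <- square_lattice(4)
  # mother mA (frames 0..9) divides into p01_01 and sis so that newly born
  # focal cells exist; everything else sits still on a wide lattice
  pos_site <- pos * 8
  pts <- do.call(rbind, lapply(0:59, function(f) {
    keep <- rownames(pos)[rownames(pos) != "p01_01" | f >= 10]
    data.frame(track_id = keep, frame = f,
               x = pos_site[keep, 1], y = pos_site[keep, 2], z = pos_site[keep, 3])
  }))
  pts <- rbind(pts,
               data.frame(track_id = "mA", frame = 0:9, x = 8, y = 8, z = 0),
               data.frame(track_id = "sis", frame = 10:59, x = 8, y = 6.5, z = 0))
  f <- lineage_forest(pts, data.frame(child_id = c("p01_01", "sis"), parent_id = "mA"))
  fp <- follow_pairs(f, horizons_h = c(2, 6), seed = 5)
  expect_equal(fp$fraction, c(1, 1))
  expect_gt(fp$n_pairs[1], 0)
  # horizons beyond the movie are excluded, not counted
  fp2 <- follow_pairs(f, horizons_h = c(2, 100), seed = 5)
  expect_true(is.nan(fp2$fraction[2]))
  expect_gt(fp2$n_excluded[2], 0)
  # determinism under a fixed seed
  expect_equal(follow_pairs(f, horizons_h = c(2, 6), seed = 11),
               follow_pairs(f, horizons_h = c(2, 6), seed = 11))
})

test_that("separation fractions cannot rise with horizon when cells only gain blockers", {
  # frozen positions except for one blocker that appears between the focal
  # pair after the first horizon: the still-neighbors fraction can only drop
  base <- rbind(focal = c(0, 0, 0), partner = c(2.2, 0, 0),
                far1 = c(30, 0, 0), far2 = c(0, 30, 0))
  mk_pts <- function(id, frames, p) {
    data.frame(track_id = id, frame = frames, x = p[1], y = p[2], z = p[3])
  }
  pts <- rbind(
    mk_pts("mom", 0:9, c(0, -1, 0)),
    mk_pts("focal", 10:120, base["focal", ]),
    mk_pts("sis", 10:120, c(-2.2, 0, 0)),
    mk_pts("partner", 0:120, base["partner", ]),
    mk_pts("far1", 0:120, base["far1", ]),
    mk_pts("far2", 0:120, base["far2", ]),
    mk_pts("intruder", 30:120, c(1.1, 0, 0)))   # appears at 6 h, blocks the pair
  f <- lineage_forest(pts, data.frame(child_id = c("focal", "sis"), parent_id = "mom"))
  fp <- follow_pairs(f, horizons_h = c(2, 10), seed = 3)
  expect_true(all(diff(fp$fraction) <= 1e-9))
  expect_lt(fp$fraction[2], fp$fraction[1])
})

test_that("sister separation is stratified by type and flags scattered types", {
  cfg <- sim_config(movie_length_h = 30, n_initial_cells = 14)
  ds <- simulate_crypt(cfg, seed = 12)
  tf <- backpropagate(ds$forest, ds$truth$endpoint_types)
  ss <- sister_separation(tf, horizons_h = 2, seed = 7)
  expect_true(all(ss$fraction >= 0 & ss$fraction <= 1, na.rm = TRUE))
  expect_true(all(ss$type %in% cell_type_levels()))
  # forest without divisions -> empty result with warning
  solo <- lineage_forest(data.frame(track_id = "a", frame = 0:10, x = 0, y = 0, z = 0))
  tf0 <- backpropagate(solo, c(a = "STEM"))
  expect_warning(out <- sister_separation(tf0), "no divisions")
  expect_equal(nrow(out), 0L)
})
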