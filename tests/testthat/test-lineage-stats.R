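test_that("sister histogram applies the double-count and column-normalisation rule", {
  s <- sisters_forest(list(c("STEM", "STEM"), c("STEM", "TA"), c("TA", "TA")))
  h <- sister_type_histogram(s$typed)
  expect_equal(h$raw["STEM", "STEM"], 2)
  expect_equal(h$raw["STEM", "TA"], 1)
  expect_equal(h$raw["TA", "STEM"], 1)
  expect_equal(h$raw["TA", "TA"], 2)
  expect_equal(h$freq["STEM", "STEM"], 2 / 3)
  expect_equal(h$freq["TA", "STEM"], 1 / 3)
  expect_equal(h$freq["STEM", "TA"], 1 / 3)
  expect_equal(h$same_type_fraction, 2 / 3)
  expect_equal(h$n_pairs, 3L)
  # occupied columns sum to 1; the raw matrix is symmetric
  cs <- colSums(h$freq[, colSums(h$raw) > 0])
  expect_equal(unname(cs), rep(1, length(cs)))
  expect_equal(h$raw, t(h$raw))
})

test_that("all-same-type pairs give an identity-like normalised matrix", {
  s <- sisters_forest(list(c("PANETH", "PANETH"), c("GOBLET", "GOBLET")))
  h <- sister_type_histogram(s$typed)
  expect_equal(h$freq["PANETH", "PANETH"], 1)
  expect_equal(h$freq["GOBLET", "GOBLET"], 1)
  expect_equal(h$same_type_fraction, 1)
})

test_that("forests without end-point sisters warn and pairs with UNKNOWN are excluded", {
  solo <- lineage_forest(data.frame(track_id = "a", frame = 0:5, x = 0, y = 0, z = 0))
  expect_warning(h <- sister_type_histogram(backpropagate(solo, c(a = "TA"))),
                 "no end-point sister")
  expect_equal(h$n_pairs, 0L)
  s <- sisters_forest(list(c("STEM", "STEM"), c("TA", "UNKNOWN")))
  h2 <- sister_type_histogram(s$typed)
  expect_equal(h2$n_pairs, 1L)
  expect_equal(h2$n_excluded, 1L)
})

test_that("end-point ages measure time since birth, or the movie length for root tracks", {
  # 60 h movie at 0.2 h/frame: 300 frames; birth at 40 h = frame 200
  pts <- rbind(data.frame(track_id = "m", frame = 0:199, x = 0, y = 0, z = 0),
               data.frame(track_id = "d1", frame = 200:300, x = 0, y = 0, z = 0),
               data.frame(track_id = "d2", frame = 200:300, x = 0, y = 0, z = 0),
               data.frame(track_id = "old", frame = 0:300, x = 0, y = 0, z = 0))
  f <- lineage_forest(pts, data.frame(child_id = c("d1", "d2"), parent_id = "m"))
  tf <- backpropagate(f, c(d1 = "EEC", d2 = "EEC", old = "ENTEROCYTE"))
  ages <- endpoint_ages(tf)
  expect_equal(ages$EEC, c(20, 20))
  expect_equal(ages$ENTEROCYTE, 60)
  expect_length(ages$PANETH, 0L)
})

test_that("divisions are counted per maximal same-type segment", {
  # chain of 5 consecutive enterocyte forks below a TA ancestor
  children <- list(r = c("e1", "x1"))
  prev <- "e1"
  for (i in 1:5) {
    children[[prev]] <- c(sprintf("e%d", i + 1), sprintf("y%d", i))
    prev <- sprintf("e%d", i + 1)
  }
  f <- forest_from_tree(children, len = 3L)
  lv <- leaves_of(list(children = children))
  et <- stats::setNames(rep("ENTEROCYTE", length(lv)), lv)
  et["x1"] <- "TA"
  tf <- backpropagate(f, et)
  dv <- divisions_per_type(tf)
  expect_equal(sort(dv$ENTEROCYTE, decreasing = TRUE)[1], 5)
  # the TA segment (root r + leaf x1) has one dividing track: r
  expect_equal(dv$TA, 1)
  # a Paneth mother dividing once scores 1 for its segment; undivided
  # segments score 0
  s <- sisters_forest(list(c("PANETH", "PANETH")))
  dvp <- divisions_per_type(s$typed)
  expect_equal(dvp$PANETH, 1)
  solo <- lineage_forest(data.frame(track_id = "a", frame = 0:5, x = 0, y = 0, z = 0))
  expect_equal(divisions_per_type(backpropagate(solo, c(a = "GOBLET")))$GOBLET, 0)
})

test_that("cycle durations cover complete fork-to-fork cycles only", {
  # m: frames 0..99 (incomplete, starts at movie start)
  # d1: frames 100..174 divides -> complete cycle of 75 frames = 15 h
  pts <- rbind(data.frame(track_id = "m", frame = 0:99, x = 0, y = 0, z = 0),
               data.frame(track_id = "d1", frame = 100:174, x = 0, y = 0, z = 0),
               data.frame(track_id = "d2", frame = 100:300, x = 0, y = 0, z = 0),
               data.frame(track_id = "g1", frame = 175:300, x = 0, y = 0, z = 0),
               data.frame(track_id = "g2", frame = 175:300, x = 0, y = 0, z = 0))
  f <- lineage_forest(pts, data.frame(child_id = c("d1", "d2", "g1", "g2"),
                                      parent_id = c("m", "m", "d1", "d1")))
  tf <- backpropagate(f, c(d2 = "STEM", g1 = "STEM", g2 = "STEM"))
  cyc <- cycle_durations(tf)
  expect_equal(cyc$STEM, 15)
  expect_length(unlist(cyc), 1L)   # m's cycle is incomplete and excluded
})

test_that("simulated cycle durations recover the configured means", {
  cfg <- sim_config(movie_length_h = 40, n_initial_cells = 20)
  ds <- simulate_crypt(cfg, seed = 31)
  tf <- backpropagate(ds$forest, ds$truth$endpoint_types)
  cyc <- cycle_durations(tf)
  for (t in c("STEM", "TA")) {
    x <- cyc[[t]]
    if (length(x) >= 20) {
      sem <- stats::sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - cfg$cycle_mean_h[[t]]), 2.5 * sem + 0.3)
    }
  }
})

test_that("the two-type subtree census matches brute-force enumeration", {
  # STEM -> (STEM, TA subtree): one STEM|TA subtree
  children <- list(r = c("s", "t"), t = c("t1", "t2"))
  f <- forest_from_tree(children, len = 3L)
  tf <- backpropagate(f, c(s = "STEM", t1 = "TA", t2 = "TA"))
  cen <- two_type_subtrees(tf)
  expect_equal(unname(cen$counts["STEM|TA"]), 1L)
  expect_equal(sum(cen$counts), 1L)
  # a pure-type tree has no two-type subtree
  tf2 <- backpropagate(f, c(s = "STEM", t1 = "STEM", t2 = "STEM"))
  expect_equal(sum(two_type_subtrees(tf2)$counts), 0L)

  # randomized forests against an independent recursive enumeration
  set.seed(44)
  lev <- c("STEM", "TA", "ENTEROCYTE", "PANETH")
  for (rep in 1:15) {
    tree <- random_tree(5L, p_split = 0.7)
    f <- forest_from_tree(tree$children, len = 2L, extra_roots = tree$root)
    lv <- leaves_of(tree)
    tf <- backpropagate(f, stats::setNames(sample(lev, length(lv), TRUE), lv))
    cen <- two_type_subtrees(tf)
    # oracle: for every node, list descendant types by explicit recursion
    desc_types <- function(id) {
      d1 <- f$tracks[id, "daughter1"]
      own <- tf$track_types[[id]]
      own <- if (own == "UNKNOWN") character(0) else own
      if (is.na(d1)) return(own)
      unique(c(own, desc_types(d1), desc_types(f$tracks[id, "daughter2"])))
    }
    desc_ids <- function(id) {
      d1 <- f$tracks[id, "daughter1"]
      if (is.na(d1)) return(id)
      c(id, desc_ids(d1), desc_ids(f$tracks[id, "daughter2"]))
    }
    expected <- character(0)
    for (id in f$tracks$track_id) {
      ts <- sort(desc_types(id))
      if (length(ts) != 2L) next
      p <- f$tracks[id, "parent"]
      if (!is.na(p) && length(desc_types(p)) == 2L) next
      # same >50% dead/lost exclusion, via independent subtree listing
      if (mean(f$tracks[desc_ids(id), "end_reason"] %in% c("death", "lost")) > 0.5) next
      expected <- c(expected, paste(ts, collapse = "|"))
    }
    got <- rep(names(cen$counts), cen$counts)
    expect_equal(sort(as.character(got)), sort(as.character(expected)))
  }
})
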