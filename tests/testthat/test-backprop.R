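test_that("the four fork rules assign mother types and transitions as documented", {
  f <- forest_from_tree(list(m = c("d1", "d2")), len = 11L)
  # R2: symmetric fate, no transition
  tf <- backpropagate(f, c(d1 = "ENTEROCYTE", d2 = "ENTEROCYTE"))
  expect_identical(unname(tf$track_types["m"]), "ENTEROCYTE")
  expect_equal(nrow(tf$transitions), 0L)
  # R3: stem beats the other daughter; transition in the non-stem daughter
  tf <- backpropagate(f, c(d1 = "STEM", d2 = "TA"))
  expect_identical(unname(tf$track_types["m"]), "STEM")
  expect_equal(tf$transitions$track_id, "d2")
  expect_identical(tf$transitions$from_type, "STEM")
  expect_identical(tf$transitions$to_type, "TA")
  # R4: TA vs a non-stem daughter
  tf <- backpropagate(f, c(d1 = "TA", d2 = "ENTEROCYTE"))
  expect_identical(unname(tf$track_types["m"]), "TA")
  expect_equal(tf$transitions$track_id, "d2")
  # two distinct terminal types cannot be resolved
  tf <- backpropagate(f, c(d1 = "PANETH", d2 = "GOBLET"))
  expect_identical(unname(tf$track_types["m"]), "UNKNOWN")
  expect_equal(nrow(tf$conflicts), 1L)
})

test_that("an undivided track keeps its end-point type over its whole span", {
  pts <- data.frame(track_id = "solo", frame = 0:9, x = 0, y = 0, z = 0)
  f <- lineage_forest(pts)
  tf <- backpropagate(f, c(solo = "GOBLET"))
  expect_equal(tf$intervals,
               data.frame(track_id = "solo", start_frame = 0L, end_frame = 9L,
                          type = "GOBLET"))
  expect_equal(nrow(tf$transitions), 0L)
})

test_that("a dead or unknown sister does not constrain the fork", {
  f <- forest_from_tree(list(m = c("d1", "d2")), len = 5L,
                        movie_end_frame = 20L,
                        end_reasons = data.frame(track_id = "d2",
                                                 end_reason = "death"))
  tf <- backpropagate(f, c(d1 = "PANETH"))
  expect_identical(unname(tf$track_types["m"]), "PANETH")
  expect_length(tf$low_confidence, 0L)     # dead sister: the documented rule
  # lost sister: same inheritance but flagged low-confidence
  f2 <- forest_from_tree(list(m = c("d1", "d2")), len = 5L, movie_end_frame = 20L)
  tf2 <- backpropagate(f2, c(d1 = "PANETH"))
  expect_identical(unname(tf2$track_types["m"]), "PANETH")
  expect_identical(tf2$low_confidence, "m")
  # both daughters unknown: no type is invented
  tf3 <- backpropagate(f2, c(d1 = "UNKNOWN"))
  expect_identical(unname(tf3$track_types["m"]), "UNKNOWN")
})

test_that("a three-generation tree resolves rule chains along the path", {
  children <- list(r = c("a", "b"), a = c("a1", "a2"), b = c("b1", "b2"))
  f <- forest_from_tree(children, len = 10L)
  tf <- backpropagate(f, c(a1 = "STEM", a2 = "TA", b1 = "ENTEROCYTE", b2 = "ENTEROCYTE"))
  expect_identical(unname(tf$track_types[c("r", "a", "b")]), c("STEM", "STEM", "ENTEROCYTE"))
  # transitions: STEM->TA in a2, STEM->ENTEROCYTE in b
  expect_setequal(tf$transitions$track_id, c("a2", "b"))
  # hand-enumerated oracle agrees
  orc <- oracle_backprop(children, c(a1 = "STEM", a2 = "TA",
                                     b1 = "ENTEROCYTE", b2 = "ENTEROCYTE"))
  expect_identical(unname(tf$track_types[names(orc$types)]), unname(orc$types))
  expect_setequal(tf$transitions$track_id, orc$transition_tracks)
})

test_that("transition events sit at the floor midpoint with the track's position there", {
  coords <- list(m = c(0, 0, 0), d1 = c(1, 2, 3), d2 = c(4, 5, 6))
  f <- forest_from_tree(list(m = c("d1", "d2")), len = 11L, coords = coords)
  tf <- backpropagate(f, c(d1 = "STEM", d2 = "TA"))
  d2_span <- c(first_frame_of(f, "d2"), last_frame_of(f, "d2"))
  expect_equal(tf$transitions$event_frame, (d2_span[1] + d2_span[2]) %/% 2L)
  expect_equal(unlist(tf$transitions[1, c("x", "y", "z")], use.names = FALSE),
               c(4, 5, 6))
  expect_equal(tf$transitions$t_h, tf$transitions$event_frame * 0.2)
})

test_that("intervals are contiguous, non-overlapping and cover every track", {
  set.seed(20)
  lev <- cell_type_levels()
  for (rep in 1:20) {
    tree <- random_tree(4L, p_split = 0.65)
    f <- forest_from_tree(tree$children, len = 4L, extra_roots = tree$root)
    lv <- leaves_of(tree)
    tf <- backpropagate(f, stats::setNames(sample(lev, length(lv), TRUE), lv))
    for (id in f$tracks$track_id) {
      iv <- tf$intervals[tf$intervals$track_id == id, , drop = FALSE]
      iv <- iv[order(iv$start_frame), ]
      expect_equal(iv$start_frame[1], f$tracks[id, "first_frame"])
      expect_equal(iv$end_frame[nrow(iv)], f$tracks[id, "last_frame"])
      if (nrow(iv) > 1) {
        expect_equal(iv$start_frame[-1], iv$end_frame[-nrow(iv)] + 1L)
      }
    }
    # conservation: transitions along any root-to-leaf path equal the type
    # changes between consecutive intervals along that path
    for (leaf in lv) {
      path <- leaf
      while (!is.na(f$tracks[path[1], "parent"])) path <- c(f$tracks[path[1], "parent"], path)
      ivp <- do.call(rbind, lapply(path, function(id) {
        tf$intervals[tf$intervals$track_id == id, , drop = FALSE]
      }))
      ivp <- ivp[order(ivp$start_frame), ]
      # transitions are only defined between two known types; interval
      # boundaries into or out of UNKNOWN segments carry no event
      a <- ivp$type[-nrow(ivp)]; b <- ivp$type[-1]
      n_changes <- sum(a != b & a != "UNKNOWN" & b != "UNKNOWN")
      n_trans <- sum(tf$transitions$track_id %in% path)
      expect_equal(n_trans, n_changes)
    }
  }
})

test_that("backpropagation is independent of track iteration order", {
  set.seed(8)
  tree <- random_tree(4L, p_split = 0.7)
  f <- forest_from_tree(tree$children, len = 3L, extra_roots = tree$root)
  lv <- leaves_of(tree)
  et <- stats::setNames(sample(cell_type_levels(), length(lv), TRUE), lv)
  tf1 <- backpropagate(f, et)
  # rebuild the forest with shuffled point order; same content
  sh <- sample(nrow(f$points))
  f2 <- lineage_forest(f$points[sh, ],
                       data.frame(child_id = c(f$tracks$daughter1, f$tracks$daughter2),
                                  parent_id = rep(f$tracks$track_id, 2))[
                         !is.na(c(f$tracks$daughter1, f$tracks$daughter2)), ],
                       movie_end_frame = f$movie_end_frame)
  tf2 <- backpropagate(f2, et[sample(length(et))])
  expect_equal(tf1$track_types, tf2$track_types)
  expect_equal(tf1$transitions, tf2$transitions)
})

test_that("collect_transitions returns one event per planted commitment", {
  cfg <- sim_config(movie_length_h = 30, n_initial_cells = 12)
  ds <- simulate_crypt(cfg, seed = 9)
  tf <- backpropagate(ds$forest, ds$truth$endpoint_types)
  ev <- collect_transitions(tf)
  expect_setequal(ev$track_id, ds$truth$transitions$track_id)
  expect_equal(nrow(ev), nrow(ds$truth$transitions))
  # no type changes anywhere -> empty list
  f <- forest_from_tree(list(m = c("d1", "d2")), len = 3L)
  expect_equal(nrow(collect_transitions(backpropagate(f, c(d1 = "TA", d2 = "TA")))), 0L)
})
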