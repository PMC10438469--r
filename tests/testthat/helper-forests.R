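# Builders and independent oracles shared across the test files.

# Build a lineage forest from a fork table: `children` is a named list
# mapping each dividing node to its two daughters. Every node occupies
# `len` consecutive frames; daughters start right after their mother.
# Coordinates default to zero (topology-only tests) unless `coords` maps
# node -> c(x, y, z).
forest_from_tree <- function(children, len = 3L, coords = NULL,
                             movie_end_frame = NULL, dt = 0.2,
                             end_reasons = NULL, extra_roots = NULL) {
  kids <- unlist(children, use.names = FALSE)
  nodes <- union(union(names(children), kids), extra_roots)
  roots <- setdiff(nodes, kids)
  depth <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  depth[roots] <- 0L
  repeat {
    prog <- FALSE
    for (p in names(children)) {
      if (!is.na(depth[p]) && is.na(depth[children[[p]][1]])) {
        depth[children[[p]]] <- depth[p] + 1L
        prog <- TRUE
      }
    }
    if (!prog) break
  }
  pts <- do.call(rbind, lapply(nodes, function(nd) {
    fr <- (depth[[nd]] * len):((depth[[nd]] + 1L) * len - 1L)
    xyz <- if (!is.null(coords) && nd %in% names(coords)) coords[[nd]] else c(0, 0, 0)
    data.frame(track_id = nd, frame = fr, x = xyz[1], y = xyz[2], z = xyz[3])
  }))
  links <- if (length(children)) {
    do.call(rbind, lapply(names(children), function(p) {
      data.frame(child_id = children[[p]], parent_id = p)
    }))
  } else NULL
  lineage_forest(pts, links, movie_end_frame = movie_end_frame,
                 frame_interval_h = dt, end_reasons = end_reasons)
}

# random binary tree topology up to `max_depth` generations
random_tree <- function(max_depth = 4L, p_split = 0.6, prefix = "n") {
  children <- list()
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    paste0(prefix, counter)
  }
  grow <- function(id, depth) {
    if (depth < max_depth && stats::runif(1) < p_split) {
      d <- c(new_id(), new_id())
      children[[id]] <<- d
      grow(d[1], depth + 1L)
      grow(d[2], depth + 1L)
    }
  }
  root <- new_id()
  grow(root, 0L)
  list(root = root, children = children)
}

leaves_of <- function(tree) {
  kids <- unlist(tree$children, use.names = FALSE)
  setdiff(union(names(tree$children), union(kids, tree$root)), names(tree$children))
}

# independent rule applier: iterate to a fixpoint over the fork table
# instead of traversing the tree, then read off transition tracks
oracle_rule <- function(t1, t2) {
  if (t1 == "UNKNOWN" && t2 == "UNKNOWN") return("UNKNOWN")
  if (t1 == "UNKNOWN") return(t2)
  if (t2 == "UNKNOWN") return(t1)
  if (t1 == t2) return(t1)
  if ("STEM" %in% c(t1, t2)) return("STEM")
  if ("TA" %in% c(t1, t2)) return("TA")
  "UNKNOWN"
}

oracle_backprop <- function(children, leaf_types) {
  kids_all <- unlist(children, use.names = FALSE)
  nodes <- union(names(children), kids_all)
  types <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  types[names(leaf_types)] <- leaf_types
  repeat {
    prog <- FALSE
    for (p in names(children)) {
      if (!is.na(types[p])) next
      ds <- children[[p]]
      t1 <- types[ds[1]]; t2 <- types[ds[2]]
      if (!is.na(t1) && !is.na(t2)) {
        types[p] <- oracle_rule(t1, t2)
        prog <- TRUE
      }
    }
    if (!prog) break
  }
  kids <- unlist(children, use.names = FALSE)
  trans <- kids[vapply(kids, function(k) {
    pa <- names(children)[vapply(children, function(d) k %in% d, logical(1))]
    tp <- types[pa]; tk <- types[k]
    !is.na(tp) && !is.na(tk) && tp != "UNKNOWN" && tk != "UNKNOWN" && tp != tk
  }, logical(1))]
  list(types = types, transition_tracks = as.character(unname(trans)))
}

# exact assignment oracle: bitmask DP over stain cells; each track either
# takes an allowed stain cell or stays unmatched; maximise cardinality,
# then minimise total distance (same objective as the solver, different
# algorithm)
oracle_best_assignment <- function(D, max_dist = Inf) {
  n <- nrow(D); m <- ncol(D)
  K <- (n + m + 1) * max(c(D[D <= max_dist], 1)) + 1
  memo <- new.env(parent = emptyenv())
  rec <- function(i, mask) {
    if (i > n) return(0)
    key <- paste(i, mask)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    best <- rec(i + 1L, mask)          # leave track i unmatched
    for (j in seq_len(m)) {
      if (!bitwAnd(mask, bitwShiftL(1L, j - 1L)) && D[i, j] <= max_dist) {
        best <- min(best, D[i, j] - K + rec(i + 1L, bitwOr(mask, bitwShiftL(1L, j - 1L))))
      }
    }
    memo[[key]] <- best
    best
  }
  obj <- rec(1L, 0L)
  card <- 0L
  while (obj < -K / 2) {               # recover cardinality and raw cost
    obj <- obj + K
    card <- card + 1L
  }
  list(cardinality = card, cost = obj)
}

# forest whose end-point sister pairs are exactly the given type pairs
sisters_forest <- function(pair_types) {
  children <- list()
  types <- character(0)
  for (i in seq_along(pair_types)) {
    m <- sprintf("m%d", i)
    ds <- sprintf("m%d_%s", i, c("a", "b"))
    children[[m]] <- ds
    types[ds] <- pair_types[[i]]
  }
  f <- forest_from_tree(children, len = 5L)
  list(typed = backpropagate(f, types), forest = f)
}

first_frame_of <- function(forest, id) forest$tracks[id, "first_frame"]
last_frame_of <- function(forest, id) forest$tracks[id, "last_frame"]
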