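#' Neighbor score of a candidate cell pair
#'
#' For a candidate pair A, B and a third "blocking" cell S, the score is
#' (dAS + dBS) / dAB. By the triangle inequality it is at least 1, with the
#' minimum attained when S lies exactly between A and B; large values mean
#' no cell comes between the pair.
#'
#' @param A,B 3D positions of the candidate pair (A != B).
#' @param S 3D position of the third cell, or a matrix of positions (one
#'   row per cell).
#' @return numeric score(s).
#' @export
neighbor_score <- function(A, B, S) {
  A <- as.numeric(A); B <- as.numeric(B)
  dAB <- sqrt(sum((A - B)^2))
  if (dAB == 0) stop("neighbor score undefined: A and B coincide")
  if (!is.matrix(S)) S <- matrix(S, nrow = 1L)
  dAS <- sqrt(rowSums(sweep(S, 2L, A)^2))
  dBS <- sqrt(rowSums(sweep(S, 2L, B)^2))
  unname((dAS + dBS) / dAB)
}

# min-over-S neighbor scores for a set of candidate pairs (index matrix
# pairs: 2 columns into pos); S ranges over all other cells in the frame
pair_min_scores <- function(pos, pairs) {
  n <- nrow(pos)
  if (n <= 2L) return(rep(Inf, nrow(pairs)))
  G <- pos %*% t(pos)
  sq <- diag(G)
  D <- sqrt(pmax(outer(sq, rep(1, n)) + outer(rep(1, n), sq) - 2 * G, 0))
  i <- pairs[, 1L]; j <- pairs[, 2L]
  M <- D[i, , drop = FALSE] + D[j, , drop = FALSE]
  M[cbind(seq_len(nrow(pairs)), i)] <- Inf
  M[cbind(seq_len(nrow(pairs)), j)] <- Inf
  apply(M, 1L, min) / D[cbind(i, j)]
}

#' Are two cells neighbors in a frame?
#'
#' B must be among A's `k_candidates` nearest cells (Euclidean), and the
#' pair's neighbor score, minimised over every other cell S in the frame,
#' must be strictly greater than `cutoff`. With no third cell present the
#' minimum is +Inf and the pair are neighbors. The strict cutoff means a
#' pair whose best blocker forms an exact equilateral triangle (score 2) is
#' not a neighbor pair.
#'
#' @param a_id,b_id row names into `positions`.
#' @param positions numeric matrix of all cells in the frame (rownames are
#'   ids).
#' @param k_candidates candidate-partner count (default 20).
#' @param cutoff score cutoff (default 2, strict).
#' @return logical.
#' @export
pair_is_neighbor <- function(a_id, b_id, positions, k_candidates = 20L, cutoff = 2) {
  ia <- match(a_id, rownames(positions))
  ib <- match(b_id, rownames(positions))
  if (is.na(ia) || is.na(ib)) stop("both cells must be present in the frame")
  d <- sqrt(colSums((t(positions) - positions[ia, ])^2))
  d[ia] <- Inf
  kth <- sort(d)[min(k_candidates, length(d) - 1L)]
  if (d[ib] > kth) return(FALSE)
  sc <- pair_min_scores(positions, cbind(ia, ib))
  sc > cutoff
}

#' Per-frame neighbor graph
#'
#' Builds the adjacency graph of one frame under the neighbor-score rule:
#' edges are cell pairs, drawn from each cell's `k_candidates` nearest
#' cells, whose min-over-S score exceeds `cutoff`. Candidate pairs from
#' either endpoint are pooled, so the graph is symmetric by construction.
#'
#' @param positions numeric matrix (rownames are cell ids).
#' @inheritParams pair_is_neighbor
#' @param frame frame index stored with the graph.
#' @return object of class `neighbor_graph`: `ids`, `edges` (data frame
#'   `a`, `b`, `score`), `frame`.
#' @export
neighbor_graph <- function(positions, k_candidates = 20L, cutoff = 2,
                           frame = NA_integer_) {
  n <- nrow(positions)
  ids <- rownames(positions)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n < 2L) {
    return(structure(list(ids = ids,
                          edges = data.frame(a = character(0), b = character(0),
                                             score = numeric(0)),
                          frame = frame, k_candidates = k_candidates,
                          cutoff = cutoff), class = "neighbor_graph"))
  }
  G <- positions %*% t(positions)
  sq <- diag(G)
  D <- sqrt(pmax(outer(sq, rep(1, n)) + outer(rep(1, n), sq) - 2 * G, 0))
  diag(D) <- Inf
  k <- min(k_candidates, n - 1L)
  cand <- lapply(seq_len(n), function(i) {
    js <- order(D[i, ])[seq_len(k)]
    cbind(pmin(i, js), pmax(i, js))
  })
  pairs <- unique(do.call(rbind, cand))
  sc <- pair_min_scores(positions, pairs)
  keep <- sc > cutoff
  na <- ids[pairs[keep, 1L]]; nb <- ids[pairs[keep, 2L]]
  edges <- data.frame(a = pmin(na, nb), b = pmax(na, nb), score = sc[keep])
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(ids = ids, edges = edges, frame = frame,
                 k_candidates = k_candidates, cutoff = cutoff),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  deg <- graph_degrees(x)
  cat("Neighbor graph (frame ", x$frame, "): ", length(x$ids), " cells, ",
      nrow(x$edges), " edges, median degree ",
      if (length(deg)) stats::median(deg) else 0, "\n", sep = "")
  invisible(x)
}

#' Node degrees of a neighbor graph
#' @param graph a `neighbor_graph`.
#' @return named integer vector over all cells in the frame.
#' @export
graph_degrees <- function(graph) {
  deg <- stats::setNames(integer(length(graph$ids)), graph$ids)
  if (nrow(graph$edges)) {
    t1 <- table(graph$edges$a); t2 <- table(graph$edges$b)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

has_edge <- function(graph, a, b) {
  any((graph$edges$a == a & graph$edges$b == b) |
        (graph$edges$a == b & graph$edges$b == a))
}

# cache of per-frame neighbor graphs over a forest
graph_provider <- function(forest, k_candidates = 20L, cutoff = 2) {
  cache <- new.env(parent = emptyenv())
  function(frame) {
    key <- as.character(frame)
    g <- cache[[key]]
    if (is.null(g)) {
      g <- neighbor_graph(positions_at_frame(forest, frame),
                          k_candidates = k_candidates, cutoff = cutoff,
                          frame = frame)
      cache[[key]] <- g
    }
    g
  }
}

# follow one cell forward to `frame`, substituting a random daughter
# whenever the current track divides; returns NA if the lineage dies or
# is lost before `frame`
follow_to_frame <- function(forest, track_id, frame) {
  tr <- forest$tracks
  id <- track_id
  repeat {
    if (tr[id, "last_frame"] >= frame) return(id)
    d1 <- tr[id, "daughter1"]
    if (is.na(d1)) return(NA_character_)
    id <- if (stats::runif(1) < 0.5) d1 else tr[id, "daughter2"]
  }
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Neighbor persistence of newly born cells
#'
#' For every newly born cell, its neighbor partners are selected
#' `selection_delay_h` after the division (when nuclei have returned to the
#' basal side), and each (focal, partner) pair is followed for each
#' horizon. If a member of a pair divides during follow-up, one of its
#' daughters (chosen uniformly with the seeded RNG) is followed instead.
#' A pair counts as still-neighbors at a horizon iff the (possibly
#' substituted) pair is an edge of the neighbor graph at the frame nearest
#' the horizon. Pairs whose follow window extends beyond the movie are
#' excluded and counted; pairs whose lineage dies or is lost count as
#' separated.
#'
#' @param forest a `lineage_forest`.
#' @param horizons_h follow-up horizons in hours (default 2 and 10).
#' @param k_candidates,cutoff neighbor-graph parameters.
#' @param selection_delay_h delay between division and partner selection.
#' @param seed RNG seed for daughter substitution.
#' @param focal_tracks optionally restrict the focal cells.
#' @return data frame per horizon: `horizon_h`, `fraction`, `n_pairs`,
#'   `n_excluded`.
#' @export
follow_pairs <- function(forest, horizons_h = c(2, 10), k_candidates = 20L,
                         cutoff = 2, selection_delay_h = 1, seed = 1L,
                         focal_tracks = NULL) {
  dt <- forest$frame_interval_h
  gp <- graph_provider(forest, k_candidates, cutoff)
  tr <- forest$tracks
  newborn <- tr$track_id[!is.na(tr$parent)]
  if (!is.null(focal_tracks)) newborn <- intersect(newborn, focal_tracks)
  sel_off <- round(selection_delay_h / dt)
  res <- lapply(horizons_h, function(h) c(kept = 0, still = 0, excl = 0))
  names(res) <- as.character(horizons_h)
  with_seed(seed, {
    for (id in newborn) {
      fs <- tr[id, "first_frame"] + sel_off
      if (fs > tr[id, "last_frame"]) next     # focal gone before selection
      g0 <- gp(fs)
      e <- g0$edges
      partners <- c(e$b[e$a == id], e$a[e$b == id])
      if (!length(partners)) next
      for (h in horizons_h) {
        fh <- fs + round(h / dt)
        key <- as.character(h)
        if (fh > forest$movie_end_frame) {
          res[[key]]["excl"] <- res[[key]]["excl"] + length(partners)
          next
        }
        gh <- gp(fh)
        for (p in partners) {
          id2 <- follow_to_frame(forest, id, fh)
          p2 <- follow_to_frame(forest, p, fh)
          res[[key]]["kept"] <- res[[key]]["kept"] + 1
          if (!is.na(id2) && !is.na(p2) && has_edge(gh, id2, p2)) {
            res[[key]]["still"] <- res[[key]]["still"] + 1
          }
        }
      }
    }
  })
  out <- data.frame(horizon_h = horizons_h,
                    fraction = vapply(res, function(r) {
                      if (r[["kept"]] > 0) r[["still"]] / r[["kept"]] else NaN
                    }, numeric(1)),
                    n_pairs = vapply(res, `[[`, numeric(1), "kept"),
                    n_excluded = vapply(res, `[[`, numeric(1), "excl"))
  rownames(out) <- NULL
  out
}

#' Separation of same-type sister pairs
#'
#' Applies the [follow_pairs()] protocol to sister pairs that share the
#' same inferred type: partners are the two daughters of a fork, selected
#' `selection_delay_h` after their birth, followed per horizon with random
#' daughter substitution, and the still-neighbors fraction is reported per
#' cell type.
#'
#' @param typed a `typed_forest`.
#' @inheritParams follow_pairs
#' @return data frame `type`, `horizon_h`, `fraction`, `n_pairs`,
#'   `n_excluded`.
#' @export
sister_separation <- function(typed, horizons_h = c(2, 10), k_candidates = 20L,
                              cutoff = 2, selection_delay_h = 1, seed = 1L) {
  forest <- typed$forest
  dt <- forest$frame_interval_h
  tr <- forest$tracks
  forks <- tr[!is.na(tr$daughter1), , drop = FALSE]
  if (!nrow(forks)) {
    warning("no divisions in forest: no sister pairs to follow")
    return(data.frame(type = character(0), horizon_h = numeric(0),
                      fraction = numeric(0), n_pairs = numeric(0),
                      n_excluded = numeric(0)))
  }
  ty <- typed$track_types
  same <- ty[forks$daughter1] == ty[forks$daughter2] &
    ty[forks$daughter1] != "UNKNOWN"
  forks <- forks[same, , drop = FALSE]
  gp <- graph_provider(forest, k_candidates, cutoff)
  sel_off <- round(selection_delay_h / dt)
  acc <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(forks))) {
      d1 <- forks$daughter1[i]; d2 <- forks$daughter2[i]
      type <- ty[[d1]]
      fs <- tr[d1, "first_frame"] + sel_off
      if (fs > min(tr[d1, "last_frame"], tr[d2, "last_frame"])) next
      for (h in horizons_h) {
        fh <- fs + round(h / dt)
        key <- paste(type, h)
        if (is.null(acc[[key]])) acc[[key]] <- c(kept = 0, still = 0, excl = 0)
        if (fh > forest$movie_end_frame) {
          acc[[key]]["excl"] <- acc[[key]]["excl"] + 1
          next
        }
        a <- follow_to_frame(forest, d1, fh)
        b <- follow_to_frame(forest, d2, fh)
        acc[[key]]["kept"] <- acc[[key]]["kept"] + 1
        if (!is.na(a) && !is.na(b) && has_edge(gp(fh), a, b)) {
          acc[[key]]["still"] <- acc[[key]]["still"] + 1
        }
      }
    }
  })
  if (!length(acc)) {
    warning("no same-type sister pairs observable at the selection frame")
    return(data.frame(type = character(0), horizon_h = numeric(0),
                      fraction = numeric(0), n_pairs = numeric(0),
                      n_excluded = numeric(0)))
  }
  parts <- strsplit(names(acc), " ", fixed = TRUE)
  out <- data.frame(type = vapply(parts, `[[`, character(1), 1L),
                    horizon_h = as.numeric(vapply(parts, `[[`, character(1), 2L)),
                    fraction = vapply(acc, function(r) {
                      if (r[["kept"]] > 0) r[["still"]] / r[["kept"]] else NaN
                    }, numeric(1)),
                    n_pairs = vapply(acc, `[[`, numeric(1), "kept"),
                    n_excluded = vapply(acc, `[[`, numeric(1), "excl"))
  out <- out[order(out$type, out$horizon_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}
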