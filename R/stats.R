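real_types <- function() setdiff(cell_type_levels(), "UNKNOWN")

endpoint_sister_pairs <- function(typed) {
  forest <- typed$forest
  tr <- forest$tracks
  forks <- tr[!is.na(tr$daughter1), , drop = FALSE]
  d1 <- forks$daughter1; d2 <- forks$daughter2
  at_end <- tr[d1, "last_frame"] == forest$movie_end_frame &
    tr[d2, "last_frame"] == forest$movie_end_frame &
    is.na(tr[d1, "daughter1"]) & is.na(tr[d2, "daughter1"])
  data.frame(daughter1 = d1[at_end], daughter2 = d2[at_end],
             type1 = unname(typed$track_types[d1[at_end]]),
             type2 = unname(typed$track_types[d2[at_end]]))
}

#' Sister-type histogram at the movie end point
#'
#' For sister pairs in which both cells are alive at the movie end point,
#' counts every type combination. Per the column-wise convention, for each
#' type column the pairs with at least one member of that type are counted,
#' same-type pairs counting twice in their own column; each column of the
#' normalised matrix is divided by its sum. Pairs with an `UNKNOWN` member
#' are excluded and reported.
#'
#' @param typed a `typed_forest`.
#' @return object of class `sister_type_histogram` with `raw` (symmetric
#'   count matrix), `freq` (column-normalised), `n_pairs`, `n_excluded`,
#'   `same_type_fraction`.
#' @export
sister_type_histogram <- function(typed) {
  pairs <- endpoint_sister_pairs(typed)
  keep <- pairs$type1 != "UNKNOWN" & pairs$type2 != "UNKNOWN"
  excl <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  lev <- real_types()
  raw <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  if (!nrow(pairs)) {
    warning("no end-point sister pairs")
  } else {
    for (i in seq_len(nrow(pairs))) {
      raw[pairs$type1[i], pairs$type2[i]] <- raw[pairs$type1[i], pairs$type2[i]] + 1
      raw[pairs$type2[i], pairs$type1[i]] <- raw[pairs$type2[i], pairs$type1[i]] + 1
    }
  }
  cs <- colSums(raw)
  freq <- sweep(raw, 2L, ifelse(cs > 0, cs, 1), `/`)
  freq[, cs == 0] <- NA_real_
  same <- if (nrow(pairs)) mean(pairs$type1 == pairs$type2) else NaN
  structure(list(raw = raw, freq = freq, n_pairs = nrow(pairs),
                 n_excluded = excl, same_type_fraction = same),
            class = "sister_type_histogram")
}

#' @export
print.sister_type_histogram <- function(x, ...) {
  cat("End-point sister pairs: ", x$n_pairs, " (", x$n_excluded,
      " excluded), same-type fraction ", round(x$same_type_fraction, 3),
      "\n", sep = "")
  occupied <- colSums(x$raw) > 0
  print(round(x$freq[occupied, occupied, drop = FALSE], 3))
  invisible(x)
}

#' End-point cell ages per type
#'
#' Age of each cell present at the movie end point: the time since its
#' birth (its track's first frame); cells present from the movie start,
#' which were never seen to be born, get the full movie length.
#'
#' @param typed a `typed_forest`.
#' @param movie_length_h movie duration in hours; defaults to
#'   `movie_end_frame * frame_interval_h`.
#' @return named list of per-type age vectors (hours).
#' @export
endpoint_ages <- function(typed, movie_length_h = NULL) {
  forest <- typed$forest
  dt <- forest$frame_interval_h
  if (is.null(movie_length_h)) movie_length_h <- forest$movie_end_frame * dt
  tr <- forest$tracks
  ep <- tr[tr$last_frame == forest$movie_end_frame & is.na(tr$daughter1), , drop = FALSE]
  age <- ifelse(is.na(ep$parent), movie_length_h,
                movie_length_h - ep$first_frame * dt)
  type <- unname(typed$track_types[ep$track_id])
  out <- split(age, factor(type, levels = cell_type_levels()))
  lapply(out, unname)
}

# connected same-type lineage segments: a daughter extends its mother's
# segment iff it has no transition and shares the mother's end type
type_segments <- function(typed) {
  tr <- typed$forest$tracks
  ty <- typed$track_types
  trans_tracks <- typed$transitions$track_id
  seg <- stats::setNames(seq_len(nrow(tr)), tr$track_id)
  ord <- tr$track_id[order(tr$first_frame)]
  for (id in ord) {
    p <- tr[id, "parent"]
    if (!is.na(p) && !(id %in% trans_tracks) && ty[[p]] == ty[[id]]) {
      seg[id] <- seg[[p]]
    }
  }
  seg
}

#' Number of divisions per cell type
#'
#' Within each maximal same-type connected lineage segment, counts the
#' division forks whose mother carries that type, and reports the
#' per-segment distribution for each type.
#'
#' @param typed a `typed_forest`.
#' @return named list (per type) of integer vectors, one entry per
#'   segment.
#' @export
divisions_per_type <- function(typed) {
  tr <- typed$forest$tracks
  ty <- typed$track_types
  seg <- type_segments(typed)
  divides <- !is.na(tr$daughter1)
  out <- stats::setNames(vector("list", length(real_types())), real_types())
  for (t in real_types()) {
    in_t <- tr$track_id[ty[tr$track_id] == t]
    if (!length(in_t)) { out[[t]] <- integer(0); next }
    segs <- split(in_t, seg[in_t])
    out[[t]] <- unname(vapply(segs, function(ids) {
      sum(divides[match(ids, tr$track_id)])
    }, numeric(1)))
  }
  out
}

#' Cell-cycle durations per type
#'
#' Complete cycles only: tracks that begin at a division and end at a
#' division. The duration is the fork-to-fork time and is attributed to
#' the track's inferred type at its division.
#'
#' @param typed a `typed_forest`.
#' @return named list of per-type durations (hours).
#' @export
cycle_durations <- function(typed) {
  forest <- typed$forest
  dt <- forest$frame_interval_h
  tr <- forest$tracks
  complete <- !is.na(tr$parent) & !is.na(tr$daughter1)
  dur <- (tr$last_frame[complete] + 1L - tr$first_frame[complete]) * dt
  type <- unname(typed$track_types[tr$track_id[complete]])
  out <- split(dur, factor(type, levels = cell_type_levels()))
  lapply(out, unname)
}

subtree_ids <- function(tr, root) {
  out <- character(0)
  stack <- root
  while (length(stack)) {
    id <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, id)
    d1 <- tr[id, "daughter1"]
    if (!is.na(d1)) stack <- c(stack, d1, tr[id, "daughter2"])
  }
  out
}

#' Census of maximal two-type subtrees
#'
#' Enumerates the maximal subtrees whose cells comprise exactly two
#' distinct inferred types (`UNKNOWN` never counts as a type): a subtree
#' rooted at a track qualifies when it contains exactly two types and is
#' maximal, i.e. its root is a tree root or the subtree rooted at the
#' parent contains a third type. Subtrees in which more than half of the
#' cells died or were lost are excluded and counted.
#'
#' @param typed a `typed_forest`.
#' @return object of class `subtree_census`: `counts` (named by unordered
#'   type pair, `"A|B"` with A < B), `n_excluded`, and `roots` (the census
#'   subtree roots).
#' @export
two_type_subtrees <- function(typed) {
  forest <- typed$forest
  tr <- forest$tracks
  ty <- typed$track_types
  ids <- tr$track_id
  # bottom-up distinct-type sets per subtree
  tset <- stats::setNames(vector("list", length(ids)), ids)
  ord <- ids[order(tr$first_frame, decreasing = TRUE)]
  for (id in ord) {
    s <- if (ty[[id]] == "UNKNOWN") character(0) else ty[[id]]
    d1 <- tr[id, "daughter1"]
    if (!is.na(d1)) s <- union(s, union(tset[[d1]], tset[[tr[id, "daughter2"]]]))
    tset[[id]] <- sort(s)
  }
  nt <- vapply(tset, length, integer(1))
  parent <- stats::setNames(tr$parent, ids)
  cand <- ids[nt == 2L & (is.na(parent[ids]) | nt[parent[ids]] > 2L)]
  counts <- integer(0)
  n_excl <- 0L
  roots <- character(0)
  for (id in cand) {
    sub <- subtree_ids(tr, id)
    frac_bad <- mean(tr[sub, "end_reason"] %in% c("death", "lost"))
    if (frac_bad > 0.5) { n_excl <- n_excl + 1L; next }
    key <- paste(tset[[id]], collapse = "|")
    counts[key] <- if (is.na(counts[key])) 1L else counts[key] + 1L
    roots <- c(roots, id)
  }
  structure(list(counts = counts, n_excluded = n_excl, roots = roots),
            class = "subtree_census")
}

#' @export
print.subtree_census <- function(x, ...) {
  cat("Two-type subtree census: ", sum(x$counts), " subtrees (",
      x$n_excluded, " excluded)\n", sep = "")
  if (length(x$counts)) {
    tot <- sum(x$counts)
    for (k in names(sort(x$counts, decreasing = TRUE))) {
      cat(sprintf("  %-22s %4d  (%.1f%%)\n", k, x$counts[[k]],
                  100 * x$counts[[k]] / tot))
    }
  }
  invisible(x)
}
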