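new_typed_forest <- function(forest, intervals, transitions,
                             track_types = NULL, conflicts = NULL,
                             low_confidence = character(0),
                             endpoint_types = NULL) {
  if (is.null(track_types)) {
    last <- intervals[!duplicated(intervals$track_id, fromLast = TRUE), ]
    track_types <- stats::setNames(last$type, last$track_id)
    track_types <- track_types[forest$tracks$track_id]
    names(track_types) <- forest$tracks$track_id
  }
  structure(list(forest = forest, intervals = intervals,
                 transitions = transitions, track_types = track_types,
                 conflicts = conflicts, low_confidence = low_confidence,
                 endpoint_types = endpoint_types),
            class = "typed_forest")
}

#' Backpropagate end-point cell types along lineage trees
#'
#' Starting from the typed cells at the movie end point, types are
#' propagated from the leaves towards the roots of every lineage tree,
#' assigning one type per track and, where a mother and a daughter differ,
#' a transition event placed halfway through the daughter's observed
#' lifetime. At each division fork the rules are applied in order:
#' (R2) if both daughters carry the same inferred type, the mother is that
#' type; (R3) if exactly one daughter is a stem cell, the mother is a stem
#' cell; (R4) if one daughter is TA and the other is not a stem cell, the
#' mother is TA. A dead daughter does not constrain the fork: the mother
#' inherits the living daughter's type. Daughters of unknown type (lost
#' tracks, unmatched end points) are treated the same way but the mother is
#' flagged low-confidence. Two daughters with distinct terminally
#' differentiated types cannot be resolved; the mother becomes `UNKNOWN`
#' and the fork is reported as a conflict.
#'
#' @param forest a `lineage_forest`.
#' @param endpoint_types named character vector of end-point types for
#'   terminal tracks (an `endpoint_typing` object is also accepted);
#'   terminal tracks without an entry get `UNKNOWN`.
#' @return an object of class `typed_forest` with elements `intervals`
#'   (contiguous per-track type intervals covering every track),
#'   `transitions`, `track_types`, `conflicts` and `low_confidence`.
#' @export
backpropagate <- function(forest, endpoint_types) {
  if (inherits(endpoint_types, "endpoint_typing")) {
    endpoint_types <- endpoint_types$endpoint_types
  }
  tr <- forest$tracks
  bad <- setdiff(names(endpoint_types), tr$track_id)
  if (length(bad)) stop("endpoint types for unknown track(s): ", paste(bad, collapse = ", "))
  bad_t <- setdiff(unique(endpoint_types), cell_type_levels())
  if (length(bad_t)) stop("unknown cell type label(s): ", paste(bad_t, collapse = ", "))

  type <- stats::setNames(rep(NA_character_, nrow(tr)), tr$track_id)
  low_conf <- character(0)
  conflicts <- list()

  # daughters always start after their mother, so processing tracks by
  # decreasing first frame visits every fork after both its daughters
  ord <- tr$track_id[order(tr$first_frame, tr$track_id, decreasing = TRUE)]
  for (id in ord) {
    d1 <- tr[id, "daughter1"]
    if (is.na(d1)) {
      type[id] <- if (id %in% names(endpoint_types)) endpoint_types[[id]] else "UNKNOWN"
      next
    }
    d2 <- tr[id, "daughter2"]
    t1 <- type[[d1]]; t2 <- type[[d2]]
    if (t1 == "UNKNOWN" || t2 == "UNKNOWN") {
      other <- if (t1 == "UNKNOWN") t2 else t1
      unk <- if (t1 == "UNKNOWN") d1 else d2
      type[id] <- other                       # may itself be UNKNOWN
      if (tr[unk, "end_reason"] != "death" && other != "UNKNOWN") {
        low_conf <- c(low_conf, id)
      }
    } else if (t1 == t2) {                    # R2: symmetric fate
      type[id] <- t1
    } else if (t1 == "STEM" || t2 == "STEM") { # R3: stem wins asymmetric forks
      type[id] <- "STEM"
    } else if (t1 == "TA" || t2 == "TA") {     # R4: TA vs non-stem
      type[id] <- "TA"
    } else {
      type[id] <- "UNKNOWN"
      conflicts[[length(conflicts) + 1L]] <-
        data.frame(track_id = id, daughter1 = d1, daughter2 = d2,
                   type1 = t1, type2 = t2)
    }
  }

  # transitions: daughter type differs from mother type (both known)
  parent <- stats::setNames(tr$parent, tr$track_id)
  has_parent <- !is.na(parent)
  mtype <- rep(NA_character_, nrow(tr))
  mtype[has_parent] <- type[parent[has_parent]]
  is_trans <- has_parent & !is.na(mtype) & mtype != "UNKNOWN" &
    type != "UNKNOWN" & mtype != type
  ev_ids <- tr$track_id[is_trans]
  ev_frame <- (tr$first_frame[is_trans] + tr$last_frame[is_trans]) %/% 2L

  pos <- matrix(NA_real_, length(ev_ids), 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  if (length(ev_ids)) {
    key_pts <- paste(forest$points$track_id, forest$points$frame)
    idx <- match(paste(ev_ids, ev_frame), key_pts)
    pos <- as.matrix(forest$points[idx, c("x", "y", "z")])
  }
  transitions <- data.frame(track_id = ev_ids,
                            from_type = mtype[is_trans],
                            to_type = unname(type[ev_ids]),
                            event_frame = ev_frame,
                            t_h = ev_frame * forest$frame_interval_h,
                            x = pos[, 1L], y = pos[, 2L], z = pos[, 3L])
  rownames(transitions) <- NULL

  # piecewise-constant intervals covering each track
  ivl <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    id <- tr$track_id[i]
    k <- match(id, ev_ids)
    if (!is.na(k)) {
      ef <- ev_frame[k]
      if (ef > tr$first_frame[i]) {
        ivl[[i]] <- data.frame(track_id = id,
                               start_frame = c(tr$first_frame[i], ef),
                               end_frame = c(ef - 1L, tr$last_frame[i]),
                               type = c(transitions$from_type[k], type[[id]]))
        next
      }
    }
    ivl[[i]] <- data.frame(track_id = id, start_frame = tr$first_frame[i],
                           end_frame = tr$last_frame[i], type = type[[id]])
  }
  intervals <- do.call(rbind, ivl)
  rownames(intervals) <- NULL
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else NULL

  new_typed_forest(forest, intervals, transitions, track_types = type,
                   conflicts = conflicts, low_confidence = unique(low_conf),
                   endpoint_types = endpoint_types)
}

#' Transition events with positions
#'
#' One event per mother/daughter type mismatch, placed at the midpoint of
#' the daughter track's observed lifetime, with the cell's 3D position at
#' that frame. This is where a lineage is inferred to have committed to its
#' new type.
#'
#' @param typed a `typed_forest`.
#' @return data frame `track_id`, `from_type`, `to_type`, `event_frame`,
#'   `t_h`, `x`, `y`, `z`.
#' @export
collect_transitions <- function(typed) {
  stopifnot(inherits(typed, "typed_forest"))
  typed$transitions
}

#' Inferred type of a track at a given frame
#' @param typed a `typed_forest`.
#' @param track_id track identifier.
#' @param frame integer frame.
#' @export
type_at <- function(typed, track_id, frame) {
  iv <- typed$intervals
  hit <- iv$track_id == track_id & iv$start_frame <= frame & iv$end_frame >= frame
  if (!any(hit)) stop("track ", track_id, " has no type at frame ", frame)
  iv$type[which(hit)[1L]]
}

#' @export
print.typed_forest <- function(x, ...) {
  cat("Typed lineage forest: ", nrow(x$forest$tracks), " tracks, ",
      nrow(x$transitions), " type transitions, ",
      if (is.null(x$conflicts)) 0L else nrow(x$conflicts), " conflicts\n", sep = "")
  print(table(x$track_types))
  invisible(x)
}

#' @export
summary.typed_forest <- function(object, ...) {
  list(types = table(object$track_types),
       n_transitions = nrow(object$transitions),
       transition_kinds = if (nrow(object$transitions))
         table(paste(object$transitions$from_type, "->", object$transitions$to_type)),
       n_conflicts = if (is.null(object$conflicts)) 0L else nrow(object$conflicts),
       n_low_confidence = length(object$low_confidence))
}

#' Plot a typed lineage forest
#'
#' Draws the classic lineage-tree diagram (time running downward, forks at
#' divisions) with branches coloured by inferred type and transition events
#' marked.
#'
#' @param x a `typed_forest`.
#' @param roots which trees to draw (default all roots).
#' @param ... passed to [graphics::plot()].
#' @export
plot.typed_forest <- function(x, roots = NULL, ...) {
  forest <- x$forest
  tr <- forest$tracks
  if (is.null(roots)) roots <- root_ids(forest)
  pal <- c(STEM = "#1b9e77", TA = "#7570b3", ENTEROCYTE = "#d95f02",
           EEC = "#e7298a", PANETH = "#66a61e", GOBLET = "#e6ab02",
           IMPC = "#a6761d", UNKNOWN = "grey60")
  xpos <- new.env(parent = emptyenv()); cnt <- 0
  leaf_order <- function(id) {
    d1 <- tr[id, "daughter1"]
    if (is.na(d1)) {
      cnt <<- cnt + 1
      assign(id, cnt, envir = xpos)
    } else {
      leaf_order(d1); leaf_order(tr[id, "daughter2"])
      assign(id, (get(d1, envir = xpos) + get(tr[id, "daughter2"], envir = xpos)) / 2,
             envir = xpos)
    }
  }
  for (r in roots) leaf_order(r)
  dt <- forest$frame_interval_h
  graphics::plot(NA, xlim = c(0.5, cnt + 0.5),
                 ylim = c(forest$movie_end_frame * dt, 0),
                 xlab = "", ylab = "time (h)", xaxt = "n", ...)
  iv <- x$intervals
  draw <- function(id) {
    px <- get(id, envir = xpos)
    seg <- iv[iv$track_id == id, , drop = FALSE]
    for (j in seq_len(nrow(seg))) {
      graphics::segments(px, seg$start_frame[j] * dt, px, (seg$end_frame[j] + 1) * dt,
                         col = pal[[seg$type[j]]], lwd = 2)
    }
    d1 <- tr[id, "daughter1"]
    if (!is.na(d1)) {
      d2 <- tr[id, "daughter2"]
      y <- (tr[id, "last_frame"] + 1) * dt
      graphics::segments(get(d1, envir = xpos), y, get(d2, envir = xpos), y,
                         col = pal[[x$track_types[[id]]]], lwd = 2)
      draw(d1); draw(d2)
    }
  }
  for (r in roots) draw(r)
  ev <- x$transitions[x$transitions$track_id %in% ls(xpos), , drop = FALSE]
  if (nrow(ev)) {
    exs <- vapply(ev$track_id, function(id) get(id, envir = xpos), numeric(1))
    graphics::points(exs, ev$event_frame * dt, pch = 25, bg = "black", cex = 0.8)
  }
  graphics::legend("bottomright", legend = names(pal), col = pal, lwd = 2,
                   cex = 0.6, bg = "white")
  invisible(x)
}
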