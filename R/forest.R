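#' Build a lineage forest from tracked-nuclei tables
#'
#' The forest is the columnar representation of a set of tracked cells:
#' a points table with one row per (track, frame) and a tracks table with
#' one row per cell, carrying its parent, its 0 or 2 daughters and the
#' reason its track ends. Positions are 3D micrometres with anisotropy
#' already corrected; time is stored as integer frames and converted to
#' hours through `frame_interval_h` (default 0.2 h, i.e. one frame every
#' 12 minutes).
#'
#' @param points data frame with columns `track_id`, `frame`, `x`, `y`, `z`
#'   (the tabular file format uses `x_um`, `y_um`, `z_um`; both are
#'   accepted).
#' @param links data frame with columns `child_id`, `parent_id`; each parent
#'   must appear exactly twice (division forks are binary).
#' @param movie_end_frame last frame of the recording; defaults to the
#'   largest frame present.
#' @param frame_interval_h hours per frame.
#' @param end_reasons optional data frame (`track_id`, `end_reason`) marking
#'   tracks that end in `"death"`. Tracks ending before the movie end
#'   without daughters and without an explicit reason are conservatively
#'   labelled `"lost"`; lost or dead cells cannot anchor end-point types.
#' @return an object of class `lineage_forest`.
#' @export
lineage_forest <- function(points, links = NULL, movie_end_frame = NULL,
                           frame_interval_h = 0.2, end_reasons = NULL) {
  nm <- names(points)
  for (ax in c("x", "y", "z")) {
    um <- paste0(ax, "_um")
    if (!ax %in% nm && um %in% nm) names(points)[nm == um] <- ax
    nm <- names(points)
  }
  need <- c("track_id", "frame", "x", "y", "z")
  if (!all(need %in% names(points))) {
    stop("points table needs columns: ", paste(need, collapse = ", "))
  }
  points <- data.frame(track_id = as.character(points$track_id),
                       frame = as.integer(points$frame),
                       x = as.numeric(points$x), y = as.numeric(points$y),
                       z = as.numeric(points$z))
  points <- points[order(points$track_id, points$frame), , drop = FALSE]
  rownames(points) <- NULL

  ids <- unique(points$track_id)
  first_frame <- tapply(points$frame, points$track_id, min)[ids]
  last_frame <- tapply(points$frame, points$track_id, max)[ids]
  n_pts <- tapply(points$frame, points$track_id, length)[ids]
  bad <- ids[n_pts != (last_frame - first_frame + 1L)]
  if (length(bad)) {
    stop("structural error: non-consecutive or duplicated frames in track(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(movie_end_frame)) movie_end_frame <- max(points$frame)
  movie_end_frame <- as.integer(movie_end_frame)
  if (any(last_frame > movie_end_frame)) {
    stop("structural error: track(s) extend beyond movie_end_frame: ",
         paste(ids[last_frame > movie_end_frame], collapse = ", "))
  }

  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  d1 <- d2 <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(links) && nrow(links)) {
    links <- data.frame(child_id = as.character(links$child_id),
                        parent_id = as.character(links$parent_id))
    miss <- setdiff(unique(c(links$child_id, links$parent_id)), ids)
    if (length(miss)) {
      stop("structural error: link references unknown track(s): ",
           paste(miss, collapse = ", "))
    }
    if (anyDuplicated(links$child_id)) {
      stop("structural error: track(s) with more than one parent: ",
           paste(unique(links$child_id[duplicated(links$child_id)]), collapse = ", "))
    }
    parent[links$child_id] <- links$parent_id
    kids <- split(links$child_id, links$parent_id)
    nk <- vapply(kids, length, integer(1))
    if (any(nk != 2L)) {
      stop("structural error: parent(s) with ", paste(unique(nk[nk != 2L]), collapse = "/"),
           " daughters (must be exactly 2): ", paste(names(kids)[nk != 2L], collapse = ", "))
    }
    for (p in names(kids)) {
      ks <- sort(kids[[p]])
      d1[p] <- ks[1L]; d2[p] <- ks[2L]
      if (any(first_frame[ks] != last_frame[p] + 1L)) {
        stop("structural error: daughters of ", p,
             " must start at frame ", last_frame[p] + 1L)
      }
    }
  }

  end_reason <- stats::setNames(rep(NA_character_, length(ids)), ids)
  end_reason[!is.na(d1)] <- "division"
  end_reason[is.na(d1) & last_frame == movie_end_frame] <- "movie_end"
  open <- is.na(end_reason)
  if (!is.null(end_reasons) && nrow(end_reasons)) {
    er <- stats::setNames(as.character(end_reasons$end_reason),
                          as.character(end_reasons$track_id))
    er <- er[names(er) %in% ids[open]]
    bad_reason <- setdiff(unique(er), c("death", "lost"))
    if (length(bad_reason)) stop("unknown end_reason value(s): ", paste(bad_reason, collapse = ", "))
    end_reason[names(er)] <- er
  }
  end_reason[is.na(end_reason)] <- "lost"

  tracks <- data.frame(track_id = ids, parent = unname(parent),
                       daughter1 = unname(d1), daughter2 = unname(d2),
                       first_frame = as.integer(unname(first_frame)),
                       last_frame = as.integer(unname(last_frame)),
                       end_reason = unname(end_reason))
  rownames(tracks) <- tracks$track_id
  structure(list(points = points, tracks = tracks,
                 movie_end_frame = movie_end_frame,
                 frame_interval_h = frame_interval_h),
            class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  tr <- x$tracks
  cat("Lineage forest: ", nrow(tr), " tracks (", sum(is.na(tr$parent)),
      " roots, ", sum(!is.na(tr$daughter1)), " divisions), frames 0..",
      x$movie_end_frame, " at ", x$frame_interval_h, " h/frame\n", sep = "")
  cat("  end reasons:", paste(names(table(tr$end_reason)),
                              table(tr$end_reason), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.lineage_forest <- function(object, ...) {
  tr <- object$tracks
  list(n_tracks = nrow(tr), n_roots = sum(is.na(tr$parent)),
       n_divisions = sum(!is.na(tr$daughter1)),
       n_endpoint = sum(tr$last_frame == object$movie_end_frame),
       end_reasons = table(tr$end_reason),
       movie_end_frame = object$movie_end_frame,
       movie_length_h = object$movie_end_frame * object$frame_interval_h)
}

root_ids <- function(forest) forest$tracks$track_id[is.na(forest$tracks$parent)]

#' Tracks present at the movie end point
#' @param forest a `lineage_forest`.
#' @return character vector of track ids whose last frame is the movie end.
#' @export
endpoint_tracks <- function(forest) {
  forest$tracks$track_id[forest$tracks$last_frame == forest$movie_end_frame]
}

#' Positions of all cells present in one frame
#' @param forest a `lineage_forest`.
#' @param frame integer frame index.
#' @return numeric matrix with columns x, y, z and track ids as row names.
#' @export
positions_at_frame <- function(forest, frame) {
  p <- forest$points[forest$points$frame == frame, , drop = FALSE]
  m <- as.matrix(p[, c("x", "y", "z")])
  rownames(m) <- p$track_id
  m
}

track_point <- function(forest, track_id, frame) {
  p <- forest$points
  row <- p[p$track_id == track_id & p$frame == frame, , drop = FALSE]
  if (!nrow(row)) stop("track ", track_id, " has no point at frame ", frame)
  c(x = row$x[1], y = row$y[1], z = row$z[1])
}

sister_of <- function(forest, track_id) {
  p <- forest$tracks[track_id, "parent"]
  if (is.na(p)) return(NA_character_)
  ds <- unlist(forest$tracks[p, c("daughter1", "daughter2")], use.names = FALSE)
  setdiff(ds, track_id)
}

## ---- tabular I/O ----------------------------------------------------------

#' Read / write a lineage forest
#'
#' Two on-disk dialects are supported. The native tabular format is a
#' directory of plain CSV files: `tracks.csv` (track_id, frame, x_um, y_um,
#' z_um), `links.csv` (child_id, parent_id), `metadata.csv` (key, value;
#' keys `movie_end_frame` and `frame_interval_h`) and an optional
#' `end_reasons.csv` (track_id, end_reason). The tracker-JSON dialect is a
#' single JSON object with `tracks` (id + list of [frame, x, y, z] points),
#' `links` (child/parent id pairs) and optional `movie_end_frame`,
#' `frame_interval_h` and `end_reasons` entries; unknown keys are ignored.
#' A schema ships in `inst/extdata/tracker-json-schema.json`.
#'
#' @param path directory (tabular) or file (tracker-json).
#' @param format `"tabular"` or `"tracker-json"`.
#' @return `read_forest()` returns a `lineage_forest`; `write_forest()`
#'   returns `path` invisibly.
#' @export
read_forest <- function(path, format = c("tabular", "tracker-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (format == "tabular") {
    tracks_file <- file.path(path, "tracks.csv")
    if (!file.exists(tracks_file)) stop("parse error: missing ", tracks_file)
    points <- utils::read.csv(tracks_file)
    links_file <- file.path(path, "links.csv")
    links <- if (file.exists(links_file)) utils::read.csv(links_file, colClasses = "character") else NULL
    meta_file <- file.path(path, "metadata.csv")
    mef <- NULL; fih <- 0.2
    if (file.exists(meta_file)) {
      meta <- utils::read.csv(meta_file)
      kv <- stats::setNames(meta$value, meta$key)
      if ("movie_end_frame" %in% names(kv)) mef <- as.integer(kv[["movie_end_frame"]])
      if ("frame_interval_h" %in% names(kv)) fih <- as.numeric(kv[["frame_interval_h"]])
    }
    er_file <- file.path(path, "end_reasons.csv")
    er <- if (file.exists(er_file)) utils::read.csv(er_file, colClasses = "character") else NULL
    lineage_forest(points, links, movie_end_frame = mef,
                   frame_interval_h = fih, end_reasons = er)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(obj$tracks)) stop("parse error: tracker-json file has no 'tracks' entry")
    pts <- lapply(obj$tracks, function(tr) {
      if (is.null(tr$id) || is.null(tr$points)) {
        stop("parse error: tracker-json track record needs 'id' and 'points'")
      }
      m <- do.call(rbind, lapply(tr$points, function(q) as.numeric(unlist(q)[1:4])))
      data.frame(track_id = as.character(tr$id), frame = as.integer(m[, 1L]),
                 x = m[, 2L], y = m[, 3L], z = m[, 4L])
    })
    points <- do.call(rbind, pts)
    links <- NULL
    if (length(obj$links)) {
      lk <- do.call(rbind, lapply(obj$links, function(q) as.character(unlist(q)[1:2])))
      links <- data.frame(child_id = lk[, 1L], parent_id = lk[, 2L])
    }
    er <- NULL
    if (length(obj$end_reasons)) {
      er <- data.frame(track_id = as.character(names(obj$end_reasons)),
                       end_reason = as.character(unlist(obj$end_reasons)))
    }
    lineage_forest(points, links,
                   movie_end_frame = if (!is.null(obj$movie_end_frame)) as.integer(obj$movie_end_frame),
                   frame_interval_h = if (!is.null(obj$frame_interval_h)) as.numeric(obj$frame_interval_h) else 0.2,
                   end_reasons = er)
  }
}

#' @rdname read_forest
#' @param forest a `lineage_forest`.
#' @export
write_forest <- function(forest, path, format = c("tabular", "tracker-json")) {
  format <- match.arg(format)
  if (format == "tabular") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    pts <- forest$points
    names(pts) <- c("track_id", "frame", "x_um", "y_um", "z_um")
    utils::write.csv(pts, file.path(path, "tracks.csv"), row.names = FALSE)
    tr <- forest$tracks
    links <- data.frame(child_id = c(tr$daughter1, tr$daughter2),
                        parent_id = c(tr$track_id, tr$track_id))
    links <- links[!is.na(links$child_id), , drop = FALSE]
    links <- links[order(links$child_id), , drop = FALSE]
    utils::write.csv(links, file.path(path, "links.csv"), row.names = FALSE)
    meta <- data.frame(key = c("movie_end_frame", "frame_interval_h"),
                       value = c(forest$movie_end_frame, forest$frame_interval_h))
    utils::write.csv(meta, file.path(path, "metadata.csv"), row.names = FALSE)
    er <- tr[tr$end_reason %in% c("death", "lost"), c("track_id", "end_reason")]
    utils::write.csv(er, file.path(path, "end_reasons.csv"), row.names = FALSE)
  } else {
    sp <- split(forest$points, forest$points$track_id)
    tracks <- lapply(names(sp), function(id) {
      p <- sp[[id]]
      list(id = id, points = lapply(seq_len(nrow(p)), function(i) {
        c(p$frame[i], p$x[i], p$y[i], p$z[i])
      }))
    })
    tr <- forest$tracks
    links <- Map(c, c(tr$daughter1, tr$daughter2), c(tr$track_id, tr$track_id))
    links <- unname(links[!is.na(c(tr$daughter1, tr$daughter2))])
    er <- tr$end_reason[tr$end_reason %in% c("death", "lost")]
    names(er) <- tr$track_id[tr$end_reason %in% c("death", "lost")]
    obj <- list(format = "tracker-json", tracks = tracks, links = links,
                movie_end_frame = forest$movie_end_frame,
                frame_interval_h = forest$frame_interval_h,
                end_reasons = as.list(er))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read / write a typed forest
#'
#' A typed forest is stored as the tabular forest directory plus
#' `intervals.csv` (track_id, start_frame, end_frame, type) and
#' `transitions.csv`. Reading back reproduces the saved content exactly.
#'
#' @param typed a `typed_forest` as returned by [backpropagate()].
#' @param path output directory.
#' @export
write_typed_forest <- function(typed, path) {
  stopifnot(inherits(typed, "typed_forest"))
  untyped <- setdiff(typed$forest$tracks$track_id, typed$intervals$track_id)
  if (length(untyped)) stop("untyped track(s): ", paste(untyped, collapse = ", "))
  write_forest(typed$forest, path, format = "tabular")
  utils::write.csv(typed$intervals, file.path(path, "intervals.csv"), row.names = FALSE)
  utils::write.csv(typed$transitions, file.path(path, "transitions.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_typed_forest
#' @export
read_typed_forest <- function(path) {
  forest <- read_forest(path, format = "tabular")
  intervals <- utils::read.csv(file.path(path, "intervals.csv"),
                               colClasses = c(track_id = "character"))
  transitions <- utils::read.csv(file.path(path, "transitions.csv"),
                                 colClasses = c(track_id = "character"))
  new_typed_forest(forest, intervals, transitions)
}

#' Read an end-point staining table
#'
#' CSV with columns `stain_cell_id`, `x`, `y`, `z` (micrometres,
#' post-fixation coordinates) and one column per marker, either numeric
#' intensities or logical positivity calls.
#' @param path CSV file.
#' @export
read_stain_table <- function(path) {
  st <- utils::read.csv(path, colClasses = c(stain_cell_id = "character"))
  need <- c("stain_cell_id", "x", "y", "z")
  if (!all(need %in% names(st))) stop("stain table needs columns: ", paste(need, collapse = ", "))
  miss <- setdiff(markers(), names(st))
  if (length(miss)) stop("stain table missing marker column(s): ", paste(miss, collapse = ", "))
  st
}

#' Read crypt-villus axis annotations
#'
#' CSV with columns `frame`, `point_index`, `x`, `y`, `z`, `is_neck`.
#' Control points (is_neck = 0) are ordered crypt-bottom first; each
#' annotated frame carries 3 to 6 of them plus exactly one neck point.
#' @param path CSV file.
#' @return data frame, one row per annotated point.
#' @export
read_axis_annotations <- function(path) {
  an <- utils::read.csv(path)
  need <- c("frame", "point_index", "x", "y", "z", "is_neck")
  if (!all(need %in% names(an))) stop("axis annotation needs columns: ", paste(need, collapse = ", "))
  an
}
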