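#' Fit the crypt-villus axis for one frame
#'
#' Interpolates a natural cubic spline through the annotated control points
#' (ordered crypt-bottom first) and reparameterises it to arc length by
#' dense sampling. The annotated crypt-neck point is projected onto the
#' curve to record the neck's arc-length coordinate.
#'
#' @param control_points numeric matrix (>= 3 rows, columns x, y, z in
#'   micrometres); consecutive points must not coincide.
#' @param neck_point 3D position of the crypt neck.
#' @param frame frame index the annotation belongs to.
#' @param step arc-length sampling step in micrometres (default 0.25).
#' @return object of class `crypt_axis` with the densely sampled curve,
#'   cumulative arc length, total length and `r_neck`.
#' @export
fit_axis <- function(control_points, neck_point = NULL, frame = NA_integer_,
                     step = 0.25) {
  P <- as.matrix(control_points)
  if (nrow(P) < 3L) stop("axis needs at least 3 control points, got ", nrow(P))
  if (ncol(P) != 3L) stop("control points must be 3D")
  seg <- sqrt(rowSums(diff(P)^2))
  if (any(seg == 0)) stop("coincident consecutive control points")
  tt <- c(0, cumsum(seg))
  # oversample in the chord parameter, then measure arc length cumulatively
  n_dense <- max(50L, ceiling(4 * tt[length(tt)] / step))
  tg <- seq(0, tt[length(tt)], length.out = n_dense)
  Q <- cbind(stats::spline(tt, P[, 1L], xout = tg, method = "natural")$y,
             stats::spline(tt, P[, 2L], xout = tg, method = "natural")$y,
             stats::spline(tt, P[, 3L], xout = tg, method = "natural")$y)
  s <- c(0, cumsum(sqrt(rowSums(diff(Q)^2))))
  total <- s[length(s)]
  # resample at uniform arc length
  sg <- seq(0, total, by = step)
  if (sg[length(sg)] < total) sg <- c(sg, total)
  tq <- stats::approx(s, tg, xout = sg, ties = "ordered")$y
  R <- cbind(stats::spline(tt, P[, 1L], xout = tq, method = "natural")$y,
             stats::spline(tt, P[, 2L], xout = tq, method = "natural")$y,
             stats::spline(tt, P[, 3L], xout = tq, method = "natural")$y)
  ax <- structure(list(frame = frame, control_points = P,
                       neck_point = neck_point, points = R, arclen = sg,
                       total_length = total, step = step, r_neck = NA_real_),
                  class = "crypt_axis")
  if (!is.null(neck_point)) {
    ax$r_neck <- project_onto_axis(matrix(neck_point, nrow = 1L), ax)$r
  }
  ax
}

#' @export
print.crypt_axis <- function(x, ...) {
  cat("Crypt-villus axis (frame ", x$frame, "): ", nrow(x$control_points),
      " control points, length ", round(x$total_length, 2), " um, neck at r = ",
      round(x$r_neck, 2), " um\n", sep = "")
  invisible(x)
}

#' Project cell positions onto a fitted axis
#'
#' For each position, finds the arc-length coordinate `r` that minimises
#' the distance `d` to the curve: nearest dense sample (spacing `step`,
#' default 0.25 um) followed by local parabolic refinement of the squared
#' distance. Distances use all three coordinates by default; `use_z =
#' FALSE` projects in the xy plane only.
#'
#' @param positions numeric matrix, one row per cell (x, y, z).
#' @param axis a `crypt_axis`.
#' @param use_z include the z coordinate in the distance.
#' @return data frame with columns `r` (arc length, micrometres, before
#'   per-frame zeroing) and `d` (residual distance).
#' @export
project_onto_axis <- function(positions, axis, use_z = TRUE) {
  X <- as.matrix(positions)
  if (ncol(X) != 3L) stop("positions must be 3D")
  dims <- if (use_z) 1:3 else 1:2
  Q <- axis$points[, dims, drop = FALSE]
  P <- X[, dims, drop = FALSE]
  M <- nrow(Q)
  D2 <- outer(rowSums(P^2), rep(1, M)) + outer(rep(1, nrow(P)), rowSums(Q^2)) -
    2 * P %*% t(Q)
  D2[D2 < 0] <- 0
  jm <- max.col(-D2, ties.method = "first")
  s <- axis$arclen
  r <- s[jm]
  d2 <- D2[cbind(seq_len(nrow(P)), jm)]
  if (M >= 3L) {
    i <- seq_len(nrow(P))
    j <- pmin(pmax(jm, 2L), M - 1L)   # refine around endpoint hits too
    y0 <- D2[cbind(i, j - 1L)]; y1 <- D2[cbind(i, j)]; y2 <- D2[cbind(i, j + 1L)]
    x0 <- s[j - 1L]; x1 <- s[j]; x2 <- s[j + 1L]
    # quadratic through the three samples; vertex of the parabola
    denom <- (y0 - 2 * y1 + y2)
    ok <- denom > 0
    if (any(ok)) {
      # uniform-spacing vertex formula is inexact at the appended end point,
      # so use the general three-point form
      a <- y0[ok]; b <- y1[ok]; cc <- y2[ok]
      xa <- x0[ok]; xb <- x1[ok]; xc <- x2[ok]
      num <- a * (xb^2 - xc^2) + b * (xc^2 - xa^2) + cc * (xa^2 - xb^2)
      den <- 2 * (a * (xb - xc) + b * (xc - xa) + cc * (xa - xb))
      xv <- num / den
      xv <- pmin(pmax(xv, xa), xc)
      ii <- i[ok]
      r[ii] <- xv
      # recompute d at the refined point by linear interpolation of the curve
      jlo <- ifelse(xv >= x1[ok], j[ok], j[ok] - 1L)
      frac <- (xv - s[jlo]) / (s[jlo + 1L] - s[jlo])
      Qr <- Q[jlo, , drop = FALSE] + (Q[jlo + 1L, , drop = FALSE] - Q[jlo, , drop = FALSE]) * frac
      d2[ii] <- rowSums((P[ii, , drop = FALSE] - Qr)^2)
    }
  }
  data.frame(r = r, d = sqrt(d2))
}

#' Zero and normalise axis positions within one frame
#'
#' The bottom-most cell (lowest `r`) defines position zero for its frame;
#' positions are then divided by the distance from the crypt neck to that
#' zero, so the neck sits at normalised position 1 in every frame.
#'
#' @param r arc-length positions of all cells present in the frame.
#' @param axis the frame's `crypt_axis` (supplies `r_neck`).
#' @return data frame `r` (zeroed, micrometres) and `r_norm`.
#' @export
zero_and_normalize <- function(r, axis) {
  if (!length(r)) stop("no cells in frame")
  r_offset <- min(r)
  denom <- axis$r_neck - r_offset
  if (!is.finite(denom) || denom <= 0) {
    stop("crypt neck at or below the bottom-most cell (frame ", axis$frame, ")")
  }
  data.frame(r = r - r_offset, r_norm = (r - r_offset) / denom)
}

fit_axes_from_annotations <- function(annotations, step = 0.25) {
  axes <- list()
  for (f in sort(unique(annotations$frame))) {
    an <- annotations[annotations$frame == f, , drop = FALSE]
    neck <- an[an$is_neck != 0, , drop = FALSE]
    cp <- an[an$is_neck == 0, , drop = FALSE]
    cp <- cp[order(cp$point_index), , drop = FALSE]
    if (nrow(neck) != 1L) stop("frame ", f, " needs exactly one neck point")
    axes[[as.character(f)]] <- fit_axis(as.matrix(cp[, c("x", "y", "z")]),
                                        neck_point = as.numeric(neck[1, c("x", "y", "z")]),
                                        frame = f, step = step)
  }
  axes
}

nearest_axis <- function(axes, frame, max_frame_gap = 5L) {
  key <- as.character(frame)
  if (!is.null(axes[[key]])) return(axes[[key]])
  av <- as.integer(names(axes))
  gap <- abs(av - frame)
  if (!length(av) || min(gap) > max_frame_gap) {
    stop("no axis annotation within ", max_frame_gap, " frames of frame ", frame)
  }
  axes[[as.character(av[which.min(gap)])]]
}

#' Per-cell positions along the crypt-villus axis
#'
#' Fits the axis for every annotated frame, projects every tracked cell in
#' the requested frames onto its frame's axis, and applies the per-frame
#' zeroing and neck normalisation. Frames without their own annotation
#' reuse the nearest annotated frame within `max_frame_gap` frames.
#'
#' @param forest a `lineage_forest`.
#' @param annotations axis annotation table (see
#'   [read_axis_annotations()]), or a list of `crypt_axis` objects named by
#'   frame.
#' @param frames frames to process (default: all frames with cells).
#' @param max_frame_gap furthest annotation reuse, in frames.
#' @param use_z include z in the projection distance.
#' @param step spline sampling step (micrometres).
#' @return data frame `track_id`, `frame`, `r`, `d`, `r_norm`.
#' @export
axis_positions <- function(forest, annotations, frames = NULL,
                           max_frame_gap = 5L, use_z = TRUE, step = 0.25) {
  axes <- if (is.data.frame(annotations)) {
    fit_axes_from_annotations(annotations, step = step)
  } else annotations
  if (is.null(frames)) frames <- sort(unique(forest$points$frame))
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    pos <- positions_at_frame(forest, f)
    if (!nrow(pos)) next
    ax <- nearest_axis(axes, f, max_frame_gap)
    pr <- project_onto_axis(pos, ax, use_z = use_z)
    zn <- zero_and_normalize(pr$r, ax)
    out[[i]] <- data.frame(track_id = rownames(pos), frame = f,
                           r = zn$r, d = pr$d, r_norm = zn$r_norm)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Migration speed along the crypt-villus axis
#'
#' Signed speed toward the villus for each track: the difference between
#' the zeroed axis position at the track's last and first observed frames,
#' divided by the elapsed time. A regression variant (least-squares slope
#' of `r` over time across all the track's frames) is available but is not
#' the default.
#'
#' @param forest a `lineage_forest`.
#' @param positions output of [axis_positions()] covering at least each
#'   track's first and last frames.
#' @param method `"endpoints"` (default) or `"regression"`.
#' @return data frame `track_id`, `speed_um_h`, `duration_h`.
#' @export
migration_speeds <- function(forest, positions, method = c("endpoints", "regression")) {
  method <- match.arg(method)
  dt <- forest$frame_interval_h
  tr <- forest$tracks
  out <- data.frame(track_id = character(0), speed_um_h = numeric(0),
                    duration_h = numeric(0))
  for (i in seq_len(nrow(tr))) {
    if (tr$last_frame[i] <= tr$first_frame[i]) next
    p <- positions[positions$track_id == tr$track_id[i], , drop = FALSE]
    if (!nrow(p)) next
    for (f in c(tr$first_frame[i], tr$last_frame[i])) {
      if (!f %in% p$frame) stop("no axis position for track ", tr$track_id[i],
                                " at frame ", f)
    }
    dur <- (tr$last_frame[i] - tr$first_frame[i]) * dt
    sp <- if (method == "endpoints") {
      (p$r[p$frame == tr$last_frame[i]] - p$r[p$frame == tr$first_frame[i]]) / dur
    } else {
      unname(stats::coef(stats::lm(r ~ I(frame * dt), data = p))[2L])
    }
    out <- rbind(out, data.frame(track_id = tr$track_id[i], speed_um_h = sp,
                                 duration_h = dur))
  }
  rownames(out) <- NULL
  out
}
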