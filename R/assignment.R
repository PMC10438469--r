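## Dense linear assignment by shortest augmenting paths (Jonker-Volgenant
## style, row by row with dual potentials). No installed package provides
## weighted bipartite matching, so this is implemented here and verified
## against exhaustive permutation in the tests.
lap_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n); v <- numeric(m)
  p <- integer(m + 1L)          # p[j + 1]: row assigned to column j (0 = free); j = 0 virtual
  way <- integer(m)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])
      cur <- cost[i0, free_j] - u[i0] - v[free_j]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd]] <- j0
      }
      jm <- free_j[which.min(minv[free_j])]
      delta <- minv[jm]
      ujs <- which(used)
      rows_used <- p[ujs]
      u[rows_used] <- u[rows_used] + delta
      real_used <- ujs[ujs > 1L] - 1L
      v[real_used] <- v[real_used] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- jm
      if (p[j0 + 1L] == 0L) break
    }
    while (j0 != 0L) {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
    }
  }
  colsol <- p[-1L]                       # row assigned to each column
  rowsol <- integer(n)
  rowsol[colsol[colsol > 0L]] <- which(colsol > 0L)
  rowsol
}

as_point_matrix <- function(x, id_col) {
  if (is.matrix(x)) {
    m <- x[, 1:3, drop = FALSE]
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
    return(m)
  }
  m <- as.matrix(x[, c("x", "y", "z")])
  rownames(m) <- as.character(x[[id_col]])
  m
}

#' Match stained end-point cells to tracked end-point cells
#'
#' One-to-one assignment between the tracked cells present at the movie end
#' point and the cells segmented in the (post-fixation) staining images,
#' minimising the total Euclidean distance subject to every matched pair
#' being at most `max_match_distance` apart. Among assignments satisfying
#' the gate, the matching of maximal cardinality with minimal total distance
#' is returned; cost ties are broken towards the lexicographically smallest
#' (track_id, stain_cell_id) pairs. Replaces the manual correction used with
#' min-cost-flow linking in the original protocol by an auditable distance
#' gate plus an ambiguity report.
#'
#' @param endpoint_points positions of tracked end-point cells: matrix with
#'   track ids as row names, or data frame with `track_id`, `x`, `y`, `z`.
#' @param stain_points positions of stained cells: matrix with stain ids as
#'   row names, or data frame with `stain_cell_id`, `x`, `y`, `z`.
#' @param max_match_distance gate in micrometres (default 10, about one
#'   nucleus diameter).
#' @param pre_align if `TRUE`, rigidly pre-registers the stain points by
#'   translating their centroid onto the end-point centroid before matching.
#' @return object of class `stain_assignment`: `pairs` (track_id,
#'   stain_cell_id, distance), `unmatched_tracks`, `unmatched_stains`,
#'   `total_cost`.
#' @export
match_stained_to_tracked <- function(endpoint_points, stain_points,
                                     max_match_distance = 10,
                                     pre_align = FALSE) {
  stopifnot(max_match_distance > 0)
  A <- as_point_matrix(endpoint_points, "track_id")
  B <- as_point_matrix(stain_points, "stain_cell_id")
  if (!nrow(A) || !nrow(B)) stop("both point sets must be non-empty")
  A <- A[order(rownames(A)), , drop = FALSE]
  B <- B[order(rownames(B)), , drop = FALSE]
  shift <- c(0, 0, 0)
  if (pre_align) {
    shift <- colMeans(A) - colMeans(B)
    B <- sweep(B, 2L, shift, `+`)
  }
  n <- nrow(A); m <- nrow(B)
  # coordinate-wise differences: exact zeros for identical points
  D <- sqrt(outer(A[, 1L], B[, 1L], `-`)^2 + outer(A[, 2L], B[, 2L], `-`)^2 +
              outer(A[, 3L], B[, 3L], `-`)^2)
  allowed <- D <= max_match_distance

  dmax <- max(D[allowed], 0)
  K <- (n + m + 1) * max(dmax, 1) + 1
  FBIG <- (n + m + 2) * K
  N <- n + m
  C <- matrix(0, N, N)
  real <- matrix(FBIG, n, m)
  # epsilon tie-break towards lexicographically smallest (row, col) pairs
  eps <- 1e-9 * (outer(seq_len(n), rep(1, m)) + outer(rep(1, n), seq_len(m)) / (m + 1))
  real[allowed] <- D[allowed] - K + eps[allowed]
  C[seq_len(n), seq_len(m)] <- real
  rowsol <- lap_solve(C)
  ri <- seq_len(n)
  matched <- rowsol[ri] <= m & allowed[cbind(ri, pmin(rowsol[ri], m))]
  pairs <- data.frame(track_id = rownames(A)[ri][matched],
                      stain_cell_id = rownames(B)[rowsol[ri][matched]],
                      distance = D[cbind(ri[matched], rowsol[ri][matched])])
  pairs <- pairs[order(pairs$track_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_tracks = setdiff(rownames(A), pairs$track_id),
                 unmatched_stains = setdiff(rownames(B), pairs$stain_cell_id),
                 total_cost = sum(pairs$distance),
                 max_match_distance = max_match_distance,
                 pre_align_shift = shift),
            class = "stain_assignment")
}

#' @export
print.stain_assignment <- function(x, ...) {
  cat("Stain-to-track assignment: ", nrow(x$pairs), " pairs (",
      length(x$unmatched_tracks), " tracks / ", length(x$unmatched_stains),
      " stain cells unmatched), total cost ", round(x$total_cost, 3),
      " um, gate ", x$max_match_distance, " um\n", sep = "")
  invisible(x)
}

#' Assign end-point cell types to a lineage forest
#'
#' Calls a type for every stained cell from its marker panel, matches the
#' stained cells to the tracked cells present at the movie end point, and
#' returns the per-track end-point types. Unmatched end-point tracks and
#' tracks that ended early (death, lost) get `UNKNOWN`.
#'
#' @param forest a `lineage_forest`.
#' @param stain staining table: data frame with `stain_cell_id`, `x`, `y`,
#'   `z` and one column per marker (numeric intensities, or logicals for
#'   pre-called positivity).
#' @param thresholds named per-marker intensity thresholds; default `NULL`
#'   computes per-marker Otsu thresholds over the table. Ignored when the
#'   marker columns are logical.
#' @param max_match_distance,pre_align passed to
#'   [match_stained_to_tracked()].
#' @return object of class `endpoint_typing`: `endpoint_types` (named
#'   character over all terminal tracks), `assignment`, `stain_types`,
#'   `conflicts`, `match_rate`.
#' @export
assign_endpoint_types <- function(forest, stain, thresholds = NULL,
                                  max_match_distance = 10, pre_align = FALSE) {
  terminals <- forest$tracks$track_id[is.na(forest$tracks$daughter1)]
  ep <- endpoint_tracks(forest)
  types <- stats::setNames(rep("UNKNOWN", length(terminals)), terminals)
  if (is.null(stain) || !nrow(stain)) {
    warning("empty stain table: all end-point types UNKNOWN")
    return(structure(list(endpoint_types = types, assignment = NULL,
                          stain_types = character(0), conflicts = integer(0),
                          match_rate = 0), class = "endpoint_typing"))
  }
  mk <- markers()
  logical_calls <- all(vapply(stain[mk], is.logical, logical(1)))
  if (logical_calls) {
    calls <- as.matrix(stain[, mk])
  } else {
    if (is.null(thresholds)) thresholds <- otsu_thresholds(stain)
    calls <- call_positivity(stain[, mk], thresholds)
  }
  stain_types <- call_type(calls)
  conflicts <- attr(stain_types, "conflicts")
  names(stain_types) <- stain$stain_cell_id

  epp <- positions_at_frame(forest, forest$movie_end_frame)
  epp <- epp[rownames(epp) %in% ep, , drop = FALSE]
  asg <- match_stained_to_tracked(epp, stain, max_match_distance, pre_align)
  if (!nrow(asg$pairs)) warning("no stained cell matched any tracked end-point cell")
  types[asg$pairs$track_id] <- unname(stain_types[asg$pairs$stain_cell_id])
  structure(list(endpoint_types = types, assignment = asg,
                 stain_types = stain_types,
                 conflicts = conflicts,
                 match_rate = nrow(asg$pairs) / length(ep)),
            class = "endpoint_typing")
}

#' @export
print.endpoint_typing <- function(x, ...) {
  cat("End-point typing: match rate ", round(100 * x$match_rate, 1), "%, ",
      length(x$conflicts), " marker-pattern conflicts\n", sep = "")
  print(table(x$endpoint_types))
  invisible(x)
}
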