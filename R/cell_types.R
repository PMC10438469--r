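#' Marker panel and cell-type vocabulary
#'
#' The typing scheme uses six end-point markers: Olfm4 (stem cells),
#' Cga (enteroendocrine cells), Aldob (aldolase beta, enterocytes),
#' KRT20 (enterocytes and goblet cells), WGA (mucus, i.e. Paneth, goblet
#' and immature mucus-producing cells) and Lyz (Paneth cells).
#' Aldolase beta is spelled `Aldob` in all tables to keep column names ASCII.
#'
#' @return `markers()` returns the six marker names in canonical order;
#'   `cell_type_levels()` returns the nine type labels, `UNKNOWN` last.
#' @export
markers <- function() c("Olfm4", "Cga", "Aldob", "KRT20", "WGA", "Lyz")

#' @rdname markers
#' @export
cell_type_levels <- function() {
  c("STEM", "TA", "ENTEROCYTE", "EEC", "PANETH", "GOBLET", "IMPC", "UNKNOWN")
}

#' Call per-marker positivity from staining intensities
#'
#' A marker is positive iff its intensity is strictly greater than its
#' threshold; a cell whose intensity sits exactly at the threshold is
#' negative.
#'
#' @param intensities named numeric vector, or a data frame / matrix with one
#'   column per marker; all six markers must be present and non-negative.
#' @param thresholds named numeric vector of per-marker thresholds.
#' @return logical vector (or matrix, one row per cell) of positivity calls.
#' @export
call_positivity <- function(intensities, thresholds) {
  mk <- markers()
  if (is.data.frame(intensities)) intensities <- as.matrix(intensities[, intersect(colnames(intensities), mk), drop = FALSE])
  if (is.matrix(intensities)) {
    missing_mk <- setdiff(mk, colnames(intensities))
    if (length(missing_mk)) stop("missing marker intensities: ", paste(missing_mk, collapse = ", "))
    missing_th <- setdiff(mk, names(thresholds))
    if (length(missing_th)) stop("missing marker thresholds: ", paste(missing_th, collapse = ", "))
    x <- intensities[, mk, drop = FALSE]
    if (any(x < 0)) stop("marker intensities must be non-negative")
    out <- sweep(x, 2L, thresholds[mk], `>`)
    colnames(out) <- mk
    return(out)
  }
  missing_mk <- setdiff(mk, names(intensities))
  if (length(missing_mk)) stop("missing marker intensities: ", paste(missing_mk, collapse = ", "))
  missing_th <- setdiff(mk, names(thresholds))
  if (length(missing_th)) stop("missing marker thresholds: ", paste(missing_th, collapse = ", "))
  if (any(intensities[mk] < 0)) stop("marker intensities must be non-negative")
  stats::setNames(as.vector(intensities[mk]) > as.vector(thresholds[mk]), mk)
}

#' Call a cell type from a marker positivity pattern
#'
#' Implements the end-point typing table: Olfm4+ cells are stem; Cga+ are
#' enteroendocrine; Aldob+ (KRT20 allowed either way) are enterocytes;
#' WGA+Lyz+ are Paneth; WGA+KRT20+Lyz- are goblet; WGA+ only are immature
#' mucus-producing cells (IMPC); cells negative for all six markers are
#' transit-amplifying (TA). Any pattern outside the table maps to `UNKNOWN`
#' and is reported as a conflict. The mapping is total: each of the 2^6
#' patterns yields exactly one label.
#'
#' @param calls logical vector named by marker (one cell), or a logical
#'   matrix with one row per cell and one column per marker.
#' @return a character vector of type labels; the `"conflicts"` attribute
#'   holds the row indices (or `1` for a single cell) whose pattern fell
#'   outside the table.
#' @export
call_type <- function(calls) {
  single <- !is.matrix(calls)
  if (single) calls <- matrix(calls[markers()], nrow = 1L, dimnames = list(NULL, markers()))
  mk <- markers()
  if (!all(mk %in% colnames(calls))) stop("marker calls must cover: ", paste(mk, collapse = ", "))
  o <- calls[, "Olfm4"]; cg <- calls[, "Cga"]; a <- calls[, "Aldob"]
  k <- calls[, "KRT20"]; w <- calls[, "WGA"]; l <- calls[, "Lyz"]
  type <- rep("UNKNOWN", nrow(calls))
  type[o & !cg & !a & !k & !w & !l] <- "STEM"
  type[cg & !o & !a & !k & !w & !l] <- "EEC"
  type[a & !o & !cg & !w & !l] <- "ENTEROCYTE"          # KRT20 free
  type[w & l & !o & !cg & !a & !k] <- "PANETH"
  type[w & k & !l & !o & !cg & !a] <- "GOBLET"
  type[w & !k & !l & !o & !cg & !a] <- "IMPC"
  type[!o & !cg & !a & !k & !w & !l] <- "TA"
  attr(type, "conflicts") <- which(type == "UNKNOWN")
  if (single) {
    conf <- attr(type, "conflicts")
    type <- type[1L]
    attr(type, "conflicts") <- conf
  }
  type
}

#' Per-marker Otsu thresholds for a staining table
#'
#' Default thresholding when no fixed thresholds are supplied: for each
#' marker, Otsu's criterion (maximal between-class variance) is evaluated on
#' a 256-bin histogram of the observed intensities. Degenerate markers
#' (constant intensity) get that constant as threshold, so that under the
#' strict `>` rule every cell is called negative.
#'
#' @param stain data frame with one numeric column per marker.
#' @param n_bins number of histogram bins.
#' @return named numeric vector of thresholds.
#' @export
otsu_thresholds <- function(stain, n_bins = 256L) {
  mk <- markers()
  missing_mk <- setdiff(mk, colnames(stain))
  if (length(missing_mk)) stop("missing marker columns: ", paste(missing_mk, collapse = ", "))
  vapply(mk, function(m) otsu1(stain[[m]], n_bins), numeric(1))
}

otsu1 <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  # the criterion plateaus across empty gaps; take the plateau midpoint
  idx <- which(between >= max(between) - 1e-9 * max(between))
  breaks[as.integer(round(mean(range(idx)))) + 1L]
}
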