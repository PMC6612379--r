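# Foot segmentation and the lateral / anteroposterior weight-distribution
# indices. Coordinate convention: row 1 = anterior (toes), column 1 = the
# subject's left.

#' Time-averaged frame of a recording
#'
#' @param recording a `ppr_recording`.
#' @param aggregate `"mean"` (default) or `"median"`, applied per sensor
#'   across frames.
#' @return a numeric matrix of the recording's grid shape.
#' @export
mean_frame <- function(recording, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  fr <- recording$frames
  if (aggregate == "mean") rowMeans(fr, dims = 2)
  else apply(fr, c(1, 2), stats::median)
}

#' Segment the two feet in a pressure frame
#'
#' Thresholds the frame, labels connected components, and takes the two
#' carrying the most load; the component with the smaller load-weighted
#' column centroid is the left foot. If only one component is found but load
#' is present on both sides of the vertical midline, the frame is split at
#' the midline instead. Each foot is then divided into anterior and
#' posterior parts at the midpoint row of its occupied row span (anterior =
#' rows up to and including the boundary).
#'
#' @param frame a numeric pressure matrix (typically [mean_frame()]).
#' @param threshold_frac sensors at or below `threshold_frac * max(frame)`
#'   are treated as unloaded.
#' @return a `foot_regions` list: logical `left_mask` and `right_mask`, and
#'   integer `ap_boundary_row_left`, `ap_boundary_row_right`.
#' @export
segment_feet <- function(frame, threshold_frac = 1e-3) {
  stopifnot(is.matrix(frame))
  if (all(frame <= 0)) stop("segmentation error: frame carries no load")
  on <- frame > threshold_frac * max(frame)
  lab <- EBImage::bwlabel(on)
  ncomp <- max(lab)
  cols <- col(frame)
  if (ncomp >= 2L) {
    load <- vapply(seq_len(ncomp), function(k) sum(frame[lab == k]), 0)
    top2 <- order(load, decreasing = TRUE)[1:2]
    cent <- vapply(top2, function(k)
      sum(frame[lab == k] * cols[lab == k]) / sum(frame[lab == k]), 0)
    left_k <- top2[which.min(cent)]
    right_k <- top2[which.max(cent)]
    left_mask <- lab == left_k
    right_mask <- lab == right_k
  } else {
    mid <- (ncol(frame) + 1) / 2
    left_mask <- on & cols < mid
    right_mask <- on & cols > mid
    if (sum(frame[left_mask]) == 0 || sum(frame[right_mask]) == 0)
      stop("segmentation error: a single blob with all load on one side of the midline")
  }
  foot_regions(left_mask, right_mask,
               span_midpoint(left_mask), span_midpoint(right_mask))
}

span_midpoint <- function(mask) {
  occ <- which(rowSums(mask) > 0)
  floor((min(occ) + max(occ)) / 2)
}

#' Construct a foot-regions object
#'
#' @param left_mask,right_mask disjoint, non-empty logical matrices of the
#'   grid shape.
#' @param ap_boundary_row_left,ap_boundary_row_right row index splitting the
#'   foot into anterior (rows `<=` boundary) and posterior parts; must lie
#'   within the foot's occupied row span.
#' @return a `foot_regions` list.
#' @export
foot_regions <- function(left_mask, right_mask,
                         ap_boundary_row_left, ap_boundary_row_right) {
  stopifnot(is.logical(left_mask), is.logical(right_mask),
            identical(dim(left_mask), dim(right_mask)))
  if (any(left_mask & right_mask)) stop("foot masks overlap")
  if (!any(left_mask) || !any(right_mask)) stop("a foot mask is empty")
  check_boundary <- function(mask, b, side) {
    occ <- which(rowSums(mask) > 0)
    if (b < min(occ) || b >= max(occ))
      stop(sprintf("AP boundary row %d outside the %s foot's row span [%d, %d)",
                   b, side, min(occ), max(occ)))
  }
  check_boundary(left_mask, ap_boundary_row_left, "left")
  check_boundary(right_mask, ap_boundary_row_right, "right")
  structure(list(left_mask = left_mask, right_mask = right_mask,
                 ap_boundary_row_left = as.integer(ap_boundary_row_left),
                 ap_boundary_row_right = as.integer(ap_boundary_row_right)),
            class = "foot_regions")
}

#' Compute the weight distribution of a recording
#'
#' Load fractions are measured on the time-aggregated frame: the share of
#' total load carried by each foot, and within each foot the share carried
#' anterior versus posterior of its AP boundary.
#'
#' @param recording a `ppr_recording`.
#' @param regions a `foot_regions`; segmented automatically from the
#'   aggregated frame when omitted.
#' @param aggregate `"mean"` or `"median"` (see [mean_frame()]).
#' @return a `weight_distribution` list with `left_pct`, `right_pct`,
#'   `ant_left_pct`, `post_left_pct`, `ant_right_pct`, `post_right_pct`.
#'   Left + right sums to 100; within each foot anterior + posterior sums
#'   to 100.
#' @export
compute_distribution <- function(recording, regions = NULL,
                                 aggregate = c("mean", "median")) {
  stopifnot(inherits(recording, "ppr_recording"))
  m <- mean_frame(recording, aggregate)
  if (is.null(regions)) regions <- segment_feet(m)
  stopifnot(inherits(regions, "foot_regions"))
  if (!identical(dim(regions$left_mask), dim(m)))
    stop("regions were built for a different grid shape")
  rows <- row(m)
  foot <- function(mask, boundary) {
    tot <- sum(m[mask])
    ant <- sum(m[mask & rows <= boundary])
    c(tot = tot, ant = ant)
  }
  L <- foot(regions$left_mask, regions$ap_boundary_row_left)
  R <- foot(regions$right_mask, regions$ap_boundary_row_right)
  total <- L[["tot"]] + R[["tot"]]
  if (total == 0) stop("zero total load under the foot masks")
  lp <- 100 * L[["tot"]] / total
  # a foot carrying no load has an undefined AP split (possible only with
  # caller-supplied regions; segment_feet never returns an unloaded mask)
  al <- if (L[["tot"]] > 0) 100 * L[["ant"]] / L[["tot"]] else NA_real_
  ar <- if (R[["tot"]] > 0) 100 * R[["ant"]] / R[["tot"]] else NA_real_
  structure(list(left_pct = lp, right_pct = 100 - lp,
                 ant_left_pct = al, post_left_pct = 100 - al,
                 ant_right_pct = ar, post_right_pct = 100 - ar),
            class = "weight_distribution")
}

#' Postural indices OLWD and APWD
#'
#' The overall lateral weight distribution is `OLWD = 50 - left%`, where
#' `left%` is the percentage of total load on the left foot: zero when the
#' load is bilaterally balanced, positive when shifted to the right,
#' negative when shifted to the left. The anteroposterior index of each foot
#' is `APWD = 50 - posterior%`, with `posterior%` the posterior share of
#' that foot's own load: positive = anterior shift, negative = posterior.
#' All indices lie in `[-50, 50]`.
#'
#' @param dist a `weight_distribution` (or a `ppr_recording`, which is
#'   passed through [compute_distribution()] first).
#' @param ... passed on to [compute_distribution()] for recordings.
#' @return a `postural_indices` list with `olwd`, `apwd_left`, `apwd_right`.
#' @export
postural_indices <- function(dist, ...) {
  if (inherits(dist, "ppr_recording")) dist <- compute_distribution(dist, ...)
  stopifnot(inherits(dist, "weight_distribution"))
  structure(list(olwd = 50 - dist$left_pct,
                 apwd_left = 50 - dist$post_left_pct,
                 apwd_right = 50 - dist$post_right_pct),
            class = "postural_indices")
}

#' @export
print.postural_indices <- function(x, ...) {
  cat(sprintf("OLWD %+.2f%%  APWD left %+.2f%%  APWD right %+.2f%%\n",
              x$olwd, x$apwd_left, x$apwd_right))
  invisible(x)
}

#' Index table for a set of recordings
#'
#' @param recordings a list of `ppr_recording` (e.g. a `posture_cohort`).
#' @param ... passed on to [compute_distribution()].
#' @return a data.frame with one row per recording: `subject`, `condition`,
#'   `olwd`, `apwd_left`, `apwd_right`.
#' @export
index_table <- function(recordings, ...) {
  rows <- lapply(recordings, function(r) {
    idx <- postural_indices(r, ...)
    data.frame(subject = r$subject_id, condition = r$condition,
               olwd = idx$olwd, apwd_left = idx$apwd_left,
               apwd_right = idx$apwd_right)
  })
  do.call(rbind, rows)
}
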