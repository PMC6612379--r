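# Categorical classification of weight-distribution shifts: each clenching
# condition is compared with the same subject's rest recording.

LATERAL_LEVELS <- c("No change", "Right", "Left")
AP_LEVELS <- c("No change", "Anterior", "Posterior")
CLENCH_CONDITIONS <- c("CL", "CLR", "CLL")

classify_delta <- function(delta, epsilon_pp, levels) {
  if (epsilon_pp < 0) stop("'epsilon_pp' must be non-negative")
  out <- rep(levels[1], length(delta))
  out[delta > epsilon_pp] <- levels[2]
  out[delta < -epsilon_pp] <- levels[3]
  factor(out, levels = levels)
}

#' Classify the lateral shift of a condition against rest
#'
#' The shift is the OLWD difference `delta = olwd_condition - olwd_rest`.
#' Differences of at most `epsilon_pp` percentage points in magnitude count
#' as "No change" (a closed tolerance band: ties at exactly `epsilon_pp`
#' are no change); larger positive differences are a shift to the right,
#' larger negative ones to the left. The tolerance exists because a
#' continuous index never reproduces exactly; its default of half a
#' percentage point is deliberately small.
#'
#' @param olwd_condition,olwd_rest OLWD indices (vectorised).
#' @param epsilon_pp non-negative no-change tolerance in percentage points.
#' @return factor with levels `No change`, `Right`, `Left`.
#' @export
classify_lateral <- function(olwd_condition, olwd_rest, epsilon_pp = 0.5)
  classify_delta(olwd_condition - olwd_rest, epsilon_pp, LATERAL_LEVELS)

#' Classify the anteroposterior shift of a condition against rest
#'
#' As [classify_lateral()], applied to one foot's APWD: positive differences
#' beyond the tolerance are anterior shifts, negative ones posterior.
#'
#' @param apwd_condition,apwd_rest APWD indices for one foot (vectorised).
#' @param epsilon_pp non-negative no-change tolerance in percentage points.
#' @return factor with levels `No change`, `Anterior`, `Posterior`.
#' @export
classify_ap <- function(apwd_condition, apwd_rest, epsilon_pp = 0.5)
  classify_delta(apwd_condition - apwd_rest, epsilon_pp, AP_LEVELS)

check_complete <- function(labels, by) {
  tab <- table(labels$subject, interaction(labels[by], drop = FALSE))
  if (any(tab != 1L))
    stop("each subject needs exactly one label per ", paste(by, collapse = " x "))
}

#' Tabulate lateral shift labels into a multiple-response table
#'
#' @param labels data.frame with columns `subject`, `condition` (one of
#'   `CL`, `CLR`, `CLL`) and `label` (a value or factor with the levels of
#'   [classify_lateral()]); exactly one row per subject and condition.
#' @return an `mr_table` with rows No change / Right / Left and columns
#'   CL, CLR, CLL; every column sums to the number of subjects.
#' @export
tabulate_lateral <- function(labels) {
  stopifnot(all(c("subject", "condition", "label") %in% names(labels)))
  labels$condition <- factor(labels$condition, levels = CLENCH_CONDITIONS)
  if (anyNA(labels$condition)) stop("condition must be one of CL, CLR, CLL")
  check_complete(labels, "condition")
  counts <- table(factor(labels$label, levels = LATERAL_LEVELS),
                  labels$condition)
  mr_table(unclass(counts))
}

#' Tabulate per-foot anteroposterior shift labels
#'
#' @param labels data.frame with columns `subject`, `condition`, `foot`
#'   (`LF` or `RF`) and `label` (levels of [classify_ap()]); exactly one row
#'   per subject, condition and foot.
#' @return an `mr_table` with rows No change / Anterior / Posterior and the
#'   six condition-by-foot columns CL-LF, CL-RF, CLR-LF, CLR-RF, CLL-LF,
#'   CLL-RF.
#' @export
tabulate_ap <- function(labels) {
  stopifnot(all(c("subject", "condition", "foot", "label") %in% names(labels)))
  labels$condition <- factor(labels$condition, levels = CLENCH_CONDITIONS)
  labels$foot <- factor(labels$foot, levels = c("LF", "RF"))
  if (anyNA(labels$condition) || anyNA(labels$foot))
    stop("condition must be CL/CLR/CLL and foot must be LF/RF")
  check_complete(labels, c("condition", "foot"))
  col <- factor(paste(labels$condition, labels$foot, sep = "-"),
                levels = as.vector(t(outer(CLENCH_CONDITIONS, c("LF", "RF"),
                                           paste, sep = "-"))))
  counts <- table(factor(labels$label, levels = AP_LEVELS), col)
  mr_table(unclass(counts))
}

#' Classify a cohort's index table against rest
#'
#' Convenience wrapper: takes the per-recording index table of a cohort,
#' matches every clenching condition with the same subject's rest row, and
#' returns the lateral and per-foot AP label frames ready for
#' [tabulate_lateral()] / [tabulate_ap()].
#'
#' @param indices data.frame as returned by [index_table()]; must contain a
#'   `RES` row and rows for `CL`, `CLR`, `CLL` for every subject.
#' @param epsilon_pp no-change tolerance in percentage points.
#' @return list with data.frames `lateral` and `ap`.
#' @export
classify_cohort <- function(indices, epsilon_pp = 0.5) {
  need <- c("subject", "condition", "olwd", "apwd_left", "apwd_right")
  stopifnot(all(need %in% names(indices)))
  rest <- indices[indices$condition == "RES", ]
  if (any(duplicated(rest$subject)))
    stop("duplicated RES recording for subject ",
         rest$subject[duplicated(rest$subject)][1])
  lat <- NULL; ap <- NULL
  for (cond in CLENCH_CONDITIONS) {
    cur <- indices[indices$condition == cond, ]
    missing <- setdiff(rest$subject, cur$subject)
    if (length(missing) || nrow(cur) != nrow(rest))
      stop("missing condition ", cond, " for subject(s): ",
           paste(union(missing, setdiff(cur$subject, rest$subject)),
                 collapse = ", "))
    cur <- cur[match(rest$subject, cur$subject), ]
    lat <- rbind(lat, data.frame(
      subject = rest$subject, condition = cond,
      label = classify_lateral(cur$olwd, rest$olwd, epsilon_pp)))
    ap <- rbind(ap,
      data.frame(subject = rest$subject, condition = cond, foot = "LF",
                 label = classify_ap(cur$apwd_left, rest$apwd_left, epsilon_pp)),
      data.frame(subject = rest$subject, condition = cond, foot = "RF",
                 label = classify_ap(cur$apwd_right, rest$apwd_right, epsilon_pp)))
  }
  list(lateral = lat, ap = ap)
}
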