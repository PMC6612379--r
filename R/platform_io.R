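#' @importFrom data.table fread
#' @importFrom jsonlite read_json write_json
NULL

#' Occlusal condition labels
#'
#' The four mandibular states under which a recording can be taken: rest with
#' no tooth contact (`RES`), bilateral clench at maximum intercuspation
#' (`CL`), unilateral clench on the right (`CLR`) and on the left (`CLL`).
#' @export
OCCLUSAL_CONDITIONS <- c("RES", "CL", "CLR", "CLL")

#' Construct a pressure-platform recording
#'
#' A recording is an ordered sequence of equally spaced pressure frames taken
#' on a sensor mat while a subject stands still under one occlusal condition.
#' Frames are stored as a 3-dimensional array `(rows, columns, frames)`;
#' row 1 is the anterior (toe) edge of the mat, column 1 the subject's left.
#' The timestamp of frame `k` is `(k - 1) * frame_interval_s`.
#'
#' @param frames numeric array with `dim = c(n_rows, n_cols, n_frames)`,
#'   all values non-negative. A single matrix is accepted for a one-frame
#'   recording.
#' @param subject_id character scalar identifying the subject.
#' @param condition one of `r toString(OCCLUSAL_CONDITIONS)`.
#' @param frame_interval_s seconds between consecutive frames. The default
#'   0.02 s matches an 8-second acquisition of 400 frames.
#' @param mat_width_mm,mat_height_mm physical mat dimensions (width spans
#'   columns, height spans rows).
#' @return an object of class `ppr_recording`.
#' @export
new_recording <- function(frames, subject_id, condition,
                          frame_interval_s = 0.02,
                          mat_width_mm = 432, mat_height_mm = 368) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a (rows, cols, frames) array or a single matrix")
  if (dim(frames)[3] < 1L) stop("a recording must contain at least one frame")
  if (anyNA(frames) || any(frames < 0))
    stop("pressure values must be non-negative and non-missing")
  condition <- match.arg(condition, OCCLUSAL_CONDITIONS)
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop("'frame_interval_s' must be a positive number")
  structure(
    list(frames = frames,
         subject_id = as.character(subject_id)[1],
         condition = condition,
         frame_interval_s = frame_interval_s,
         mat_width_mm = mat_width_mm,
         mat_height_mm = mat_height_mm),
    class = "ppr_recording")
}

#' @export
print.ppr_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Pressure recording: subject %s, condition %s\n",
              x$subject_id, x$condition))
  cat(sprintf("  %d frames of %d x %d sensors every %g s (%.1f s total)\n",
              d[3], d[1], d[2], x$frame_interval_s, d[3] * x$frame_interval_s))
  cat(sprintf("  mat %g x %g mm, mean total load %.2f\n",
              x$mat_width_mm, x$mat_height_mm,
              mean(colSums(matrix(x$frames, d[1] * d[2], d[3])))))
  invisible(x)
}

#' Number of frames in a recording
#' @param recording a `ppr_recording`.
#' @return integer frame count.
#' @export
n_frames <- function(recording) dim(recording$frames)[3]

#' Frame timestamps of a recording
#' @param recording a `ppr_recording`.
#' @return numeric vector of seconds from recording start, one per frame.
#' @export
frame_times <- function(recording)
  (seq_len(n_frames(recording)) - 1) * recording$frame_interval_s

ppr_paths <- function(path) {
  stem <- sub("\\.ppr\\.(json|csv)$", "", path)
  list(json = paste0(stem, ".ppr.json"), csv = paste0(stem, ".ppr.csv"))
}

#' Write a recording to disk (ppr-v1 format)
#'
#' The on-disk format is a JSON header (`*.ppr.json`: grid shape, frame
#' interval, condition, mat dimensions) next to a headerless CSV
#' (`*.ppr.csv`) holding one block of `n_rows` lines per frame, in frame
#' order. Values are written with full round-trip precision so that
#' [read_recording()] restores them bit-identically.
#'
#' @param recording a valid `ppr_recording`.
#' @param path destination path; the `.ppr.json`/`.ppr.csv` suffix pair is
#'   added (or normalised) automatically.
#' @return the JSON header path, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "ppr_recording"))
  d <- dim(recording$frames)
  p <- ppr_paths(path)
  header <- list(
    format = "ppr-v1",
    subject_id = recording$subject_id,
    condition = recording$condition,
    n_rows = d[1], n_cols = d[2], n_frames = d[3],
    frame_interval_s = recording$frame_interval_s,
    mat_width_mm = recording$mat_width_mm,
    mat_height_mm = recording$mat_height_mm,
    frames_csv = basename(p$csv))
  jsonlite::write_json(header, p$json, auto_unbox = TRUE, digits = NA)
  # stack frames into (n_frames * n_rows) x n_cols; %.17g round-trips doubles
  flat <- matrix(aperm(recording$frames, c(1, 3, 2)), d[1] * d[3], d[2])
  lines <- do.call(paste, c(lapply(seq_len(d[2]), function(j)
    sprintf("%.17g", flat[, j])), sep = ","))
  writeLines(lines, p$csv)
  invisible(p$json)
}

#' Read a recording from disk (ppr-v1 format)
#'
#' @param path path to the `.ppr.json` header (or its stem) written by
#'   [write_recording()].
#' @return a `ppr_recording`.
#' @export
read_recording <- function(path) {
  p <- ppr_paths(path)
  if (!file.exists(p$json)) stop("recording header not found: ", p$json)
  h <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  if (!identical(h$format, "ppr-v1"))
    stop("unsupported recording format: ", h$format %||% "<missing>")
  for (f in c("condition", "n_rows", "n_cols", "n_frames", "frame_interval_s"))
    if (is.null(h[[f]])) stop("malformed header: missing field '", f, "'")
  if (!h$condition %in% OCCLUSAL_CONDITIONS)
    stop("unknown condition label '", h$condition, "' in ", p$json)
  csv <- file.path(dirname(p$json), h$frames_csv %||% basename(p$csv))
  if (!file.exists(csv)) stop("frame data not found: ", csv)
  dt <- data.table::fread(csv, header = FALSE, sep = ",", fill = FALSE)
  m <- as.matrix(dt)
  if (ncol(m) != h$n_cols || nrow(m) != h$n_rows * h$n_frames)
    stop(sprintf("frame data is %d x %d but header declares %d frames of %d x %d",
                 nrow(m), ncol(m), h$n_frames, h$n_rows, h$n_cols))
  if (anyNA(m) || !is.numeric(m))
    stop("non-numeric pressure value at CSV row ",
         which(apply(is.na(m), 1, any))[1])
  if (any(m < 0)) {
    bad <- which(apply(m < 0, 1, any))[1]
    stop(sprintf("negative pressure value in frame %d, grid row %d",
                 (bad - 1) %/% h$n_rows + 1, (bad - 1) %% h$n_rows + 1))
  }
  frames <- aperm(array(m, dim = c(h$n_rows, h$n_frames, h$n_cols)), c(1, 3, 2))
  new_recording(frames, h$subject_id %||% "unknown", h$condition,
                h$frame_interval_s, h$mat_width_mm %||% NA_real_,
                h$mat_height_mm %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- multiple-response count tables ----------------------------------------

canonical_shift_label <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  out <- x
  out[grepl("nochange|noshift", key)] <- "No change"
  out[grepl("right", key) & !grepl("nochange", key)] <- "Right"
  out[grepl("left", key) & !grepl("nochange", key)] <- "Left"
  out[grepl("ant", key)] <- "Anterior"
  out[grepl("post", key)] <- "Posterior"
  out
}

#' Construct a multiple-response count table
#'
#' A shift-by-condition table in which every subject contributes exactly one
#' response per column, so all column sums equal the number of subjects and
#' the grand total is `n_subjects * n_columns`. Responses from the same
#' subject recur across columns, which is what invalidates the classical
#' Pearson test on this table (see [corrected_test()]).
#'
#' @param counts non-negative integer matrix with row and column dimnames
#'   (shift categories by conditions).
#' @param n_subjects number of subjects; inferred from the common column sum
#'   when omitted.
#' @return an object of class `mr_table`.
#' @export
mr_table <- function(counts, n_subjects = NULL) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("row", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("col", seq_len(ncol(counts)))
  dimnames(counts) <- list(rownames(counts), colnames(counts))
  cs <- colSums(counts)
  if (length(unique(cs)) != 1L)
    stop("column sums differ (", paste(cs, collapse = ", "),
         "): each subject must give exactly one response per column")
  if (is.null(n_subjects)) n_subjects <- cs[1]
  if (n_subjects != cs[1])
    stop("declared n_subjects (", n_subjects,
         ") does not match the common column sum (", cs[1], ")")
  structure(list(counts = counts, n_subjects = as.integer(n_subjects)),
            class = "mr_table")
}

#' @export
print.mr_table <- function(x, ...) {
  cat(sprintf("Multiple-response table: %d shift categories x %d columns, N = %d subjects\n",
              nrow(x$counts), ncol(x$counts), x$n_subjects))
  print(x$counts)
  invisible(x)
}

#' Read a multiple-response count table from CSV
#'
#' Expects a plain UTF-8 CSV whose first row holds column labels and whose
#' first column holds shift-category labels. Marginal "Total" rows/columns,
#' if present, are dropped. Row labels are normalised case-insensitively to
#' canonical spellings ("No change", "Right", "Left", "Anterior",
#' "Posterior"). The number of subjects is inferred as the common column
#' sum; unequal column sums violate the one-response-per-subject-per-column
#' design and raise an error.
#'
#' @param path CSV file path.
#' @return an `mr_table`.
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a label column plus counts")
  labels <- trimws(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  keep_r <- !grepl("^total$", labels, ignore.case = TRUE)
  keep_c <- !grepl("^total$", trimws(colnames(m)), ignore.case = TRUE)
  m <- m[keep_r, keep_c, drop = FALSE]
  labels <- labels[keep_r]
  if (!is.numeric(m) || anyNA(m) || any(m != round(m)))
    stop("non-integer cell in count table ", path)
  rownames(m) <- canonical_shift_label(labels)
  colnames(m) <- trimws(colnames(m))
  mr_table(m)
}

#' Write a multiple-response count table to CSV
#'
#' @param table an `mr_table`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "mr_table"))
  df <- data.frame(Shift = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
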