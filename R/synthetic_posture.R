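# Synthetic two-foot plantar pressure maps with controlled lateral and
# anteroposterior load displacement, emulating a resistive sensor mat.

#' Elliptical foot template
#'
#' One foot is modelled as an elliptical Gaussian-weighted blob with finite
#' support (weights are exactly zero outside the ellipse), so that the two
#' feet are separated by a clear central gap and left/right segmentation is
#' unambiguous. Weights are normalised to sum to 1.
#'
#' @param shape grid shape `c(n_rows, n_cols)`; the default 52 x 44 matches
#'   a 2288-sensor mat whose longer (432 mm) axis spans the rows.
#' @param side `"left"` or `"right"` (column 1 is the subject's left).
#' @param centroid_row,centroid_col blob centre in grid coordinates;
#'   defaults place the foot at mid-height, 27% / 73% of the mat width.
#' @param semi_rows,semi_cols ellipse semi-axes in grid units.
#' @return a list with the weight matrix `mask` (sums to 1), the centroid,
#'   and `side`; class `foot_template`.
#' @export
foot_template <- function(shape = c(52, 44), side = c("left", "right"),
                          centroid_row = NULL, centroid_col = NULL,
                          semi_rows = NULL, semi_cols = NULL) {
  side <- match.arg(side)
  nr <- shape[1]; nc <- shape[2]
  if (is.null(centroid_row)) centroid_row <- (nr + 1) / 2
  if (is.null(centroid_col))
    centroid_col <- if (side == "left") 0.27 * nc else 0.73 * nc
  if (is.null(semi_rows)) semi_rows <- 0.38 * nr
  if (is.null(semi_cols)) semi_cols <- 0.16 * nc
  dr <- (seq_len(nr) - centroid_row) / semi_rows
  dc <- (seq_len(nc) - centroid_col) / semi_cols
  e <- outer(dr^2, dc^2, `+`)
  w <- exp(-2 * e)
  w[e > 1] <- 0
  if (all(w == 0)) stop("foot template has empty support; check its geometry")
  structure(list(mask = w / sum(w),
                 centroid_row = centroid_row, centroid_col = centroid_col,
                 side = side),
            class = "foot_template")
}

#' Per-condition displacement effect
#'
#' Encodes how an occlusal condition displaces the standing load relative to
#' the subject's baseline: `lateral_shift_pp` percentage points of total load
#' moved toward the right foot (so the OLWD index increases by exactly that
#' amount), and `ap_shift_pp_left` / `ap_shift_pp_right` percentage points of
#' each foot's own load moved anteriorly (each APWD index increases by that
#' amount). `noise_sd` is the log-scale standard deviation of multiplicative
#' per-sensor, per-frame measurement noise; multiplicative noise keeps
#' pressures non-negative.
#'
#' @param lateral_shift_pp signed percentage points, positive = rightward.
#' @param ap_shift_pp_left,ap_shift_pp_right signed percentage points,
#'   positive = anterior.
#' @param noise_sd non-negative noise scale (0 = noiseless).
#' @return a `condition_effect` list.
#' @export
condition_effect <- function(lateral_shift_pp = 0, ap_shift_pp_left = 0,
                             ap_shift_pp_right = 0, noise_sd = 0) {
  stopifnot(noise_sd >= 0)
  structure(list(lateral_shift_pp = lateral_shift_pp,
                 ap_shift_pp_left = ap_shift_pp_left,
                 ap_shift_pp_right = ap_shift_pp_right,
                 noise_sd = noise_sd),
            class = "condition_effect")
}

# anterior/posterior split row of a template: midpoint of its occupied row
# span (anterior = rows <= boundary). Matches the rule segment_feet() applies,
# so injected AP fractions are recovered exactly by the analysis side.
template_ap_boundary <- function(mask) {
  occ <- which(rowSums(mask) > 0)
  as.integer(floor((min(occ) + max(occ)) / 2))
}

scale_ap <- function(mask, anterior_frac, boundary) {
  nr <- nrow(mask)
  ant <- mask; ant[seq_len(nr) > boundary, ] <- 0
  post <- mask - ant
  sa <- sum(ant); sp <- sum(post)
  if (sa == 0 || sp == 0)
    stop("template cannot express an anterior/posterior split")
  ant * (anterior_frac / sa) + post * ((1 - anterior_frac) / sp)
}

#' Generate one synthetic pressure recording
#'
#' Builds a noiseless base frame from two foot templates whose total weights
#' and within-foot anterior/posterior weights are rescaled so that the
#' recording's measured load fractions equal `baseline` displaced by
#' `effect` exactly, then replicates it over frames with optional
#' multiplicative log-normal noise (mean 1, so the expected frame equals the
#' base frame). Lateral shift rescales the two feet's total weights rather
#' than moving the blobs; the anteroposterior shift rescales each foot's
#' anterior versus posterior half. The injected effect therefore equals the
#' change in the measured index, which is what makes parameter-recovery
#' checks exact in the noiseless limit.
#'
#' @param subject_id subject label.
#' @param condition occlusal condition label (`RES`, `CL`, `CLR`, `CLL`).
#' @param baseline list with the subject's resting load targets, in percent:
#'   `left_pct` (share of total load on the left foot), `post_left_pct` and
#'   `post_right_pct` (posterior share within each foot).
#' @param effect a [condition_effect()].
#' @param n_frames number of frames (default 400, i.e. 8 s at 50 Hz).
#' @param shape grid shape `c(n_rows, n_cols)`.
#' @param total_load total load in sensor units spread over the mat.
#' @param frame_interval_s seconds between frames.
#' @param seed optional integer; when given the recording is a deterministic
#'   function of its arguments.
#' @return a `ppr_recording`; the generator's ground-truth segmentation is
#'   attached as attribute `"truth"` (left/right support masks and the AP
#'   boundary rows).
#' @export
generate_recording <- function(subject_id, condition,
                               baseline = list(left_pct = 50,
                                               post_left_pct = 50,
                                               post_right_pct = 50),
                               effect = condition_effect(),
                               n_frames = 400, shape = c(52, 44),
                               total_load = 700, frame_interval_s = 0.02,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_frames < 1) stop("'n_frames' must be at least 1")
  left_pct <- baseline$left_pct - effect$lateral_shift_pp
  post_l <- baseline$post_left_pct - effect$ap_shift_pp_left
  post_r <- baseline$post_right_pct - effect$ap_shift_pp_right
  fr <- c(left_pct, post_l, post_r)
  if (any(fr < 0 | fr > 100))
    stop("effect pushes a load fraction outside [0, 100]: ",
         paste(sprintf("%.1f", fr), collapse = ", "))
  tl <- foot_template(shape, "left")
  tr <- foot_template(shape, "right")
  bl <- template_ap_boundary(tl$mask)
  br <- template_ap_boundary(tr$mask)
  base <- total_load *
    ((left_pct / 100) * scale_ap(tl$mask, 1 - post_l / 100, bl) +
     (1 - left_pct / 100) * scale_ap(tr$mask, 1 - post_r / 100, br))
  frames <- array(base, dim = c(shape, n_frames))
  if (effect$noise_sd > 0) {
    s <- effect$noise_sd
    frames <- frames * exp(stats::rnorm(length(frames), -s^2 / 2, s))
  }
  rec <- new_recording(frames, subject_id, condition, frame_interval_s)
  attr(rec, "truth") <- list(left_mask = tl$mask > 0, right_mask = tr$mask > 0,
                             ap_boundary_row_left = bl,
                             ap_boundary_row_right = br)
  rec
}

#' Default per-condition effect distributions for cohort simulation
#'
#' Mean effects encode the direction the study design probes: a unilateral
#' clench tends to displace body weight toward the opposite side (rightward
#' for a left-side clench), while a bilateral clench has no systematic
#' lateral direction and a mild anterior tendency is shared by all clenching
#' conditions. Values are free simulation parameters, not estimates of any
#' particular cohort.
#'
#' @param lateral_sd,ap_sd between-subject SDs of the condition effects (pp).
#' @param noise_sd per-sensor, per-frame measurement noise scale.
#' @return named list (`CL`, `CLR`, `CLL`) of effect-distribution parameters.
#' @export
default_effect_spec <- function(lateral_sd = 2.5, ap_sd = 2.5,
                                noise_sd = 0.05) {
  spec <- list(
    CL  = list(lateral_mean = 0,  ap_mean_left = 1, ap_mean_right = 1),
    CLR = list(lateral_mean = -3, ap_mean_left = 1, ap_mean_right = 1),
    CLL = list(lateral_mean = 3,  ap_mean_left = 1, ap_mean_right = 1))
  lapply(spec, function(e)
    c(e, list(lateral_sd = lateral_sd, ap_sd = ap_sd, noise_sd = noise_sd)))
}

#' Zero-effect (null) per-condition spec
#'
#' All condition effects are identically zero, so any shift the pipeline
#' classifies is driven purely by measurement noise. Useful for null-cohort
#' and type-I-error simulations.
#'
#' @param noise_sd per-sensor, per-frame measurement noise scale.
#' @return named list (`CL`, `CLR`, `CLL`) of effect-distribution parameters.
#' @export
null_effect_spec <- function(noise_sd = 0) {
  e <- list(lateral_mean = 0, lateral_sd = 0, ap_mean_left = 0,
            ap_mean_right = 0, ap_sd = 0, noise_sd = noise_sd)
  list(CL = e, CLR = e, CLL = e)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic cohort of four-condition recordings
#'
#' Emulates the repeated-measures design: each subject is measured once at
#' rest (`RES`) and once per clenching condition (`CL`, `CLR`, `CLL`).
#' Per-subject baselines are drawn around a balanced stance (left share and
#' per-foot posterior shares ~ truncated Normal(50, `sigma_subject`)), and
#' per-condition effects are drawn from `effect_spec`. Because every
#' condition is compared with the same rest recording downstream, the
#' cohort reproduces the within-subject correlation across conditions that
#' motivates the multiple-response correction.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param effect_spec per-condition effect distributions, as from
#'   [default_effect_spec()]. Entries are lists with `lateral_mean`,
#'   `lateral_sd`, `ap_mean_left`, `ap_mean_right`, `ap_sd`, `noise_sd`.
#'   The rest recording carries no effect but the same measurement noise
#'   (taken from the first entry).
#' @param n_frames,shape,total_load,frame_interval_s passed to
#'   [generate_recording()].
#' @param sigma_subject between-subject SD of baseline percentages (pp).
#' @param seed integer seed; the cohort is a deterministic function of it.
#' @return list of `4 * n_subjects` recordings (class `posture_cohort`),
#'   ordered subject-major with conditions RES, CL, CLR, CLL; the drawn
#'   effects are attached as attribute `"effects"`.
#' @export
generate_cohort <- function(n_subjects, effect_spec = default_effect_spec(),
                            n_frames = 400, shape = c(52, 44),
                            total_load = 700, frame_interval_s = 0.02,
                            sigma_subject = 2, seed = 1) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  recs <- vector("list", 4L * n_subjects)
  effects <- NULL
  k <- 0L
  for (i in seq_len(n_subjects)) {
    id <- sprintf("S%03d", i)
    baseline <- list(
      left_pct = rnorm_trunc(1, 50, sigma_subject, 30, 70),
      post_left_pct = rnorm_trunc(1, 50, sigma_subject, 30, 70),
      post_right_pct = rnorm_trunc(1, 50, sigma_subject, 30, 70))
    for (cond in c("RES", "CL", "CLR", "CLL")) {
      # measurement noise is a property of the instrument, not the occlusal
      # state: the rest recording is as noisy as any other, which is what
      # makes all condition-vs-rest differences share the rest error
      eff <- if (cond == "RES")
        condition_effect(noise_sd = effect_spec[[1]]$noise_sd)
      else {
        p <- effect_spec[[cond]]
        condition_effect(
          lateral_shift_pp = stats::rnorm(1, p$lateral_mean, p$lateral_sd),
          ap_shift_pp_left = stats::rnorm(1, p$ap_mean_left, p$ap_sd),
          ap_shift_pp_right = stats::rnorm(1, p$ap_mean_right, p$ap_sd),
          noise_sd = p$noise_sd)
      }
      k <- k + 1L
      recs[[k]] <- generate_recording(id, cond, baseline, eff,
                                      n_frames = n_frames, shape = shape,
                                      total_load = total_load,
                                      frame_interval_s = frame_interval_s)
      effects <- rbind(effects, data.frame(
        subject = id, condition = cond,
        lateral_shift_pp = eff$lateral_shift_pp,
        ap_shift_pp_left = eff$ap_shift_pp_left,
        ap_shift_pp_right = eff$ap_shift_pp_right))
    }
  }
  structure(recs, class = "posture_cohort", effects = effects)
}

#' @export
print.posture_cohort <- function(x, ...) {
  cat(sprintf("Synthetic posture cohort: %d recordings (%d subjects x 4 conditions)\n",
              length(x), length(x) / 4L))
  invisible(x)
}
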