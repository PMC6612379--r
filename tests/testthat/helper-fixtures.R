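# Shared fixtures: the two published-style count tables, built in code, and
# small helpers for recordings.

table1_counts <- matrix(
  c(5, 8, 7,
    1, 6, 13,
    1, 14, 5),
  nrow = 3,
  dimnames = list(c("No change", "Right", "Left"), c("CL", "CLR", "CLL")))

table2_counts <- matrix(
  c(2, 12, 6,
    4, 7, 9,
    5, 7, 8,
    4, 7, 9,
    2, 11, 7,
    3, 12, 5),
  nrow = 3,
  dimnames = list(c("No change", "Anterior", "Posterior"),
                  c("CL-LF", "CL-RF", "CLR-LF", "CLR-RF", "CLL-LF", "CLL-RF")))

table1_fixture <- function() mr_table(table1_counts)
table2_fixture <- function() mr_table(table2_counts)

# left<->right mirror of a recording (flip columns of every frame)
mirror_recording <- function(rec) {
  fr <- rec$frames[, rev(seq_len(dim(rec$frames)[2])), , drop = FALSE]
  new_recording(fr, rec$subject_id, rec$condition, rec$frame_interval_s,
                rec$mat_width_mm, rec$mat_height_mm)
}

# random valid multiple-response table: n subjects pick one of r categories
# in each of c columns; resampled until no shift category is empty overall
random_mr_table <- function(r = 3, c = 3, n = 20) {
  repeat {
    m <- sapply(seq_len(c), function(j)
      tabulate(sample.int(r, n, replace = TRUE), r))
    if (all(rowSums(m) > 0)) break
  }
  dimnames(m) <- list(paste0("cat", seq_len(r)), paste0("cond", seq_len(c)))
  mr_table(m)
}

# brute-force Pearson statistic: explicit double loop over cells
brute_force_pearson <- function(counts) {
  s <- 0
  n <- sum(counts)
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts))) {
      e <- sum(counts[i, ]) * sum(counts[, j]) / n
      s <- s + (counts[i, j] - e)^2 / e
    }
  s
}

sim_shape <- c(26, 22)  # reduced grid used by simulation-heavy tests
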