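# Correspondence analysis of a shift-by-condition table: SVD of the
# standardized residual matrix, with row and column categories displayed
# jointly in principal coordinates (symmetric map).

#' Correspondence analysis of a count table
#'
#' Decomposes the correspondence matrix `P = counts / grand total`.
#' With row masses `r = rowSums(P)` and column masses `c = colSums(P)`,
#' the standardized residual matrix is
#' `S = diag(r)^(-1/2) (P - r c') diag(c)^(-1/2)`, and its singular value
#' decomposition `S = U D V'` yields principal coordinates
#' `F = diag(r)^(-1/2) U D` (rows) and `G = diag(c)^(-1/2) V D` (columns).
#' Each axis's inertia is the squared singular value; the total inertia
#' equals the naive Pearson statistic of the table divided by the grand
#' total. Axes are oriented canonically: the sign of each axis is chosen so
#' that the column point with the largest mass-weighted coordinate
#' magnitude is positive, making output reproducible across SVD
#' implementations.
#'
#' @param table an [mr_table()] (or plain count matrix) with no zero row or
#'   column total.
#' @return a `ca_result`: `row_coords`, `col_coords` (axes in columns),
#'   `singular_values`, `axis_inertias`, `axis_inertia_pct`,
#'   `total_inertia`, `row_masses`, `col_masses`, `grand_total`.
#' @export
correspondence_analysis <- function(table) {
  m <- if (inherits(table, "mr_table")) table$counts else as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: zero row or column total")
  n <- sum(m)
  P <- m / n
  rmass <- rowSums(P)
  cmass <- colSums(P)
  S <- diag(1 / sqrt(rmass)) %*% (P - outer(rmass, cmass)) %*%
    diag(1 / sqrt(cmass))
  sv <- svd(S)
  keep <- which(sv$d > 1e-12)
  k <- length(keep)
  if (k == 0) {
    F0 <- matrix(0, nrow(m), 0, dimnames = list(rownames(m), NULL))
    G0 <- matrix(0, ncol(m), 0, dimnames = list(colnames(m), NULL))
    return(structure(list(row_coords = F0, col_coords = G0,
                          singular_values = numeric(0),
                          axis_inertias = numeric(0),
                          axis_inertia_pct = numeric(0),
                          total_inertia = 0, row_masses = rmass,
                          col_masses = cmass, grand_total = n),
                     class = "ca_result"))
  }
  d <- sv$d[keep]
  Fc <- diag(1 / sqrt(rmass)) %*% sv$u[, keep, drop = FALSE] %*% diag(d, k)
  Gc <- diag(1 / sqrt(cmass)) %*% sv$v[, keep, drop = FALSE] %*% diag(d, k)
  # canonical orientation: dominant mass-weighted column point positive
  for (a in seq_len(k)) {
    j <- which.max(abs(cmass * Gc[, a]))
    if (Gc[j, a] < 0) { Gc[, a] <- -Gc[, a]; Fc[, a] <- -Fc[, a] }
  }
  dimnames(Fc) <- list(rownames(m), paste0("Axis", seq_len(k)))
  dimnames(Gc) <- list(colnames(m), paste0("Axis", seq_len(k)))
  inert <- d^2
  structure(list(row_coords = Fc, col_coords = Gc,
                 singular_values = d,
                 axis_inertias = inert,
                 axis_inertia_pct = 100 * inert / sum(inert),
                 total_inertia = sum(inert),
                 row_masses = rmass, col_masses = cmass, grand_total = n),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, digits = 4, ...) {
  cat(sprintf("Correspondence analysis: total inertia %.5f over %d axes\n",
              x$total_inertia, length(x$singular_values)))
  if (length(x$singular_values)) {
    cat("  axis inertias (%):",
        paste(sprintf("%.1f", x$axis_inertia_pct), collapse = ", "), "\n")
    cat("Row principal coordinates:\n")
    print(round(x$row_coords, digits))
    cat("Column principal coordinates:\n")
    print(round(x$col_coords, digits))
  }
  invisible(x)
}

#' Factorial-plane coordinates for two CA axes
#'
#' @param ca a `ca_result`.
#' @param axis_a,axis_b axis indices (1-based) to place on the horizontal
#'   and vertical axis.
#' @return data.frame with one row per category: `label`, `type`
#'   (`"row"`/`"col"`), `x`, `y`, plus the two axes' inertia percentages as
#'   attribute `"inertia_pct"`.
#' @export
factorial_plane <- function(ca, axis_a = 1, axis_b = 2) {
  stopifnot(inherits(ca, "ca_result"))
  k <- length(ca$singular_values)
  if (axis_a < 1 || axis_b < 1 || axis_a > k || axis_b > k)
    stop("requested axis out of range: the solution has ", k, " axis/axes")
  df <- rbind(
    data.frame(label = rownames(ca$row_coords), type = "row",
               x = ca$row_coords[, axis_a], y = ca$row_coords[, axis_b]),
    data.frame(label = rownames(ca$col_coords), type = "col",
               x = ca$col_coords[, axis_a], y = ca$col_coords[, axis_b]))
  rownames(df) <- NULL
  attr(df, "inertia_pct") <- ca$axis_inertia_pct[c(axis_a, axis_b)]
  df
}

#' Plot a CA factorial plane (symmetric map)
#'
#' @param x a `ca_result`.
#' @param axes length-2 integer vector of axes to display.
#' @param ... further arguments passed to [plot()].
#' @export
plot.ca_result <- function(x, axes = c(1, 2), ...) {
  pl <- factorial_plane(x, axes[1], axes[2])
  ip <- attr(pl, "inertia_pct")
  plot(pl$x, pl$y, type = "n",
       xlab = sprintf("Axis %d (%.1f%%)", axes[1], ip[1]),
       ylab = sprintf("Axis %d (%.1f%%)", axes[2], ip[2]), ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 2)
  with(pl, {
    graphics::points(x[type == "row"], y[type == "row"], pch = 17, col = 2)
    graphics::points(x[type == "col"], y[type == "col"], pch = 19, col = 4)
    graphics::text(x, y, label, pos = 3, cex = 0.8)
  })
  invisible(pl)
}
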