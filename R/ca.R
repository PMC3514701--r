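#' Build a malformation-by-pattern contingency table
#'
#' Rows are the ten organ-system malformation groups plus a
#' no-malformation row (`No-Mal`); columns are the vertebral pattern
#' classes, either all eight or collapsed to the four-level grouping that
#' ignores lumbo-sacral shifts. A subject contributes one count to every
#' system row in which it is affected (multiple-response rows are not
#' down-weighted), and to `No-Mal` when no available system is affected.
#' Subjects with no evaluable pattern or with every system non-available
#' are excluded.
#'
#' @param classified per-subject classification tibble
#'   ([classify_cohort()]).
#' @param coded per-subject malformation records ([code_findings()]).
#' @param grouping `"eight_level"` or `"four_level"`.
#' @return integer matrix with malformation rows and pattern columns.
#' @export
build_contingency <- function(classified, coded,
                              grouping = c("eight_level", "four_level")) {
  grouping <- match.arg(grouping)
  dat <- dplyr::inner_join(classified, coded, by = "subject_id")
  dat <- dat[!is.na(dat$pattern) & !dat$all_non_available, , drop = FALSE]

  col_fac <- if (grouping == "eight_level") {
    factor(dat$pattern, levels = pattern_levels())
  } else {
    pattern_group4(dat$pattern)
  }
  systems <- organ_systems()
  out <- matrix(0L, nrow = length(systems) + 1L, ncol = nlevels(col_fac),
                dimnames = list(c(systems, "No-Mal"), levels(col_fac)))
  for (s in systems) {
    hit <- dat[[s]] == "affected"
    out[s, ] <- as.integer(table(col_fac[hit]))
  }
  nomal <- dat$n_systems_affected == 0L
  out["No-Mal", ] <- as.integer(table(col_fac[nomal]))
  out
}

#' Simple correspondence analysis of a contingency table
#'
#' Decomposes the table's chi-square inertia by singular value
#' decomposition of the matrix of standardized residuals
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}`, where `P` is the
#' correspondence matrix (counts over the grand total) and `r`, `c` the
#' row and column masses. Principal inertias are the squared singular
#' values; row and column principal coordinates are the mass-rescaled
#' singular vectors scaled by the singular values; the total inertia
#' equals the Pearson chi-square statistic divided by the grand total.
#'
#' @param tab nonnegative count matrix with row and column names.
#' @return object of class `ca_result`: list with `sv`, `inertia`,
#'   `percent`, `total_inertia`, `row_coords`, `col_coords`,
#'   `row_mass`, `col_mass`, `ndim`, and `dropped` (labels of zero-margin
#'   rows/columns removed with a warning).
#' @export
correspondence_analysis <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("contingency table must be nonnegative")
  if (sum(tab) <= 0) stop("contingency table must have a positive total")
  if (is.null(rownames(tab))) rownames(tab) <- paste0("r", seq_len(nrow(tab)))
  if (is.null(colnames(tab))) colnames(tab) <- paste0("c", seq_len(ncol(tab)))

  dropped <- character()
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    dropped <- c(rownames(tab)[zr], colnames(tab)[zc])
    warning("dropping zero-margin rows/columns: ",
            paste(dropped, collapse = ", "))
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("correspondence analysis needs at least a 2x2 table after ",
         "dropping zero margins")
  }

  n <- sum(tab)
  P <- tab / n
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  dec <- svd(S)
  ndim <- min(nrow(tab), ncol(tab)) - 1L
  sv <- dec$d[seq_len(ndim)]
  inertia <- sv^2
  total <- sum(inertia)
  percent <- if (total > 0) 100 * inertia / total else rep(0, ndim)

  # principal coordinates: F = D_r^{-1/2} U D,  G = D_c^{-1/2} V D
  Fm <- sweep(dec$u[, seq_len(ndim), drop = FALSE] %*% diag(sv, ndim),
              1, sqrt(r), "/")
  Gm <- sweep(dec$v[, seq_len(ndim), drop = FALSE] %*% diag(sv, ndim),
              1, sqrt(cc), "/")
  dimnames(Fm) <- list(rownames(tab), paste0("Dim", seq_len(ndim)))
  dimnames(Gm) <- list(colnames(tab), paste0("Dim", seq_len(ndim)))

  structure(list(sv = sv, inertia = inertia, percent = percent,
                 total_inertia = total, row_coords = Fm, col_coords = Gm,
                 row_mass = r, col_mass = cc, ndim = ndim,
                 dropped = dropped, n = n),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, digits = 4, ...) {
  cat("Correspondence analysis:", length(x$row_mass), "rows x",
      length(x$col_mass), "columns,", x$ndim, "dimensions\n")
  cat("Total inertia:", format(x$total_inertia, digits = digits), "\n")
  tab <- data.frame(inertia = x$inertia, percent = x$percent)
  rownames(tab) <- paste0("Dim", seq_len(x$ndim))
  print(round(tab, digits))
  invisible(x)
}

#' Order rows and columns along the first principal axis
#'
#' The SVD sign is arbitrary, so the orientation is anchored: when a
#' `No-Mal` row is present all coordinates are flipped as needed so that
#' its first-dimension coordinate is negative (no-malformation group on
#' the left). Labels are returned sorted by their first-dimension
#' principal coordinate. A table at (near) independence has no usable
#' axis and is flagged degenerate.
#'
#' @param result a `ca_result`.
#' @param anchor_row row label anchored to the negative side (default
#'   `"No-Mal"`; ignored with a message if absent).
#' @return list with `rows` and `cols` tibbles (`label`, `coord`, sorted)
#'   and logical `degenerate`.
#' @export
interpret_axis <- function(result, anchor_row = "No-Mal") {
  stopifnot(inherits(result, "ca_result"))
  degenerate <- result$total_inertia < 1e-12
  Fm <- result$row_coords
  Gm <- result$col_coords
  if (!degenerate && anchor_row %in% rownames(Fm) &&
      Fm[anchor_row, 1] > 0) {
    Fm[, 1] <- -Fm[, 1]
    Gm[, 1] <- -Gm[, 1]
  }
  rows <- tibble::tibble(label = rownames(Fm), coord = Fm[, 1])
  cols <- tibble::tibble(label = rownames(Gm), coord = Gm[, 1])
  list(rows = rows[order(rows$coord), ],
       cols = cols[order(cols$coord), ],
       degenerate = degenerate)
}

#' Biplot of a correspondence analysis
#'
#' Symmetric map: rows and columns both in principal coordinates on the
#' first two dimensions (or the single dimension for 2-row/column
#' tables).
#'
#' @param x a `ca_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ca_result <- function(x, ...) {
  d2 <- if (x$ndim >= 2L) 2L else 1L
  xs <- c(x$row_coords[, 1], x$col_coords[, 1])
  ys <- if (d2 == 2L) c(x$row_coords[, 2], x$col_coords[, 2])
        else rep(0, length(xs))
  graphics::plot(xs, ys, type = "n",
                 xlab = sprintf("Dim 1 (%.1f%%)", x$percent[1]),
                 ylab = if (d2 == 2L)
                   sprintf("Dim 2 (%.1f%%)", x$percent[2]) else "",
                 ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 2)
  graphics::text(x$row_coords[, 1],
                 if (d2 == 2L) x$row_coords[, 2] else rep(0, nrow(x$row_coords)),
                 rownames(x$row_coords), col = "firebrick")
  graphics::text(x$col_coords[, 1],
                 if (d2 == 2L) x$col_coords[, 2] else rep(0, nrow(x$col_coords)),
                 rownames(x$col_coords), col = "navy")
  invisible(x)
}
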