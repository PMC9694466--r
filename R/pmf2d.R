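#' 2D potential of mean force by Boltzmann inversion
#'
#' Histograms the two reaction coordinates (Loop I / Loop II RMSD) and
#' inverts the occupancy: \code{F = -kB T ln(count / max_count)} per bin,
#' so the most occupied bin sits at F = 0. Empty bins are masked (not zero
#' and never infinite in output arithmetic); their display value is the
#' maximum occupied F + 1 kcal/mol.
#'
#' Bins are half-open [lo, hi) with the right-most bin closed.
#'
#' @param x,y per-frame reaction coordinates (Angstrom), equal length.
#' @param bins number of bins per axis (default 50) or a list of two
#'   explicit break vectors.
#' @param T temperature (K).
#' @param pad fractional range padding when breaks are derived from data.
#' @return object of class \code{pmf_grid}: \code{xbreaks}, \code{ybreaks},
#'   \code{F} (matrix, NA on empty bins), \code{display} (empty bins filled
#'   for plotting), \code{counts}, \code{mask}, \code{T}.
#' @export
compute_pmf2d <- function(x, y, bins = 50, T = 310, pad = 0.05) {
  if (length(x) != length(y)) .fail("x and y must have equal length")
  if (is.list(bins)) {
    xb <- bins[[1]]; yb <- bins[[2]]
  } else {
    if (length(x) < bins) .fail("fewer frames than bins")
    rx <- range(x); ry <- range(y)
    ex <- max(diff(rx), 1e-6) * pad; ey <- max(diff(ry), 1e-6) * pad
    xb <- seq(rx[1] - ex, rx[2] + ex, length.out = bins + 1)
    yb <- seq(ry[1] - ey, ry[2] + ey, length.out = bins + 1)
  }
  ix <- .bin_index(x, xb); iy <- .bin_index(y, yb)
  counts <- matrix(0L, length(xb) - 1, length(yb) - 1)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  occ <- counts > 0
  if (sum(occ) == 1)
    warning("all frames fall in a single bin; flat PMF", call. = FALSE)
  kT <- .const$R * T
  F <- matrix(NA_real_, nrow(counts), ncol(counts))
  F[occ] <- -kT * log(counts[occ] / max(counts))
  disp <- F
  disp[!occ] <- max(F, na.rm = TRUE) + 1
  structure(list(xbreaks = xb, ybreaks = yb, F = F, display = disp,
                 counts = counts, mask = !occ, T = T),
            class = "pmf_grid")
}

# half-open binning [lo, hi), right-most bin closed; out-of-range clamped
.bin_index <- function(v, breaks) {
  i <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(i, 1L), length(breaks) - 1L)
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("pmf_grid: %d x %d bins, %d occupied, F range [0, %.2f] kcal/mol\n",
              nrow(x$F), ncol(x$F), sum(!x$mask), max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Locate free-energy basins on a PMF grid
#'
#' Local minima over 8-neighborhoods of occupied bins, retained when their
#' F lies below (global minimum + depth_threshold). The global-minimum bin
#' is always a basin. Ties within a plateau keep the lowest (row, column)
#' bin.
#'
#' @param grid a \code{pmf_grid}.
#' @param depth_threshold kcal/mol above the global minimum (default 1.0).
#' @return data.frame with columns \code{ix}, \code{iy}, \code{x},
#'   \code{y} (bin centers), \code{F}, \code{count}.
#' @export
locate_basins <- function(grid, depth_threshold = 1.0) {
  F <- grid$F
  nr <- nrow(F); nc <- ncol(F)
  if (all(grid$mask)) .fail("grid has no occupied bins")
  is_min <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(F[i, j])) next
    nb <- expand.grid(di = -1:1, dj = -1:1)
    nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
    ok <- TRUE; strict <- FALSE
    for (k in seq_len(nrow(nb))) {
      ii <- i + nb$di[k]; jj <- j + nb$dj[k]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || is.na(F[ii, jj])) next
      if (F[ii, jj] < F[i, j]) { ok <- FALSE; break }
      if (F[ii, jj] > F[i, j]) strict <- TRUE
      # plateau tie-break: keep the lowest-index bin
      if (F[ii, jj] == F[i, j] &&
          (ii < i || (ii == i && jj < j))) { ok <- FALSE; break }
    }
    is_min[i, j] <- ok
  }
  keep <- which(is_min & F <= depth_threshold, arr.ind = TRUE)
  gm <- which(F == 0, arr.ind = TRUE)[1, , drop = FALSE]
  if (!any(keep[, 1] == gm[1] & keep[, 2] == gm[2]))
    keep <- rbind(gm, keep)
  xc <- (grid$xbreaks[-1] + grid$xbreaks[-length(grid$xbreaks)]) / 2
  yc <- (grid$ybreaks[-1] + grid$ybreaks[-length(grid$ybreaks)]) / 2
  out <- data.frame(ix = keep[, 1], iy = keep[, 2],
                    x = xc[keep[, 1]], y = yc[keep[, 2]],
                    F = F[keep], count = grid$counts[keep])
  out[order(out$F, out$ix, out$iy), , drop = FALSE]
}

#' Project metastate RMSD labels onto a PMF grid
#'
#' Each metastate's (Loop I, Loop II) mean RMSD label is mapped to its
#' containing bin (half-open binning; labels on a bin edge go to the
#' lower-index bin via the half-open rule) and annotated with that bin's
#' free energy. Labels outside the axis ranges are clamped with a warning.
#'
#' @param grid a \code{pmf_grid}.
#' @param labels data.frame with columns \code{rmsd_loopI},
#'   \code{rmsd_loopII} (e.g. from \code{\link{metastate_representatives}}).
#' @return the labels with added columns \code{ix}, \code{iy}, \code{F}.
#' @export
project_states_on_pmf <- function(grid, labels) {
  x <- labels$rmsd_loopI; y <- labels$rmsd_loopII
  outside <- x < min(grid$xbreaks) | x > max(grid$xbreaks) |
             y < min(grid$ybreaks) | y > max(grid$ybreaks)
  if (any(outside))
    warning(sum(outside), " label(s) outside the grid; clamped",
            call. = FALSE)
  ix <- .bin_index(x, grid$xbreaks)
  iy <- .bin_index(y, grid$ybreaks)
  labels$ix <- ix; labels$iy <- iy
  labels$F <- grid$display[cbind(ix, iy)]
  labels
}
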