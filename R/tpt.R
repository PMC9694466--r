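#' Transition path theory: committors, net flux and pathway decomposition
#'
#' Forward committor from the standard linear system, backward committor
#' from the time-reversed chain, gross flux
#' \code{f_ij = pi_i qminus_i T_ij qplus_j}, net flux
#' \code{f+_ij = max(0, f_ij - f_ji)}, and pathways by iterative bottleneck
#' decomposition: repeatedly remove the strongest (max-bottleneck) path's
#' flux until the residual is below 1e-8 of the total. Equal-bottleneck
#' candidates are broken by shortest, then lexicographically smallest,
#' state sequence.
#'
#' @param model an \code{msm_model}.
#' @param source,sink disjoint microstate index sets (indices into the
#'   active set / transition matrix).
#' @return object of class \code{tpt_result}: \code{qplus}, \code{qminus},
#'   \code{net_flux} (matrix), \code{total_flux}, \code{pathways} (list of
#'   state sequences), \code{path_flux}, \code{cum_fraction}.
#' @export
tpt_flux_pathways <- function(model, source, sink) {
  Tm <- model$T; pi <- model$pi
  n <- nrow(Tm)
  source <- unique(as.integer(source)); sink <- unique(as.integer(sink))
  if (length(intersect(source, sink)) > 0 ||
      length(source) == 0 || length(sink) == 0)
    .fail("source and sink must be disjoint non-empty state sets")
  if (any(c(source, sink) < 1) || any(c(source, sink) > n))
    .fail("source/sink states outside the active set")
  U <- setdiff(seq_len(n), c(source, sink))
  qp <- numeric(n); qp[sink] <- 1
  if (length(U) > 0) {
    A <- diag(length(U)) - Tm[U, U, drop = FALSE]
    b <- rowSums(Tm[U, sink, drop = FALSE])
    qp[U] <- solve(A, b)
  }
  # time-reversed chain
  Tb <- t(Tm) * outer(1 / pi, pi)
  qm <- numeric(n); qm[source] <- 1
  if (length(U) > 0) {
    A <- diag(length(U)) - Tb[U, U, drop = FALSE]
    b <- rowSums(Tb[U, source, drop = FALSE])
    qm[U] <- solve(A, b)
  }
  f <- outer(pi * qm, qp) * Tm
  diag(f) <- 0
  f[, source] <- 0; f[sink, ] <- 0
  fnet <- pmax(f - t(f), 0)   # first argument keeps the matrix dims
  total <- sum(fnet[source, , drop = FALSE]) -
           sum(fnet[, source, drop = FALSE])
  if (total <= 0) .fail("total reactive flux is zero")
  stopifnot(abs(total - (sum(fnet[, sink]) - sum(fnet[sink, ]))) < 1e-10)

  paths <- list(); fluxes <- numeric(0)
  resid <- fnet
  repeat {
    bp <- .best_bottleneck_path(resid, source, sink)
    if (is.null(bp) || bp$bottleneck <= 1e-8 * total) break
    paths[[length(paths) + 1]] <- bp$path
    fluxes <- c(fluxes, bp$bottleneck)
    for (k in seq_len(length(bp$path) - 1))
      resid[bp$path[k], bp$path[k + 1]] <-
        resid[bp$path[k], bp$path[k + 1]] - bp$bottleneck
    if (sum(fluxes) >= total * (1 - 1e-8)) break
  }
  ord <- order(-fluxes, vapply(paths, paste, "", collapse = ","))
  paths <- paths[ord]; fluxes <- fluxes[ord]
  structure(list(source = source, sink = sink, qplus = qp, qminus = qm,
                 net_flux = fnet, total_flux = total, pathways = paths,
                 path_flux = fluxes,
                 cum_fraction = cumsum(fluxes) / total),
            class = "tpt_result")
}

# widest (max-bottleneck) path from any source to any sink on capacities f;
# ties by shortest then lexicographically smallest node sequence
.best_bottleneck_path <- function(f, source, sink) {
  n <- nrow(f)
  caps <- sort(unique(f[f > 0]), decreasing = TRUE)
  if (length(caps) == 0) return(NULL)
  # binary search the largest capacity that still connects source to sink
  lo <- 1; hi <- length(caps); best <- NA
  reach <- function(cmin) {
    adj <- f >= cmin
    seen <- rep(FALSE, n); seen[source] <- TRUE
    queue <- source
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    any(seen[sink])
  }
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2
    if (reach(caps[mid])) { best <- mid; hi <- mid - 1 } else lo <- mid + 1
  }
  if (is.na(best)) return(NULL)
  b <- caps[best]
  # BFS on the thresholded graph for the shortest path, expanding neighbors
  # in index order so the first sink hit is lexicographically smallest
  adj <- f >= b
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n); seen[source] <- TRUE
  queue <- sort(source)
  hit <- NA
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v %in% sink) { hit <- v; break }
    for (w in which(adj[v, ])) if (!seen[w]) {
      seen[w] <- TRUE; prev[w] <- v; queue <- c(queue, w)
    }
  }
  if (is.na(hit)) return(NULL)
  path <- hit
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  list(path = path, bottleneck = b)
}

#' @export
print.tpt_result <- function(x, ...) {
  cat(sprintf("tpt_result: total flux %.4g, %d pathways\n",
              x$total_flux, length(x$pathways)))
  for (k in seq_len(min(5, length(x$pathways))))
    cat(sprintf("  %5.1f%%  %s\n", 100 * x$path_flux[k] / x$total_flux,
                paste(x$pathways[[k]], collapse = " -> ")))
  invisible(x)
}

#' Dominant states by cumulative pathway flux
#'
#' Takes the shortest prefix of the flux-sorted pathways whose cumulative
#' flux fraction strictly exceeds the threshold and returns the union of
#' states on those pathways with their flux shares.
#'
#' @param tpt a \code{tpt_result}.
#' @param threshold cumulative flux fraction (default 0.60, the dominant
#'   >60 percent rule).
#' @return list with \code{pathways} (selected indices), \code{states}
#'   (data.frame state / flux_share).
#' @export
select_dominant_states <- function(tpt, threshold = 0.60) {
  if (tpt$total_flux <= 0) .fail("total flux is zero")
  k <- match(TRUE, tpt$cum_fraction > threshold)
  if (is.na(k)) k <- length(tpt$pathways)
  sel <- seq_len(k)
  states <- sort(unique(unlist(tpt$pathways[sel])))
  share <- vapply(states, function(s)
    sum(tpt$path_flux[sel][vapply(tpt$pathways[sel], function(p) s %in% p,
                                  logical(1))]) / tpt$total_flux,
    numeric(1))
  list(pathways = sel,
       states = data.frame(state = states, flux_share = share))
}

#' Representative frames and loop-RMSD labels per metastate
#'
#' For each metastate: the \code{n_rep} frames nearest (Euclidean, feature
#' space) to the metastate's stationary-weighted center of its microstate
#' centers; the metastate RMSD label is the mean Loop I / Loop II RMSD of
#' those frames against the trajectory reference. The start state is the
#' metastate with the lowest mean loop RMSD; the end state the one with
#' the highest stationary weight.
#'
#' @param model an \code{msm_model} with metastates assigned.
#' @param clustering result of \code{\link{cluster_microstates}} (for
#'   centers and the discrete trajectory).
#' @param features the feature matrix used for clustering.
#' @param traj,structure trajectory and structure for the RMSD labels.
#' @param loopI,loopII region names for the two loop selections.
#' @param n_rep representatives per metastate (default 10).
#' @return data.frame per metastate: \code{metastate}, \code{weight},
#'   \code{rmsd_loopI}, \code{rmsd_loopII}, \code{is_start}, \code{is_end};
#'   attribute \code{representatives} lists frame indices.
#' @export
metastate_representatives <- function(model, clustering, features, traj,
                                      structure, loopI = "LoopI",
                                      loopII = "LoopII", n_rep = 10) {
  if (is.null(model$metastates)) .fail("metastates not assigned")
  assign_micro <- model$metastates$assignment
  n_meta <- max(assign_micro)
  # map frames to active-set microstates
  dtraj <- clustering$dtraj
  micro_of_frame <- match(dtraj, model$active)
  selI <- select_atoms(structure, region = loopI)
  selII <- select_atoms(structure, region = loopII)
  prot <- select_atoms(structure, role = "protein")
  reps <- vector("list", n_meta)
  out <- data.frame(metastate = seq_len(n_meta),
                    weight = model$metastates$weights,
                    rmsd_loopI = NA_real_, rmsd_loopII = NA_real_)
  for (m in seq_len(n_meta)) {
    micro <- which(assign_micro == m)
    w <- model$pi[micro] / sum(model$pi[micro])
    ctr <- colSums(clustering$centers[model$active[micro], , drop = FALSE] * w)
    frames <- which(micro_of_frame %in% micro)
    if (length(frames) == 0) next
    if (length(frames) < n_rep)
      warning(sprintf("metastate %d has only %d frames (< %d): using all",
                      m, length(frames), n_rep), call. = FALSE)
    d2 <- colSums((t(features[frames, , drop = FALSE]) - ctr)^2)
    take <- frames[order(d2, frames)][seq_len(min(n_rep, length(frames)))]
    reps[[m]] <- take
    sub <- new_trajectory(traj$coords[take, , , drop = FALSE],
                          dt_ps = traj$dt_ps, ref_frame = 1L)
    ref <- .frame(traj, traj$ref_frame)
    out$rmsd_loopI[m] <- mean(rmsd_series(sub, reference = ref,
                                          measure_sel = selI,
                                          fit_sel = prot))
    out$rmsd_loopII[m] <- mean(rmsd_series(sub, reference = ref,
                                           measure_sel = selII,
                                           fit_sel = prot))
  }
  mean_rmsd <- (out$rmsd_loopI + out$rmsd_loopII) / 2
  out$is_start <- seq_len(n_meta) == which.min(mean_rmsd)
  out$is_end <- seq_len(n_meta) == which.max(out$weight)
  attr(out, "representatives") <- reps
  out
}
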