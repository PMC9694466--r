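#' Featurize a trajectory for Markov state modelling
#'
#' Superposes every frame onto the trajectory reference using the rigid
#' (non-flexible) residues and returns the flattened 3D coordinates of the
#' flexible residues: a frames x (3 * n_selected_atoms) matrix.
#'
#' @param traj a \code{toy_trajectory}.
#' @param structure a \code{param_structure}.
#' @param flexible_residues residue numbers selected by the RMSF gate.
#' @return numeric feature matrix.
#' @export
featurize <- function(traj, structure, flexible_residues) {
  if (length(flexible_residues) == 0)
    .fail(paste("empty flexible set; lower the RMSF threshold or check",
                "that the trajectory has mobile regions"))
  flex <- select_atoms(structure, role = "protein",
                       residues = flexible_residues)
  prot <- select_atoms(structure, role = "protein")
  rigid <- setdiff(prot, flex)
  if (length(rigid) < 3) rigid <- prot
  ref <- .frame(traj, traj$ref_frame)
  nf <- n_frames(traj)
  out <- matrix(0, nf, 3 * length(flex))
  for (t in seq_len(nf)) {
    fr <- .frame(traj, t)
    fit <- kabsch_superpose(fr[rigid, , drop = FALSE],
                            ref[rigid, , drop = FALSE])
    out[t, ] <- as.numeric(t(apply_transform(fr, fit)[flex, , drop = FALSE]))
  }
  out
}

# k-means++ seeding (deterministic given the RNG state)
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ])^2)
  if (k > 1) for (c in 2:k) {
    p <- d2 / sum(d2)
    centers[c] <- if (all(d2 == 0)) which.min(seq_len(n) %in% centers)
      else sample.int(n, 1, prob = p)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[c], ])^2))
  }
  x[centers, , drop = FALSE]
}

#' Cluster frames into microstates
#'
#' k-means with k-means++ initialization (own seeding, Lloyd iterations via
#' \code{stats::kmeans}); a fixed seed gives deterministic labels.
#'
#' @param features frames x d feature matrix.
#' @param k number of microstates (must not exceed the number of distinct
#'   feature rows).
#' @param seed integer seed.
#' @return list with \code{dtraj} (frame microstate labels, 1-based),
#'   \code{centers} (k x d) and \code{inertia} (total within-cluster sum of
#'   squares).
#' @export
cluster_microstates <- function(features, k, seed = 1) {
  features <- as.matrix(features)
  if (k > nrow(features)) .fail("k exceeds the number of frames")
  ndist <- nrow(unique(features))
  if (k > ndist) .fail("k = %d exceeds the %d distinct points", k, ndist)
  set.seed(split_seed(seed, "kmeans"))
  init <- .kmeanspp_init(features, k)
  init <- init + 1e-10 * matrix(seq_len(length(init)), nrow(init))  # de-dup
  km <- suppressWarnings(
    kmeans(features, centers = init, iter.max = 200, algorithm = "Lloyd"))
  list(dtraj = as.integer(km$cluster), centers = km$centers,
       inertia = km$tot.withinss)
}

#' Estimate a Markov state model from a discrete trajectory
#'
#' Sliding-window transition counts at the given lag; reversible estimation
#' by count symmetrization \code{C <- (C + t(C)) / 2} (default on); the
#' transition matrix is the row-normalized count matrix restricted to the
#' largest connected set. The stationary distribution comes from the
#' leading left eigenvector and implied timescales from
#' \code{t_i = -lag / log(lambda_i)}.
#'
#' @param dtraj integer vector (or list of vectors) of microstate labels.
#' @param lag lag time in frames (>= 1).
#' @param reversible symmetrize counts before normalization.
#' @return object of class \code{msm_model}: \code{C}, \code{T}, \code{pi},
#'   \code{timescales}, \code{active} (microstate ids of the connected
#'   set), \code{dtraj}, \code{lag}; \code{metastates} is filled by
#'   \code{\link{coarse_grain_metastates}}.
#' @export
estimate_msm <- function(dtraj, lag = 1, reversible = TRUE) {
  if (lag < 1) .fail("lag must be >= 1")
  if (!is.list(dtraj)) dtraj <- list(dtraj)
  ns <- max(unlist(dtraj))
  C <- matrix(0, ns, ns)
  for (d in dtraj) {
    if (length(d) > lag) {
      from <- d[seq_len(length(d) - lag)]
      to <- d[(lag + 1):length(d)]
      tab <- table(factor(from, levels = 1:ns), factor(to, levels = 1:ns))
      C <- C + unclass(tab)
    }
  }
  C0 <- C
  if (reversible) C <- (C + t(C)) / 2
  # largest connected set on the count graph
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "max")
  comp <- igraph::components(g)
  active <- which(comp$membership == which.max(comp$csize))
  if (length(active) < ns)
    warning(sprintf("disconnected chain: restricting to %d of %d states",
                    length(active), ns), call. = FALSE)
  Ca <- C[active, active, drop = FALSE]
  rs <- rowSums(Ca)
  empty <- rs == 0
  if (any(empty)) {
    warning(sprintf("%d states with no outgoing counts dropped", sum(empty)),
            call. = FALSE)
    active <- active[!empty]
    Ca <- C[active, active, drop = FALSE]
    rs <- rowSums(Ca)
  }
  Tm <- Ca / rs
  pi <- stationary_distribution(Tm)
  ev <- eigen(Tm, only.values = TRUE)$values
  lam <- sort(Mod(ev), decreasing = TRUE)
  lam <- lam[-1]
  lam <- lam[lam > 1e-12 & lam < 1 - 1e-12]
  ts <- sort(-lag / log(lam), decreasing = TRUE)
  stopifnot(all(abs(rowSums(Tm) - 1) < 1e-10),
            max(abs(as.numeric(pi %*% Tm) - pi)) < 1e-8)
  structure(list(C = C0, T = Tm, pi = pi, timescales = ts,
                 active = active, dtraj = dtraj, lag = lag,
                 reversible = reversible, metastates = NULL),
            class = "msm_model")
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("msm_model: %d active microstates, lag %d\n",
              length(x$active), x$lag))
  cat("leading implied timescales:",
      paste(signif(head(x$timescales, 3), 4), collapse = ", "), "\n")
  if (!is.null(x$metastates))
    cat("metastates:", max(x$metastates$assignment), "\n")
  invisible(x)
}

#' Merge microstates into metastates (spectral, PCCA-style)
#'
#' Fuzzy memberships from the first \code{n_meta} right eigenvectors of the
#' transition matrix via the inner-simplex construction; crisp assignment
#' is the argmax membership. Metastate stationary weights sum the
#' microstate stationary distribution over members.
#'
#' @param model an \code{msm_model}.
#' @param n_meta number of metastates (2..n_microstates).
#' @param im_tol tolerance on imaginary parts of the dominant eigenvalues.
#' @return the model with \code{metastates}: list of \code{membership}
#'   (n_micro x n_meta), \code{assignment} (crisp), \code{weights}.
#' @export
coarse_grain_metastates <- function(model, n_meta, im_tol = 1e-8) {
  ns <- nrow(model$T)
  if (n_meta < 2 || n_meta > ns) .fail("n_meta must be in [2, %d]", ns)
  e <- eigen(model$T)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- e$values[ord][1:n_meta]
  if (any(abs(Im(vals)) > im_tol))
    .fail(paste("complex dominant eigenvalues; use reversible estimation",
                "(estimate_msm(..., reversible = TRUE))"))
  V <- Re(e$vectors[, ord[1:n_meta], drop = FALSE])
  V[, 1] <- 1
  # inner-simplex vertices: successively most distant rows
  idx <- integer(n_meta)
  idx[1] <- which.max(rowSums(V^2))
  W <- V
  for (k in 2:n_meta) {
    v <- W[idx[k - 1], ]
    W <- W - outer(as.numeric(W %*% v) / sum(v * v), v)
    idx[k] <- which.max(rowSums(W^2))
  }
  chi <- V %*% solve(V[idx, , drop = FALSE])
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  assign <- apply(chi, 1, which.max)
  w <- vapply(seq_len(n_meta), function(m) sum(model$pi[assign == m]),
              numeric(1))
  model$metastates <- list(membership = chi, assignment = assign, weights = w)
  model
}
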