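#' Stationary distribution of a row-stochastic matrix
#'
#' Leading left eigenvector, normalized to sum 1.
#'
#' @param P row-stochastic matrix.
#' @return numeric stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

.check_stochastic <- function(P, tol = 1e-8) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    .fail("transition matrix must be square")
  if (any(P < -tol)) .fail("transition matrix has negative entries")
  if (any(abs(rowSums(P) - 1) > tol))
    .fail("transition matrix rows must sum to 1")
}

#' Generate a synthetic trajectory with known hidden-state dynamics
#'
#' Hidden metastable states evolve by a discrete-time Markov chain; each
#' frame is the current state's reference coordinates plus isotropic
#' Gaussian displacement. The returned manifest records the full ground
#' truth (state sequence, generator matrix, designed contact and
#' interaction frequency tables) for parameter-recovery tests.
#'
#' Designed frequencies are occupancy expectations: a contact or interaction
#' is evaluated on each state's noise-free reference geometry and its
#' designed fraction is the stationary-weighted sum over states.
#'
#' @param structure a \code{param_structure}.
#' @param hidden_T row-stochastic transition matrix between hidden states.
#' @param state_refs list of per-state reference coordinate matrices
#'   (congruent with \code{structure}), e.g. from \code{\link{toy_state_refs}}.
#' @param noise_sd isotropic Gaussian displacement sd per coordinate
#'   (Angstrom), >= 0.
#' @param n_frames number of frames.
#' @param seed integer master seed (split per stage; identical inputs give
#'   identical output).
#' @param dt_ps frame interval in picoseconds (default 100, the output
#'   interval of the emulated simulations).
#' @param contact_cutoff distance (Angstrom) defining designed contacts.
#' @param init_state starting hidden state (default: drawn from the
#'   stationary distribution).
#' @return list with elements \code{trajectory} (class \code{toy_trajectory})
#'   and \code{manifest} (class \code{truth_manifest}).
#' @export
generate_trajectory <- function(structure, hidden_T, state_refs, noise_sd,
                                n_frames, seed, dt_ps = 100,
                                contact_cutoff = 4.5, init_state = NULL) {
  .check_stochastic(hidden_T)
  if (noise_sd < 0) .fail("noise_sd must be non-negative")
  n_state <- nrow(hidden_T)
  if (length(state_refs) != n_state)
    .fail("state_refs must supply one coordinate set per hidden state")
  n_atoms <- nrow(structure$atoms)
  for (s in seq_len(n_state))
    if (nrow(state_refs[[s]]) != n_atoms)
      .fail("state_refs[[%d]] has %d atoms, structure has %d",
            s, nrow(state_refs[[s]]), n_atoms)

  pi0 <- stationary_distribution(hidden_T)
  set.seed(split_seed(seed, "hidden"))
  states <- integer(n_frames)
  states[1] <- if (is.null(init_state))
    sample.int(n_state, 1, prob = pi0) else as.integer(init_state)
  if (n_frames > 1) for (t in 2:n_frames)
    states[t] <- sample.int(n_state, 1, prob = hidden_T[states[t - 1], ])

  set.seed(split_seed(seed, "noise"))
  coords <- array(0, c(n_frames, n_atoms, 3))
  for (t in seq_len(n_frames)) {
    disp <- if (noise_sd > 0)
      matrix(rnorm(3 * n_atoms, sd = noise_sd), n_atoms, 3) else 0
    coords[t, , ] <- state_refs[[states[t]]] + disp
  }

  traj <- new_trajectory(coords, dt_ps = dt_ps, ref_frame = 1L)
  contacts <- .designed_contacts(structure, state_refs, pi0, contact_cutoff)
  inter <- .designed_interactions(structure, state_refs, pi0)
  manifest <- structure(
    list(states = states, hidden_T = hidden_T, state_refs = state_refs,
         stationary = pi0, contacts = contacts, interactions = inter,
         seed = seed),
    class = "truth_manifest")
  list(trajectory = traj, manifest = manifest)
}

# atom pairs (non-bonded, different residues) within cutoff in >=1 state
.designed_contacts <- function(structure, state_refs, pi0, cutoff) {
  n <- nrow(structure$atoms)
  bonded <- matrix(FALSE, n, n)
  if (nrow(structure$bonds))
    bonded[cbind(structure$bonds$i, structure$bonds$j)] <- TRUE
  inlist <- vector("list", length(state_refs))
  for (s in seq_along(state_refs)) {
    d <- as.matrix(dist(state_refs[[s]]))
    inlist[[s]] <- d <= cutoff
  }
  any_in <- Reduce(`|`, inlist)
  resno <- structure$atoms$resno
  idx <- which(upper.tri(any_in) & any_in & !bonded &
               outer(resno, resno, "!="), arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(i = integer(0), j = integer(0), fraction = numeric(0)))
  frac <- rowSums(vapply(seq_along(state_refs), function(s)
    pi0[s] * inlist[[s]][idx], numeric(nrow(idx))))
  data.frame(i = idx[, 1], j = idx[, 2], fraction = frac)
}

# (residue, interaction type) designed frequencies from state geometries
.designed_interactions <- function(structure, state_refs, pi0) {
  lig <- select_atoms(structure, role = "ligand")
  if (length(lig) == 0)
    return(data.frame(resno = integer(0), type = character(0),
                      fraction = numeric(0)))
  per_state <- lapply(state_refs, function(xyz)
    detect_frame_interactions(xyz, structure, lig))
  all_rows <- unique(do.call(rbind, per_state)[, c("resno", "type")])
  if (is.null(all_rows) || nrow(all_rows) == 0)
    return(data.frame(resno = integer(0), type = character(0),
                      fraction = numeric(0)))
  frac <- vapply(seq_len(nrow(all_rows)), function(r) {
    sum(vapply(seq_along(per_state), function(s) {
      hit <- any(per_state[[s]]$resno == all_rows$resno[r] &
                 per_state[[s]]$type == all_rows$type[r])
      if (hit) pi0[s] else 0
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(resno = all_rows$resno, type = all_rows$type,
                    fraction = frac)
  out[order(out$resno, out$type), , drop = FALSE]
}

#' Construct and validate a trajectory
#'
#' @param coords frames x atoms x 3 array (Angstrom).
#' @param dt_ps frame interval (ps).
#' @param ref_frame reference frame index.
#' @return an object of class \code{toy_trajectory}.
#' @export
new_trajectory <- function(coords, dt_ps = 100, ref_frame = 1L) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    .fail("coords must be a frames x atoms x 3 array")
  if (dim(coords)[1] < 1) .fail("trajectory needs at least one frame")
  if (!all(is.finite(coords))) .fail("coordinates must be finite")
  structure(list(coords = coords, dt_ps = dt_ps,
                 ref_frame = as.integer(ref_frame)),
            class = "toy_trajectory")
}

#' @export
print.toy_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("toy_trajectory: %d frames x %d atoms, dt = %g ps\n",
              d[1], d[2], x$dt_ps))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{toy_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]
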