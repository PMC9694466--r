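#' Toy molecular-mechanics energy model
#'
#' Vacuum energy of a subset of the structure: harmonic bonds
#' (\code{k (r - r0)^2}) plus Lennard-Jones and Coulomb nonbonded terms with
#' 1-2 and 1-3 exclusions (1-4 pairs and beyond at full strength). Returns
#' closures with analytic gradient, used for minimization and normal-mode
#' analysis.
#'
#' @param structure a \code{param_structure}.
#' @param group atom indices included (default: all atoms).
#' @param dielectric interior dielectric.
#' @return list with \code{energy(x)} and \code{gradient(x)} taking an
#'   n x 3 coordinate matrix, plus \code{masses}, \code{group}.
#' @export
toy_energy_model <- function(structure, group = seq_len(nrow(structure$atoms)),
                             dielectric = 1) {
  a <- structure$atoms
  n <- length(group)
  b <- structure$bonds
  b <- b[b$i %in% group & b$j %in% group, , drop = FALSE]
  bi <- match(b$i, group); bj <- match(b$j, group)
  # bond-graph distances for exclusions
  excl12 <- cbind(bi, bj)
  gdist <- .bond_graph_dist(nrow(a), structure$bonds)[group, group,
                                                     drop = FALSE]
  up <- which(upper.tri(matrix(0, n, n)) & gdist >= 3, arr.ind = TRUE)
  pi_ <- up[, 1]; pj_ <- up[, 2]
  qq <- .const$coulomb * a$charge[group][pi_] * a$charge[group][pj_] /
    dielectric
  rmin <- a$rmin2[group][pi_] + a$rmin2[group][pj_]
  epsij <- sqrt(a$eps[group][pi_] * a$eps[group][pj_])
  r0 <- b$r0; kk <- b$k

  energy <- function(x) {
    e <- 0
    if (length(bi)) {
      d <- sqrt(rowSums((x[bi, , drop = FALSE] - x[bj, , drop = FALSE])^2))
      e <- e + sum(kk * (d - r0)^2)
    }
    if (length(pi_)) {
      d <- sqrt(rowSums((x[pi_, , drop = FALSE] - x[pj_, , drop = FALSE])^2))
      s6 <- (rmin / d)^6
      e <- e + sum(epsij * (s6^2 - 2 * s6)) + sum(qq / d)
    }
    e
  }
  gradient <- function(x) {
    g <- matrix(0, n, 3)
    if (length(bi)) {
      dx <- x[bi, , drop = FALSE] - x[bj, , drop = FALSE]
      d <- sqrt(rowSums(dx^2))
      coef <- 2 * kk * (d - r0) / d
      gv <- dx * coef
      for (ax in 1:3) {
        g[, ax] <- g[, ax] + tapply(c(gv[, ax], -gv[, ax]),
                                    factor(c(bi, bj), levels = seq_len(n)),
                                    sum, default = 0)
      }
    }
    if (length(pi_)) {
      dx <- x[pi_, , drop = FALSE] - x[pj_, , drop = FALSE]
      d <- sqrt(rowSums(dx^2))
      s6 <- (rmin / d)^6
      dEdr <- epsij * 12 * (s6 - s6^2) / d - qq / d^2
      gv <- dx * (dEdr / d)
      for (ax in 1:3) {
        g[, ax] <- g[, ax] + tapply(c(gv[, ax], -gv[, ax]),
                                    factor(c(pi_, pj_), levels = seq_len(n)),
                                    sum, default = 0)
      }
    }
    g
  }
  list(energy = energy, gradient = gradient,
       masses = a$mass[group], group = group)
}

# shortest bond-path distances (number of bonds) between all atoms
.bond_graph_dist <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0) return(matrix(Inf, n_atoms, n_atoms))
  g <- igraph::make_empty_graph(n = n_atoms, directed = FALSE)
  g <- igraph::add_edges(g, t(as.matrix(bonds[, c("i", "j")])))
  igraph::distances(g)
}

#' Minimize coordinates under an energy model
#'
#' BFGS minimization with the model's analytic gradient.
#'
#' @param coords starting n x 3 coordinates.
#' @param model from \code{\link{toy_energy_model}} (or any list with
#'   \code{energy}/\code{gradient} closures).
#' @param maxit iteration cap.
#' @return minimized n x 3 coordinate matrix.
#' @export
minimize_coords <- function(coords, model, maxit = 500) {
  n <- nrow(coords)
  res <- optim(as.numeric(coords),
               fn = function(v) model$energy(matrix(v, n, 3)),
               gr = function(v) as.numeric(model$gradient(matrix(v, n, 3))),
               method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-14))
  matrix(res$par, n, 3)
}

#' Vibrational entropy of one harmonic mode
#'
#' Quantum harmonic-oscillator entropy
#' \code{S = R * (x / (exp(x) - 1) - log(1 - exp(-x)))} with
#' \code{x = h nu / (kB T)}, in kcal/(mol K).
#'
#' @param x dimensionless \code{h nu / (kB T)}.
#' @return entropy in kcal/(mol K).
#' @export
harmonic_mode_entropy <- function(x) {
  .const$R * (x / expm1(x) - log1p(-exp(-x)))
}

#' Normal-mode vibrational entropy
#'
#' Builds the mass-weighted Hessian by central finite differences of the
#' analytic gradient at a supplied minimum, removes the (up to six)
#' near-zero rigid-body modes, and sums the harmonic-oscillator entropy of
#' the remaining modes. Errors if the input is not a minimum (gradient norm
#' above tolerance, more than six near-zero modes, or a strongly negative
#' eigenvalue).
#'
#' @param coords minimized n x 3 coordinates.
#' @param model energy model (see \code{\link{toy_energy_model}}); its
#'   \code{masses} element supplies atomic masses (amu).
#' @param T temperature (K).
#' @param h finite-difference step (Angstrom).
#' @param grad_tol max allowed gradient component at the minimum.
#' @param zero_tol eigenvalue magnitude below which a mode counts as
#'   rigid-body (kcal/mol/A^2/amu).
#' @return list with \code{S_vib} (kcal/(mol K)), \code{frequencies_Hz},
#'   \code{eigenvalues}, \code{n_zero}.
#' @export
vibrational_entropy <- function(coords, model, T = 310, h = 1e-4,
                                grad_tol = 1e-4, zero_tol = 1e-5) {
  n <- nrow(coords)
  g0 <- model$gradient(coords)
  if (max(abs(g0)) > grad_tol)
    .fail("not a minimum: max gradient component %.3g exceeds %.3g",
          max(abs(g0)), grad_tol)
  dim3 <- 3 * n
  H <- matrix(0, dim3, dim3)
  v0 <- as.numeric(coords)
  for (k in seq_len(dim3)) {
    vp <- v0; vp[k] <- vp[k] + h
    vm <- v0; vm[k] <- vm[k] - h
    H[, k] <- (as.numeric(model$gradient(matrix(vp, n, 3))) -
               as.numeric(model$gradient(matrix(vm, n, 3)))) / (2 * h)
  }
  H <- (H + t(H)) / 2
  m <- rep(model$masses, 3)      # flattened column-major: atom index recycles
  H <- H / sqrt(outer(m, m))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  # rigid-body gate scales with the stiffest mode (finite-difference noise)
  thresh <- zero_tol * max(1, max(abs(ev)))
  zero <- abs(ev) < thresh
  if (sum(zero) > 6)
    .fail("not a minimum: %d near-zero modes (max 6 rigid-body expected)",
          sum(zero))
  if (any(ev < -10 * thresh))
    .fail("not a minimum: negative eigenvalue %.3g", min(ev))
  lam <- ev[!zero]
  nu <- sqrt(lam) * .const$omega_conv / (2 * pi)
  x <- .const$h * nu / (.const$kB * T)
  list(S_vib = sum(harmonic_mode_entropy(x)), frequencies_Hz = nu,
       eigenvalues = ev, n_zero = sum(zero))
}

#' Normal-mode entropy contribution to binding (-T dS)
#'
#' For each selected frame the complex, receptor and ligand are minimized
#' separately under the toy energy model restricted to each group, their
#' vibrational entropies computed by normal-mode analysis, and
#' \code{-T dS = -T (S_complex - S_receptor - S_ligand)} averaged over
#' frames.
#'
#' @param traj a \code{toy_trajectory}.
#' @param structure a \code{param_structure}.
#' @param receptor_sel,ligand_sel atom index sets.
#' @param frames frame indices used (entropy is costly; a handful of frames
#'   is the working default at toy scale).
#' @param T temperature (K).
#' @return list with \code{minus_TdS} (kcal/mol, mean over frames),
#'   \code{se} and per-frame values.
#' @export
nma_entropy <- function(traj, structure, receptor_sel, ligand_sel,
                        frames = 1, T = 310) {
  groups <- list(complex = sort(c(receptor_sel, ligand_sel)),
                 receptor = receptor_sel, ligand = ligand_sel)
  vals <- vapply(frames, function(fr) {
    x <- .frame(traj, fr)
    S <- vapply(groups, function(g) {
      if (length(g) == 1) return(0)  # single atom: no internal modes
      mod <- toy_energy_model(structure, g)
      xm <- minimize_coords(x[g, , drop = FALSE], mod)
      vibrational_entropy(xm, mod, T = T)$S_vib
    }, numeric(1))
    -T * (S[["complex"]] - S[["receptor"]] - S[["ligand"]])
  }, numeric(1))
  list(minus_TdS = mean(vals),
       se = if (length(vals) > 1) sd(vals) / sqrt(length(vals)) else 0,
       per_frame = vals)
}
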