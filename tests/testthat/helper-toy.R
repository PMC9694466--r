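# shared fixtures, built in code

# the default two-state toy system
toy_system <- function(n_frames = 200, noise_sd = 0.1, seed = 42,
                       hidden_T = matrix(c(0.9, 0.1, 0.1, 0.9), 2,
                                         byrow = TRUE),
                       config = toy_config()) {
  st <- generate_topology(config)
  refs <- toy_state_refs(st, open_shift = config$open_shift)
  gen <- generate_trajectory(st, hidden_T, refs, noise_sd = noise_sd,
                             n_frames = n_frames, seed = seed)
  list(structure = st, traj = gen$trajectory, manifest = gen$manifest,
       refs = refs)
}

# minimal structure from coordinates and parameter vectors, for unit tests
tiny_structure <- function(xyz, charge = 0, rmin2 = 2, eps = 0.1,
                           born = 1.5, radius = 2, elem = "C",
                           resno = seq_len(nrow(xyz)), role = "protein",
                           mass = 12, bonds = NULL, name = "X",
                           donor = FALSE, acceptor = FALSE,
                           aromatic = FALSE, ring = NA_integer_,
                           cation = FALSE, anion = FALSE,
                           hydrophobic = FALSE) {
  n <- nrow(xyz)
  rep_n <- function(x) rep_len(x, n)
  atoms <- data.frame(name = rep_n(name), elem = rep_n(elem),
                      resno = rep_n(resno), resname = "XXX", chain = "A",
                      role = rep_n(role), charge = rep_n(charge),
                      rmin2 = rep_n(rmin2), eps = rep_n(eps),
                      born = rep_n(born), radius = rep_n(radius),
                      mass = rep_n(mass), donor = rep_n(donor),
                      acceptor = rep_n(acceptor), aromatic = rep_n(aromatic),
                      ring = rep_n(ring), cation = rep_n(cation),
                      anion = rep_n(anion), hydrophobic = rep_n(hydrophobic),
                      stringsAsFactors = FALSE)
  if (is.null(bonds))
    bonds <- data.frame(i = integer(0), j = integer(0),
                        r0 = numeric(0), k = numeric(0))
  regions <- data.frame(name = character(0), start = integer(0),
                        end = integer(0))
  new_param_structure(atoms, regions, bonds, xyz)
}

# trajectory from a list of frames
traj_from_frames <- function(frames, dt_ps = 100) {
  arr <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
  new_trajectory(arr, dt_ps = dt_ps)
}

# independent quaternion (Horn) superposition oracle
horn_rmsd <- function(mobile, target) {
  n <- nrow(mobile)
  Pm <- sweep(mobile, 2, colMeans(mobile))
  Pt <- sweep(target, 2, colMeans(target))
  M <- crossprod(Pm, Pt)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lmax <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(Pm^2) + sum(Pt^2) - 2 * lmax) / n
  sqrt(max(0, e2))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}
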