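#' Construct an MM/GBSA energy report
#'
#' Enforces the ledger identities \code{dE_bind = dE_elec + dE_vdW +
#' dE_covalent + dG_solv} and \code{dG_cal = dE_bind + minus_TdS} by
#' construction.
#'
#' @param dE_elec,dE_vdW,dE_covalent,dG_solv mean components (kcal/mol).
#' @param minus_TdS entropy contribution -T dS (kcal/mol).
#' @param se named numeric vector of standard errors per component.
#' @param n_frames number of frames averaged.
#' @return object of class \code{energy_report}.
#' @export
energy_report <- function(dE_elec, dE_vdW, dE_covalent, dG_solv,
                          minus_TdS = 0, se = NULL, n_frames = NA) {
  dE_bind <- dE_elec + dE_vdW + dE_covalent + dG_solv
  dG_cal <- dE_bind + minus_TdS
  structure(list(dE_elec = dE_elec, dE_vdW = dE_vdW,
                 dE_covalent = dE_covalent, dG_solv = dG_solv,
                 dE_bind = dE_bind, minus_TdS = minus_TdS, dG_cal = dG_cal,
                 se = se, n_frames = n_frames),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  comp <- c(dE_vdW = x$dE_vdW, dE_elec = x$dE_elec,
            dE_covalent = x$dE_covalent, dG_solv = x$dG_solv,
            dE_bind = x$dE_bind, minus_TdS = x$minus_TdS, dG_cal = x$dG_cal)
  cat("MM/GBSA energy report (kcal/mol, n =", x$n_frames, "frames)\n")
  print(round(comp, 2))
  invisible(x)
}

# classify cross pairs by bond-path distance: bonds, 1-4, nonbonded
.cross_pair_classes <- function(structure, groupA, groupB) {
  gd <- .bond_graph_dist(nrow(structure$atoms), structure$bonds)
  sub <- gd[groupA, groupB, drop = FALSE]
  idx <- function(cond) {
    w <- which(cond, arr.ind = TRUE)
    data.frame(i = groupA[w[, 1]], j = groupB[w[, 2]])
  }
  list(bonds = idx(sub == 1), excl13 = idx(sub == 2), pair14 = idx(sub == 3))
}

.bond_energy <- function(xyz, structure, pairs) {
  if (nrow(pairs) == 0) return(0)
  b <- structure$bonds
  key <- paste(pmin(pairs$i, pairs$j), pmax(pairs$i, pairs$j))
  bk <- paste(b$i, b$j)
  m <- match(key, bk)
  d <- sqrt(rowSums((xyz[pairs$i, , drop = FALSE] -
                     xyz[pairs$j, , drop = FALSE])^2))
  sum(b$k[m] * (d - b$r0[m])^2)
}

# per-frame MM/GBSA components for one group split
.frame_mmgbsa <- function(xyz, structure, receptor_sel, ligand_sel, cls,
                          dielectric, eps_solvent, probe, gamma, n_points) {
  excl <- rbind(cls$bonds, cls$excl13)
  mm <- mm_interaction_energy(xyz, structure, receptor_sel, ligand_sel,
                              dielectric, exclude = rbind(excl, cls$pair14))
  # covalent term: cross bonds + full-strength 1-4 elec/vdW across the link
  cov <- .bond_energy(xyz, structure, cls$bonds)
  if (nrow(cls$pair14) > 0) {
    a <- structure$atoms
    d <- sqrt(rowSums((xyz[cls$pair14$i, , drop = FALSE] -
                       xyz[cls$pair14$j, , drop = FALSE])^2))
    qq <- .const$coulomb * a$charge[cls$pair14$i] * a$charge[cls$pair14$j] /
      dielectric
    rmin <- a$rmin2[cls$pair14$i] + a$rmin2[cls$pair14$j]
    epsij <- sqrt(a$eps[cls$pair14$i] * a$eps[cls$pair14$j])
    s6 <- (rmin / d)^6
    cov <- cov + sum(qq / d) + sum(epsij * (s6^2 - 2 * s6))
  }
  both <- sort(c(receptor_sel, ligand_sel))
  sc <- solvation_energy(xyz, structure, both, eps_solvent, probe, gamma,
                         n_points)
  sr <- solvation_energy(xyz, structure, receptor_sel, eps_solvent, probe,
                         gamma, n_points)
  sl <- solvation_energy(xyz, structure, ligand_sel, eps_solvent, probe,
                         gamma, n_points)
  c(elec = mm$elec, vdw = mm$vdw, cov = cov,
    solv = (sc$polar - sr$polar - sl$polar) +
           (sc$nonpolar - sr$nonpolar - sl$nonpolar))
}

#' MM/GBSA binding free energy (single-trajectory protocol)
#'
#' Complex, receptor and ligand are scored on identical frames;
#' \code{dX = X_complex - X_receptor - X_ligand} per frame, averaged over
#' frames. The covalent term collects cross bonds and full-strength 1-4
#' electrostatic/van der Waals pairs across the covalent link (zero when
#' the groups share no bonds); bonded 1-2 and 1-3 cross pairs are excluded
#' from the nonbonded sums.
#'
#' @param traj a \code{toy_trajectory}.
#' @param structure a \code{param_structure}.
#' @param receptor_sel,ligand_sel disjoint atom index sets.
#' @param frames frame indices to score, or \code{stride} to take every
#'   stride-th frame.
#' @param stride frame stride when \code{frames} is NULL.
#' @param T temperature (K).
#' @param entropy_frames frame indices for normal-mode entropy; NULL skips
#'   the entropy term (minus_TdS = 0).
#' @param dielectric,eps_solvent,probe,gamma,n_points energy parameters
#'   (see \code{\link{mm_interaction_energy}}, \code{\link{solvation_energy}}).
#' @return an \code{\link{energy_report}}.
#' @export
mmgbsa_binding <- function(traj, structure, receptor_sel, ligand_sel,
                           frames = NULL, stride = 1, T = 310,
                           entropy_frames = NULL, dielectric = 1,
                           eps_solvent = 78.5, probe = 1.4, gamma = 0.0072,
                           n_points = 240) {
  if (is.null(frames)) frames <- seq(1, n_frames(traj), by = stride)
  if (length(frames) == 0) .fail("frame stride yields no frames")
  cls <- .cross_pair_classes(structure, receptor_sel, ligand_sel)
  per <- vapply(frames, function(fr)
    .frame_mmgbsa(.frame(traj, fr), structure, receptor_sel, ligand_sel,
                  cls, dielectric, eps_solvent, probe, gamma, n_points),
    numeric(4))
  mu <- rowMeans(per)
  nse <- if (length(frames) > 1)
    apply(per, 1, sd) / sqrt(length(frames)) else rep(0, 4)
  names(nse) <- rownames(per)
  mtds <- 0; ent_se <- 0
  if (!is.null(entropy_frames)) {
    ent <- nma_entropy(traj, structure, receptor_sel, ligand_sel,
                       frames = entropy_frames, T = T)
    mtds <- ent$minus_TdS; ent_se <- ent$se
  }
  energy_report(dE_elec = mu[["elec"]], dE_vdW = mu[["vdw"]],
                dE_covalent = mu[["cov"]], dG_solv = mu[["solv"]],
                minus_TdS = mtds,
                se = c(nse, minus_TdS = ent_se), n_frames = length(frames))
}

#' Per-residue decomposition of the protein-ligand interaction
#'
#' Cross interaction terms (vdW, electrostatic, GB polar) are assigned to
#' the protein residue of each atom pair; the nonpolar column is the
#' residue's surface-burial change (gamma times the SASA lost by its atoms
#' upon complexation). Residue totals of the pairwise columns sum exactly
#' to the whole-system cross terms.
#'
#' @param traj a \code{toy_trajectory}.
#' @param structure a \code{param_structure}.
#' @param ligand_sel ligand atom indices; every other atom is treated as
#'   receptor.
#' @param frames frame indices (default: all).
#' @param dielectric,eps_solvent,probe,gamma,n_points energy parameters.
#' @return data.frame with columns \code{resno}, \code{vdw}, \code{elec},
#'   \code{polar}, \code{nonpolar}, \code{total}; attribute \code{totals}
#'   carries the whole-system cross terms for the conservation check.
#' @export
per_residue_decomposition <- function(traj, structure, ligand_sel,
                                      frames = NULL, dielectric = 1,
                                      eps_solvent = 78.5, probe = 1.4,
                                      gamma = 0.0072, n_points = 240) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (length(frames) == 0) .fail("no frames selected")
  a <- structure$atoms
  receptor_sel <- setdiff(seq_len(nrow(a)), ligand_sel)
  cls <- .cross_pair_classes(structure, receptor_sel, ligand_sel)
  skip <- matrix(FALSE, length(receptor_sel), length(ligand_sel))
  for (p in list(cls$bonds, cls$excl13)) if (nrow(p)) {
    skip[cbind(match(p$i, receptor_sel), match(p$j, ligand_sel))] <- TRUE
  }
  resno <- a$resno[receptor_sel]
  ures <- sort(unique(resno))
  acc <- matrix(0, length(ures), 4,
                dimnames = list(ures, c("vdw", "elec", "polar", "nonpolar")))
  qq <- .const$coulomb * outer(a$charge[receptor_sel], a$charge[ligand_sel]) /
    dielectric
  rmin <- outer(a$rmin2[receptor_sel], a$rmin2[ligand_sel], "+")
  epsij <- sqrt(outer(a$eps[receptor_sel], a$eps[ligand_sel]))
  fac <- .const$gb * (1 - 1 / eps_solvent)
  RR <- outer(a$born[receptor_sel], a$born[ligand_sel])
  qqs <- outer(a$charge[receptor_sel], a$charge[ligand_sel])
  rgrp <- factor(resno, levels = ures)
  for (fr in frames) {
    xyz <- .frame(traj, fr)
    r <- .cross_dist(xyz[receptor_sel, , drop = FALSE],
                     xyz[ligand_sel, , drop = FALSE])
    s6 <- (rmin / r)^6
    vdw <- epsij * (s6^2 - 2 * s6); vdw[skip] <- 0
    el <- qq / r; el[skip] <- 0
    # GB cross pairs appear twice in the ordered double sum
    pol <- -2 * fac * qqs / sqrt(r^2 + RR * exp(-r^2 / (4 * RR)))
    sas_c <- shrake_rupley_sasa(xyz, a$radius, probe, n_points)
    sas_r <- shrake_rupley_sasa(xyz[receptor_sel, , drop = FALSE],
                                a$radius[receptor_sel], probe, n_points)
    dnp <- gamma * (sas_c[receptor_sel] - sas_r)
    acc[, "vdw"] <- acc[, "vdw"] + tapply(rowSums(vdw), rgrp, sum)
    acc[, "elec"] <- acc[, "elec"] + tapply(rowSums(el), rgrp, sum)
    acc[, "polar"] <- acc[, "polar"] + tapply(rowSums(pol), rgrp, sum)
    acc[, "nonpolar"] <- acc[, "nonpolar"] + tapply(dnp, rgrp, sum)
  }
  acc <- acc / length(frames)
  out <- data.frame(resno = ures, vdw = acc[, "vdw"], elec = acc[, "elec"],
                    polar = acc[, "polar"], nonpolar = acc[, "nonpolar"])
  out$total <- out$vdw + out$elec + out$polar + out$nonpolar
  attr(out, "totals") <- c(vdw = sum(out$vdw), elec = sum(out$elec),
                           polar = sum(out$polar),
                           nonpolar = sum(out$nonpolar))
  rownames(out) <- NULL
  out
}
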