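#' Kabsch superposition
#'
#' Least-squares rigid-body fit of a mobile point set onto a target by the
#' Kabsch SVD construction; reflections are rejected so the returned
#' rotation is always proper (determinant +1).
#'
#' Convention: rows are points; the fitted coordinates are
#' \code{mobile \%*\% R + rep(t, each = n)}.
#'
#' @param mobile n x 3 matrix.
#' @param target n x 3 matrix.
#' @param weights optional non-negative weights per point.
#' @return list with \code{R} (3 x 3 rotation), \code{t} (translation),
#'   \code{rmsd} (weighted RMSD after the fit, Angstrom).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  n <- nrow(mobile)
  if (n != nrow(target)) .fail("point sets must have equal size")
  if (n < 3) .fail("superposition needs at least 3 points")
  w <- if (is.null(weights)) rep(1, n) else weights
  if (any(w < 0) || sum(w) <= 0) .fail("weights must be non-negative")
  w <- w / sum(w)
  cm <- colSums(mobile * w); ct <- colSums(target * w)
  Pm <- sweep(mobile, 2, cm); Pt <- sweep(target, 2, ct)
  # collinearity check: centered points must span >= 2 dimensions
  if (sum(svd(Pm * sqrt(w))$d > 1e-8 * max(1, max(abs(Pm)))) < 2)
    .fail("points are collinear; superposition is degenerate")
  H <- crossprod(Pm * w, Pt)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$u, sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- ct - as.numeric(cm %*% R)
  fitted <- mobile %*% R + matrix(tr, n, 3, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((fitted - target)^2)))
  list(R = R, t = tr, rmsd = rmsd)
}

#' Apply a superposition transform
#' @param xyz n x 3 coordinates.
#' @param fit result of \code{\link{kabsch_superpose}}.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  xyz %*% fit$R + matrix(fit$t, nrow(xyz), 3, byrow = TRUE)
}

.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD against a reference
#'
#' Each frame is superposed onto the reference using the fit selection and
#' the RMSD is then measured over the measure selection.
#'
#' @param traj a \code{toy_trajectory}.
#' @param reference reference frame index, or an atoms x 3 matrix.
#' @param measure_sel atom indices measured.
#' @param fit_sel atom indices used for the superposition (default: the
#'   measure selection).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = traj$ref_frame,
                        measure_sel, fit_sel = measure_sel) {
  if (length(measure_sel) == 0 || length(fit_sel) == 0)
    .fail("empty selection")
  ref <- if (is.matrix(reference)) reference else
    traj$coords[reference, , , drop = TRUE]
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (t in seq_len(nf)) {
    fr <- .frame(traj, t)
    fit <- kabsch_superpose(fr[fit_sel, , drop = FALSE],
                            ref[fit_sel, , drop = FALSE])
    moved <- apply_transform(fr, fit)
    out[t] <- .rmsd(moved[measure_sel, , drop = FALSE],
                    ref[measure_sel, , drop = FALSE])
  }
  out
}

#' Per-atom RMSF profile
#'
#' Frames are first superposed onto the first frame over the selection, the
#' mean structure is computed, every frame is re-superposed onto that mean
#' (one iteration), and RMSF_i = sqrt(<|r_i - <r_i>|^2>).
#'
#' @param traj a \code{toy_trajectory}.
#' @param sel atom indices (default: all atoms).
#' @return numeric vector of RMSF values (Angstrom), named by atom index.
#' @export
rmsf_profile <- function(traj, sel = seq_len(dim(traj$coords)[2])) {
  nf <- n_frames(traj)
  if (nf < 2) .fail("RMSF requires at least 2 frames")
  sub <- traj$coords[, sel, , drop = FALSE]
  ref <- sub[1, , , drop = TRUE]
  if (length(sel) == 1) ref <- matrix(ref, 1, 3)
  aligned <- array(0, dim(sub))
  for (t in seq_len(nf)) {
    fr <- sub[t, , , drop = TRUE]
    if (length(sel) == 1) fr <- matrix(fr, 1, 3)
    if (length(sel) >= 3) fr <- apply_transform(fr, kabsch_superpose(fr, ref))
    aligned[t, , ] <- fr
  }
  m <- apply(aligned, c(2, 3), mean)
  for (t in seq_len(nf)) {
    fr <- aligned[t, , , drop = TRUE]
    if (length(sel) == 1) fr <- matrix(fr, 1, 3)
    if (length(sel) >= 3) fr <- apply_transform(fr, kabsch_superpose(fr, m))
    aligned[t, , ] <- fr
  }
  m <- apply(aligned, c(2, 3), mean)
  dev2 <- sweep(aligned, c(2, 3), m)^2
  out <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames & axes, times 3
  names(out) <- sel
  out
}

#' Residues whose RMSF strictly exceeds a threshold
#'
#' The flexible-residue gate used for MSM featurization: residues with RMSF
#' greater than the threshold (strict inequality) are selected, in index
#' order.
#'
#' @param rmsf named numeric vector (names = residue numbers) or a
#'   data.frame with columns \code{resno} and \code{rmsf}.
#' @param threshold Angstrom, default 2.
#' @return sorted integer vector of residue numbers.
#' @export
select_flexible_residues <- function(rmsf, threshold = 2) {
  if (is.data.frame(rmsf)) {
    res <- rmsf$resno; val <- rmsf$rmsf
  } else {
    if (length(rmsf) == 0) .fail("empty RMSF profile")
    res <- as.integer(names(rmsf)); val <- as.numeric(rmsf)
  }
  sort(res[val > threshold])
}

#' RMSF profile aggregated per residue
#'
#' @param traj a \code{toy_trajectory}.
#' @param structure a \code{param_structure}.
#' @param role role filter for the atoms considered (default protein).
#' @return data.frame with columns \code{resno} and \code{rmsf} (mean over
#'   the residue's atoms).
#' @export
residue_rmsf <- function(traj, structure, role = "protein") {
  sel <- select_atoms(structure, role = role)
  prof <- rmsf_profile(traj, sel)
  resno <- structure$atoms$resno[sel]
  agg <- tapply(prof, resno, mean)
  data.frame(resno = as.integer(names(agg)), rmsf = as.numeric(agg))
}

#' Classify switch conformations from loop RMSD coordinates
#'
#' Threshold classifier over the (Loop I, Loop II) RMSD plane: each zone is
#' an axis-aligned rectangle \code{c(xmin, xmax, ymin, ymax)}; zones must be
#' disjoint. Points in no zone are labelled "other".
#'
#' @param loopI_rmsd,loopII_rmsd numeric vectors (Angstrom).
#' @param zones named list of rectangles, e.g.
#'   \code{list(typeA = c(0, 2, 0, 2), typeB = c(0, 2, 4, 9), open = c(4, 9, 4, 9))}.
#' @return factor of labels (zone names plus "other").
#' @export
classify_switch_state <- function(loopI_rmsd, loopII_rmsd, zones) {
  zn <- names(zones)
  if (length(zones) > 1) {
    for (a in seq_len(length(zones) - 1)) for (b in (a + 1):length(zones)) {
      za <- zones[[a]]; zb <- zones[[b]]
      if (za[1] < zb[2] && zb[1] < za[2] && za[3] < zb[4] && zb[3] < za[4])
        .fail("zones '%s' and '%s' overlap", zn[a], zn[b])
    }
  }
  lab <- rep("other", length(loopI_rmsd))
  for (k in seq_along(zones)) {
    z <- zones[[k]]
    inz <- loopI_rmsd >= z[1] & loopI_rmsd < z[2] &
           loopII_rmsd >= z[3] & loopII_rmsd < z[4]
    lab[inz] <- zn[k]
  }
  factor(lab, levels = c(zn, "other"))
}

#' Fraction of frames per switch-state label
#'
#' @inheritParams classify_switch_state
#' @return data.frame with columns \code{label} and \code{fraction}
#'   (percent of frames).
#' @export
switch_state_fractions <- function(loopI_rmsd, loopII_rmsd, zones) {
  lab <- classify_switch_state(loopI_rmsd, loopII_rmsd, zones)
  tab <- table(lab)
  data.frame(label = names(tab),
             fraction = 100 * as.numeric(tab) / length(lab))
}
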