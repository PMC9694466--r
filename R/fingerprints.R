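#' Default geometric interaction rules
#'
#' Community-standard thresholds for the implemented interaction types;
#' every value is configurable. Types are named from the ligand's
#' perspective (HBDonor = the ligand donates; Cationic = the ligand carries
#' the cation), the convention of the fingerprint tables this reproduces.
#'
#' @param hydrophobic_max C/S-to-C/S distance (Angstrom).
#' @param hbond_max donor-acceptor distance.
#' @param hbond_angle_min D-H...A angle in degrees (applied only when the
#'   donor has an explicit bonded hydrogen).
#' @param pistack_max face-to-face centroid distance.
#' @param pistack_angle_max face-to-face ring-plane angle (degrees).
#' @param pistack_edge_max edge-to-face centroid distance.
#' @param pistack_edge_angles edge-to-face plane-angle window (degrees).
#' @param ionic_max opposite-formal-charge distance.
#' @param cationpi_max cation-to-ring-centroid distance.
#' @return named list of thresholds.
#' @export
interaction_rules <- function(hydrophobic_max = 4.5, hbond_max = 3.5,
                              hbond_angle_min = 130, pistack_max = 5.5,
                              pistack_angle_max = 30, pistack_edge_max = 6.5,
                              pistack_edge_angles = c(60, 90),
                              ionic_max = 4.5, cationpi_max = 4.5) {
  list(hydrophobic_max = hydrophobic_max, hbond_max = hbond_max,
       hbond_angle_min = hbond_angle_min, pistack_max = pistack_max,
       pistack_angle_max = pistack_angle_max,
       pistack_edge_max = pistack_edge_max,
       pistack_edge_angles = pistack_edge_angles,
       ionic_max = ionic_max, cationpi_max = cationpi_max)
}

#' Protein residues forming the ligand pocket in one frame
#'
#' Residues with at least one heavy atom within the cutoff of any ligand
#' heavy atom (6 Angstrom calculation-zone convention).
#'
#' @param xyz atoms x 3 coordinates.
#' @param structure a \code{param_structure}.
#' @param ligand_sel ligand atom indices.
#' @param cutoff Angstrom (default 6).
#' @return sorted integer vector of residue numbers.
#' @export
define_pocket <- function(xyz, structure, ligand_sel, cutoff = 6.0) {
  if (length(ligand_sel) == 0) .fail("empty ligand selection")
  a <- structure$atoms
  prot <- which(a$role == "protein" & a$elem != "H")
  lig <- ligand_sel[a$elem[ligand_sel] != "H"]
  if (length(prot) == 0 || length(lig) == 0) return(integer(0))
  d <- .cross_dist(xyz[prot, , drop = FALSE], xyz[lig, , drop = FALSE])
  near <- apply(d, 1, min) <= cutoff
  sort(unique(a$resno[prot[near]]))
}

# centroid and unit normal of a ring (>= 3 atoms)
.ring_geometry <- function(xyz) {
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = s$v[, 3])
}

.plane_angle <- function(n1, n2) {
  ca <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  acos(pmin(1, ca)) * 180 / pi
}

#' Detect protein-ligand interactions in one frame
#'
#' Deterministic application of the geometric rule set to the typing flags
#' carried by the structure (donor/acceptor/aromatic/charged/hydrophobic).
#' A residue can carry several interaction types in the same frame.
#'
#' Implemented types: Hydrophobic, HBDonor, HBAcceptor, PiStacking,
#' Cationic, Anionic, CationPi (ligand-perspective naming).
#'
#' @param xyz atoms x 3 coordinates.
#' @param structure a \code{param_structure}.
#' @param ligand_sel ligand atom indices.
#' @param rules threshold set from \code{\link{interaction_rules}}.
#' @return data.frame with columns \code{resno}, \code{type}.
#' @export
detect_frame_interactions <- function(xyz, structure, ligand_sel,
                                      rules = interaction_rules()) {
  a <- structure$atoms
  needed <- c("donor", "acceptor", "aromatic", "cation", "anion",
              "hydrophobic")
  for (fl in needed) if (any(is.na(a[[fl]])))
    .fail("missing typing flag '%s' for atom %d", fl, which(is.na(a[[fl]]))[1])
  prot <- which(a$role == "protein")
  hits <- list()
  add <- function(res, type) {
    if (length(res)) hits[[length(hits) + 1]] <<-
      data.frame(resno = res, type = type)
  }
  pair_res <- function(pi_, li_, cutoff) {
    if (length(pi_) == 0 || length(li_) == 0) return(integer(0))
    d <- .cross_dist(xyz[pi_, , drop = FALSE], xyz[li_, , drop = FALSE])
    unique(a$resno[pi_[apply(d <= cutoff, 1, any)]])
  }
  carbonish <- a$elem %in% c("C", "S")
  add(pair_res(prot[a$hydrophobic[prot] & carbonish[prot]],
               ligand_sel[a$hydrophobic[ligand_sel] & carbonish[ligand_sel]],
               rules$hydrophobic_max), "Hydrophobic")
  # H-bonds: donor-acceptor distance, plus angle when an explicit H exists
  hb <- function(don, acc) {
    if (length(don) == 0 || length(acc) == 0) return(integer(0))
    d <- .cross_dist(xyz[don, , drop = FALSE], xyz[acc, , drop = FALSE])
    ok <- d <= rules$hbond_max
    if (any(ok)) {
      w <- which(ok, arr.ind = TRUE)
      for (r in seq_len(nrow(w))) {
        dat <- don[w[r, 1]]; aat <- acc[w[r, 2]]
        hyd <- .bonded_hydrogens(structure, dat)
        if (length(hyd)) {
          ang <- max(vapply(hyd, function(h)
            .angle_deg(xyz[dat, ], xyz[h, ], xyz[aat, ]), numeric(1)))
          if (ang < rules$hbond_angle_min) ok[w[r, 1], w[r, 2]] <- FALSE
        }
      }
    }
    ok
  }
  lig_don <- ligand_sel[a$donor[ligand_sel]]
  prot_acc <- prot[a$acceptor[prot]]
  ok <- hb(lig_don, prot_acc)
  if (length(ok) && any(ok))
    add(unique(a$resno[prot_acc[apply(ok, 2, any)]]), "HBDonor")
  prot_don <- prot[a$donor[prot]]
  lig_acc <- ligand_sel[a$acceptor[ligand_sel]]
  ok <- hb(prot_don, lig_acc)
  if (length(ok) && any(ok))
    add(unique(a$resno[prot_don[apply(ok, 1, any)]]), "HBAcceptor")
  # pi-stacking between complete rings on both sides
  lrings <- .rings_of(structure, ligand_sel)
  prings <- .rings_of(structure, prot)
  for (lr in lrings) for (pr in prings) {
    gl <- .ring_geometry(xyz[lr, , drop = FALSE])
    gp <- .ring_geometry(xyz[pr, , drop = FALSE])
    dc <- sqrt(sum((gl$centroid - gp$centroid)^2))
    ang <- .plane_angle(gl$normal, gp$normal)
    face <- dc <= rules$pistack_max && ang <= rules$pistack_angle_max
    edge <- dc <= rules$pistack_edge_max &&
      ang >= rules$pistack_edge_angles[1] &&
      ang <= rules$pistack_edge_angles[2]
    if (face || edge) add(a$resno[pr[1]], "PiStacking")
  }
  add(pair_res(prot[a$anion[prot]], ligand_sel[a$cation[ligand_sel]],
               rules$ionic_max), "Cationic")
  add(pair_res(prot[a$cation[prot]], ligand_sel[a$anion[ligand_sel]],
               rules$ionic_max), "Anionic")
  # cation-pi in either orientation
  cp <- integer(0)
  for (pr in prings) {
    ctr <- .ring_geometry(xyz[pr, , drop = FALSE])$centroid
    lc <- ligand_sel[a$cation[ligand_sel]]
    if (length(lc)) {
      d <- sqrt(colSums((t(xyz[lc, , drop = FALSE]) - ctr)^2))
      if (any(d <= rules$cationpi_max)) cp <- c(cp, a$resno[pr[1]])
    }
  }
  for (lr in lrings) {
    ctr <- .ring_geometry(xyz[lr, , drop = FALSE])$centroid
    pc <- prot[a$cation[prot]]
    if (length(pc)) {
      d <- sqrt(colSums((t(xyz[pc, , drop = FALSE]) - ctr)^2))
      cp <- c(cp, a$resno[pc[d <= rules$cationpi_max]])
    }
  }
  add(unique(cp), "CationPi")
  if (length(hits) == 0)
    return(data.frame(resno = integer(0), type = character(0)))
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$resno, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.bonded_hydrogens <- function(structure, atom) {
  b <- structure$bonds
  nb <- c(b$j[b$i == atom], b$i[b$j == atom])
  nb[structure$atoms$elem[nb] == "H"]
}

.angle_deg <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  ca <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

# ring atom groups (by ring id) fully inside a selection
.rings_of <- function(structure, sel) {
  a <- structure$atoms
  ids <- unique(a$ring[sel][!is.na(a$ring[sel])])
  out <- list()
  for (id in ids) {
    members <- which(!is.na(a$ring) & a$ring == id)
    if (all(members %in% sel) && length(members) >= 3)
      out[[length(out) + 1]] <- members
  }
  out
}

#' Interaction frequencies over a trajectory
#'
#' Applies \code{\link{detect_frame_interactions}} to every frame and
#' reports, per (residue, type), the percentage of frames in which it
#' fires. Rows below the report threshold are dropped from the reported
#' table but kept in the raw one.
#'
#' @param traj a \code{toy_trajectory}.
#' @param structure a \code{param_structure}.
#' @param ligand_sel ligand atom indices.
#' @param rules rule set.
#' @param report_threshold percent (default 30); reporting keeps rows with
#'   frequency strictly greater than this.
#' @param frames frame indices (default: all).
#' @return object of class \code{fingerprint_table}: \code{raw} and
#'   \code{reported} data.frames (resno, type, frequency), plus the
#'   thresholds used.
#' @export
interaction_frequencies <- function(traj, structure, ligand_sel,
                                    rules = interaction_rules(),
                                    report_threshold = 30, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (length(frames) == 0) .fail("no frames")
  counts <- new.env(parent = emptyenv())
  for (fr in frames) {
    hits <- detect_frame_interactions(.frame(traj, fr), structure,
                                      ligand_sel, rules)
    if (nrow(hits)) for (r in seq_len(nrow(hits))) {
      key <- paste(hits$resno[r], hits$type[r], sep = "|")
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  keys <- ls(counts)
  if (length(keys)) {
    parts <- strsplit(keys, "|", fixed = TRUE)
    raw <- data.frame(
      resno = as.integer(vapply(parts, `[`, "", 1)),
      type = vapply(parts, `[`, "", 2),
      frequency = 100 * vapply(keys, function(k) counts[[k]], numeric(1)) /
        length(frames))
    raw <- raw[order(raw$resno, raw$type), , drop = FALSE]
    rownames(raw) <- NULL
  } else {
    raw <- data.frame(resno = integer(0), type = character(0),
                      frequency = numeric(0))
  }
  structure(list(raw = raw,
                 reported = raw[raw$frequency > report_threshold, ,
                                drop = FALSE],
                 report_threshold = report_threshold),
            class = "fingerprint_table")
}

#' @export
print.fingerprint_table <- function(x, ...) {
  cat(sprintf("fingerprint_table: %d rows (%d above %g%%)\n",
              nrow(x$raw), nrow(x$reported), x$report_threshold))
  print(head(x$reported, 15))
  invisible(x)
}

#' Frequency differences between two fingerprint tables
#'
#' Delta = B - A per (residue, type) row over the union of rows (absent
#' rows count as 0), sorted by decreasing absolute delta.
#'
#' @param tableA,tableB \code{fingerprint_table} objects or raw data.frames
#'   with columns resno, type, frequency.
#' @return data.frame resno, type, freq_A, freq_B, delta.
#' @export
compare_fingerprints <- function(tableA, tableB) {
  fa <- if (inherits(tableA, "fingerprint_table")) tableA$raw else tableA
  fb <- if (inherits(tableB, "fingerprint_table")) tableB$raw else tableB
  key <- function(d) paste(d$resno, d$type, sep = "|")
  u <- union(key(fa), key(fb))
  ma <- fa$frequency[match(u, key(fa))]; ma[is.na(ma)] <- 0
  mb <- fb$frequency[match(u, key(fb))]; mb[is.na(mb)] <- 0
  parts <- strsplit(u, "|", fixed = TRUE)
  out <- data.frame(resno = as.integer(vapply(parts, `[`, "", 1)),
                    type = vapply(parts, `[`, "", 2),
                    freq_A = ma, freq_B = mb, delta = mb - ma)
  out <- out[order(-abs(out$delta), out$resno, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-system fingerprint tables into one report
#'
#' Builds the cross-system frequency table; a row is kept when its maximum
#' frequency across systems strictly exceeds the threshold.
#'
#' @param tables named list of \code{fingerprint_table} objects.
#' @param threshold report threshold in percent (default 30).
#' @return data.frame with resno, type and one frequency column per system.
#' @export
fingerprint_report <- function(tables, threshold = 30) {
  raws <- lapply(tables, function(t)
    if (inherits(t, "fingerprint_table")) t$raw else t)
  key <- function(d) paste(d$resno, d$type, sep = "|")
  u <- Reduce(union, lapply(raws, key))
  parts <- strsplit(u, "|", fixed = TRUE)
  out <- data.frame(resno = as.integer(vapply(parts, `[`, "", 1)),
                    type = vapply(parts, `[`, "", 2))
  for (nm in names(raws)) {
    v <- raws[[nm]]$frequency[match(u, key(raws[[nm]]))]
    v[is.na(v)] <- 0
    out[[nm]] <- v
  }
  mx <- do.call(pmax, out[names(raws)])
  out <- out[mx > threshold, , drop = FALSE]
  out <- out[order(out$resno, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
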