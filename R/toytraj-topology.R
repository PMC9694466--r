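#' Default configuration for the coarse-grained toy system
#'
#' The generator emulates a small GTPase-like protein with two flexible loop
#' regions that undergo metastable open/closed transitions, a multi-atom
#' rigid ligand bound in a pocket formed by the second loop, a bound
#' nucleotide analogue and a divalent ion. One coarse-grained particle
#' represents each protein residue; the ligand carries explicit interaction
#' typing (aromatic hexagon, H-bond donor/acceptor, charged center) so that
#' fingerprint rules fire by construction.
#'
#' @param n_res number of protein residues (beads).
#' @param regions named list of inclusive 1-based residue ranges,
#'   \code{list(LoopI = c(30, 42), LoopII = c(57, 63))} by default (the loop
#'   subranges of the switch regions used as PMF reaction coordinates).
#' @param ligand logical; include the 10-atom rigid ligand.
#' @param nucleotide logical; include the 4-atom nucleotide analogue.
#' @param ion logical; include one divalent ion.
#' @param ligand_anchor residue the ligand pocket centers on.
#' @param nucleotide_anchor residue the nucleotide sits next to.
#' @param covalent_link_res protein residue covalently bonded to the ligand
#'   tail (the warhead link of a covalent inhibitor, a pocket-adjacent
#'   cysteine-like bead); \code{NA} for a noncovalent ligand.
#' @param open_shift axial displacement (Angstrom) of the loop regions in
#'   the "open" hidden state relative to the "closed" reference.
#' @param charge,rmin2,eps,born,mass default per-bead parameters: partial
#'   charge (e), Lennard-Jones r_min/2 (Angstrom), well depth (kcal/mol),
#'   Born radius (Angstrom), mass (amu).
#' @return a list of generator settings consumed by
#'   \code{\link{generate_topology}}.
#' @export
toy_config <- function(n_res = 70,
                       regions = list(LoopI = c(30, 42), LoopII = c(57, 63)),
                       ligand = TRUE, nucleotide = TRUE, ion = TRUE,
                       ligand_anchor = 60, nucleotide_anchor = 15,
                       covalent_link_res = 56, open_shift = 8,
                       charge = 0, rmin2 = 2.0, eps = 0.12,
                       born = 1.7, mass = 110) {
  list(n_res = n_res, regions = regions, ligand = ligand,
       nucleotide = nucleotide, ion = ion,
       ligand_anchor = ligand_anchor, nucleotide_anchor = nucleotide_anchor,
       covalent_link_res = covalent_link_res, open_shift = open_shift,
       charge = charge, rmin2 = rmin2, eps = eps, born = born, mass = mass)
}

# helix placement of protein beads: ~3.8 A between consecutive beads
.helix_coords <- function(n, radius = 2.3, turn = 100, rise = 1.5) {
  i <- seq_len(n) - 1
  th <- i * turn * pi / 180
  cbind(x = radius * cos(th), y = radius * sin(th), z = rise * i)
}

# outward (radial, in-plane) unit vector at a bead position
.radial_unit <- function(p) {
  u <- c(p[1], p[2], 0)
  n <- sqrt(sum(u^2))
  if (n < 1e-9) c(1, 0, 0) else u / n
}

.blank_atoms <- function(n) {
  data.frame(name = character(n), elem = character(n), resno = integer(n),
             resname = character(n), chain = character(n), role = character(n),
             charge = numeric(n), rmin2 = numeric(n), eps = numeric(n),
             born = numeric(n), radius = numeric(n), mass = numeric(n),
             donor = logical(n), acceptor = logical(n), aromatic = logical(n),
             ring = NA_integer_, cation = logical(n), anion = logical(n),
             hydrophobic = logical(n), stringsAsFactors = FALSE)
}

#' Construct the coarse-grained topology
#'
#' Builds a \code{param_structure}: the annotated atom table (with energy
#' parameters and interaction typing), the region table, the bond list
#' (with reference lengths taken from the built geometry) and the reference
#' coordinates. Deterministic for a fixed config.
#'
#' @param config a list from \code{\link{toy_config}}.
#' @return an object of class \code{param_structure} with elements
#'   \code{atoms} (data.frame), \code{regions} (data.frame name/start/end),
#'   \code{bonds} (data.frame i/j/r0/k) and \code{xyz} (atoms x 3 matrix of
#'   reference ("closed") coordinates).
#' @export
generate_topology <- function(config = toy_config()) {
  n_res <- config$n_res
  regs <- config$regions
  if (length(regs) > 0) {
    rg <- data.frame(name = names(regs),
                     start = vapply(regs, `[`, 0, 1L),
                     end = vapply(regs, `[`, 0, 2L),
                     stringsAsFactors = FALSE)
    if (any(rg$start < 1) || any(rg$end < rg$start))
      .fail("malformed region range in config")
    if (any(rg$end > n_res))
      .fail("region '%s' exceeds the %d-residue chain",
            rg$name[which(rg$end > n_res)[1]], n_res)
    if (nrow(rg) > 1) {
      for (a in seq_len(nrow(rg) - 1)) for (b in (a + 1):nrow(rg)) {
        if (rg$start[a] <= rg$end[b] && rg$start[b] <= rg$end[a])
          .fail("regions '%s' and '%s' overlap", rg$name[a], rg$name[b])
      }
    }
  } else {
    rg <- data.frame(name = character(0), start = integer(0), end = integer(0))
  }

  prot <- .blank_atoms(n_res)
  prot$name <- "CA"; prot$elem <- "C"; prot$resno <- seq_len(n_res)
  prot$resname <- "ALA"; prot$chain <- "A"; prot$role <- "protein"
  prot$charge <- config$charge; prot$rmin2 <- config$rmin2
  prot$eps <- config$eps; prot$born <- config$born
  prot$radius <- config$rmin2; prot$mass <- config$mass
  prot$hydrophobic <- TRUE
  # designed pocket chemistry (only meaningful if the residue exists)
  .set <- function(df, i, ...) {
    if (i >= 1 && i <= nrow(df)) { v <- list(...)
      for (k in names(v)) df[i, k] <- v[[k]] }
    df
  }
  anchor <- min(config$ligand_anchor, n_res)
  # polar/charged beads get hetero-atom LJ radii so the planted H-bond and
  # salt-bridge distances (2.9 / 3.4 A) sit outside the repulsive wall
  prot <- .set(prot, 16, resname = "LYS", cation = TRUE, donor = TRUE,
               charge = 1, hydrophobic = FALSE, elem = "N",
               rmin2 = 1.4, radius = 1.4)
  # pocket chemistry around the ligand anchor: donor / anion / acceptor
  prot <- .set(prot, anchor - 3, resname = "SER", donor = TRUE,
               hydrophobic = FALSE, elem = "O", charge = 0.2,
               rmin2 = 1.4, radius = 1.4)
  prot <- .set(prot, anchor + 3, resname = "GLU", anion = TRUE,
               acceptor = TRUE, charge = -1, hydrophobic = FALSE,
               elem = "O", rmin2 = 1.4, radius = 1.4)
  prot <- .set(prot, anchor + 4, resname = "THR", acceptor = TRUE,
               hydrophobic = FALSE, elem = "O", charge = -0.3,
               rmin2 = 1.4, radius = 1.4)
  xyz <- .helix_coords(n_res)

  atoms <- prot
  bonds <- data.frame(i = seq_len(max(n_res - 1, 0)),
                      j = seq_len(max(n_res - 1, 0)) + 1L)
  next_res <- n_res

  if (isTRUE(config$ligand)) {
    p0 <- xyz[anchor, ]; u <- .radial_unit(p0)
    v <- c(-u[2], u[1], 0)              # in-plane perpendicular
    w <- c(0, 0, 1)
    ctr <- p0 + 3.6 * u
    lig <- .blank_atoms(10)
    next_res <- next_res + 1L
    lig$resno <- next_res; lig$resname <- "LIG"; lig$chain <- "L"
    lig$role <- "ligand"; lig$elem <- "C"; lig$mass <- 12
    lig$charge <- 0; lig$rmin2 <- 1.9; lig$eps <- 0.09
    lig$born <- 1.6; lig$radius <- 1.9
    lig$name <- c(paste0("C", 1:6), "N1", "O1", "N2", "C7")
    # aromatic hexagon in the (v, w) plane, facing the helix
    ang <- (0:5) * pi / 3
    ring <- t(vapply(ang, function(a)
      ctr + 1.39 * (cos(a) * v + sin(a) * w), numeric(3)))
    lig$aromatic[1:6] <- TRUE; lig$ring[1:6] <- 1L
    lig$hydrophobic[1:6] <- TRUE
    # substituents planted at designed distances from the pocket residues
    # (H-bonds at 2.9 A, salt bridge at 3.4 A: far from rule thresholds)
    toward <- function(res, d) {
      if (!is.na(res) && res >= 1 && res <= n_res) {
        p <- xyz[res, ]
        p + d * (ctr - p) / sqrt(sum((ctr - p)^2))
      } else ctr + d * w
    }
    sub <- rbind(toward(anchor + 4, 2.9),       # N1 donor -> THR acceptor
                 toward(anchor - 3, 2.9),       # O1 acceptor <- SER donor
                 toward(anchor + 3, 3.4),       # N2 cation -> GLU anion
                 toward(config$covalent_link_res %||% NA, 1.8)) # warhead C
    lxyz <- rbind(ring, sub)
    lig$elem[7] <- "N"; lig$donor[7] <- TRUE; lig$charge[7] <- 0.3
    lig$hydrophobic[7] <- FALSE
    lig$elem[8] <- "O"; lig$acceptor[8] <- TRUE; lig$charge[8] <- -0.5
    lig$hydrophobic[8] <- FALSE
    lig$elem[9] <- "N"; lig$cation[9] <- TRUE; lig$charge[9] <- 1
    lig$hydrophobic[9] <- FALSE
    lig$hydrophobic[10] <- TRUE
    lig$rmin2[7:9] <- 1.45; lig$radius[7:9] <- 1.45
    off <- nrow(atoms)
    lb <- rbind(cbind(1:5, 2:6), c(6, 1), c(1, 7), c(4, 8), c(7, 9), c(6, 10))
    bonds <- rbind(bonds, data.frame(i = lb[, 1] + off, j = lb[, 2] + off))
    if (!is.na(config$covalent_link_res) && config$covalent_link_res <= n_res)
      bonds <- rbind(bonds,
                     data.frame(i = config$covalent_link_res, j = off + 10L))
    atoms <- rbind(atoms, lig); xyz <- rbind(xyz, lxyz)
  }

  if (isTRUE(config$nucleotide)) {
    anchor <- min(config$nucleotide_anchor, n_res)
    p0 <- xyz[anchor, ]; u <- .radial_unit(p0)
    ctr <- p0 + 4.0 * u
    nuc <- .blank_atoms(4)
    next_res <- next_res + 1L
    nuc$resno <- next_res; nuc$resname <- "GDP"; nuc$chain <- "N"
    nuc$role <- "nucleotide"
    nuc$name <- c("C1'", "P", "O2", "C2")
    nuc$elem <- c("C", "P", "O", "C"); nuc$mass <- c(12, 31, 16, 12)
    nuc$charge <- c(0, -1, -0.5, 0); nuc$rmin2 <- 1.9; nuc$eps <- 0.1
    nuc$born <- 1.6; nuc$radius <- 1.9
    nuc$acceptor[3] <- TRUE; nuc$hydrophobic[c(1, 4)] <- TRUE
    nxyz <- rbind(ctr, ctr + c(0, 0, 1.6), ctr + c(0, 0, 3.0),
                  ctr + 1.5 * u)
    off <- nrow(atoms)
    bonds <- rbind(bonds, data.frame(i = off + c(1L, 2L, 1L),
                                     j = off + c(2L, 3L, 4L)))
    atoms <- rbind(atoms, nuc); xyz <- rbind(xyz, nxyz)
  }

  if (isTRUE(config$ion)) {
    mg <- .blank_atoms(1)
    next_res <- next_res + 1L
    mg$resno <- next_res; mg$resname <- "MG"; mg$chain <- "I"
    mg$role <- "ion"; mg$name <- "MG"; mg$elem <- "Mg"
    mg$charge <- 2; mg$rmin2 <- 0.8; mg$eps <- 0.875
    mg$born <- 1.0; mg$radius <- 0.8; mg$mass <- 24
    mg$cation <- TRUE
    # beside the nucleotide phosphate if present, else beside the chain end
    pos <- if (isTRUE(config$nucleotide)) {
      xyz[nrow(xyz) - 2, ] + c(3.5, 0, 0)
    } else xyz[nrow(xyz), ] + c(4, 0, 0)
    atoms <- rbind(atoms, mg); xyz <- rbind(xyz, matrix(pos, 1))
  }

  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  d <- sqrt(rowSums((xyz[bonds$i, , drop = FALSE] -
                     xyz[bonds$j, , drop = FALSE])^2))
  bonds$r0 <- d; bonds$k <- 300
  new_param_structure(atoms, rg, bonds, xyz)
}

#' Construct and validate a param_structure
#'
#' @param atoms annotated atom table (see \code{\link{generate_topology}}).
#' @param regions data.frame with columns name, start, end.
#' @param bonds data.frame with columns i, j (1-based atom indices) and
#'   optionally r0 (reference length, Angstrom) and k (kcal/mol/A^2).
#' @param xyz reference coordinates, atoms x 3.
#' @return a \code{param_structure}.
#' @export
new_param_structure <- function(atoms, regions, bonds, xyz) {
  atoms$resno <- as.integer(atoms$resno)
  if (any(atoms$resno < 1)) .fail("residue indices must be strictly positive")
  for (p in c("charge", "rmin2", "eps", "born"))
    if (any(is.na(atoms[[p]]))) .fail("missing parameter '%s'", p)
  if (nrow(regions) > 0) {
    res <- unique(atoms$resno[atoms$role == "protein"])
    bad <- regions$end > max(c(res, 0)) | regions$start < min(c(res, Inf))
    if (any(bad)) .fail("region '%s' outside existing residues",
                        regions$name[which(bad)[1]])
  }
  if (nrow(bonds) > 0) {
    if (any(bonds$i == bonds$j)) .fail("bond list must be irreflexive")
    ij <- cbind(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    bonds$i <- ij[, 1]; bonds$j <- ij[, 2]
    bonds <- bonds[!duplicated(bonds[, c("i", "j")]), , drop = FALSE]
    if (max(bonds$j) > nrow(atoms)) .fail("bond references missing atom")
  }
  structure(list(atoms = atoms, regions = regions, bonds = bonds, xyz = xyz),
            class = "param_structure")
}

#' @export
print.param_structure <- function(x, ...) {
  tab <- table(x$atoms$role)
  cat("param_structure:", nrow(x$atoms), "atoms (",
      paste(names(tab), tab, collapse = ", "), ")\n")
  if (nrow(x$regions) > 0)
    cat("regions:", paste(sprintf("%s[%d-%d]", x$regions$name,
                                  x$regions$start, x$regions$end),
                          collapse = " "), "\n")
  cat("bonds:", nrow(x$bonds), "\n")
  invisible(x)
}

#' Select atom indices by role, residue or region
#'
#' @param structure a \code{param_structure}.
#' @param role optional role filter ("protein", "ligand", "nucleotide", "ion").
#' @param residues optional residue numbers.
#' @param region optional region name(s) from the structure's region table.
#' @param heavy drop hydrogens if TRUE.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(structure, role = NULL, residues = NULL,
                         region = NULL, heavy = FALSE) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(role)) keep <- keep & a$role %in% role
  if (!is.null(region)) {
    rg <- structure$regions
    miss <- setdiff(region, rg$name)
    if (length(miss)) .fail("unknown region '%s'", miss[1])
    rr <- unlist(lapply(region, function(nm) {
      r <- rg[rg$name == nm, ]
      seq(r$start, r$end)
    }))
    residues <- union(residues, rr)
    keep <- keep & a$role == "protein"
  }
  if (!is.null(residues)) keep <- keep & a$resno %in% residues
  if (heavy) keep <- keep & a$elem != "H"
  which(keep)
}

#' Per-state reference coordinates for open/closed loop dynamics
#'
#' The "closed" state is the built reference geometry; each additional state
#' displaces every loop-region bead along the helix axis by the given
#' shift, moving the loops out of the pocket so that contacts and
#' interactions formed by loop residues break in the open state.
#'
#' @param structure a \code{param_structure}.
#' @param open_shift axial displacement (Angstrom) for the open state.
#' @param states names of the states to build; shifts are recycled.
#' @param shifts displacement per state (Angstrom), default c(0, open_shift).
#' @return named list of atoms x 3 coordinate matrices.
#' @export
toy_state_refs <- function(structure, open_shift = 8,
                           states = c("closed", "open"),
                           shifts = c(0, open_shift)) {
  loops <- select_atoms(structure, region = structure$regions$name)
  out <- lapply(seq_along(states), function(s) {
    xyz <- structure$xyz
    if (shifts[s] != 0 && length(loops))
      xyz[loops, 3] <- xyz[loops, 3] + shifts[s]
    xyz
  })
  names(out) <- states
  out
}
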