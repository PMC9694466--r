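#' Write a DCD trajectory file
#'
#' Writes a CHARMM-style binary DCD (little-endian, no unit cell, 32-bit
#' float coordinates).
#'
#' @param coords frames x atoms x 3 array (Angstrom).
#' @param file output path.
#' @param dt_ps frame interval (ps), stored in the header.
#' @return the file path, invisibly.
#' @export
write_dcd <- function(coords, file, dt_ps = 100) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  con <- file(file, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(84); writeChar("CORD", con, 4, eos = NULL)
  wi(c(nf, 1, 1, nf, 0, 0, 0, 0, 0))    # icntrl 1-9
  wf(dt_ps)                              # delta (charmm: float32)
  wi(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 24))  # icntrl 11-20, charmm version 24
  wi(84)
  title <- sprintf("%-80s", "synthetic coarse-grained trajectory")
  wi(4 + 80); wi(1); writeChar(title, con, 80, eos = NULL); wi(4 + 80)
  wi(4); wi(na); wi(4)
  for (t in seq_len(nf)) for (ax in 1:3) {
    wi(4 * na); wf(coords[t, , ax]); wi(4 * na)
  }
  invisible(file)
}

#' Read a DCD trajectory file
#'
#' Strict reader for the format written by \code{\link{write_dcd}}: any
#' malformed or truncated record raises an error naming the byte offset.
#'
#' @param file path to a DCD file.
#' @return frames x atoms x 3 array.
#' @export
read_dcd <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  pos <- 0
  ri <- function(n) {
    v <- readBin(con, "integer", n, size = 4, endian = "little")
    if (length(v) < n)
      .fail("truncated DCD '%s' at byte offset %d", file, pos + 4 * length(v))
    pos <<- pos + 4 * n
    v
  }
  rf <- function(n) {
    v <- readBin(con, "numeric", n, size = 4, endian = "little")
    if (length(v) < n)
      .fail("truncated DCD '%s' at byte offset %d", file, pos + 4 * length(v))
    pos <<- pos + 4 * n
    v
  }
  if (ri(1) != 84) .fail("malformed DCD '%s' at byte offset 0", file)
  magic <- readChar(con, 4); pos <- pos + 4
  if (!identical(magic, "CORD"))
    .fail("malformed DCD '%s': bad magic at byte offset 4", file)
  icntrl_a <- ri(9)
  rf(1)                          # delta
  icntrl_b <- ri(10)
  nf <- icntrl_a[1]
  if (ri(1) != 84) .fail("malformed DCD '%s' at byte offset %d", file, pos - 4)
  tsz <- ri(1); ntitle <- ri(1)
  readChar(con, 80 * ntitle); pos <- pos + 80 * ntitle
  if (ri(1) != tsz) .fail("malformed DCD '%s': title block", file)
  if (ri(1) != 4) .fail("malformed DCD '%s': atom-count block", file)
  na <- ri(1)
  if (ri(1) != 4) .fail("malformed DCD '%s': atom-count block", file)
  coords <- array(NA_real_, c(nf, na, 3))
  for (t in seq_len(nf)) for (ax in 1:3) {
    if (ri(1) != 4 * na)
      .fail("malformed DCD '%s': frame %d block size at byte offset %d",
            file, t, pos - 4)
    coords[t, , ax] <- rf(na)
    if (ri(1) != 4 * na)
      .fail("malformed DCD '%s': frame %d block size at byte offset %d",
            file, t, pos - 4)
  }
  coords
}

#' Write a toy system to standard formats
#'
#' Writes topology + reference frame as PDB, all frames as DCD, and the
#' per-atom parameters / typing flags / regions / bonds as a JSON sidecar.
#' Optionally writes the ground-truth manifest alongside.
#'
#' @param structure a \code{param_structure}.
#' @param trajectory a \code{toy_trajectory}.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @param manifest optional \code{truth_manifest} to serialize.
#' @return named character vector of written paths, invisibly.
#' @export
write_system <- function(structure, trajectory, dir, prefix = "system",
                         manifest = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  a <- structure$atoms
  ref <- trajectory$coords[trajectory$ref_frame, , ]
  pdb_path <- file.path(dir, paste0(prefix, ".pdb"))
  bio3d::write.pdb(file = pdb_path, xyz = as.numeric(t(ref)),
                   type = ifelse(a$role == "protein", "ATOM", "HETATM"),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   elesy = substr(a$elem, 1, 2))
  dcd_path <- file.path(dir, paste0(prefix, ".dcd"))
  write_dcd(trajectory$coords, dcd_path, dt_ps = trajectory$dt_ps)
  side_path <- file.path(dir, paste0(prefix, "_params.json"))
  side <- list(atoms = a, regions = structure$regions,
               bonds = structure$bonds,
               dt_ps = trajectory$dt_ps, ref_frame = trajectory$ref_frame)
  jsonlite::write_json(side, side_path, digits = NA, auto_unbox = TRUE)
  paths <- c(pdb = pdb_path, dcd = dcd_path, params = side_path)
  if (!is.null(manifest)) {
    man_path <- file.path(dir, paste0(prefix, "_manifest.json"))
    jsonlite::write_json(
      list(states = manifest$states, hidden_T = manifest$hidden_T,
           stationary = manifest$stationary,
           state_refs = lapply(manifest$state_refs, unclass),
           contacts = manifest$contacts, interactions = manifest$interactions,
           seed = manifest$seed),
      man_path, digits = NA, auto_unbox = TRUE)
    paths <- c(paths, manifest = man_path)
  }
  invisible(paths)
}

#' Read a toy system back from disk
#'
#' Rereads the PDB/DCD/sidecar written by \code{\link{write_system}} and
#' reconstructs the \code{param_structure} and \code{toy_trajectory}.
#' Atom-count mismatches between the PDB and the DCD raise an error.
#'
#' @param dir directory containing the files.
#' @param prefix file name prefix used at write time.
#' @return list with elements \code{structure} and \code{trajectory}.
#' @export
read_system <- function(dir, prefix = "system") {
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, "_params.json")),
                              simplifyVector = TRUE)
  atoms <- as.data.frame(side$atoms)
  atoms$ring <- as.integer(atoms$ring)
  pdb <- bio3d::read.pdb(file.path(dir, paste0(prefix, ".pdb")))
  if (nrow(pdb$atom) != nrow(atoms))
    .fail("PDB has %d atoms but sidecar has %d", nrow(pdb$atom), nrow(atoms))
  if (!all(pdb$atom$resno == atoms$resno))
    .fail("PDB residue numbering disagrees with sidecar")
  coords <- read_dcd(file.path(dir, paste0(prefix, ".dcd")))
  if (dim(coords)[2] != nrow(atoms))
    .fail("DCD has %d atoms but PDB/sidecar has %d",
          dim(coords)[2], nrow(atoms))
  regions <- as.data.frame(side$regions)
  bonds <- as.data.frame(side$bonds)
  ref <- as.integer(side$ref_frame %||% 1L)
  st <- new_param_structure(atoms, regions, bonds, coords[ref, , ])
  tr <- new_trajectory(coords, dt_ps = side$dt_ps %||% 100, ref_frame = ref)
  list(structure = st, trajectory = tr)
}
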