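# Atom-role assignment rules.  Water oxygens are recognised from common
# water residue names under both PDB v3 and GROMACS dialects; HFIP
# fluorines from fluoroalcohol residue names with F* atom names; peptide
# hydrogens from standard amino-acid residue names with H*/Q* atom names
# (Q denotes pseudo-atoms of overlapped methyl/methylene protons).
.WATER_RES <- c("SOL", "WAT", "HOH", "TIP", "T3P", "T4P", "T5P", "SPC")
.HFIP_RES <- c("HFP", "HFI", "FIP", "HIP6", "HFIP")
.AA_RES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")

#' Assign analysis roles from atom and residue names
#'
#' Maps each atom to one of the roles `"peptide-H"`, `"fluorine"`,
#' `"water-O"` or `"other"` using residue/atom naming rules covering PDB v3
#' and GROMACS conventions.  Unrecognised residue names either raise an
#' error listing the offending atoms (`strict = TRUE`) or fall back to
#' `"other"`.
#'
#' @param atoms data frame with `name`, `resname` columns.
#' @param strict error on unknown residue names?
#' @return the atom table with a `role` column.
#' @export
assign_roles <- function(atoms, strict = TRUE) {
  rn <- toupper(trimws(atoms$resname))
  an <- toupper(trimws(atoms$name))
  role <- rep("other", nrow(atoms))
  water <- rn %in% .WATER_RES
  role[water & (an %in% c("OW", "O") | grepl("^O", an))] <- "water-O"
  hfip <- rn %in% .HFIP_RES
  role[hfip & grepl("^F", an)] <- "fluorine"
  pept <- rn %in% .AA_RES
  role[pept & grepl("^[HQ]", an)] <- "peptide-H"
  known <- water | hfip | pept | rn %in% c("CL", "NA", "ION", "CL-", "NA+")
  if (strict && any(!known)) {
    bad <- unique(paste(atoms$resname, atoms$name)[!known])
    stop("unassigned atoms (unknown residue naming): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (+%d more)", length(bad) - 10))
  }
  atoms$role <- role
  atoms
}

#' Read a trajectory from standard or internal formats
#'
#' Topology formats: internal text format (self-contained), GRO, PDB.
#' Frame formats: DCD (read with bio3d), or a second GRO/PDB holding the
#' same atoms when only a single extra frame is needed.  XTC and TRR are
#' compressed binary formats with no reader available here and are
#' rejected with an explanatory error.  Roles are assigned by naming rules
#' (see [assign_roles()]); coordinates are returned in nm.
#'
#' @param topology_path path to internal/GRO/PDB file.
#' @param frames_path optional path to DCD frames.
#' @param dt snapshot interval in ps (required unless the internal format,
#'   which stores it, is read).
#' @param strict_roles error on unknown residue names?
#' @param box_edge cubic box edge in nm, required for PDB topologies
#'   lacking a CRYST1 record.
#' @return a [trajectory].
#' @export
read_trajectory <- function(topology_path, frames_path = NULL, dt = NULL,
                            strict_roles = TRUE, box_edge = NULL) {
  if (!file.exists(topology_path)) stop("no such file: ", topology_path)
  ext <- tolower(tools::file_ext(topology_path))
  if (!is.null(frames_path)) {
    fext <- tolower(tools::file_ext(frames_path))
    if (fext %in% c("xtc", "trr"))
      stop("XTC/TRR frames are not supported (no reader available); ",
           "convert to DCD or the internal text format")
  }
  if (ext %in% c("trj", "solvnoe", "txt"))
    return(read_trajectory_internal(topology_path))
  top <- switch(ext,
    gro = .read_gro(topology_path),
    pdb = .read_pdb(topology_path, box_edge),
    stop("unsupported topology format: .", ext))
  atoms <- assign_roles(top$atoms, strict = strict_roles)
  if (is.null(frames_path)) {
    if (is.null(dt)) dt <- 1
    coords <- array(top$xyz, dim = c(nrow(atoms), 3L, 1L))
  } else {
    if (is.null(dt)) stop("'dt' (ps) is required when reading frame files")
    fext <- tolower(tools::file_ext(frames_path))
    if (fext != "dcd") stop("unsupported frame format: .", fext)
    dcd <- bio3d::read.dcd(frames_path, verbose = FALSE)
    nf <- nrow(dcd)
    na <- ncol(dcd) / 3L
    if (na != nrow(atoms))
      stop(sprintf("topology has %d atoms but frames carry %d",
                   nrow(atoms), na))
    coords <- array(NA_real_, dim = c(na, 3L, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(dcd[f, ], ncol = 3L, byrow = TRUE) / 10
  }
  trajectory(coords, box_edge = top$box_edge, dt = if (is.null(dt)) 1 else dt,
             atoms = atoms)
}

.read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  if (is.na(n)) stop("malformed GRO file: bad atom count")
  al <- lines[3:(2 + n)]
  atoms <- data.frame(
    resid = as.integer(substr(al, 1, 5)),
    resname = trimws(substr(al, 6, 10)),
    name = trimws(substr(al, 11, 15)),
    stringsAsFactors = FALSE)
  xyz <- cbind(as.numeric(substr(al, 21, 28)),
               as.numeric(substr(al, 29, 36)),
               as.numeric(substr(al, 37, 44)))
  boxv <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])
  if (length(boxv) >= 3 && max(abs(diff(boxv[1:3]))) > 1e-6)
    stop("only cubic boxes are supported")
  key <- paste(atoms$resid, atoms$resname)
  atoms$mol_id <- as.integer(factor(key, levels = unique(key)))
  list(atoms = atoms, xyz = xyz, box_edge = boxv[1])
}

.read_pdb <- function(path, box_edge) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  atoms <- data.frame(resid = a$resno, resname = a$resid, name = a$elety,
                      stringsAsFactors = FALSE)
  atoms$mol_id <- as.integer(factor(paste(atoms$resid, atoms$resname),
                                    levels = unique(paste(atoms$resid,
                                                          atoms$resname))))
  be <- box_edge
  if (is.null(be)) {
    cr <- grep("^CRYST1", readLines(path), value = TRUE)
    if (length(cr))
      be <- as.numeric(substr(cr[1], 7, 15)) / 10
    else stop("PDB lacks CRYST1; supply 'box_edge' (nm)")
  }
  list(atoms = atoms, xyz = cbind(a$x, a$y, a$z) / 10, box_edge = be)
}

#' Write a trajectory in the internal text format
#'
#' Plain-text, self-contained format: a header holding box, dt and the atom
#' table, followed by one block of `x y z` (nm, full precision) per frame.
#' Reading it back reproduces the trajectory bit-identically.
#'
#' @param traj a [trajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- nrow(traj$atoms)
  writeLines(c("#SOLVNOE-TRAJ 1",
               sprintf("natoms %d nframes %d dt_ps %.17g box_nm %.17g",
                       na, nf, traj$dt, traj$box_edge)), con)
  at <- traj$atoms
  writeLines(sprintf("atom %s %s %d %s %d", at$name, at$resname, at$resid,
                     at$role, at$mol_id), con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("frame %d", f), con)
    m <- traj$coords[, , f, drop = FALSE]
    writeLines(sprintf("%.17g %.17g %.17g", m[, 1, 1], m[, 2, 1], m[, 3, 1]),
               con)
  }
  invisible(path)
}

#' Read the internal trajectory format
#'
#' @param path file written by [write_trajectory()].
#' @return a [trajectory].
#' @export
read_trajectory_internal <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#SOLVNOE-TRAJ"))
    stop("not an internal-format trajectory: ", path)
  hdr <- strsplit(lines[2], "\\s+")[[1]]
  val <- function(key) hdr[which(hdr == key) + 1L]
  na <- as.integer(val("natoms")); nf <- as.integer(val("nframes"))
  dt <- as.numeric(val("dt_ps")); box <- as.numeric(val("box_nm"))
  at <- lines[3:(2 + na)]
  parts <- strsplit(at, " ")
  atoms <- data.frame(
    name = vapply(parts, `[`, "", 2L),
    resname = vapply(parts, `[`, "", 3L),
    resid = as.integer(vapply(parts, `[`, "", 4L)),
    role = vapply(parts, `[`, "", 5L),
    mol_id = as.integer(vapply(parts, `[`, "", 6L)),
    stringsAsFactors = FALSE)
  body <- lines[-(1:(2 + na))]
  coord_lines <- body[!startsWith(body, "frame")]
  if (length(coord_lines) != na * nf)
    stop(sprintf("expected %d coordinate lines, found %d", na * nf,
                 length(coord_lines)))
  xyz <- matrix(scan(text = coord_lines, quiet = TRUE), ncol = 3L,
                byrow = TRUE)
  coords <- array(NA_real_, dim = c(na, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- xyz[((f - 1) * na + 1):(f * na), , drop = FALSE]
  trajectory(coords, box_edge = box, dt = dt, atoms = atoms)
}

#' Write a single frame as a GRO file
#'
#' @param traj a [trajectory].
#' @param path output path.
#' @param frame frame index.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, frame = 1L) {
  at <- traj$atoms
  m <- traj$coords[, , frame, drop = FALSE]
  lines <- c("trajectory frame written by solvnoe",
             sprintf("%5d", nrow(at)),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     at$resid %% 100000L, substr(at$resname, 1, 5),
                     substr(at$name, 1, 5), seq_len(nrow(at)) %% 100000L,
                     m[, 1, 1], m[, 2, 1], m[, 3, 1]),
             sprintf("%10.5f%10.5f%10.5f", traj$box_edge, traj$box_edge,
                     traj$box_edge))
  writeLines(lines, path)
  invisible(path)
}
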