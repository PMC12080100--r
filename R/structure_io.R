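# All-atom protein structures: parsing, residue views, backbone/side-chain
# dihedrals and center-of-mass geometry.

ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    other = 0)
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                   other = 1.70)

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

AA_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")

# chi-angle atom name quadruples per residue type (first three chi angles)
CHI_ATOMS <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","NE")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","CE")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"), c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

infer_element <- function(name, elesy = NULL) {
  if (!is.null(elesy) && !is.na(elesy) && nzchar(trimws(elesy))) {
    e <- toupper(trimws(elesy))
  } else {
    # first non-digit character of the atom name
    e <- toupper(sub("^[0-9]*", "", trimws(name)))
    e <- substr(e, 1L, 1L)
  }
  if (e %in% c("C", "H", "N", "O", "S")) e else "other"
}

#' Parse an all-atom protein structure from a PDB or PQR file
#'
#' PQR rows (PDB variant with per-atom partial charge and radius after the
#' coordinates) populate `charge` and `radius`; plain PDB atoms get `NA`
#' charge and an element-based van der Waals radius. Waters and non-protein
#' heteroatoms are excluded from residue views but retained in `$hetero`.
#' Altloc records other than `' '`/`'A'` are dropped; insertion codes are
#' appended to the author residue id. Only the first model of a multi-model
#' file is read.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"pdb"`, `"pqr"`; `"auto"` uses the
#'   extension (`.pqr` means PQR).
#' @param permissive if `TRUE`, unknown residue types are mapped to a generic
#'   residue (`"UNK"`) instead of raising an error.
#' @return a `ProteinStructure`: list with `atoms` (data frame: serial, name,
#'   element, residue_index, residue_type, chain, resid, x, y, z, charge,
#'   radius, mass), `residues` (one row per residue view with a `ca_idx`
#'   pointer into `atoms`), `hetero`, and `source_format`.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "pqr"),
                            permissive = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  }
  pdb <- if (format == "pqr") bio3d::read.pqr(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", " ", "A"), , drop = FALSE]
  build_structure(at, source_format = toupper(format), permissive = permissive)
}

# assemble a ProteinStructure from a bio3d-style atom data frame
build_structure <- function(at, source_format, permissive = FALSE) {
  elesy <- if ("elesy" %in% names(at)) at$elesy else rep(NA_character_, nrow(at))
  element <- mapply(infer_element, at$elety, elesy, USE.NAMES = FALSE)
  insert <- if ("insert" %in% names(at)) at$insert else rep(NA_character_, nrow(at))
  insert[is.na(insert)] <- ""
  resid_id <- paste0(at$chain, ":", at$resno, insert)
  is_pqr <- identical(source_format, "PQR")
  charge <- if (is_pqr) at$o else rep(NA_real_, nrow(at))
  radius <- if (is_pqr) at$b else unname(ELEMENT_RADII[element])
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = element,
    residue_type = trimws(at$resid), chain = as.character(at$chain),
    resid = resid_id, resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    charge = charge, radius = radius,
    mass = unname(ELEMENT_MASSES[element]),
    record = at$type,
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- "A"
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in structure")

  is_protein <- atoms$record == "ATOM" & atoms$residue_type != "HOH"
  unknown <- is_protein & !(atoms$residue_type %in% STANDARD_AA)
  if (any(unknown)) {
    if (permissive) atoms$residue_type[unknown] <- "UNK"
    else stop("unknown residue type(s): ",
              paste(unique(atoms$residue_type[unknown]), collapse = ", "),
              " (use permissive = TRUE to map to a generic residue)")
  }
  hetero <- atoms[!is_protein, , drop = FALSE]
  prot <- atoms[is_protein, , drop = FALSE]
  if (nrow(prot) == 0L) stop("no protein atoms in structure")

  # residue views in file order; residue_index is 0-based
  key <- paste(prot$resid, prot$residue_type)
  first_seen <- !duplicated(key)
  res_keys <- key[first_seen]
  prot$residue_index <- match(key, res_keys) - 1L
  residues <- data.frame(
    residue_index = seq_along(res_keys) - 1L,
    residue_type = prot$residue_type[first_seen],
    chain = prot$chain[first_seen],
    resid = prot$resid[first_seen],
    resno = prot$resno[first_seen],
    stringsAsFactors = FALSE
  )
  ca_idx <- integer(nrow(residues))
  for (i in seq_len(nrow(residues))) {
    rows <- which(prot$residue_index == residues$residue_index[i] &
                  prot$name == "CA")
    if (length(rows) == 0L)
      stop("residue ", residues$resid[i], " (", residues$residue_type[i],
           ") lacks a CA atom")
    ca_idx[i] <- rows[1L]
  }
  residues$ca_idx <- ca_idx

  structure(list(atoms = prot, residues = residues, hetero = hetero,
                 source_format = source_format),
            class = "ProteinStructure")
}

#' @export
print.ProteinStructure <- function(x, ...) {
  cat("<ProteinStructure> ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " atoms (", x$source_format, ")\n", sep = "")
  invisible(x)
}

n_residues <- function(s) nrow(s$residues)

atom_coords <- function(s, rows = NULL) {
  a <- if (is.null(rows)) s$atoms else s$atoms[rows, , drop = FALSE]
  cbind(a$x, a$y, a$z)
}

ca_coords <- function(s) atom_coords(s, s$residues$ca_idx)

# look up one named atom of residue i (0-based); NULL when absent
residue_atom <- function(s, i, name) {
  rows <- which(s$atoms$residue_index == i & s$atoms$name == name)
  if (length(rows) == 0L) return(NULL)
  c(s$atoms$x[rows[1L]], s$atoms$y[rows[1L]], s$atoms$z[rows[1L]])
}

#' Signed dihedral angle from four points
#'
#' Standard four-point torsion in radians, in (-pi, pi].
#' @param p1,p2,p3,p4 numeric 3-vectors (angstrom).
#' @return angle in radians.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(-y, x)
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

# phi/psi continuity breaks at numbering gaps or CA-CA distance > 4.5 A
chain_connected <- function(s, i, j) {
  ri <- s$residues[i + 1L, ]; rj <- s$residues[j + 1L, ]
  if (!identical(ri$chain, rj$chain)) return(FALSE)
  if (abs(rj$resno - ri$resno) != 1L) return(FALSE)
  pi_ <- atom_coords(s, ri$ca_idx); pj <- atom_coords(s, rj$ca_idx)
  sqrt(sum((pi_ - pj)^2)) <= 4.5
}

#' Backbone and side-chain dihedrals of one residue
#'
#' Computes phi, psi and the first three chi angles where the defining atoms
#' exist. Angles that do not exist (chain termini, chain breaks, residue
#' types without the side-chain atoms) are flagged `exists = FALSE` and
#' their value must be ignored by consumers.
#'
#' @param s a `ProteinStructure`.
#' @param i residue index (0-based).
#' @return list with elements `phi`, `psi`, `chi1`, `chi2`, `chi3`, each a
#'   list `(angle, exists)` with the angle in radians.
#' @export
backbone_dihedrals <- function(s, i) {
  nres <- n_residues(s)
  if (i < 0L || i >= nres) stop("residue index out of range: ", i)
  none <- list(angle = 0, exists = FALSE)
  get4 <- function(pts) {
    if (any(vapply(pts, is.null, logical(1L)))) return(none)
    list(angle = dihedral_angle(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]]),
         exists = TRUE)
  }
  phi <- none
  if (i > 0L && chain_connected(s, i - 1L, i)) {
    phi <- get4(list(residue_atom(s, i - 1L, "C"), residue_atom(s, i, "N"),
                     residue_atom(s, i, "CA"), residue_atom(s, i, "C")))
  }
  psi <- none
  if (i < nres - 1L && chain_connected(s, i, i + 1L)) {
    psi <- get4(list(residue_atom(s, i, "N"), residue_atom(s, i, "CA"),
                     residue_atom(s, i, "C"), residue_atom(s, i + 1L, "N")))
  }
  rtype <- s$residues$residue_type[i + 1L]
  chis <- CHI_ATOMS[[rtype]]
  chi <- list(none, none, none)
  if (!is.null(chis)) {
    for (k in seq_len(min(3L, length(chis)))) {
      pts <- lapply(chis[[k]], function(nm) residue_atom(s, i, nm))
      chi[[k]] <- get4(pts)
    }
  }
  list(phi = phi, psi = psi, chi1 = chi[[1L]], chi2 = chi[[2L]],
       chi3 = chi[[3L]])
}

center_of_mass <- function(s) {
  xyz <- atom_coords(s)
  m <- s$atoms$mass
  colSums(xyz * m) / sum(m)
}

#' Distance from a residue's CA to the protein center of mass
#'
#' @param s a `ProteinStructure` (atom masses required).
#' @param i residue index (0-based).
#' @return distance in angstrom.
#' @export
com_distance <- function(s, i) {
  if (i < 0L || i >= n_residues(s)) stop("residue index out of range: ", i)
  com <- center_of_mass(s)
  ca <- atom_coords(s, s$residues$ca_idx[i + 1L])
  sqrt(sum((ca - com)^2))
}

#' Write a structure as a fixed-column PDB file
#'
#' @param s a `ProteinStructure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L,
    ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name),
    a$residue_type, a$chain, a$resno %% 10000L, a$x, a$y, a$z, 1, 0,
    ifelse(a$element == "other", "X", a$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# apply a rigid motion (and optional reflection) to every atom; test utility
# but exported because ensemble tooling uses it.

#' Rigidly transform a structure
#'
#' Applies `x -> R x + t` to every atom coordinate (protein and hetero).
#' @param s a `ProteinStructure`.
#' @param R 3x3 rotation (or improper rotation) matrix.
#' @param t length-3 translation, angstrom.
#' @return the transformed `ProteinStructure`.
#' @export
transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  for (fld in c("atoms", "hetero")) {
    a <- s[[fld]]
    if (nrow(a) == 0L) next
    xyz <- cbind(a$x, a$y, a$z) %*% t(R)
    s[[fld]]$x <- xyz[, 1L] + t[1L]
    s[[fld]]$y <- xyz[, 2L] + t[2L]
    s[[fld]]$z <- xyz[, 3L] + t[3L]
  }
  s
}

#' Random rotation matrix
#' @param rng_state ignored; draws from the current RNG stream.
#' @return 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(rng_state = NULL) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  matrix(c(
    a*a + b*b - c*c - d*d, 2*(b*c - a*d),         2*(b*d + a*c),
    2*(b*c + a*d),         a*a - b*b + c*c - d*d, 2*(c*d - a*b),
    2*(b*d - a*c),         2*(c*d + a*b),         a*a - b*b - c*c + d*d
  ), 3L, 3L, byrow = TRUE)
}
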