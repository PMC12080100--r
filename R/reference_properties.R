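# Reference calculators: mass-weighted radius of gyration, Shrake-Rupley
# solvent-accessible surface area with deterministic golden-spiral sphere
# points, and the null-model pKa baseline.

#' Mass-weighted radius of gyration
#'
#' @param s a `ProteinStructure` (atom masses required).
#' @return Rg in angstrom.
#' @export
radius_of_gyration <- function(s) {
  xyz <- atom_coords(s)
  m <- s$atoms$mass
  com <- colSums(xyz * m) / sum(m)
  d2 <- rowSums(sweep(xyz, 2L, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe over van der Waals spheres using `n_points` quasi-uniform
#' sphere points per atom (golden-spiral construction; no RNG). Radii come
#' from the structure (PQR radii when parsed from PQR, else the bundled
#' element table). Per-residue values sum to the molecular value exactly.
#'
#' @param s a `ProteinStructure`.
#' @param probe probe radius, angstrom (water: 1.4).
#' @param n_points sphere points per atom (>= 12).
#' @return list with `molecular` (nm^2), `per_residue` (nm^2 vector, one per
#'   residue view) and `per_atom` (nm^2).
#' @export
sasa <- function(s, probe = 1.4, n_points = 960) {
  if (n_points < 12L) stop("n_points must be >= 12")
  xyz <- atom_coords(s)
  r <- s$atoms$radius + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  # neighbor candidates via squared-distance threshold per atom pair
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + r)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    surf <- sweep(pts * r[i], 2L, xyz[i, ], "+")   # n_points x 3
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- rowSums(sweep(surf[acc, , drop = FALSE], 2L, xyz[j, ])^2)
      keep <- dj2 >= r[j]^2
      acc[acc] <- keep
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  per_atom <- area / 100  # A^2 -> nm^2
  per_res <- as.numeric(rowsum(per_atom, group = s$atoms$residue_index))
  list(molecular = sum(per_atom), per_residue = per_res, per_atom = per_atom)
}

#' Reference (model-compound) pKa table for the null model
#'
#' Bundled defaults on the commonly used experimental reference scale; they
#' are this package's configurable choice of scale, exposed so an alternative
#' table can be supplied.
#' @return named numeric vector over the ionizable residue types.
#' @export
null_pka_table <- function() {
  c(ASP = 3.65, GLU = 4.25, HIS = 6.54, LYS = 10.40, TYR = 9.84, CYS = 8.55)
}

#' Null-model pKa
#'
#' The null model assigns every ionizable residue its reference pKa, i.e. a
#' predicted shift of exactly zero.
#' @param residue_type 3-letter code.
#' @param table reference table, default [null_pka_table()].
#' @return the reference pKa.
#' @export
null_pka <- function(residue_type, table = null_pka_table()) {
  if (!(residue_type %in% names(table)))
    stop("not an ionizable residue type: ", residue_type,
         " (ionizable: ", paste(names(table), collapse = ", "), ")")
  unname(table[[residue_type]])
}

#' RMSE of pKa predictions against measured values
#' @param predicted,measured numeric vectors.
#' @return root-mean-square error.
#' @export
pka_rmse <- function(predicted, measured) {
  sqrt(mean((predicted - measured)^2))
}
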