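# Synthetic all-atom protein chains with assignable charges and analytically
# computable stand-in targets. These emulate small proteins (backbone +
# minimal side chains + optional hydrogens) so every downstream stage is
# testable offline; they make no claim of physical realism.

# ideal backbone internal coordinates (angstrom / degrees)
.BB <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530, b_cb_g = 1.520, b_n_h = 1.010, b_ca_ha = 1.090,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_ca_c_o = 120.5,
  a_c_ca_cb = 110.1, a_ca_cb_g = 114.0,
  t_n_c_ca_cb = 122.6, omega = 180
)

# conformation -> (phi, psi) in degrees
.CONF_ANGLES <- list(helix = c(-57, -47), extended = c(180, 180),
                     coil = NULL)

#' Specification for a synthetic structure
#'
#' @param n_residues number of residues (>= 1).
#' @param conformation `"helix"` (phi ~ -57, psi ~ -47), `"extended"`
#'   (phi ~ psi ~ 180) or `"coil"` (phi/psi drawn uniformly).
#' @param jitter_sd Gaussian positional noise sd, angstrom (>= 0).
#' @param seed integer; fully determines the output.
#' @param include_hydrogens attach backbone H/HA atoms.
#' @param sequence optional string of 1-letter residue codes; random over the
#'   20 standard types when absent.
#' @return a `SynthSpec` list.
#' @export
synth_spec <- function(n_residues, conformation = c("helix", "extended", "coil"),
                       jitter_sd = 0, seed = 1L, include_hydrogens = FALSE,
                       sequence = NULL) {
  conformation <- match.arg(conformation)
  if (n_residues < 1L) stop("n_residues must be >= 1")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  structure(list(n_residues = as.integer(n_residues),
                 conformation = conformation, jitter_sd = jitter_sd,
                 seed = as.integer(seed),
                 include_hydrogens = include_hydrogens, sequence = sequence),
            class = "SynthSpec")
}

deg <- function(x) x * pi / 180

# natural-extension-reference-frame placement of D from A-B-C
nerf_place <- function(A, B, C, r, theta_deg, phi_deg) {
  th <- deg(theta_deg); ph <- deg(phi_deg)
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  C + d[1L] * bc + d[2L] * m + d[3L] * n
}

# gamma atom name that carries chi1, per residue type (NULL if none)
gamma_atom_name <- function(rtype) {
  chis <- CHI_ATOMS[[rtype]]
  if (is.null(chis)) return(NULL)
  chis[[1L]][4L]
}

#' Generate a synthetic all-atom structure
#'
#' Backbone built from ideal internal coordinates for the chosen
#' conformation, minimal side chains (CB plus one chi1-bearing atom where
#' the residue type allows), optional backbone hydrogens, then Gaussian
#' positional jitter. Deterministic per seed.
#'
#' @param spec a [synth_spec()].
#' @return a `ProteinStructure` with `source_format = "synthetic"`.
#' @export
generate_structure <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  n <- spec$n_residues
  set.seed(spec$seed)
  seq3 <- if (!is.null(spec$sequence)) {
    one <- strsplit(toupper(spec$sequence), "")[[1L]]
    if (length(one) != n) stop("sequence length != n_residues")
    three <- names(AA_ONE)[match(one, AA_ONE)]
    if (any(is.na(three))) stop("unknown 1-letter code in sequence")
    three
  } else {
    sample(STANDARD_AA, n, replace = TRUE)
  }
  ang <- .CONF_ANGLES[[spec$conformation]]
  phis <- if (is.null(ang)) stats::runif(n, -180, 180) else rep(ang[1L], n)
  psis <- if (is.null(ang)) stats::runif(n, -180, 180) else rep(ang[2L], n)
  chi1s <- stats::runif(n, -180, 180)  # side-chain rotamers always random

  Ns <- CAs <- Cs <- matrix(NA_real_, n, 3L)
  Ns[1L, ] <- c(0, 0, 0)
  CAs[1L, ] <- c(.BB$b_n_ca, 0, 0)
  # first C placed in the xy-plane at the ideal N-CA-C angle
  thet <- deg(.BB$a_n_ca_c)
  Cs[1L, ] <- CAs[1L, ] + .BB$b_ca_c * c(-cos(thet), sin(thet), 0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      Ns[i + 1L, ] <- nerf_place(Ns[i, ], CAs[i, ], Cs[i, ], .BB$b_c_n,
                                 .BB$a_ca_c_n, psis[i])
      CAs[i + 1L, ] <- nerf_place(CAs[i, ], Cs[i, ], Ns[i + 1L, ], .BB$b_n_ca,
                                  .BB$a_c_n_ca, .BB$omega)
      Cs[i + 1L, ] <- nerf_place(Cs[i, ], Ns[i + 1L, ], CAs[i + 1L, ],
                                 .BB$b_ca_c, .BB$a_n_ca_c, phis[i + 1L])
    }
  }

  rows <- list(); serial <- 0L
  add <- function(name, rtype, resno, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      type = "ATOM", eleno = serial, elety = name, alt = "A",
      resid = rtype, chain = "A", resno = resno, insert = "",
      x = xyz[1L], y = xyz[2L], z = xyz[3L], o = NA_real_, b = NA_real_,
      elesy = infer_element(name), stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    rt <- seq3[i]
    add("N", rt, i, Ns[i, ])
    add("CA", rt, i, CAs[i, ])
    add("C", rt, i, Cs[i, ])
    o_tors <- if (i < n) psis[i] + 180 else psis[i] + 180
    add("O", rt, i, nerf_place(Ns[i, ], CAs[i, ], Cs[i, ], .BB$b_c_o,
                               .BB$a_ca_c_o, o_tors))
    if (rt != "GLY") {
      cb <- nerf_place(Cs[i, ], Ns[i, ], CAs[i, ], .BB$b_ca_cb,
                       .BB$a_c_ca_cb, .BB$t_n_c_ca_cb)
      add("CB", rt, i, cb)
      gname <- gamma_atom_name(rt)
      if (!is.null(gname)) {
        add(gname, rt, i, nerf_place(Ns[i, ], CAs[i, ], cb, .BB$b_cb_g,
                                     .BB$a_ca_cb_g, chi1s[i]))
      }
    }
    if (spec$include_hydrogens) {
      add("H", rt, i, nerf_place(Cs[i, ], CAs[i, ], Ns[i, ], .BB$b_n_h,
                                 119, 180))
      add("HA", rt, i, nerf_place(Cs[i, ], Ns[i, ], CAs[i, ], .BB$b_ca_ha,
                                  109, -120))
    }
  }
  at <- do.call(rbind, rows)
  if (spec$jitter_sd > 0) {
    at$x <- at$x + stats::rnorm(nrow(at), sd = spec$jitter_sd)
    at$y <- at$y + stats::rnorm(nrow(at), sd = spec$jitter_sd)
    at$z <- at$z + stats::rnorm(nrow(at), sd = spec$jitter_sd)
  }
  s <- build_structure(at, source_format = "synthetic")
  s$spec <- spec
  s
}

#' Load the bundled simplified partial-charge table
#'
#' A small CHARMM-flavoured (residue type, atom name) -> charge table for the
#' atoms the synthetic builder produces. `"*"` rows apply to any residue type.
#' @return data frame with columns `residue_type`, `atom_name`, `charge`.
#' @export
default_charge_table <- function() {
  path <- system.file("extdata", "partial_charges.tsv", package = "pgnn")
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Assign partial charges from a named charge table
#'
#' Every atom gets a `charge`; atoms absent from the table get 0 with one
#' summary warning.
#'
#' @param s a `ProteinStructure`.
#' @param table data frame (residue_type, atom_name, charge); `"*"` matches
#'   any residue type. Defaults to the bundled table.
#' @return `s` with `atoms$charge` populated.
#' @export
assign_charges <- function(s, table = default_charge_table()) {
  key_exact <- paste(table$residue_type, table$atom_name)
  q <- rep(NA_real_, nrow(s$atoms))
  hit <- match(paste(s$atoms$residue_type, s$atoms$name), key_exact)
  q[!is.na(hit)] <- table$charge[hit[!is.na(hit)]]
  wc <- table$residue_type == "*"
  hit2 <- match(s$atoms$name, table$atom_name[wc])
  fill <- is.na(q) & !is.na(hit2)
  q[fill] <- table$charge[wc][hit2[fill]]
  if (any(is.na(q))) {
    warning(sum(is.na(q)), " atom(s) not in charge table; assigned 0")
    q[is.na(q)] <- 0
  }
  s$atoms$charge <- q
  s
}

# documented proxy constants for the synthetic targets (not reference-software
# values): Stokes-Einstein-like diffusion in water at 298 K and a Born-like
# solvation proxy.
SYNTH_CONST <- c(
  rh_factor = 1.29,      # Rh = 1.29 * Rg                     [dimensionless]
  kappa_t   = 2450,      # Dt = kappa_t / Rh      [nm^2/us * angstrom]
  kappa_r   = 1.84e5,    # Dr = kappa_r / Rh^3    [1/us * angstrom^3]
  born      = 685.6      # dG = -born * sum(q^2) / Rh   [kJ/mol * angstrom]
)

#' Analytic stand-in targets for a synthetic structure
#'
#' Rg is exact (mass-weighted); the other five are documented closed-form
#' proxies so that normalization, masking and training paths are exercised
#' with targets in realistic ranges: Rh = 1.29 Rg; Dt, Dr from
#' Stokes-Einstein-like constants for water at 298 K; V as the sum of atomic
#' sphere volumes; dGsol as a Born-like charge term. When charges are absent
#' the dGsol entry is masked out.
#'
#' @param s a `ProteinStructure`.
#' @return list with `targets` (named 6-vector: dG_sol kJ/mol, Rg angstrom,
#'   Rh angstrom, Dt nm^2/us, Dr 1/us, V nm^3) and `mask` (6 logicals).
#' @export
synth_targets <- function(s) {
  rg <- radius_of_gyration(s)
  rh <- SYNTH_CONST[["rh_factor"]] * rg
  dt <- SYNTH_CONST[["kappa_t"]] / rh
  dr <- SYNTH_CONST[["kappa_r"]] / rh^3
  v <- sum(4 / 3 * pi * s$atoms$radius^3) / 1000
  has_q <- !any(is.na(s$atoms$charge))
  dg <- if (has_q) -SYNTH_CONST[["born"]] * sum(s$atoms$charge^2) / rh else 0
  list(targets = c(dG_sol = dg, Rg = rg, Rh = rh, Dt = dt, Dr = dr, V = v),
       mask = c(dG_sol = has_q, Rg = TRUE, Rh = TRUE, Dt = TRUE, Dr = TRUE,
                V = TRUE))
}

TARGET_NAMES <- c("dG_sol", "Rg", "Rh", "Dt", "Dr", "V")

#' Generate a synthetic training dataset
#'
#' Structures with randomized length, conformation and sequence; a
#' configurable fraction of records drops the dGsol target to mirror partial
#' solvation-energy coverage in realistic corpora.
#'
#' @param n number of structures.
#' @param seed master seed; per-structure seeds derive from it.
#' @param n_residues_range inclusive residue-count range to sample.
#' @param conformations conformations sampled uniformly.
#' @param jitter_sd positional noise, angstrom.
#' @param dg_drop_frac fraction of records whose dGsol is masked out.
#' @param with_charges assign the bundled charge table.
#' @return list with `structures`, `targets` (n x 6 matrix), `mask`
#'   (n x 6 logical), `ids`.
#' @export
generate_dataset <- function(n, seed = 1L, n_residues_range = c(12L, 32L),
                             conformations = c("helix", "extended", "coil"),
                             jitter_sd = 0.3, dg_drop_frac = 0.2,
                             with_charges = TRUE) {
  set.seed(seed)
  lens <- sample(seq(n_residues_range[1L], n_residues_range[2L]), n,
                 replace = TRUE)
  confs <- sample(conformations, n, replace = TRUE)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  drop_dg <- stats::runif(n) < dg_drop_frac
  structures <- vector("list", n)
  targets <- matrix(NA_real_, n, 6L, dimnames = list(NULL, TARGET_NAMES))
  mask <- matrix(TRUE, n, 6L, dimnames = list(NULL, TARGET_NAMES))
  for (i in seq_len(n)) {
    sp <- synth_spec(lens[i], confs[i], jitter_sd = jitter_sd,
                     seed = seeds[i])
    s <- generate_structure(sp)
    if (with_charges) s <- suppressWarnings(assign_charges(s))
    tt <- synth_targets(s)
    targets[i, ] <- tt$targets
    mask[i, ] <- tt$mask
    if (drop_dg[i]) mask[i, "dG_sol"] <- FALSE
    structures[[i]] <- s
  }
  list(structures = structures, targets = targets, mask = mask,
       ids = sprintf("synth%04d", seq_len(n)))
}

#' Write a generated dataset to disk
#'
#' One PDB per structure plus a delimited targets table (id, six targets,
#' six mask flags).
#' @param ds result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the targets table path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ds$structures)) {
    write_structure(ds$structures[[i]], file.path(dir, paste0(ds$ids[i], ".pdb")))
  }
  tab <- data.frame(id = ds$ids, ds$targets,
                    stats::setNames(as.data.frame(ds$mask),
                                    paste0("has_", TARGET_NAMES)))
  path <- file.path(dir, "targets.tsv")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
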