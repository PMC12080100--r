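# End-to-end prediction pipelines: global properties with denormalization,
# per-residue SASA, per-residue pKa with null-model reconstruction and
# ensemble averaging.

GLOBAL_UNITS <- c(dG_sol = "kJ/mol", Rg = "angstrom", Rh = "angstrom",
                  Dt = "nm^2/us", Dr = "1/us", V = "nm^3")

#' Predict global molecular properties for one structure
#'
#' Featurizes the structure, runs the network and inverts the training-set
#' normalization, so reported values are on physical scales with units
#' attached.
#'
#' @param s a `ProteinStructure`.
#' @param model a `pgnn_model` with `head_spec` `"global6"` or `"global1"`
#'   and fitted `norm_stats`.
#' @return a `PredictionReport` data frame: target, value, unit.
#' @export
predict_global <- function(s, model) {
  if (!model$config$head_spec %in% c("global6", "global1"))
    stop("model head is not a global head")
  if (is.null(model$norm_stats))
    stop("model carries no normalization statistics; predictions would be ",
         "on the normalized scale")
  g <- build_residue_graph(s)
  z <- predict_raw(model, g)
  vals <- invert_normalization(z, model$norm_stats)[1L, ]
  nm <- if (model$config$out_dim == 6L) TARGET_NAMES else
    (if (!is.null(model$target_name)) model$target_name else "target")
  data.frame(target = nm, value = as.numeric(vals),
             unit = unname(GLOBAL_UNITS[match(nm, names(GLOBAL_UNITS))]),
             stringsAsFactors = FALSE)
}

#' Predict per-residue SASA for one structure
#'
#' @param s a `ProteinStructure`.
#' @param model a `pgnn_model` with `head_spec = "residue1"` and fitted
#'   `norm_stats`.
#' @return data frame: residue_index, residue_type, rsasa (nm^2).
#' @export
predict_residue_sasa <- function(s, model) {
  if (model$config$head_spec != "residue1")
    stop("model head is not a per-residue head")
  g <- build_residue_graph(s)
  n <- n_residues(s)
  # one forward per structure; every residue is read out from the same
  # final node states
  fp <- forward_pass(model, g, residues = 0L)
  preds <- numeric(n)
  h <- fp$node_state
  for (i in seq_len(n)) {
    feats <- readout(h, g, model$config, residues = i - 1L)
    preds[i] <- ad_value(head_forward(feats, fp$wp$head, model$config))[1L]
  }
  vals <- if (!is.null(model$norm_stats))
    as.numeric(invert_normalization(matrix(preds), model$norm_stats))
  else preds
  data.frame(residue_index = seq_len(n) - 1L,
             residue_type = s$residues$residue_type, rsasa = vals,
             stringsAsFactors = FALSE)
}

ionizable_residues <- function(s, table = null_pka_table()) {
  which(s$residues$residue_type %in% names(table)) - 1L
}

#' Predict per-residue pKa values
#'
#' Per structure, the network predicts the shift from the null-model
#' (reference) pKa and the reported pKa is `null + shift`; models trained in
#' absolute space (`model$target_space == "absolute"`) report the network
#' output directly and derive the shift. Over a conformational ensemble the
#' per-residue arithmetic mean of the predictions is reported. Shift, null
#' and pKa columns are always emitted so the convention is unambiguous.
#'
#' @param structures a `ProteinStructure` or list of them (an ensemble of
#'   conformers of the same chain).
#' @param model a `pgnn_model` with a pKa head (`"pka_gsnet"` on residue
#'   graphs or `"pka_alcnet"` on atom graphs).
#' @param residues residue indices (0-based) to predict; default all
#'   ionizable residues.
#' @param table null-model reference table.
#' @return data frame: residue_index, residue_type, shift, null, pka,
#'   n_conformers.
#' @export
predict_pka <- function(structures, model, residues = NULL,
                        table = null_pka_table()) {
  if (!model$config$head_spec %in% c("pka_gsnet", "pka_alcnet"))
    stop("model head is not a pKa head")
  if (inherits(structures, "ProteinStructure")) structures <- list(structures)
  s1 <- structures[[1L]]
  if (is.null(residues)) residues <- ionizable_residues(s1, table)
  rtypes <- s1$residues$residue_type[residues + 1L]
  bad <- !(rtypes %in% names(table))
  if (any(bad))
    stop("non-ionizable residue(s) requested: ",
         paste(unique(rtypes[bad]), collapse = ", "),
         " (valid types: ", paste(names(table), collapse = ", "), ")")
  absolute <- identical(model$target_space, "absolute")
  acc <- matrix(0, length(residues), length(structures))
  local_head <- model$config$head_spec == "pka_alcnet"
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    gres <- if (!local_head) build_residue_graph(s) else NULL
    for (j in seq_along(residues)) {
      i <- residues[j]
      g <- if (local_head) build_atom_graph(s, i) else gres
      z <- predict_raw(model, g, residues = i)[1L]
      if (!is.null(model$norm_stats))
        z <- invert_normalization(matrix(z), model$norm_stats)[1L]
      acc[j, k] <- z
    }
  }
  out <- rowMeans(acc)
  nulls <- vapply(rtypes, null_pka, numeric(1L), table = table)
  shift <- if (absolute) out - nulls else out
  pka <- if (absolute) out else nulls + out
  data.frame(residue_index = residues, residue_type = rtypes,
             shift = shift, null = unname(nulls), pka = pka,
             n_conformers = length(structures), stringsAsFactors = FALSE)
}
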