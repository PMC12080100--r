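# Shared fixtures: all built in code at test time.

# small structures by construction
fix_structure <- function(n = 8L, conf = "coil", seed = 7L, jitter = 0.2,
                          charges = TRUE, hydrogens = FALSE) {
  s <- generate_structure(synth_spec(n, conf, jitter_sd = jitter, seed = seed,
                                     include_hydrogens = hydrogens))
  if (charges) s <- suppressWarnings(assign_charges(s))
  s
}

# a hand-built two-atom structure (two GLY residues, CA only) a given
# distance apart; equal masses
fix_two_point_structure <- function(d = 2) {
  at <- data.frame(
    type = "ATOM", eleno = 1:2, elety = "CA", alt = "A",
    resid = "GLY", chain = "A", resno = 1:2, insert = "",
    x = c(0, d), y = 0, z = 0, o = NA_real_, b = NA_real_, elesy = "C",
    stringsAsFactors = FALSE)
  pgnn:::build_structure(at, source_format = "synthetic")
}

# CA-only structure from explicit coordinates (one GLY per row)
fix_ca_structure <- function(coords) {
  n <- nrow(coords)
  at <- data.frame(
    type = "ATOM", eleno = seq_len(n), elety = "CA", alt = "A",
    resid = "GLY", chain = "A", resno = seq_len(n), insert = "",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    o = NA_real_, b = NA_real_, elesy = "C", stringsAsFactors = FALSE)
  pgnn:::build_structure(at, source_format = "synthetic")
}

# reduced-size model configs so unit tests stay fast; full-size networks are
# exercised in the acceptance suite
small_gsnet_config <- function(head_spec = "global6", ...) {
  model_config("gsnet", head_spec, node_dim = 30L, n_layers = 2L,
               n_heads = 3L, head_hidden = 16L, ...)
}
small_alcnet_config <- function(head_spec = "pka_alcnet", ...) {
  model_config("alcnet", head_spec, node_dim = 24L, n_layers = 2L,
               n_heads = 2L, head_hidden = 16L, ...)
}

# independent four-point dihedral oracle (plain cross/dot + atan2, written
# against the textbook definition rather than the package implementation)
oracle_dihedral <- function(p1, p2, p3, p4) {
  u1 <- p2 - p1; u2 <- p3 - p2; u3 <- p4 - p3
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(u1, u2); n2 <- cx(u2, u3)
  atan2(sum(cx(n1, n2) * u2 / sqrt(sum(u2^2))), sum(n1 * n2))
}

# independent ends-free Needleman-Wunsch identity oracle: affine gaps
# (open 10, extend 0.5), match +1, mismatch 0, free end gaps; identity =
# matches / alignment length including gap and overhang columns. Textbook
# three-matrix DP with explicit traceback.
oracle_identity <- function(a, b, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1L, m + 1L)
  PM <- PX <- PY <- matrix(0L, n + 1L, m + 1L)  # traceback: 1=M, 2=Ix, 3=Iy
  M[1L, 1L] <- 0
  M[1L, ] <- 0; M[, 1L] <- 0  # free end gaps (overhangs outside alignment)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (A[i] == B[j]) 1 else 0
      cand <- c(M[i, j], Ix[i, j], Iy[i, j])
      w <- which.max(cand)
      M[i + 1L, j + 1L] <- cand[w] + sc; PM[i + 1L, j + 1L] <- w
      cx <- c(M[i, j + 1L] - open, Ix[i, j + 1L] - ext)
      wx <- which.max(cx)
      Ix[i + 1L, j + 1L] <- cx[wx]; PX[i + 1L, j + 1L] <- c(1L, 2L)[wx]
      cy <- c(M[i + 1L, j] - open, Iy[i + 1L, j] - ext)
      wy <- which.max(cy)
      Iy[i + 1L, j + 1L] <- cy[wy]; PY[i + 1L, j + 1L] <- c(1L, 3L)[wy]
    }
  }
  # best end on the last row or column (free end gaps), M state only since
  # trailing gap columns are overhangs
  ends <- rbind(cbind(n + 1L, seq_len(m + 1L)), cbind(seq_len(n + 1L), m + 1L))
  scores <- M[ends]
  best <- which.max(scores)
  i <- ends[best, 1L]; j <- ends[best, 2L]
  end_over <- max(n + 1L - i, m + 1L - j)
  state <- 1L
  matches <- 0L; cols <- 0L
  while (i > 1L && j > 1L) {
    if (state == 1L) {
      if (M[i, j] == 0 && (i == 1L || j == 1L)) break
      matches <- matches + (A[i - 1L] == B[j - 1L])
      cols <- cols + 1L
      state <- PM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      cols <- cols + 1L
      state <- PX[i, j]; i <- i - 1L
    } else {
      cols <- cols + 1L
      state <- PY[i, j]; j <- j - 1L
    }
  }
  start_over <- max(i - 1L, j - 1L)
  matches / (cols + start_over + end_over)
}

# toy pKa record set (20 records) with exactly two planted cross-set similar
# pairs: TE01 <-> TR01 (same sequence, column 3, ASP) and TE02 <-> TR02
# (near-identical homologue, column 4, GLU). All other records differ in
# cluster, column or residue type.
fix_pka_toy <- function() {
  base <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 3L), collapse = "")  # 60-mer
  mut <- function(s, at, to) {
    v <- strsplit(s, "")[[1L]]; v[at] <- to; paste(v, collapse = "")
  }
  seq_a <- base                      # family A
  seq_a2 <- mut(base, 5L, "W")       # near-identical homologue of A
  seq_b <- paste(rep("YVTSRQPNMLKIHGFEDCA", 3L), collapse = "")  # family B
  seq_c <- local({
    set.seed(1234)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                 55L, replace = TRUE), collapse = "")
  })
  train <- pka_records(
    structure_id = sprintf("TR%02d", 1:10),
    chain = "A",
    residue_number = c(3, 4, 9, 16, 21, 21, 4, 23, 35, 42),
    residue_type = c("ASP", "GLU", "LYS", "TYR", "ASP", "ASP", "GLU", "HIS",
                     "CYS", "GLU"),
    pka = seq(3, 7.5, by = 0.5),
    sequence = c(seq_a, seq_a2, seq_a, seq_a, seq_a2, seq_b, seq_b, seq_b,
                 seq_b, seq_c))
  test <- pka_records(
    structure_id = sprintf("TE%02d", 1:10),
    chain = "A",
    residue_number = c(3, 4, 10, 17, 22, 30, 40, 8, 12, 50),
    residue_type = c("ASP", "GLU", "HIS", "GLU", "LYS", "TYR", "CYS", "GLU",
                     "ASP", "HIS"),
    pka = seq(3.2, 7.7, by = 0.5),
    sequence = c(seq_a, seq_a2, seq_c, seq_c, seq_c, seq_c, seq_c, seq_c,
                 seq_c, seq_c))
  list(train = train, test = test)
}
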