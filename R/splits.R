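# Leakage-aware splitting of residue-level pKa data: pairwise sequence
# identity, greedy identity clustering with alignment-column maps against
# each cluster representative, the three-condition similarity predicate
# (same cluster AND same alignment column AND same residue type), and
# train/validation/test construction with an auditable verification pass.

aa_identity_matrix <- function() {
  alph <- Biostrings::AA_ALPHABET
  m <- matrix(0, length(alph), length(alph), dimnames = list(alph, alph))
  diag(m) <- 1
  m
}

align_pair <- function(a, b) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "overlap",
    substitutionMatrix = aa_identity_matrix(),
    gapOpening = 10, gapExtension = 0.5)
}

#' Pairwise sequence identity
#'
#' Ends-free global alignment (match +1, mismatch 0, affine gaps open 10 /
#' extend 0.5); identity is the number of identical aligned positions
#' divided by the alignment length including gaps.
#'
#' @param a,b amino-acid sequences (1-letter strings).
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- align_pair(a, b)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  # extend the aligned region by the unaligned overhangs (ends-free columns)
  ps <- strsplit(pat, "")[[1L]]
  ss <- strsplit(sub, "")[[1L]]
  matches <- sum(ps == ss & ps != "-")
  start_over <- max(Biostrings::start(Biostrings::pattern(aln)) - 1L,
                    Biostrings::start(Biostrings::subject(aln)) - 1L)
  end_over <- max(nchar(a) - Biostrings::end(Biostrings::pattern(aln)),
                  nchar(b) - Biostrings::end(Biostrings::subject(aln)))
  matches / (length(ps) + start_over + end_over)
}

# map each position of `member` to a column of `rep_seq` (its ungapped
# position), NA where the member position aligns into a representative gap
# or outside the aligned region
column_map <- function(member, rep_seq) {
  if (identical(member, rep_seq)) return(seq_len(nchar(member)))
  aln <- align_pair(member, rep_seq)
  ps <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  ss <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  p_pos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  s_pos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  map <- rep(NA_integer_, nchar(member))
  for (k in seq_along(ps)) {
    if (ps[k] != "-") p_pos <- p_pos + 1L
    if (ss[k] != "-") s_pos <- s_pos + 1L
    if (ps[k] != "-" && ss[k] != "-") map[p_pos] <- s_pos
  }
  map
}

#' Greedy sequence-identity clustering
#'
#' Longest-first greedy clustering: each sequence joins the first existing
#' cluster whose representative it matches at identity > `threshold`, else
#' founds a new cluster. Alignment-column maps are computed against the
#' representative. (In-repo analogue of external identity-clustering tools;
#' behavioral parity with them is not claimed.)
#'
#' @param seqs named character vector of sequences (names are sequence ids).
#' @param threshold identity threshold (default 0.5).
#' @return `ClusterAssignment`: list with `cluster_id` (named integer),
#'   `representative` (per cluster), `column_maps` (per sequence).
#' @export
cluster_sequences <- function(seqs, threshold = 0.5) {
  stopifnot(length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  reps <- character(0)
  cluster_id <- stats::setNames(integer(length(seqs)), names(seqs))
  column_maps <- stats::setNames(vector("list", length(seqs)), names(seqs))
  for (i in ord) {
    s <- seqs[[i]]
    assigned <- 0L
    for (cl in seq_along(reps)) {
      if (pairwise_identity(s, reps[cl]) > threshold) { assigned <- cl; break }
    }
    if (assigned == 0L) {
      reps <- c(reps, s)
      assigned <- length(reps)
    }
    cluster_id[names(seqs)[i]] <- assigned
    column_maps[[names(seqs)[i]]] <- column_map(s, reps[assigned])
  }
  structure(list(cluster_id = cluster_id, representative = reps,
                 column_maps = column_maps, threshold = threshold),
            class = "ClusterAssignment")
}

#' Construct a pKa record table
#'
#' @param structure_id,chain,residue_number,residue_type,pka,sequence
#'   vectors of equal length; `residue_number` is the 1-based position in
#'   `sequence` (author numbering already resolved), `sequence` the parent
#'   chain sequence in 1-letter code.
#' @return data frame of `PkaRecord`s with a `seq_id` key.
#' @export
pka_records <- function(structure_id, chain, residue_number, residue_type,
                        pka, sequence) {
  ok <- residue_type %in% names(null_pka_table())
  if (!all(ok)) stop("non-ionizable residue type in records: ",
                     paste(unique(residue_type[!ok]), collapse = ", "))
  data.frame(structure_id = structure_id, chain = chain,
             residue_number = as.integer(residue_number),
             residue_type = residue_type, pka = pka, sequence = sequence,
             seq_id = paste0(structure_id, "_", chain),
             stringsAsFactors = FALSE)
}

record_column <- function(rec, clusters) {
  cm <- clusters$column_maps[[rec$seq_id]]
  if (is.null(cm) || rec$residue_number < 1L ||
      rec$residue_number > length(cm)) return(NA_integer_)
  cm[rec$residue_number]
}

#' Similarity predicate between two pKa records
#'
#' True iff all three conditions hold: the parent sequences are in the same
#' identity cluster, the residues fall in the same alignment column (via the
#' cluster representative's column map), and the residues are of the same
#' amino-acid type. A record whose residue does not map to a column is
#' treated as dissimilar (with a warning).
#'
#' @param x,y single-row `PkaRecord` data frames.
#' @param clusters a [cluster_sequences()] result covering both sequences.
#' @return logical flag.
#' @export
is_similar <- function(x, y, clusters) {
  cx <- clusters$cluster_id[[x$seq_id]]
  cy <- clusters$cluster_id[[y$seq_id]]
  if (is.na(cx) || is.na(cy) || cx != cy) return(FALSE)
  if (x$residue_type != y$residue_type) return(FALSE)
  colx <- record_column(x, clusters)
  coly <- record_column(y, clusters)
  if (is.na(colx) || is.na(coly)) {
    warning("record residue does not map to an alignment column; ",
            "treated as dissimilar")
    return(FALSE)
  }
  colx == coly
}

# all similar pairs between (or within) record tables; O(n m) exhaustive
similar_pairs <- function(a, b = NULL, clusters) {
  within <- is.null(b)
  if (within) b <- a
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    jmax <- if (within) i - 1L else nrow(b)
    for (j in seq_len(max(jmax, 0L))) {
      if (is_similar(a[i, ], b[j, ], clusters))
        pairs[[length(pairs) + 1L]] <- c(i = i, j = j)
    }
  }
  if (length(pairs)) do.call(rbind, pairs) else matrix(integer(0), 0L, 2L,
                                                       dimnames = list(NULL, c("i", "j")))
}

#' Leakage-aware train/validation/test split of pKa records
#'
#' Training and validation are drawn at approximately `ratio` : (1-ratio)
#' from `records`. Training may keep internally similar points; the
#' validation set is deduplicated internally and purged of any record
#' similar to a training record. The test set is built from the disjoint
#' `test_source` with internal dedup and removal of records similar to any
#' train or validation record (first-seen kept everywhere). A verification
#' pass re-runs the exhaustive predicate across train x test and reports
#' every similar pair found before removal.
#'
#' @param records `PkaRecord` data frame.
#' @param ratio training fraction (default 0.9).
#' @param test_source optional disjoint `PkaRecord` data frame.
#' @param clusters optional precomputed [cluster_sequences()] over all
#'   sequences involved; computed here when `NULL`.
#' @param seed split RNG seed.
#' @return list with `train`, `validation`, `test`, `clusters`, and `audit`
#'   (counts and pair lists removed at each stage plus the final train x
#'   test verification).
#' @export
split_dataset <- function(records, ratio = 0.9, test_source = NULL,
                          clusters = NULL, seed = 1L) {
  all_seqs <- c(stats::setNames(records$sequence, records$seq_id),
                if (!is.null(test_source))
                  stats::setNames(test_source$sequence, test_source$seq_id))
  all_seqs <- all_seqs[!duplicated(names(all_seqs))]
  if (is.null(clusters)) clusters <- cluster_sequences(all_seqs)

  set.seed(seed)
  n <- nrow(records)
  idx_train <- sort(sample.int(n, round(ratio * n)))
  train <- records[idx_train, , drop = FALSE]
  val <- records[setdiff(seq_len(n), idx_train), , drop = FALSE]

  audit <- list()
  # internal dedup of validation (first-seen kept)
  pw <- similar_pairs(val, clusters = clusters)
  drop_v <- unique(pw[, "i"][pw[, "i"] > pw[, "j"]])
  audit$validation_internal_pairs <- pw
  if (length(drop_v)) val <- val[-drop_v, , drop = FALSE]
  # purge validation records similar to any training record
  pv <- similar_pairs(val, train, clusters)
  audit$validation_vs_train_pairs <- pv
  if (nrow(pv)) val <- val[-unique(pv[, "i"]), , drop = FALSE]

  test <- NULL
  if (!is.null(test_source)) {
    test <- test_source
    pt <- similar_pairs(test, clusters = clusters)
    drop_t <- unique(pt[, "i"][pt[, "i"] > pt[, "j"]])
    audit$test_internal_pairs <- pt
    if (length(drop_t)) test <- test[-drop_t, , drop = FALSE]
    tv <- similar_pairs(test, rbind(train, val), clusters)
    audit$test_vs_trainval_pairs <- tv
    if (nrow(tv)) test <- test[-unique(tv[, "i"]), , drop = FALSE]
    # verification: the train x test predicate scan must come back empty
    audit$verify_train_test <- similar_pairs(test, train, clusters)
    if (nrow(audit$verify_train_test) > 0L)
      stop("leakage verification failed: similar train/test pairs remain")
  }
  audit$counts <- c(train = nrow(train), validation = nrow(val),
                    test = if (is.null(test)) NA_integer_ else nrow(test))
  list(train = train, validation = val, test = test, clusters = clusters,
       audit = audit)
}
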