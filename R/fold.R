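#' Sanitize an RNA sequence
#'
#' Uppercases, converts DNA `T` to `U`, and rejects anything outside
#' `{A, C, G, U}`.
#'
#' @param x Character vector of sequences.
#' @return Character vector over the strict RNA alphabet.
#' @export
sanitize_rna <- function(x) {
  x <- chartr("T", "U", toupper(as.character(x)))
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("invalid symbols in RNA sequence(s): ",
         paste(head(unique(unlist(strsplit(gsub("[ACGU]", "", x[bad]), ""))), 5),
               collapse = ", "))
  }
  x
}

.vienna_available <- function() nzchar(Sys.which("RNAfold"))

.vienna_fold_mfe <- function(seqs) {
  if (!.vienna_available()) stop("RNAfold not found on PATH; use engine = 'builtin'")
  out <- system2("RNAfold", c("--noPS"), input = seqs, stdout = TRUE)
  # output alternates sequence / "structure ( energy )" lines
  db <- out[seq(2, length(out), by = 2)]
  sub("^([.()]+).*$", "\\1", db)
}

.vienna_pair_probabilities <- function(seq) {
  if (!nzchar(Sys.which("python"))) stop("python not found on PATH")
  script <- paste(
    "import sys, RNA",
    "seq = sys.argv[1]",
    "fc = RNA.fold_compound(seq)",
    "fc.pf()",
    "bpp = fc.bpp()",
    "n = len(seq)",
    "for i in range(1, n + 1):",
    "    for j in range(i + 1, n + 1):",
    "        p = bpp[i][j]",
    "        if p > 0:",
    "            print(i, j, p)",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(seq)), stdout = TRUE)
  n <- nchar(seq)
  m <- matrix(0, n, n)
  if (length(out)) {
    parts <- do.call(rbind, strsplit(out, " "))
    i <- as.integer(parts[, 1]); j <- as.integer(parts[, 2]); p <- as.numeric(parts[, 3])
    m[cbind(i, j)] <- p
    m[cbind(j, i)] <- p
  }
  m
}

#' Fold RNA sequences into minimum-free-energy structures
#'
#' Returns one dot-bracket structure per sequence: `.` unpaired, matched
#' `(`/`)` paired. The builtin engine is a nearest-neighbor Zuker-style
#' dynamic program with a minimum hairpin loop of 3; sequences with no
#' stabilizing structure fold to all dots. The `"vienna"` engine shells out
#' to `RNAfold` when ViennaRNA is installed.
#'
#' @param seqs Character vector of RNA sequences (or a pool tibble with a
#'   `seq` column).
#' @param engine `"builtin"` (default) or `"vienna"`.
#' @return Character vector of dot-bracket strings.
#' @export
#' @examples
#' fold_mfe("GGAGUCCAACUCC")
fold_mfe <- function(seqs, engine = c("builtin", "vienna")) {
  engine <- match.arg(engine)
  if (is.data.frame(seqs)) seqs <- seqs$seq
  seqs <- sanitize_rna(seqs)
  if (engine == "vienna") .vienna_fold_mfe(seqs) else .fold_mfe_batch(seqs)
}

#' Base-pair probability matrix from the partition function
#'
#' McCaskill-style equilibrium probabilities that bases `i` and `j` pair,
#' over all pseudoknot-free secondary structures of the sequence. The matrix
#' is symmetric, entries lie in `[0, 1]`, rows sum to at most 1, and entries
#' are zero for non-canonical pairs or hairpin loops shorter than 3.
#'
#' @param seq A single RNA sequence.
#' @param engine `"builtin"` (default) or `"vienna"`.
#' @return An `n x n` numeric matrix.
#' @export
pair_probabilities <- function(seq, engine = c("builtin", "vienna")) {
  engine <- match.arg(engine)
  seq <- sanitize_rna(seq)
  stopifnot(length(seq) == 1)
  if (nchar(seq) > 250) {
    stop("sequence too long for global folding; use windowed_distance4_profile()")
  }
  if (engine == "vienna") .vienna_pair_probabilities(seq) else .pair_prob_cpp(seq, 0L)
}

#' Distance-4 pairing profile
#'
#' Extracts `v[i] = p[i, i + 4]` from a base-pair probability matrix: the
#' probability that position `i` pairs with the base exactly four positions
#' downstream, i.e. that `i` is the 5' closing base (stem position -1) of a
#' tri-loop hairpin.
#'
#' @param m A base-pair probability matrix (see [pair_probabilities()]).
#' @return Numeric vector of length `n - 4` (empty when `n < 5`).
#' @export
distance4_profile <- function(m) {
  n <- nrow(m)
  if (is.null(n) || n < 5) return(numeric(0))
  m[cbind(seq_len(n - 4), seq_len(n - 4) + 4L)]
}

#' Distance-4 profiles for a batch of short sequences
#'
#' Equivalent to `distance4_profile(pair_probabilities(seq))` per sequence,
#' computed in one pass in compiled code.
#'
#' @param seqs Character vector of RNA sequences (or a pool tibble).
#' @return A list of numeric vectors, one per sequence.
#' @export
distance4_profiles <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  .dist4_batch_cpp(sanitize_rna(seqs))
}

#' Sliding-window distance-4 pairing profile for long sequences
#'
#' Folds overlapping windows of the sequence with the partition function and
#' averages, per position, the probability of pairing at distance exactly
#' four over all windows that contain the pair -- the local-folding approach
#' used for transcript-length RNA. For sequences no longer than the window
#' this equals the global [distance4_profile()].
#'
#' @param seq A single RNA sequence.
#' @param window Window length in nt (default 70).
#' @param span Maximum base-pair span within a window (default = `window`).
#' @param step Offset between successive windows (default 1 = every window).
#' @return Numeric vector of length `n - 4`.
#' @export
windowed_distance4_profile <- function(seq, window = 70L, span = window, step = 1L) {
  seq <- sanitize_rna(seq)
  stopifnot(length(seq) == 1, span >= 5, span <= window)
  .windowed_dist4_cpp(seq, as.integer(window), as.integer(span), as.integer(step))
}
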