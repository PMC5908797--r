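#' Extract overlapping k-mers from a string
#'
#' @param s A single string (sequence or dot-bracket).
#' @param k Window length, `k >= 1`.
#' @return Character vector of the `max(0, nchar(s) - k + 1)` windows, left
#'   to right.
#' @export
extract_kmers <- function(s, k) {
  stopifnot(length(s) == 1, k >= 1)
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
}

#' Can a dot-bracket k-mer occur inside a valid secondary structure?
#'
#' A window over `{., (, )}` is embeddable iff it contains none of the
#' substrings `"()"`, `"(.)"`, `"(..)"` -- i.e. no bracket match within the
#' window forces a hairpin loop of fewer than 3 unpaired bases. Brackets
#' left unmatched inside the window are fine (their partners may lie outside
#' it).
#'
#' @param kmer Character vector of dot-bracket strings.
#' @return Logical vector.
#' @export
is_embeddable <- function(kmer) {
  if (any(grepl("[^.()]", kmer))) stop("dot-bracket alphabet is {., (, )}")
  !(grepl("()", kmer, fixed = TRUE) |
      grepl("(.)", kmer, fixed = TRUE) |
      grepl("(..)", kmer, fixed = TRUE))
}

#' Enumerate all embeddable dot-bracket k-mers
#'
#' Generates all `3^k` strings over `{., (, )}` and keeps those passing
#' [is_embeddable()].
#'
#' @param k Window length, at most 12 (the enumeration is `3^k`).
#' @return Character vector of embeddable k-mers, sorted.
#' @export
enumerate_embeddable <- function(k) {
  stopifnot(k >= 1)
  if (k > 12) stop("k > 12: 3^k enumeration refused")
  grid <- do.call(expand.grid, c(rep(list(c(".", "(", ")")), k),
                                 stringsAsFactors = FALSE))
  all <- do.call(paste0, grid)
  sort(all[is_embeddable(all)])
}

.kmer_alphabet <- function(pool) {
  chars <- unique(strsplit(paste(pool, collapse = ""), "")[[1]])
  seq_al <- all(chars %in% c("A", "C", "G", "U"))
  db_al <- all(chars %in% c(".", "(", ")"))
  if (!seq_al && !db_al) stop("pool mixes sequence and dot-bracket alphabets")
  if (seq_al) "sequence" else "dotbracket"
}

#' Count k-mer occurrences over a pool of strings
#'
#' Exact overlapping substring counts; the pool must be uniformly either
#' RNA sequence or dot-bracket strings. The count total over a pool of `m`
#' strings of lengths `L_i` is `sum(L_i - k + 1)`.
#'
#' @param pool Character vector of strings (or a pool tibble with `seq`).
#' @param k Window length.
#' @return A tibble with columns `kmer` and `count`, sorted by `kmer`, with
#'   attribute `total`.
#' @export
count_kmers <- function(pool, k) {
  if (is.data.frame(pool)) pool <- pool$seq
  if (length(pool) == 0) {
    out <- tibble(kmer = character(0), count = integer(0))
    attr(out, "total") <- 0L
    return(out)
  }
  .kmer_alphabet(pool)
  windows <- unlist(lapply(pool, extract_kmers, k = k), use.names = FALSE)
  tab <- table(windows)
  out <- tibble(kmer = names(tab), count = as.integer(tab)) %>%
    dplyr::arrange(.data$kmer)
  attr(out, "total") <- length(windows)
  out
}

#' Hairpin loop sizes in a dot-bracket string
#'
#' Matches brackets with a left-to-right stack (unmatched brackets in a
#' window are ignored) and, for every matched pair whose interior is all
#' dots, reports the number of enclosed dots.
#'
#' @param s A single dot-bracket string.
#' @return Integer vector of loop sizes (possibly empty), 5' to 3'.
#' @export
hairpin_loop_sizes <- function(s) {
  stopifnot(length(s) == 1)
  if (grepl("[^.()]", s)) stop("dot-bracket alphabet is {., (, )}")
  chars <- strsplit(s, "")[[1]]
  open <- integer(0)
  sizes <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      open <- c(open, i)
    } else if (chars[i] == ")") {
      if (length(open)) {
        j <- open[length(open)]
        open <- open[-length(open)]
        interior <- chars[seq(j + 1, length.out = i - j - 1)]
        if (all(interior == ".")) sizes <- c(sizes, i - j - 1L)
      }
    }
  }
  sizes
}

#' Loop-size class of a structure k-mer
#'
#' Classifies a dot-bracket window by the hairpin loop it contains:
#' `"3"`, `"4"`, `"5"`, `"6"` for a single complete loop of that size,
#' `"other/none"` otherwise.
#'
#' @param kmers Character vector of dot-bracket strings.
#' @return Character vector of classes.
#' @export
loop_size_class <- function(kmers) {
  vapply(kmers, function(s) {
    sizes <- hairpin_loop_sizes(s)
    if (length(sizes) == 1 && sizes >= 3 && sizes <= 6) as.character(sizes) else "other/none"
  }, character(1), USE.NAMES = FALSE)
}
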