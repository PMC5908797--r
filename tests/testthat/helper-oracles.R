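# Independent oracles used against the package's implementations.

# nested-loop substring counter (no vectorized tricks shared with count_kmers)
brute_count_kmers <- function(pool, k) {
  counts <- new.env(parent = emptyenv())
  for (s in pool) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      km <- substr(s, i, i + k - 1)
      counts[[km]] <- (if (is.null(counts[[km]])) 0L else counts[[km]]) + 1L
    }
  }
  km <- sort(ls(counts))
  tibble::tibble(kmer = km,
                 count = vapply(km, function(x) counts[[x]], integer(1),
                                USE.NAMES = FALSE))
}

# stack-simulation embeddability: no stack-matched pair may enclose an
# all-dot interior of fewer than 3 dots
stack_embeddable <- function(s) {
  chars <- strsplit(s, "")[[1]]
  open <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") open <- c(open, i)
    else if (chars[i] == ")") {
      if (length(open)) {
        j <- open[length(open)]
        open <- open[-length(open)]
        interior <- chars[seq(j + 1, length.out = i - j - 1)]
        if (all(interior == ".") && length(interior) < 3) return(FALSE)
      }
    }
  }
  TRUE
}

# rank-mean quantile normalization written independently (no tie handling;
# use on tie-free columns only)
rank_mean_qn <- function(m) {
  sorted_mean <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) sorted_mean[rank(col)])
}

# pair set of a dot-bracket string, as an i<j matrix
pair_set <- function(db) {
  chars <- strsplit(db, "")[[1]]
  open <- integer(0); out <- NULL
  for (i in seq_along(chars)) {
    if (chars[i] == "(") open <- c(open, i)
    else if (chars[i] == ")") {
      j <- open[length(open)]
      open <- open[-length(open)]
      out <- rbind(out, c(j, i))
    }
  }
  out[order(out[, 1]), , drop = FALSE]
}

# a transcript-style perfect planted hairpin in an unstructured background
perfect_hairpin_fixture <- function(triplet = "AAA", pair = "UA") {
  paste0("ACACAACC", "GCGGCA", substr(pair, 1, 1), triplet, substr(pair, 2, 2),
         "UGCCGC", "CCAAACAC")
}
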