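# Shared fixtures (built once per test run) and independent oracles.

fx_elements <- build_default_elements()
fx_subtypes <- canonical_mping_subtypes(fx_elements)

# Brute-force ungapped placement oracle: scan every offset on both strands
# and return the best mismatch count placements.
brute_align <- function(read, target, max_mm = 2L) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") read else rc
    L <- nchar(target); n <- nchar(s)
    if (n > L) next
    sv <- strsplit(s, "")[[1]]
    tv <- strsplit(target, "")[[1]]
    for (st in 1:(L - n + 1)) {
      mm <- sum(sv != tv[st:(st + n - 1)])
      if (mm <= max_mm)
        hits[[length(hits) + 1L]] <- data.frame(start = st, strand = strand,
                                                mismatches = mm)
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# Interval-stabbing depth oracle.
brute_depth <- function(starts, ends, tlen) {
  d <- integer(tlen)
  for (i in seq_along(starts)) {
    ix <- starts[i]:ends[i]
    d[ix] <- d[ix] + 1L
  }
  d
}

# Independent exact rank-sum oracle: enumerate every split of the midranks
# into group 1 and apply the two-tailed 2*min rule.
brute_rank_sum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n <- length(r)
  w <- sum(r[seq_len(n1)])
  ws <- apply(combn(n, n1), 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
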