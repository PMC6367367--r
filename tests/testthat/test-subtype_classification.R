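test_that("pairwise distance matches the dynamic-programming oracle", {
  a <- fx_subtypes$mPingC$sequence
  expect_equal(unname(pairwise_distance(a, a)), c(0, 0))
  b <- a; substr(b, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                         substr(a, 100, 100))[1]
  expect_equal(unname(pairwise_distance(a, b)), c(1, 0))
  # 3-bp deletion costs 3 gap columns
  del3 <- paste0(substr(a, 1, 199), substr(a, 203, 430))
  expect_equal(unname(pairwise_distance(a, del3)), c(0, 3))
  # 100 random pairs against the Levenshtein oracle (utils::adist)
  set.seed(71)
  for (i in 1:100) {
    x <- random_seq(sample(40:80, 1))
    y <- strsplit(x, "")[[1]]
    # random substitutions and indels
    for (k in seq_len(sample(0:6, 1))) {
      op <- sample(3, 1)
      p <- sample(length(y), 1)
      if (op == 1) y[p] <- sample(c("A", "C", "G", "T"), 1)
      else if (op == 2) y <- y[-p]
      else y <- append(y, sample(c("A", "C", "G", "T"), 1), after = p)
    }
    y <- paste(y, collapse = "")
    d <- pairwise_distance(x, y)
    expect_equal(unname(sum(d)), as.integer(utils::adist(x, y)))
    # symmetry
    expect_equal(sum(pairwise_distance(y, x)), sum(d))
  }
})

test_that("graph components follow the 4-difference edge rule", {
  a <- fx_subtypes$mPingC$sequence
  b <- a
  for (p in c(10, 60, 110, 160, 210, 260))  # 6 mismatches away
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), substr(b, p, p))[1]
  g <- build_subtype_graph(c(s1 = a, s2 = a, s3 = b))
  expect_equal(g$n_components, 2L)
  expect_equal(g$membership[["s1"]], g$membership[["s2"]])
  # chain: a-b 3, b-c 3, a-c 6 -> one component via transitivity
  mk <- function(base, positions) {
    for (p in positions)
      substr(base, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substr(base, p, p))[1]
    base
  }
  b3 <- mk(a, c(20, 70, 120))
  c6 <- mk(b3, c(170, 220, 270))
  g2 <- build_subtype_graph(c(a = a, b = b3, c = c6))
  expect_equal(sum(pairwise_distance(a, c6)), 6)
  expect_equal(g2$n_components, 1L)
  # empty input
  g0 <- build_subtype_graph(character(0))
  expect_equal(g0$n_components, 0L)
  # membership is a partition
  expect_true(all(names(g2$membership) == c("a", "b", "c")))
  expect_false(any(is.na(g2$membership)))
})

test_that("cohorts with k distinct subtypes give exactly k components", {
  seqs <- vapply(fx_subtypes, `[[`, "", "sequence")
  for (k in 1:4) {
    cons <- rep(seqs[1:k], each = 2)
    names(cons) <- paste0("n", seq_along(cons))
    g <- build_subtype_graph(cons)
    expect_equal(g$n_components, k)
  }
})

test_that("locus consensus assembly reconstructs the inserted element", {
  g <- simulate_genome(1, 30000, 0.44, seed = 72)
  gi <- insert_elements(g, fx_elements$mPing, 1, seed = 73)
  ev <- gi$events
  loc <- known_locus(ev$chrom, ev$tsd_start, ev$tsd_end, "mPing")
  rp <- simulate_reads(gi, coverage = 14, error_rate = 0, seed = 74)
  galn <- align_reads(all_reads(rp), g$ref)
  lr <- collect_locus_reads(rp, galn, loc)
  cons <- assemble_locus_consensus(lr, reference = g$ref, locus = loc)
  expect_true(cons$complete)
  expected <- if (ev$strand == "-")
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fx_elements$mPing$sequence)))
  else fx_elements$mPing$sequence
  expect_identical(cons$sequence, expected)
  # a coverage gap leaves the consensus incomplete
  gap_reads <- c(vapply(seq(1, 150, by = 30), function(s)
    substr(fx_elements$mPing$sequence, s, s + 49), ""),
    vapply(seq(300, 380, by = 30), function(s)
      substr(fx_elements$mPing$sequence, s, s + 49), ""))
  cg <- assemble_locus_consensus(gap_reads, reference = g$ref, locus = loc)
  expect_false(cg$complete)
  expect_error(assemble_locus_consensus(character(0)), "zero reads")
})

test_that("canonical assignment follows breakpoints, not private SNPs", {
  parent <- fx_elements$Ping16G
  expect_equal(assign_canonical(fx_subtypes$mPingC$sequence, fx_subtypes,
                                parent)$label, "mPingC")
  withSNP <- fx_subtypes$mPingB$sequence
  substr(withSNP, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                     substr(withSNP, 50, 50))[1]
  expect_equal(assign_canonical(withSNP, fx_subtypes, parent)$label,
               "mPingB")
  # a different deletion matches no canonical subtype
  other <- derive_subtype(parent, subtype_definition("x", "Ping16G",
                                                     list(c(300L, 5210L))))
  expect_equal(assign_canonical(other$sequence, fx_subtypes, parent)$label,
               "novel")
})

test_that("breakpoint-spanning reads identify subtypes at threshold", {
  g <- simulate_genome(1, 60000, 0.44, seed = 75)
  g2 <- insert_elements(g, fx_subtypes$mPingA, 2, seed = 76)
  g2 <- insert_elements(g2, fx_subtypes$mPingD, 1, seed = 77)
  rp <- simulate_reads(g2, coverage = 14, error_rate = 0, seed = 78)
  expect_setequal(detect_subtype_by_breakpoint_reads(rp, fx_subtypes),
                  c("mPingA", "mPingD"))
  # a single spanning read is below the two-read rule
  bp <- fx_subtypes$mPingB$breakpoints[1]
  one <- substr(fx_subtypes$mPingB$sequence, bp - 49, bp + 50)
  expect_length(detect_subtype_by_breakpoint_reads(one, fx_subtypes), 0)
  expect_length(detect_subtype_by_breakpoint_reads(character(0),
                                                   fx_subtypes), 0)
})
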