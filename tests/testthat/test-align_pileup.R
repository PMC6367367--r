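test_that("exact and mismatched reads place as specified", {
  set.seed(21)
  tgt <- c(chrA = random_seq(20000))
  read <- substr(tgt, 1001, 1100)
  aln <- align_reads(read, tgt)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$start, 1001L)
  expect_equal(aln$mismatches, 0L)
  expect_true(aln$unique)
  # a read with 3 substitutions is not retained under the <= 2 rule
  r3 <- read
  for (p in c(10, 50, 90))
    substr(r3, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r3, p, p))[1]
  expect_equal(nrow(align_reads(r3, tgt, max_mismatch = 2)), 0L)
  expect_equal(align_reads(r3, tgt, max_mismatch = 3)$mismatches, 3L)
  # reverse-complement reads place on the minus strand at the same spot
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  arc <- align_reads(rc, tgt)
  expect_equal(arc$start, 1001L)
  expect_equal(arc$strand, "-")
})

test_that("reads matching two identical element copies are non-unique", {
  set.seed(22)
  flank <- random_seq(3000)
  el <- fx_elements$mPing$sequence
  tgt <- c(chr = paste0(flank, el, random_seq(2000), el, random_seq(1000)))
  read <- substr(el, 101, 200)
  aln <- align_reads(read, tgt)
  expect_false(aln$unique)
  # exhaustive-scan oracle agrees on best placements for random reads
  small <- c(t1 = random_seq(1500))
  for (i in 1:15) {
    st <- sample(1:1400, 1)
    r <- substr(small, st, st + 59)
    if (runif(1) < 0.5)
      r <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(r)))
    a <- align_reads(r, small)
    b <- brute_align(r, small[[1]])
    expect_equal(a$mismatches, min(b$mismatches))
    best <- b[b$mismatches == min(b$mismatches), ]
    expect_true(a$start %in% best$start)
  }
})

test_that("alignment is invariant to read order", {
  set.seed(23)
  tgt <- c(chr = random_seq(10000))
  reads <- vapply(sample(1:9900, 30), function(s) substr(tgt, s, s + 79), "")
  a1 <- align_reads(reads, tgt)
  perm <- sample(length(reads))
  a2 <- align_reads(reads[perm], tgt)
  key1 <- sort(paste(a1$start, a1$strand, a1$mismatches))
  key2 <- sort(paste(a2$start, a2$strand, a2$mismatches))
  expect_identical(key1, key2)
})

test_that("pileup depth matches the interval-stabbing oracle", {
  el <- fx_elements$mPing
  # one error-free 100-bp read at position 1
  p1 <- element_profile(substr(el$sequence, 1, 100), el)
  expect_equal(p1$depth[1:100], rep(1L, 100))
  expect_equal(sum(p1$depth), 100L)
  # two overlapping reads give depth 2 in the overlap
  p2 <- element_profile(c(substr(el$sequence, 1, 100),
                          substr(el$sequence, 51, 150)), el)
  expect_equal(p2$depth[51:100], rep(2L, 50))
  expect_equal(p2$depth[1:50], rep(1L, 50))
  # random read sets against the brute-force oracle
  set.seed(24)
  starts <- sample(1:(430 - 60), 40, replace = TRUE)
  reads <- vapply(starts, function(s) substr(el$sequence, s, s + 59), "")
  pr <- element_profile(reads, el)
  expect_equal(pr$depth, brute_depth(starts, starts + 59L, 430L))
  # depth is capped
  pc <- pileup(clip_align_reads(reads, el), target = el, depth_cap = 2L)
  expect_true(all(pc$depth <= 2L))
})

test_that("a 20x library over the element yields Poisson-consistent depth", {
  el <- fx_elements$mPing
  rp <- suppressWarnings(
    simulate_reads(c(el = el$sequence), coverage = 20, read_length = 100,
                   insert_mean = 250, insert_sd = 30, error_rate = 0,
                   seed = 25))
  prof <- element_profile(rp, el)
  expect_gte(mean(prof$depth), 16)
  expect_lte(mean(prof$depth), 24)
})

test_that("genome mean depth is the aligned-base total over genome length", {
  g <- simulate_genome(1, 100000, 0.44, seed = 26)
  rp <- simulate_reads(g, coverage = 14, read_length = 100, error_rate = 0,
                       seed = 27)
  expect_equal(genome_mean_depth(rp, g$ref), 14.0)
  # linear in read count
  half <- structure(list(r1 = rp$r1[1:3500], r2 = rp$r2[1:3500]),
                    class = "read_pairs")
  expect_equal(genome_mean_depth(all_reads(half), g$ref), 7.0)
  expect_equal(genome_mean_depth(character(0), g$ref), 0)
})

test_that("out-of-bounds alignments are rejected", {
  el <- fx_elements$mPing
  aln <- align_reads(substr(el$sequence, 1, 100), el$sequence)
  aln$start <- 400L; aln$end <- 499L
  expect_error(pileup(aln, target = el$sequence,
                      reads = substr(el$sequence, 1, 100)), "bounds")
})

test_that("SAM ingest recovers coordinates and the mismatch filter", {
  skip_if_not_installed("Rsamtools")
  tgt <- fx_elements$mPing$sequence
  read <- substr(tgt, 11, 60)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:mPing\tLN:", nchar(tgt)),
    paste("r1", 0, "mPing", 11, 60, "50M", "*", 0, 0, read,
          strrep("I", 50), "NM:i:0", sep = "\t"),
    paste("r2", 0, "mPing", 5, 60, "50M", "*", 0, 0, read,
          strrep("I", 50), "NM:i:7", sep = "\t")), sam)
  aln <- read_sam_alignments(sam)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$read, "r1")
  expect_equal(aln$start, 11L)
  expect_equal(aln$end, 60L)
})
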