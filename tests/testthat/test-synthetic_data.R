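test_that("genome simulation is seeded, GC-controlled and validated", {
  g1 <- simulate_genome(1, 20000, 0.44, seed = 7)
  g2 <- simulate_genome(1, 20000, 0.44, seed = 7)
  expect_identical(g1$ref, g2$ref)
  expect_error(simulate_genome(1, 0, 0.44, seed = 1), "positive")
  # gc_fraction 1 gives only G/C
  gc1 <- simulate_genome(1, 12000, 1.0, seed = 2)
  expect_false(grepl("[AT]", gc1$ref[[1]]))
  # binomial concentration: GC within [0.48, 0.52] at 2 x 50 kb, gc = 0.5
  g <- simulate_genome(2, 50000, 0.5, seed = 1)
  gc <- sum(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(g$ref), "GC")) / 100000
  expect_gte(gc, 0.48); expect_lte(gc, 0.52)
})

test_that("element insertion applies the TSD rule and length bookkeeping", {
  g <- simulate_genome(1, 30000, 0.44, seed = 3)
  expect_identical(insert_elements(g, fx_elements$mPing, 0), g)
  g10 <- insert_elements(g, fx_elements$mPing, 10, seed = 5)
  seqs <- materialize_genome(g10)
  expect_equal(nchar(seqs), nchar(g$ref) + 10 * (430 + 3),
               ignore_attr = TRUE)
  # truth TSD equals the reference bases at the target site
  ev <- g10$events
  expect_equal(nrow(ev), 10L)
  for (i in seq_len(nrow(ev)))
    expect_equal(ev$tsd[i], substr(g$ref[[ev$chrom[i]]], ev$tsd_start[i],
                                   ev$tsd_end[i]))
  # genome length conservation over random configurations
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(1:6, 1)
    el <- fx_elements[[sample(c("mPing", "Pong", "Stowaway"), 1)]]
    gi <- insert_elements(g, el, n, seed = 100 + rep)
    tlen <- if (el$id == "Stowaway") 2L else 3L
    expect_equal(nchar(materialize_genome(gi)),
                 nchar(g$ref) + n * (el$length + tlen), ignore_attr = TRUE)
  }
})

test_that("AT-rich targeting hits the only AT window of a GC genome", {
  g <- simulate_genome(1, 30000, 0.44, seed = 4)
  at_at <- 15000L
  g$ref[[1]] <- paste0(strrep("G", at_at - 5L), strrep("A", 9),
                       strrep("C", 30000 - at_at - 4L))
  gi <- insert_elements(g, fx_elements$mPing, 1, target_model = "at_rich_9bp",
                        seed = 9)
  expect_true(abs(gi$events$position - at_at) <= 4)
})

test_that("nested insertion reproduces the Ping-in-Stowaway junctions", {
  g <- simulate_genome(1, 30000, 0.44, seed = 6)
  g <- insert_elements(g, fx_elements$Stowaway, 1, seed = 7)
  expect_error(insert_nested(g, known_locus("chr1", 5, 7, "Stowaway"),
                             fx_elements$Ping16A), "absent")
  gn <- insert_nested(g, NULL, fx_elements$Ping16A, inner_position = 305)
  ev <- gn$events
  nested <- ev[!is.na(ev$nested_in), ]
  expect_equal(nrow(nested), 1L)
  host <- ev[ev$element == "Stowaway", ]
  stw <- fx_elements$Stowaway$sequence
  expect_equal(nchar(host$seq), 770 + 5341 + 3)
  expect_equal(substr(host$seq, 1, 305), substr(stw, 1, 305))
  expect_equal(substr(host$seq, 306, 305 + 5341),
               fx_elements$Ping16A$sequence)
  expect_equal(substr(host$seq, 305 + 5341 + 1, 305 + 5341 + 3),
               substr(stw, 303, 305))
  expect_equal(substr(host$seq, 305 + 5341 + 4, nchar(host$seq)),
               substr(stw, 306, 770))
  # nested insertion absent from a genome without the Stowaway
  g0 <- simulate_genome(1, 30000, 0.44, seed = 6)
  expect_error(insert_nested(g0, NULL, fx_elements$Ping16A), "absent")
})

test_that("read simulation matches the library model", {
  g <- simulate_genome(1, 100000, 0.44, seed = 8)
  rp <- simulate_reads(g, coverage = 14, read_length = 100,
                       insert_mean = 500, insert_sd = 50, error_rate = 0,
                       seed = 9)
  expect_equal(length(rp$r1), 7000L)   # 14 * 1e5 / (2 * 100)
  # realized coverage within 10% of request
  expect_lt(abs(sum(nchar(all_reads(rp))) / 100000 - 14) / 14, 0.1)
  # error-free reads are exact substrings of the genome or its RC
  seqs <- materialize_genome(g)
  idx <- sample(length(rp$r1), 20)
  for (i in idx) {
    fwd <- grepl(rp$r1[i], seqs[[1]], fixed = TRUE)
    rc <- grepl(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rp$r1[i]))), seqs[[1]], fixed = TRUE)
    expect_true(fwd || rc)
  }
  # short inserts trigger the discrimination warning
  expect_warning(simulate_reads(g, coverage = 1, read_length = 100,
                                insert_mean = 180, seed = 1), "insert")
})

test_that("FASTQ output is byte-identical under a fixed seed", {
  g <- simulate_genome(1, 20000, 0.44, seed = 10)
  d1 <- file.path(tempdir(), "fq_a"); d2 <- file.path(tempdir(), "fq_b")
  for (d in c(d1, d2)) {
    rp <- simulate_reads(g, coverage = 2, seed = 42)
    write_read_pairs(rp, d)
  }
  for (m in 1:2)
    expect_identical(readLines(paste0(d1, "_", m, ".fastq")),
                     readLines(paste0(d2, "_", m, ".fastq")))
})

test_that("cohort simulation validates config and records nested truth", {
  cfg <- data.frame(accession = c("a", "a"), mping = 1)
  expect_error(simulate_cohort(cfg, fx_elements, genome_length = 20000),
               "duplicate")
  cfg <- data.frame(accession = c("x", "y"), mping = c(1, 0),
                    stow = c("none", "ping16A_stow"), coverage = 2)
  co <- simulate_cohort(cfg, fx_elements, seed = 3, genome_length = 30000)
  expect_equal(names(co$accessions), c("x", "y"))
  ty <- co$accessions$y$truth
  expect_true(any(!is.na(ty$nested_in)))
  # empty cohort: empty outputs, no error
  co0 <- simulate_cohort(data.frame(accession = character()), fx_elements,
                         genome_length = 20000)
  expect_length(co0$accessions, 0)
  expect_null(co0$truth)
})
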