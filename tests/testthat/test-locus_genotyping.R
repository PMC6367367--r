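test_that("pseudogenome construction places junctions correctly", {
  set.seed(61)
  stow <- fx_elements$Stowaway$sequence
  psg <- build_pseudogenome(stow, random_seq(2000), random_seq(2000))
  expect_equal(nchar(psg$sequence), 4770L)
  expect_equal(psg$junctions, c(2000L, 2770L))
  ping <- fx_elements$Ping16G$sequence
  psg2 <- build_pseudogenome(ping, random_seq(305), random_seq(465))
  expect_equal(nchar(psg2$sequence), 6111L)
  expect_equal(psg2$junctions, c(305L, 5646L))
  expect_error(build_pseudogenome("", "AAA", "CCC"), "empty insert")
  expect_error(build_pseudogenome("ACGT", "", "CCC"), "flank")
})

test_that("junction calling requires overhang on both sides", {
  set.seed(62)
  psg <- build_pseudogenome(fx_elements$Stowaway$sequence, random_seq(400),
                            random_seq(400), id = "t")
  # no reads: absent with zero support
  r0 <- call_junctions(character(0), psg)
  expect_equal(r0$status, "absent")
  expect_equal(sum(r0$support), 0L)
  # reads spanning each junction with 50/50 overhang
  j1 <- substr(psg$sequence, psg$junctions[1] - 49, psg$junctions[1] + 50)
  j2 <- substr(psg$sequence, psg$junctions[2] - 49, psg$junctions[2] + 50)
  rc <- call_junctions(c(j1, j1, j2, j2), psg)
  expect_equal(rc$status, "present")
  expect_equal(unname(rc$support), c(2L, 2L))
  # a read stopping 5 bp past the boundary does not span it
  short <- substr(psg$sequence, psg$junctions[1] - 94, psg$junctions[1] + 5)
  rs <- call_junctions(c(short, short), psg)
  expect_equal(unname(rs$support[1]), 0L)
})

test_that("the three Ping16A_Stow structures classify correctly", {
  cfg <- data.frame(accession = c("n1", "s1", "p1"), mping = 1,
                    stow = c("none", "stowaway_only", "ping16A_stow"),
                    coverage = 14)
  co <- simulate_cohort(cfg, fx_elements, seed = 11, genome_length = 60000)
  calls <- vapply(names(co$accessions), function(acc)
    as.character(detect_ping16A_stow(co$accessions[[acc]]$reads,
                                     co$stow_locus, co$reference$ref,
                                     fx_elements)), "")
  expect_equal(unname(calls), c("none", "stowaway_only", "ping16A_stow"))
  # nested junction reads without any Stowaway signal are inconsistent
  psg <- stow_pseudogenomes(co$reference$ref, co$stow_locus, fx_elements)
  jn <- psg$nested
  reads <- c(substr(jn$sequence, jn$junctions[1] - 49, jn$junctions[1] + 50),
             substr(jn$sequence, jn$junctions[1] - 39, jn$junctions[1] + 60),
             substr(jn$sequence, jn$junctions[2] - 49, jn$junctions[2] + 50),
             substr(jn$sequence, jn$junctions[2] - 39, jn$junctions[2] + 60))
  expect_error(detect_ping16A_stow(reads, co$stow_locus, co$reference$ref,
                                   fx_elements), "inconsistent")
})

fake_counts_profile <- function(g, a, pos = 16L, len = 430L) {
  counts <- matrix(0L, 5, len, dimnames = list(c("A", "C", "G", "T", "N"),
                                               NULL))
  counts["G", pos] <- g; counts["A", pos] <- a
  structure(list(target = "Ping", length = len, depth = colSums(counts),
                 counts = counts), class = "pileup_profile")
}

test_that("the two-read genotype rule covers all cases", {
  expect_equal(genotype_snp16(fake_counts_profile(288, 23))$call, "both")
  expect_equal(genotype_snp16(fake_counts_profile(5, 0))$call, "Ping16G")
  expect_equal(genotype_snp16(fake_counts_profile(0, 3))$call, "Ping16A")
  expect_equal(genotype_snp16(fake_counts_profile(1, 1))$call,
               "undetermined")
  expect_equal(genotype_snp16(fake_counts_profile(2, 2))$call, "both")
})

test_that("pooled genotyping applies the rule to pooled family reads", {
  expect_equal(pooled_genotype(character(0), fx_elements)$call,
               "undetermined")
  # reads from a Ping16A element pool to an A call
  el <- fx_elements$Ping16A$sequence
  reads <- vapply(1:5, function(i) substr(el, i, i + 99), "")
  gt <- pooled_genotype(reads, fx_elements)
  expect_equal(gt$call, "Ping16A")
  expect_equal(gt$level, "accession")
  expect_gte(gt$a_count, 2L)
})

test_that("minor-allele pairs resolve to their source pseudogenome", {
  expect_equal(nrow(resolve_shared_allele(list(r1 = character(),
                                               r2 = character()), list())),
               0L)
  set.seed(63)
  fl_a <- random_seq(600); fr_a <- random_seq(600)
  fl_b <- random_seq(600); fr_b <- random_seq(600)
  el <- fx_elements$mPing$sequence
  psgs <- list(A = build_pseudogenome(el, fl_a, fr_a, id = "A"),
               B = build_pseudogenome(el, fl_b, fr_b, id = "B"))
  # a pair straddling pseudogenome A: junction read + flank mate
  r1 <- substr(psgs$A$sequence, 551, 650)    # crosses left junction
  r2 <- substr(psgs$A$sequence, 101, 200)    # unique in A's left flank
  res <- resolve_shared_allele(list(r1 = r1, r2 = r2), psgs)
  expect_equal(res$assigned, "A")
  # a pair entirely inside the shared element is ambiguous
  e1 <- substr(el, 1, 100); e2 <- substr(el, 151, 250)
  expect_warning(res2 <- resolve_shared_allele(list(r1 = e1, r2 = e2),
                                               psgs), "equally")
  expect_true(is.na(res2$assigned))
})
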