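# Per-accession analysis: discovery + discrimination, read-depth copy
# numbers, presence calls, +16 genotyping (locus-level or pooled), and
# Ping16A_Stow classification. This is the glue the cohort statistics
# consume.

mate_of <- function(i, n_pairs) ifelse(i > n_pairs, i - n_pairs, i + n_pairs)

#' Collect the reads belonging to one locus
#'
#' Reads whose unique reference placement overlaps the locus window, plus
#' their mates (which may lie inside the inserted element).
#'
#' @param reads `read_pairs`.
#' @param genome_alignments full-read alignments against the reference.
#' @param locus [known_locus()] or a candidate row with `tsd_start`/`tsd_end`.
#' @param window half-width around the TSD (default insert mean + 4 sd).
#' @return character vector of reads.
#' @export
collect_locus_reads <- function(reads, genome_alignments, locus,
                                window = NULL) {
  all_reads(reads)[locus_read_ids(reads, genome_alignments, locus, window)]
}

locus_read_ids <- function(reads, genome_alignments, locus, window = NULL) {
  if (is.null(window))
    window <- reads$insert_mean + 4 * reads$insert_sd
  np <- length(reads$r1)
  ga <- genome_alignments[genome_alignments$unique, , drop = FALSE]
  hit <- ga$target == locus$chrom &
    ga$start <= locus$tsd_end + window & ga$end >= locus$tsd_start - window
  sort(unique(c(ga$read[hit], mate_of(ga$read[hit], np))))
}

# Base observed by each aligned read at a single pseudogenome position.
reads_base_at <- function(aln, reads_chr, pos) {
  cover <- aln$start <= pos & aln$end >= pos
  a <- aln[cover, , drop = FALSE]
  if (!nrow(a)) return(NULL)
  oriented <- reads_chr[a$read]
  rc <- a$strand == "-"
  if (any(rc)) oriented[rc] <- revcomp_chr(oriented[rc])
  data.frame(read = a$read, base = substr(oriented, pos - a$start + 1L,
                                          pos - a$start + 1L),
             stringsAsFactors = FALSE)
}

#' Analyze a single accession
#'
#' Runs the full per-accession pipeline: three-query insertion discovery
#' with the subtraction rule, window read-depth copy numbers for mPing,
#' Ping and Pong, element presence calls, +16 G/A genotyping (locus-level,
#' with pooled mode when the library insert is too short), shared-allele
#' resolution for "both" genotypes, and Ping16A_Stow classification when a
#' host locus is supplied.
#'
#' @param reads a `read_pairs` object.
#' @param reference named character vector of reference chromosomes.
#' @param elements element set from [build_default_elements()].
#' @param stow_locus optional [known_locus()] of the Stowaway host.
#' @param accession accession id for the summary row.
#' @param max_mismatch retention filter.
#' @param resolve attempt shared-allele resolution of "both" genotypes.
#' @return list with `$summary` (one-row data frame), `$loci`, `$estimates`,
#'   `$genotypes`, `$presence`, `$stow`, `$discrimination`.
#' @export
analyze_accession <- function(reads, reference, elements, stow_locus = NULL,
                              accession = "acc", max_mismatch = 2L,
                              resolve = TRUE) {
  stopifnot(inherits(reads, "read_pairs"))
  rv <- all_reads(reads)
  np <- length(reads$r1)
  glen <- sum(nchar(reference))
  coverage <- sum(nchar(rv)) / glen
  low_insert <- reads$insert_mean < 2 * reads$read_length + 30
  gidx <- te_index(reference)
  pidx <- te_index(reference, k = 7L)
  galn <- align_reads(rv, index = gidx, max_mismatch = max_mismatch)
  genome_mean <- sum(nchar(rv)[galn$read]) / glen

  queries <- list(mPing = elements$mPing, Ping = elements$Ping16G,
                  Pong = elements$Pong)
  cands <- lapply(queries, function(el)
    discover_insertions(reads, reference, el, max_mismatch = max_mismatch,
                        genome_index = gidx, part_index = pidx,
                        genome_alignments = galn, coverage = coverage))
  disc <- discriminate_elements(cands, low_insert = low_insert)

  profiles <- lapply(queries, function(el)
    element_profile(reads, el, max_mismatch = max_mismatch))
  estimates <- lapply(names(queries), function(nm) {
    if (genome_mean <= 0) return(NULL)
    el <- queries[[nm]]
    estimate_copy_number(profiles[[nm]], genome_mean = genome_mean,
                         element = el)
  })
  names(estimates) <- names(queries)
  presence <- lapply(names(queries), function(nm)
    call_presence(profiles[[nm]], queries[[nm]]))
  names(presence) <- names(queries)

  genotypes <- list()
  if (low_insert) {
    genotypes$pooled <- pooled_genotype(reads, elements,
                                        max_mismatch = max_mismatch)
    if (resolve && genotypes$pooled$call == "both") {
      psgs <- locus_pseudogenome_set(reads, reference, elements,
                                     disc$family, galn)
      genotypes$pooled <- resolve_genotype(genotypes$pooled, reads,
                                           reference, elements, psgs,
                                           max_mismatch = max_mismatch)
    }
    variant <- genotypes$pooled$call
  } else {
    ping_loci <- disc$Ping
    if (!is.null(ping_loci) && nrow(ping_loci)) {
      for (i in seq_len(nrow(ping_loci))) {
        loc <- known_locus(ping_loci$chrom[i], ping_loci$tsd_start[i],
                           ping_loci$tsd_end[i], "Ping")
        # locus-specific reads only: mates anchored near the locus
        lr <- collect_locus_reads(reads, galn, loc)
        id <- paste0(loc$chrom, ":", loc$tsd_start, "-", loc$tsd_end)
        gt <- genotype_ping_locus(lr, elements$Ping16G,
                                  max_mismatch = max_mismatch,
                                  locus_id = id)
        genotypes[[id]] <- gt
      }
    }
    calls <- vapply(genotypes, `[[`, "", "call")
    if (resolve && any(calls == "both")) {
      genotypes <- resolve_both_genotypes(reads, reference, elements,
                                          disc, genotypes, galn,
                                          max_mismatch = max_mismatch)
      calls <- vapply(genotypes, `[[`, "", "call")
    }
    calls <- setdiff(unique(calls), "undetermined")
    variant <- if (!length(calls)) "undetermined" else
      if (length(calls) == 1L) calls else "both"
  }

  stow <- NULL
  if (!is.null(stow_locus))
    stow <- detect_ping16A_stow(reads, stow_locus, reference, elements,
                                max_mismatch = max_mismatch)

  count_of <- function(x) if (is.null(x)) NA_integer_ else nrow(x)
  est_of <- function(x) if (is.null(x)) NA_real_ else x$value
  summary <- data.frame(
    accession = accession,
    mPing_count = count_of(disc$mPing), Ping_count = count_of(disc$Ping),
    Pong_count = count_of(disc$Pong),
    mPing_estimate = est_of(estimates$mPing),
    Ping_estimate = est_of(estimates$Ping),
    Pong_estimate = est_of(estimates$Pong),
    mPing_presence = as.character(presence$mPing),
    Ping_presence = as.character(presence$Ping),
    Pong_presence = as.character(presence$Pong),
    ping_variant = variant,
    stow_status = if (is.null(stow)) NA_character_ else as.character(stow),
    low_insert = low_insert, genome_mean = genome_mean,
    stringsAsFactors = FALSE)
  list(summary = summary, loci = disc, estimates = estimates,
       genotypes = genotypes, presence = presence, stow = stow,
       discrimination = cands, genome_alignments = galn)
}

#' Pseudogenomes of every candidate family locus of an accession
#'
#' Loci with a complete assembled consensus (reads collected around the
#' locus, greedy overlap assembly, flank-trimmed) carry the consensus, which
#' preserves locus-private variants. Loci whose consensus cannot be
#' completed carry the class template (mPing or Ping16G, oriented by the
#' junction-read strand); the class comes from the candidate's `element`
#' column, so a locus already discriminated as mPing is never treated as a
#' Ping candidate during shared-allele resolution. Names are prefixed
#' `"mPing:"` or `"Ping:"`.
#'
#' @param reads `read_pairs`.
#' @param reference reference chromosomes.
#' @param elements element set.
#' @param loci candidate loci (`te_candidates` rows); `element` of "mPing"
#'   marks mPing loci, anything else (or family-level candidates with
#'   unknown class) falls back on consensus length.
#' @param galn full-read genome alignments.
#' @return named list of pseudogenomes.
#' @export
locus_pseudogenome_set <- function(reads, reference, elements, loci, galn) {
  psgs <- list()
  if (is.null(loci) || !nrow(loci)) return(psgs)
  for (i in seq_len(nrow(loci))) {
    loc <- known_locus(loci$chrom[i], loci$tsd_start[i], loci$tsd_end[i],
                       "family")
    hint <- loci$element[i] %||% NA_character_
    is_mping <- identical(hint, "mPing")
    is_ping <- isTRUE(hint %in% c("Ping", "Ping16G", "Ping16A"))
    template_psg <- function(tmpl, prefix) {
      ins <- tmpl$sequence
      if (identical(loci$strand[i], "-")) ins <- revcomp_chr(ins)
      id <- paste0(prefix, loc$chrom, ":", loc$tsd_start)
      psgs[[id]] <<- build_locus_pseudogenome(reference, loc, ins, id = id)
    }
    if (is_ping) {
      # a full-length Ping cannot be tiled by locus reads; a "complete"
      # assembly here would be a chimera through the shared termini
      template_psg(elements$Ping16G, "Ping:")
      next
    }
    lr <- collect_locus_reads(reads, galn, loc)
    cons <- if (length(lr))
      tryCatch(assemble_locus_consensus(lr, reference = reference,
                                        locus = loc),
               error = function(e) NULL) else NULL
    if (!is.null(cons) && isTRUE(cons$complete)) {
      prefix <- if (is_mping || nchar(cons$sequence) < 1000) "mPing:" else
        "Ping:"
      id <- paste0(prefix, loc$chrom, ":", loc$tsd_start)
      psgs[[id]] <- build_locus_pseudogenome(reference, loc, cons$sequence,
                                             id = id)
    } else {
      template_psg(if (is_mping) elements$mPing else elements$Ping16G,
                   if (is_mping) "mPing:" else "Ping:")
    }
  }
  psgs
}

#' Resolve a "both" +16 genotype through per-locus pseudogenomes
#'
#' Every read covering element position 16 with a G or A (among
#' `scope_ids`, or among all reads for a pooled genotype) is aligned, with
#' its mate, to the accession's locus pseudogenomes. Reads uniquely
#' assigned to an mPing locus are removed from the allele counts — they are
#' mPing copies sharing the Ping terminus, not Ping alleles — and the
#' two-read rule is re-applied. Reads assigned to a Ping locus or left
#' unassigned keep contributing, so a genuine second Ping allele survives
#' resolution as "both".
#'
#' @param gt an `snp16_genotype` with call `"both"`.
#' @param reads `read_pairs`.
#' @param reference,elements reference and element set.
#' @param psgs pseudogenome set from [locus_pseudogenome_set()].
#' @param scope_ids read ids to scan for allele support (default all).
#' @param max_mismatch placement filter.
#' @return the updated genotype (with `$resolution` and `$resolved`).
#' @export
resolve_genotype <- function(gt, reads, reference, elements, psgs,
                             scope_ids = NULL, max_mismatch = 2L) {
  if (gt$call != "both") return(gt)
  rv <- all_reads(reads)
  np <- length(reads$r1)
  if (is.null(scope_ids)) scope_ids <- seq_along(rv)
  ca <- clip_align_reads(rv[scope_ids], elements$Ping16G,
                         max_mismatch = max_mismatch)
  cover <- which(ca$ov_start <= 16L & ca$ov_end >= 16L)
  base16 <- substr(ca$ov_seq[cover], 16L - ca$ov_start[cover] + 1L,
                   16L - ca$ov_start[cover] + 1L)
  keep <- base16 %in% c("A", "G")
  allele_reads <- scope_ids[ca$read[cover][keep]]
  base16 <- base16[keep]
  if (!length(allele_reads) || !length(psgs)) return(gt)
  pairs <- list(r1 = rv[allele_reads], r2 = rv[mate_of(allele_reads, np)])
  res <- resolve_shared_allele(pairs, psgs, max_mismatch = max_mismatch)
  res$base <- base16
  gt$resolution <- res
  from_mping <- !is.na(res$assigned) & startsWith(res$assigned, "mPing:")
  g2 <- sum(base16 == "G" & !from_mping)
  a2 <- sum(base16 == "A" & !from_mping)
  call2 <- if (g2 >= 2L && a2 < 2L) "Ping16G" else
    if (a2 >= 2L && g2 < 2L) "Ping16A" else
      if (a2 >= 2L && g2 >= 2L) "both" else "undetermined"
  if (call2 != "both") {
    gt$g_count <- as.integer(g2)
    gt$a_count <- as.integer(a2)
    gt$call <- call2
    gt$resolved <- TRUE
  } else {
    gt$resolved <- FALSE
  }
  gt
}

# Locus-level resolution pass over an accession's genotypes.
resolve_both_genotypes <- function(reads, reference, elements, disc,
                                   genotypes, galn, max_mismatch = 2L) {
  loci <- rbind(disc$mPing, disc$Ping)
  psgs <- locus_pseudogenome_set(reads, reference, elements, loci, galn)
  for (nm in names(genotypes)) {
    gt <- genotypes[[nm]]
    if (gt$call != "both") next
    parts <- strsplit(nm, "[:-]")[[1]]
    loc <- known_locus(parts[1], as.integer(parts[2]), as.integer(parts[3]),
                       "Ping")
    scope <- locus_read_ids(reads, galn, loc)
    if (!length(scope)) next
    genotypes[[nm]] <- resolve_genotype(gt, reads, reference, elements,
                                        psgs, scope_ids = scope,
                                        max_mismatch = max_mismatch)
  }
  genotypes
}

#' Analyze a simulated cohort
#'
#' Applies [analyze_accession()] to every accession of a
#' [simulate_cohort()] result and binds the summary rows.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param elements element set.
#' @param use_stow classify the Ping16A_Stow locus (requires the cohort's
#'   shared host locus).
#' @param ... passed to [analyze_accession()].
#' @return list with `$summaries` (data frame) and `$results` (per-accession
#'   detail lists).
#' @export
analyze_cohort <- function(cohort, elements, use_stow = TRUE, ...) {
  ref <- cohort$reference$ref
  res <- lapply(names(cohort$accessions), function(acc) {
    analyze_accession(cohort$accessions[[acc]]$reads, ref, elements,
                      stow_locus = if (use_stow) cohort$stow_locus else NULL,
                      accession = acc, ...)
  })
  names(res) <- names(cohort$accessions)
  summaries <- do.call(rbind, lapply(res, `[[`, "summary"))
  rownames(summaries) <- NULL
  list(summaries = summaries, results = res)
}
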