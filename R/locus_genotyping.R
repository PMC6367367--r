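# Pseudogenome junction detection and +16 G/A genotyping.
#
# A pseudogenome is an inserted segment flanked by its surrounding sequence;
# reads spanning a flank/insert boundary with enough overhang on both sides
# are junction evidence. The nested Ping16A_Stow structure is detected in
# two stages: Stowaway-in-genome junctions, then Ping-in-Stowaway junctions.
# The +16 SNP is genotyped from pileup base counts with the two-read rule;
# ambiguous accessions are resolved by assigning minor-allele read pairs to
# per-locus pseudogenomes.

#' Build a pseudogenome
#'
#' @param insert_sequence inserted segment (element or nested construct).
#' @param left_flank,right_flank flanking sequences (non-empty).
#' @param id pseudogenome identifier.
#' @return object of class `pseudogenome` with `$sequence` and `$junctions`
#'   (positions j such that the boundary lies between j and j+1).
#' @export
build_pseudogenome <- function(insert_sequence, left_flank, right_flank,
                               id = "pseudogenome") {
  insert_sequence <- toupper(as.character(insert_sequence))
  left_flank <- toupper(as.character(left_flank))
  right_flank <- toupper(as.character(right_flank))
  if (!nchar(insert_sequence)) stop("empty insert sequence")
  if (!nchar(left_flank) || !nchar(right_flank)) stop("empty flank")
  seqs <- paste0(left_flank, insert_sequence, right_flank)
  j <- c(nchar(left_flank), nchar(left_flank) + nchar(insert_sequence))
  structure(list(id = id, sequence = seqs, junctions = j,
                 flank_left = nchar(left_flank),
                 insert_length = nchar(insert_sequence)),
            class = "pseudogenome")
}

#' Count junction-spanning reads on a pseudogenome
#'
#' A read spans a junction when its retained full-length placement covers at
#' least `min_overhang` matched bases on each side of the boundary. The
#' structure is called present when total spanning support reaches
#' `min_support` with each junction covered by at least one read.
#'
#' @param reads reads (`read_pairs` or character).
#' @param pseudogenome a [build_pseudogenome()] object.
#' @param max_mismatch placement filter.
#' @param min_support total spanning reads required for presence.
#' @param min_overhang matched bases required on each side of a boundary.
#' @return list with `$support` (per junction), `$status`
#'   (`"present"`/`"absent"`).
#' @export
call_junctions <- function(reads, pseudogenome, max_mismatch = 2L,
                           min_support = 2L, min_overhang = 10L) {
  reads <- as_read_chr(reads)
  support <- setNames(integer(length(pseudogenome$junctions)),
                      paste0("j", seq_along(pseudogenome$junctions)))
  if (length(reads)) {
    idx <- te_index(setNames(pseudogenome$sequence, pseudogenome$id),
                    min_read_length = min(nchar(reads)))
    aln <- align_reads(reads, index = idx, max_mismatch = max_mismatch)
    for (k in seq_along(pseudogenome$junctions)) {
      j <- pseudogenome$junctions[k]
      support[k] <- sum(aln$start <= j - min_overhang + 1L &
                        aln$end >= j + min_overhang)
    }
  }
  status <- if (sum(support) >= min_support && all(support >= 1L))
    "present" else "absent"
  list(pseudogenome = pseudogenome$id, support = support, status = status)
}

ref_window <- function(reference, chrom, from, to) {
  substr(reference[[chrom]], max(1L, from), min(nchar(reference[[chrom]]), to))
}

#' Pseudogenomes for the Ping16A_Stow locus
#'
#' Stage A: the Stowaway inserted at the locus with genomic flanks (default
#' 2 kb). Stage B: Ping16A nested after Stowaway position 305, so the left
#' flank is the genomic context plus Stowaway 1-305 and the right flank is
#' the duplicated 3-bp target followed by Stowaway 306-770 and genomic
#' context.
#'
#' @param reference named character vector of reference chromosomes.
#' @param locus [known_locus()] of the Stowaway host (TSD coordinates).
#' @param elements element set.
#' @param flank genomic flank length.
#' @param inner_position Stowaway position after which Ping16A sits.
#' @return list with `$stow` and `$nested` pseudogenomes.
#' @export
stow_pseudogenomes <- function(reference, locus, elements, flank = 2000L,
                               inner_position = 305L) {
  p <- locus$tsd_end
  tsd <- ref_window(reference, locus$chrom, locus$tsd_start, locus$tsd_end)
  left <- ref_window(reference, locus$chrom, p - flank + 1L, p)
  right <- paste0(tsd, ref_window(reference, locus$chrom, p + 1L, p + flank))
  stow <- elements$Stowaway$sequence
  psg_a <- build_pseudogenome(stow, left, right, id = "stowaway_in_genome")
  inner_tsd <- substr(stow, inner_position - 2L, inner_position)
  psg_b <- build_pseudogenome(
    elements$Ping16A$sequence,
    paste0(left, substr(stow, 1L, inner_position)),
    paste0(inner_tsd, substr(stow, inner_position + 1L, nchar(stow)), right),
    id = "ping_in_stowaway")
  list(stow = psg_a, nested = psg_b)
}

#' Classify an accession at the Ping16A_Stow locus
#'
#' Two-stage decision: no Stowaway junction support gives `"none"`; Stowaway
#' junctions without nested Ping junctions give `"stowaway_only"`; both give
#' `"ping16A_stow"`. Nested support without Stowaway support is an
#' impossible structure and raises an error.
#'
#' @param reads accession reads.
#' @param locus Stowaway host [known_locus()].
#' @param reference reference chromosomes.
#' @param elements element set.
#' @param flank genomic flank length for the pseudogenomes.
#' @param ... passed to [call_junctions()].
#' @return `"none"`, `"stowaway_only"` or `"ping16A_stow"` with junction
#'   calls attached as attribute `calls`.
#' @export
detect_ping16A_stow <- function(reads, locus, reference, elements,
                                flank = 2000L, ...) {
  psg <- stow_pseudogenomes(reference, locus, elements, flank = flank)
  stow_call <- call_junctions(reads, psg$stow, ...)
  nested_call <- call_junctions(reads, psg$nested, ...)
  res <- if (stow_call$status == "absent") {
    if (nested_call$status == "present")
      stop("inconsistent structure: nested Ping junctions without a ",
           "Stowaway at the locus")
    "none"
  } else if (nested_call$status == "absent") "stowaway_only" else
    "ping16A_stow"
  attr(res, "calls") <- list(stow = stow_call, nested = nested_call)
  res
}

#' Genotype the +16 G/A SNP from a pileup profile
#'
#' Two-read rule: >= 2 G-supporting reads and < 2 A-supporting reads give
#' Ping16G; the converse gives Ping16A; both >= 2 give `"both"` (candidate
#' for shared-allele resolution); anything else is undetermined.
#'
#' @param profile `pileup_profile` at a Ping locus (element coordinates).
#' @param position element position of the SNP (16).
#' @param min_reads support threshold (2).
#' @return object of class `snp16_genotype` with `$g_count`, `$a_count`,
#'   `$call`.
#' @export
genotype_snp16 <- function(profile, position = 16L, min_reads = 2L) {
  g <- profile$counts["G", position]
  a <- profile$counts["A", position]
  call <- if (g >= min_reads && a < min_reads) "Ping16G" else
    if (a >= min_reads && g < min_reads) "Ping16A" else
      if (a >= min_reads && g >= min_reads) "both" else "undetermined"
  structure(list(locus = profile$target, g_count = as.integer(g),
                 a_count = as.integer(a), call = call),
            class = "snp16_genotype")
}

#' @export
print.snp16_genotype <- function(x, ...) {
  cat("<snp16_genotype>", x$locus, "G =", x$g_count, "A =", x$a_count,
      "->", x$call, "\n")
  invisible(x)
}

#' Accession-level pooled +16 genotype
#'
#' For short-insert libraries where mPing, Ping and Pong reads cannot be
#' sorted by locus, all family reads are pooled against the Ping template
#' and the two-read rule is applied to the pooled base counts at position
#' 16.
#'
#' @param reads family-associated reads.
#' @param elements element set (the Ping16G template is the pileup target).
#' @param max_mismatch placement filter.
#' @return `snp16_genotype` with `$level = "accession"`.
#' @export
pooled_genotype <- function(reads, elements, max_mismatch = 2L) {
  reads <- as_read_chr(reads)
  if (!length(reads)) {
    gt <- structure(list(locus = "pooled", g_count = 0L, a_count = 0L,
                         call = "undetermined"), class = "snp16_genotype")
    gt$level <- "accession"
    return(gt)
  }
  prof <- element_profile(reads, elements$Ping16G,
                          max_mismatch = max_mismatch)
  gt <- genotype_snp16(prof)
  gt$locus <- "pooled"
  gt$level <- "accession"
  gt
}

#' Pseudogenome of an element copy inserted at a reference locus
#'
#' @param reference reference chromosomes.
#' @param locus [known_locus()] with TSD coordinates.
#' @param element_seq the element copy's sequence (template or assembled
#'   consensus).
#' @param flank genomic flank length.
#' @param id pseudogenome id; defaults to the locus coordinates.
#' @export
build_locus_pseudogenome <- function(reference, locus, element_seq,
                                     flank = 2000L, id = NULL) {
  p <- locus$tsd_end
  tsd <- ref_window(reference, locus$chrom, locus$tsd_start, locus$tsd_end)
  left <- ref_window(reference, locus$chrom, p - flank + 1L, p)
  right <- paste0(tsd, ref_window(reference, locus$chrom, p + 1L, p + flank))
  build_pseudogenome(element_seq, left, right,
                     id = id %||% paste0(locus$chrom, ":", locus$tsd_start,
                                         "-", locus$tsd_end))
}

#' Locus-level +16 genotype from locus-specific reads
#'
#' The reads extracted for one Ping locus are aligned to the Ping element
#' template (clipped placement, so junction reads contribute their
#' element-matching part regardless of the insertion's strand) and the base
#' counts at element position 16 are genotyped with the two-read rule.
#'
#' @param locus_reads reads assigned to the locus (see
#'   [collect_locus_reads()]).
#' @param element the Ping template `te_element`.
#' @param max_mismatch placement filter.
#' @param locus_id label for the genotype.
#' @export
genotype_ping_locus <- function(locus_reads, element, max_mismatch = 2L,
                                locus_id = "Ping_locus") {
  locus_reads <- as_read_chr(locus_reads)
  if (!length(locus_reads)) {
    gt <- structure(list(locus = locus_id, g_count = 0L, a_count = 0L,
                         call = "undetermined"), class = "snp16_genotype")
    return(gt)
  }
  prof <- element_profile(locus_reads, element, max_mismatch = max_mismatch)
  gt <- genotype_snp16(prof)
  gt$locus <- locus_id
  gt
}

#' Assign minor-allele read pairs to candidate loci
#'
#' Each minor-allele read and its mate are aligned to every candidate locus
#' pseudogenome; a pair is assigned to the pseudogenome minimizing the total
#' mismatch count when that minimum is unique (both mates must align). Pairs
#' aligning equally well to two or more pseudogenomes stay unassigned (the
#' genotype remains "both") with a warning.
#'
#' @param minor_pairs list with `$r1`, `$r2` character vectors (minor-allele
#'   reads and their mates, one pair per element).
#' @param locus_pseudogenomes named list of [build_pseudogenome()] objects,
#'   one per candidate mPing/Ping locus.
#' @param max_mismatch placement filter.
#' @return data frame (pair, assigned, score); `assigned` is `NA` for
#'   unresolved pairs.
#' @export
resolve_shared_allele <- function(minor_pairs, locus_pseudogenomes,
                                  max_mismatch = 2L) {
  n <- length(minor_pairs$r1)
  if (n == 0L)
    return(data.frame(pair = integer(), assigned = character(),
                      score = integer(), stringsAsFactors = FALSE))
  targets <- vapply(locus_pseudogenomes, `[[`, "", "sequence")
  names(targets) <- names(locus_pseudogenomes) %||%
    vapply(locus_pseudogenomes, `[[`, "", "id")
  reads <- c(minor_pairs$r1, minor_pairs$r2)
  # best mismatch count per read per pseudogenome (not just the single best
  # placement): align to each pseudogenome separately
  per_tgt <- lapply(seq_along(targets), function(t) {
    i1 <- te_index(targets[t], min_read_length = min(nchar(reads)))
    a <- align_reads(reads, index = i1, max_mismatch = max_mismatch)
    mm <- rep(NA_integer_, length(reads))
    mm[a$read] <- a$mismatches
    mm
  })
  assigned <- rep(NA_character_, n)
  score <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    tot <- vapply(per_tgt, function(mm) {
      s <- mm[i] + mm[i + n]
      if (is.na(s)) NA_integer_ else as.integer(s)
    }, integer(1))
    if (all(is.na(tot))) next
    best <- min(tot, na.rm = TRUE)
    hits <- which(!is.na(tot) & tot == best)
    if (length(hits) == 1L) {
      assigned[i] <- names(targets)[hits]
      score[i] <- best
    } else {
      warning("minor-allele pair ", i, " aligns equally to ",
              length(hits), " pseudogenomes; left unassigned")
    }
  }
  data.frame(pair = seq_len(n), assigned = assigned, score = score,
             stringsAsFactors = FALSE)
}
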