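# Non-reference insertion discovery and element discrimination.
#
# A locus is evidenced by junction reads: reads whose one end matches an
# element terminus (>= len_cut_trim bases, mirroring the trimmed-match rule)
# and whose remainder maps uniquely to the reference flank. The duplicated
# target site is recovered exactly from the junction coordinate on each
# side. Discrimination uses mate pairs: one mate fully inside the element's
# diagnostic internal region (Ping 253-5164, Pong 23-5320) with the other
# anchored uniquely in the flank classifies the locus as the autonomous
# element; loci so classified are subtracted from the mPing candidate set.

#' Discover non-reference element insertions from paired-end reads
#'
#' @param reads a `read_pairs` object.
#' @param reference named character vector of reference chromosomes (without
#'   the insertions).
#' @param element query `te_element`.
#' @param max_mismatch retention filter for element/genome placements.
#' @param len_cut_trim minimum element-terminal match of a junction read.
#' @param min_flank minimum genome-side remainder of a junction read.
#' @param tsd_len duplicated-site length (3 for the mPing/Ping/Pong family).
#' @param genome_index,part_index,genome_alignments optional precomputed
#'   [te_index()]s (full-read k and short-part k) and full-read genome
#'   alignments, reused across the three element queries.
#' @param coverage approximate library coverage; below 10x the support
#'   threshold relaxes from 3 reads (at least one per side) to 2.
#' @return data frame of class `te_candidates`: chrom, tsd_start, tsd_end,
#'   element, support, support_left, support_right, internal_support.
#' @export
discover_insertions <- function(reads, reference, element,
                                max_mismatch = 2L, len_cut_trim = 10L,
                                min_flank = 15L, tsd_len = 3L,
                                genome_index = NULL, part_index = NULL,
                                genome_alignments = NULL, coverage = NULL) {
  stopifnot(inherits(reads, "read_pairs"))
  rv <- all_reads(reads)
  np <- length(reads$r1)
  if (is.null(coverage))
    coverage <- sum(nchar(rv)) / sum(nchar(reference))
  if (is.null(genome_index)) genome_index <- te_index(reference)
  if (is.null(part_index))
    part_index <- te_index(reference, k = max(7L, min(31L, min_flank %/% 2L)))

  ca <- clip_align_reads(rv, element, max_mismatch = max_mismatch,
                         min_overlap = len_cut_trim)
  tlen <- element$length
  is_l <- ca$ov_start == 1L & ca$left_clip >= min_flank
  is_r <- ca$ov_end == tlen & ca$right_clip >= min_flank
  jl <- ca[is_l & !is_r, , drop = FALSE]
  jr <- ca[is_r & !is_l, , drop = FALSE]
  parts <- c(substring(jl$oriented, 1L, jl$left_clip),
             substring(jr$oriented, nchar(jr$oriented) - jr$right_clip + 1L))
  side <- c(rep("L", nrow(jl)), rep("R", nrow(jr)))
  jreads <- c(jl$read, jr$read)
  junctions <- NULL
  if (length(parts)) {
    pa <- align_reads(parts, index = part_index, max_mismatch = 1L)
    pa <- pa[pa$unique, , drop = FALSE]
    if (nrow(pa)) {
      sd_ <- side[pa$read]
      plus <- pa$strand == "+"
      anchor_end <- (sd_ == "L") == plus
      lo <- ifelse(anchor_end, pa$end - tsd_len + 1L, pa$start)
      junctions <- data.frame(
        chrom = pa$target, tsd_start = lo, tsd_end = lo + tsd_len - 1L,
        locus_side = ifelse((sd_ == "L") == plus, "left", "right"),
        strand = ifelse(plus, "+", "-"),
        read = jreads[pa$read], stringsAsFactors = FALSE)
    }
  }
  loci <- cluster_junctions(junctions, slop = 2L)

  # mate-pair internal support
  if (!is.null(loci) && nrow(loci) && !is.null(element$internal_region)) {
    if (is.null(genome_alignments))
      genome_alignments <- align_reads(rv, index = genome_index,
                                       max_mismatch = max_mismatch)
    ir <- element$internal_region
    full <- ca[ca$left_clip == 0L & ca$right_clip == 0L, , drop = FALSE]
    internal <- full[full$ov_start >= ir[1] & full$ov_end <= ir[2], ,
                     drop = FALSE]
    if (nrow(internal)) {
      mate <- ifelse(internal$read > np, internal$read - np,
                     internal$read + np)
      ga <- genome_alignments[genome_alignments$unique, , drop = FALSE]
      m <- match(mate, ga$read)
      ok <- !is.na(m)
      if (any(ok)) {
        ganc <- ga[m[ok], , drop = FALSE]
        win <- reads$insert_mean + 4 * reads$insert_sd
        mid <- (loci$tsd_start + loci$tsd_end) / 2
        for (i in seq_len(nrow(ganc))) {
          same <- loci$chrom == ganc$target[i]
          d <- abs((ganc$start[i] + ganc$end[i]) / 2 - mid)
          d[!same] <- Inf
          j <- which.min(d)
          if (length(j) && d[j] <= win)
            loci$internal_support[j] <- loci$internal_support[j] + 1L
        }
      }
    }
  }
  if (is.null(loci)) loci <- empty_candidates(element$id)
  min_support <- if (coverage >= 10) 3L else 2L
  keep <- loci$support >= min_support
  if (min_support >= 3L)
    keep <- keep & loci$support_left >= 1L & loci$support_right >= 1L
  loci <- loci[keep, , drop = FALSE]
  loci$element <- rep(element$id, nrow(loci))
  rownames(loci) <- NULL
  class(loci) <- c("te_candidates", "data.frame")
  loci
}

empty_candidates <- function(id = character(0)) {
  data.frame(chrom = character(), tsd_start = integer(), tsd_end = integer(),
             locus_id = character(), strand = character(),
             support = integer(),
             support_left = integer(), support_right = integer(),
             internal_support = integer(),
             element = character(), stringsAsFactors = FALSE)
}

cluster_junctions <- function(junctions, slop = 2L) {
  if (is.null(junctions) || !nrow(junctions)) return(NULL)
  o <- order(junctions$chrom, junctions$tsd_start)
  j <- junctions[o, , drop = FALSE]
  grp <- integer(nrow(j)); grp[1] <- 1L
  if (nrow(j) > 1) {
    for (i in 2:nrow(j)) {
      same <- j$chrom[i] == j$chrom[i - 1L] &&
        j$tsd_start[i] <= j$tsd_end[i - 1L] + slop
      grp[i] <- if (same) grp[i - 1L] else grp[i - 1L] + 1L
    }
  }
  rows <- lapply(split(seq_len(nrow(j)), grp), function(ix) {
    g <- j[ix, , drop = FALSE]
    iv <- paste(g$tsd_start, g$tsd_end)
    modal <- names(sort(table(iv), decreasing = TRUE))[1]
    mo <- g[match(modal, iv), ]
    data.frame(chrom = mo$chrom, tsd_start = mo$tsd_start,
               tsd_end = mo$tsd_end,
               locus_id = paste0(mo$chrom, ":", mo$tsd_start, "-",
                                 mo$tsd_end),
               strand = names(sort(table(g$strand), decreasing = TRUE))[1],
               support = nrow(g),
               support_left = sum(g$locus_side == "left"),
               support_right = sum(g$locus_side == "right"),
               internal_support = 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

overlaps_any <- function(x, table, slop = 2L) {
  if (is.null(table) || !nrow(table) || !nrow(x)) return(rep(FALSE, nrow(x)))
  vapply(seq_len(nrow(x)), function(i) {
    any(table$chrom == x$chrom[i] &
        table$tsd_start <= x$tsd_end[i] + slop &
        table$tsd_end >= x$tsd_start[i] - slop)
  }, logical(1))
}

#' Discriminate mPing, Ping and Pong loci across the three query runs
#'
#' A locus with Ping-internal mate support is classed Ping; with
#' Pong-internal support, Pong; loci classed Ping or Pong are removed from
#' the mPing candidate set (the subtraction rule). Loci with support from
#' both internal regions are flagged as conflicts and excluded everywhere.
#' When the library insert size is too short to separate the elements
#' (`low_insert = TRUE`), discrimination is disabled and only a family-level
#' locus set is returned.
#'
#' @param candidates named list with elements `mPing`, `Ping`, `Pong` of
#'   `te_candidates` (the three query runs).
#' @param slop interval slop when matching loci across runs.
#' @param low_insert disable Ping/Pong discrimination (short-insert mode).
#' @return list with final `mPing`, `Ping`, `Pong` locus sets, `conflicts`,
#'   and `family` (all family-level loci).
#' @export
discriminate_elements <- function(candidates, slop = 2L, low_insert = FALSE) {
  mp <- candidates$mPing %||% empty_candidates()
  pi_ <- candidates$Ping %||% empty_candidates()
  po <- candidates$Pong %||% empty_candidates()
  if (low_insert) {
    return(list(mPing = NULL, Ping = NULL, Pong = NULL,
                conflicts = empty_candidates(), family = mp,
                low_insert = TRUE))
  }
  ping_final <- pi_[pi_$internal_support >= 1L, , drop = FALSE]
  pong_final <- po[po$internal_support >= 1L, , drop = FALSE]
  confl_p <- overlaps_any(ping_final, pong_final, slop)
  confl_q <- overlaps_any(pong_final, ping_final, slop)
  conflicts <- rbind(ping_final[confl_p, , drop = FALSE],
                     pong_final[confl_q, , drop = FALSE])
  if (nrow(conflicts))
    message(nrow(conflicts),
            " locus/loci with both Ping- and Pong-internal support ",
            "excluded as conflicts")
  ping_final <- ping_final[!confl_p, , drop = FALSE]
  pong_final <- pong_final[!confl_q, , drop = FALSE]
  drop <- overlaps_any(mp, ping_final, slop) |
    overlaps_any(mp, pong_final, slop) | overlaps_any(mp, conflicts, slop)
  list(mPing = mp[!drop, , drop = FALSE], Ping = ping_final,
       Pong = pong_final, conflicts = conflicts, family = mp,
       low_insert = FALSE)
}

#' Write candidate loci as BED-like TSV plus a JSON-lines evidence log
#'
#' The TSV uses 0-based starts (`tsd_start - 1`) in BED fashion; the
#' evidence log holds one JSON object per locus with its support counts.
#'
#' @param candidates a `te_candidates` data frame.
#' @param path output TSV path; the evidence log is written next to it as
#'   `<path>.evidence.jsonl`.
#' @export
write_candidates <- function(candidates, path) {
  bed <- data.frame(chrom = candidates$chrom,
                    start = candidates$tsd_start - 1L,
                    end = candidates$tsd_end,
                    element_class = candidates$element,
                    support = candidates$support,
                    internal_support = candidates$internal_support)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  log_path <- paste0(path, ".evidence.jsonl")
  lines <- vapply(seq_len(nrow(candidates)), function(i)
    jsonlite::toJSON(as.list(candidates[i, , drop = FALSE]),
                     auto_unbox = TRUE), "")
  writeLines(lines, log_path)
  invisible(path)
}

#' Element presence call from a pileup profile
#'
#' Present when at least `min_fraction` (default 70%) of element positions
#' are covered; absent below `absent_fraction`; otherwise partial, the
#' signature of a deletion derivative.
#'
#' @param profile `pileup_profile` over the element.
#' @param element the `te_element` (unused beyond sanity checks).
#' @param min_fraction coverage fraction required for presence.
#' @param absent_fraction fraction below which the element is absent.
#' @return `"present"`, `"absent"` or `"partial"`, with the covered fraction
#'   as attribute `fraction`.
#' @export
call_presence <- function(profile, element = NULL, min_fraction = 0.70,
                          absent_fraction = 0.10) {
  frac <- mean(profile$depth >= 1L)
  call <- if (frac >= min_fraction) "present" else
    if (frac < absent_fraction) "absent" else "partial"
  attr(call, "fraction") <- frac
  call
}
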