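# Read placement and pileup profiles.
#
# Placement is ungapped seed-and-extend: exact k-mer seeds at pigeonhole
# offsets guarantee that every placement with <= max_mismatch substitutions
# is found when floor(read_length / k) > max_mismatch. Retained alignments
# satisfy the pipeline's <= 2 mismatch filter by default. A placement is
# unique when it is the single best and its mismatch count is at least one
# lower than the second best; ties are non-unique.

#' Build a k-mer index over a target set
#'
#' @param targets named character vector or `DNAStringSet`.
#' @param k seed length; defaults to 31 capped so that three disjoint seeds
#'   fit in `min_read_length` (pigeonhole guarantee for 2 mismatches).
#' @param min_read_length shortest read the index must guarantee.
#' @return object of class `te_index`.
#' @export
te_index <- function(targets, k = NULL, min_read_length = 100L) {
  nms <- names(targets)
  targets <- as.character(targets)
  names(targets) <- nms
  if (any(nchar(targets) == 0)) stop("empty target sequence")
  if (is.null(names(targets)))
    names(targets) <- paste0("target", seq_along(targets))
  if (is.null(k)) k <- max(5L, min(31L, min_read_length %/% 3L))
  ptr <- cpp_index_build(toupper(targets), as.integer(k))
  structure(list(ptr = ptr, names = names(targets),
                 lengths = nchar(targets), k = as.integer(k)),
            class = "te_index")
}

as_read_chr <- function(reads) {
  if (inherits(reads, "read_pairs")) all_reads(reads)
  else toupper(as.character(reads))
}

#' Place reads on targets (full-length, ungapped)
#'
#' @param reads character vector, `DNAStringSet` or `read_pairs`.
#' @param targets targets to index (ignored when `index` is supplied).
#' @param index optional prebuilt [te_index()].
#' @param max_mismatch retain placements with at most this many substitutions.
#' @return data frame of class `te_alignments` with columns `read` (index
#'   into `reads`), `target`, `start`, `end`, `strand`, `mismatches`,
#'   `unique`.
#' @export
align_reads <- function(reads, targets = NULL, index = NULL,
                        max_mismatch = 2L) {
  reads <- as_read_chr(reads)
  if (!length(reads)) stop("no reads supplied")
  if (is.null(index)) {
    if (is.null(targets)) stop("supply targets or an index")
    # pigeonhole: > max_mismatch disjoint seeds must fit in the shortest read
    k <- max(5L, min(31L, min(nchar(reads)) %/% (max_mismatch + 1L)))
    index <- te_index(targets, k = k)
  }
  res <- cpp_align_full(index$ptr, reads, as.integer(max_mismatch))
  out <- data.frame(read = res$read, target = index$names[res$target],
                    start = res$start,
                    end = res$start + nchar(reads)[res$read] - 1L,
                    strand = ifelse(res$strand == 1, "-", "+"),
                    mismatches = res$mismatches,
                    unique = res$n_best == 1L &
                      res$second_mm > res$mismatches,
                    stringsAsFactors = FALSE)
  class(out) <- c("te_alignments", "data.frame")
  out
}

#' Place reads on a single target allowing terminal clipping
#'
#' The read may overhang either end of the target; mismatches are counted on
#' the overlap only, which must span at least `min_overlap` bases. Used for
#' element pileups (reads crossing an insertion junction contribute their
#' element-matching part) and junction-read capture.
#'
#' @param reads character vector, `DNAStringSet` or `read_pairs`.
#' @param target single target sequence (or `te_element`).
#' @param max_mismatch mismatch cap on the overlap.
#' @param min_overlap minimum matched overlap length.
#' @return data frame of class `te_clip_alignments` with `start` (may be
#'   <= 0 when the read overhangs the 5' end), overlap coordinates on the
#'   target (`ov_start`, `ov_end`), clip lengths in oriented-read bases and
#'   the oriented overlap substring used for pileups.
#' @export
clip_align_reads <- function(reads, target, max_mismatch = 2L,
                             min_overlap = 20L) {
  reads <- as_read_chr(reads)
  tseq <- if (inherits(target, "te_element")) target$sequence else
    toupper(as.character(target))
  res <- cpp_align_clip(reads, tseq, as.integer(max_mismatch),
                        as.integer(min_overlap))
  oriented <- reads[res$read]
  rc <- res$strand == 1
  if (any(rc)) oriented[rc] <- revcomp_chr(oriented[rc])
  lens <- nchar(oriented)
  out <- data.frame(read = res$read, start = res$start,
                    strand = ifelse(rc, "-", "+"),
                    mismatches = res$mismatches, ov_start = res$ov_start,
                    ov_end = res$ov_end, left_clip = res$left_clip,
                    right_clip = res$right_clip,
                    ov_seq = substring(oriented, res$left_clip + 1L,
                                       lens - res$right_clip),
                    oriented = oriented, stringsAsFactors = FALSE)
  attr(out, "target_length") <- nchar(tseq)
  class(out) <- c("te_clip_alignments", "data.frame")
  out
}

#' Per-position depth and base counts
#'
#' Accepts either clipped alignments (from [clip_align_reads()], the usual
#' route for element profiles) or full alignments plus the reads. Depth at a
#' position is capped at `depth_cap` (default 8000).
#'
#' @param alignments `te_clip_alignments` or `te_alignments`.
#' @param target target sequence/`te_element` (for its length and id); for
#'   clipped alignments it may be omitted.
#' @param reads original reads (needed for `te_alignments` input).
#' @param depth_cap maximum counted depth per position.
#' @return object of class `pileup_profile` with `$depth` and `$counts`
#'   (5 x length matrix, rows A,C,G,T,N).
#' @export
pileup <- function(alignments, target = NULL, reads = NULL,
                   depth_cap = 8000L) {
  if (inherits(alignments, "te_clip_alignments")) {
    tlen <- attr(alignments, "target_length")
    id <- if (inherits(target, "te_element")) target$id else "target"
    seqs <- alignments$ov_seq
    starts <- alignments$ov_start
  } else if (inherits(alignments, "te_alignments")) {
    if (is.null(reads) || is.null(target))
      stop("full alignments need `reads` and `target`")
    reads <- as_read_chr(reads)
    tseq <- if (inherits(target, "te_element")) target$sequence else
      toupper(as.character(target))
    id <- if (inherits(target, "te_element")) target$id else "target"
    tlen <- nchar(tseq)
    seqs <- reads[alignments$read]
    rc <- alignments$strand == "-"
    if (any(rc)) seqs[rc] <- revcomp_chr(seqs[rc])
    starts <- alignments$start
  } else stop("unsupported alignment object")
  if (length(seqs) && (any(starts < 1L) ||
                       any(starts + nchar(seqs) - 1L > tlen)))
    stop("alignment exceeds target bounds")
  res <- cpp_pileup(seqs, as.integer(starts), as.integer(tlen),
                    as.integer(depth_cap))
  counts <- res$counts
  rownames(counts) <- c("A", "C", "G", "T", "N")
  structure(list(target = id, length = tlen, depth = res$depth,
                 counts = counts), class = "pileup_profile")
}

#' @export
print.pileup_profile <- function(x, ...) {
  cat("<pileup_profile>", x$target, "-", x$length, "bp; mean depth",
      round(mean(x$depth), 2), "\n")
  invisible(x)
}

#' Element profile for a read set
#'
#' Convenience wrapper: clip-aligns reads to an element template and builds
#' its pileup profile.
#'
#' @inheritParams clip_align_reads
#' @param element a `te_element` (or sequence).
#' @param depth_cap pileup depth cap.
#' @export
element_profile <- function(reads, element, max_mismatch = 2L,
                            min_overlap = 20L, depth_cap = 8000L) {
  ca <- clip_align_reads(reads, element, max_mismatch = max_mismatch,
                         min_overlap = min_overlap)
  pileup(ca, target = element, depth_cap = depth_cap)
}

#' Genome-wide mean read depth
#'
#' Aligned-base total of retained full-length placements divided by genome
#' length; each read contributes once even when placed non-uniquely. For
#' very deep libraries the aligned fraction is measured on a deterministic
#' systematic subsample of `max_reads` reads and scaled to the library
#' total, which changes the result by well under the depth noise.
#'
#' @param reads reads (`read_pairs` or character).
#' @param genome named character vector of chromosomes, or a prebuilt
#'   [te_index()].
#' @param max_mismatch retention filter.
#' @param max_reads subsample cap for the aligned-fraction measurement.
#' @export
genome_mean_depth <- function(reads, genome, max_mismatch = 2L,
                              max_reads = 200000L) {
  idx <- if (inherits(genome, "te_index")) genome else te_index(genome)
  glen <- sum(idx$lengths)
  if (glen <= 0) stop("genome length must be positive")
  reads <- as_read_chr(reads)
  if (!length(reads)) return(0)
  total_bases <- sum(nchar(reads))
  sub <- reads
  if (length(reads) > max_reads)
    sub <- reads[unique(round(seq(1L, length(reads),
                                  length.out = max_reads)))]
  aln <- align_reads(sub, index = idx, max_mismatch = max_mismatch)
  frac <- sum(nchar(sub)[aln$read]) / sum(nchar(sub))
  frac * total_bases / glen
}

#' Ingest alignments from a SAM file
#'
#' Converts the SAM to BAM via Rsamtools and extracts read, target, 1-based
#' start, strand and the NM mismatch count. Records failing the
#' `max_mismatch` filter are dropped; uniqueness is taken from MAPQ > 0.
#'
#' @param path SAM file path.
#' @param max_mismatch retention filter on the NM tag.
#' @return a `te_alignments` data frame (read column holds read names).
#' @export
read_sam_alignments <- function(path, max_mismatch = 2L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("SAM ingest requires the Rsamtools package")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "seq", "mapq"),
    tag = "NM")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  nm <- b$tag$NM %||% rep(0L, length(b$pos))
  keep <- !is.na(b$pos) & !is.na(nm) & nm <= max_mismatch
  mq <- b$mapq[keep]
  out <- data.frame(read = as.character(b$qname)[keep],
                    target = as.character(b$rname)[keep],
                    start = b$pos[keep],
                    end = b$pos[keep] + nchar(as.character(b$seq))[keep] - 1L,
                    strand = as.character(b$strand)[keep],
                    mismatches = nm[keep],
                    unique = is.na(mq) | mq > 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("te_alignments", "data.frame")
  out
}

#' Write a pileup profile as TSV (position, depth, A, C, G, T, N)
#' @param profile a `pileup_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(position = seq_len(profile$length),
                   depth = profile$depth, t(profile$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
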