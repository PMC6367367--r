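# mPing subtype reconstruction and graph classification.
#
# Per-locus element sequences are rebuilt by greedy maximal-overlap merging
# of locus reads, trimmed to the TSD-bounded element using the reference
# flanks, and clustered: two sequences are connected when their optimal
# global alignment has mismatches + gap columns <= 4, and each connected
# component is a subtype. Canonical labels (mPingA-D) are assigned by
# matching deletion breakpoints against the parent element.

unit_submat <- function() {
  m <- matrix(-1, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  diag(m) <- 0
  m["N", ] <- -1; m[, "N"] <- -1
  m
}

#' Pairwise alignment distance (mismatches, gap columns)
#'
#' Optimal global alignment under unit mismatch and unit gap-column cost
#' (Levenshtein costs); the edge rule uses mismatches + gap_columns.
#'
#' @param a,b nucleotide strings.
#' @return named numeric vector `c(mismatches, gap_columns)`.
#' @export
pairwise_distance <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = unit_submat(), gapOpening = 0, gapExtension = 1)
  mm <- Biostrings::nmismatch(aln)
  total <- -Biostrings::score(aln)
  c(mismatches = mm, gap_columns = round(total - mm))
}

#' Build the subtype graph over consensus sequences
#'
#' Nodes are complete consensus sequences; edges connect pairs with
#' mismatches + gap columns <= `threshold` (default 4). Connected components
#' are the subtypes; each reports the lexicographically smallest member
#' sequence as representative.
#'
#' @param consensuses named character vector of complete sequences.
#' @param threshold edge threshold on the total distance.
#' @return list with `$membership`, `$n_components`, `$edges`,
#'   `$representatives`.
#' @export
build_subtype_graph <- function(consensuses, threshold = 4) {
  n <- length(consensuses)
  if (n == 0L)
    return(list(membership = setNames(integer(0), character(0)),
                n_components = 0L, edges = NULL,
                representatives = character(0)))
  if (is.null(names(consensuses)))
    names(consensuses) <- paste0("seq", seq_len(n))
  edges <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- pairwise_distance(consensuses[i], consensuses[j])
      if (sum(d) <= threshold)
        edges[[length(edges) + 1L]] <- data.frame(
          from = names(consensuses)[i], to = names(consensuses)[j],
          mismatches = d[1], gap_columns = d[2], distance = sum(d))
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  g <- igraph::graph_from_data_frame(
    edges %||% data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = names(consensuses)))
  comp <- igraph::components(g)
  membership <- comp$membership[names(consensuses)]
  reps <- vapply(seq_len(comp$no), function(k) {
    members <- names(membership)[membership == k]
    members[order(consensuses[members])][1]
  }, "")
  list(membership = membership, n_components = comp$no, edges = edges,
       representatives = reps)
}

#' Greedy overlap assembly of locus reads
#'
#' Stand-in for a de Bruijn assembler at desk scale: starting from the first
#' read, the contig is extended on both ends by reads (either orientation)
#' sharing an exact overlap of at least `min_overlap` bases. With error-free
#' reads tiling the locus this reconstructs the inserted element plus flank
#' stubs exactly. Supplying `reference` and `locus` trims the flanks to the
#' TSD-bounded element and sets the completeness flag (both flank anchors
#' recovered, i.e. no coverage gap).
#'
#' @param locus_reads reads assigned to one locus (character vector).
#' @param min_overlap exact-overlap length for merging.
#' @param reference,locus optional reference chromosomes and [known_locus()]
#'   used to trim flanks.
#' @param anchor flank anchor length used for trimming.
#' @return object of class `consensus_sequence` with `$sequence`,
#'   `$complete`, `$n_reads`.
#' @export
assemble_locus_consensus <- function(locus_reads, min_overlap = 20L,
                                     reference = NULL, locus = NULL,
                                     anchor = 20L) {
  locus_reads <- unique(toupper(as.character(locus_reads)))
  if (!length(locus_reads)) stop("zero reads supplied for assembly")
  pool <- unique(c(locus_reads, revcomp_chr(locus_reads)))
  contig <- pool[1]
  extend <- function(contig, right) {
    repeat {
      key <- if (right) substr(contig, nchar(contig) - min_overlap + 1L,
                               nchar(contig)) else
        substr(contig, 1L, min_overlap)
      pos <- regexpr(key, pool, fixed = TRUE)
      cand <- which(pos > 0)
      best_ext <- ""
      for (i in cand) {
        p <- pos[i]
        r <- pool[i]
        if (right) {
          ov <- p + min_overlap - 1L          # read prefix that must match
          if (ov > nchar(contig)) next
          if (substr(r, 1L, ov) !=
              substr(contig, nchar(contig) - ov + 1L, nchar(contig))) next
          ext <- substr(r, ov + 1L, nchar(r))
        } else {
          ov <- nchar(r) - p + 1L             # read suffix that must match
          if (ov > nchar(contig)) next
          if (substr(r, p, nchar(r)) != substr(contig, 1L, ov)) next
          ext <- substr(r, 1L, p - 1L)
        }
        if (nchar(ext) > nchar(best_ext)) best_ext <- ext
      }
      if (!nchar(best_ext)) break
      contig <- if (right) paste0(contig, best_ext) else
        paste0(best_ext, contig)
    }
    contig
  }
  contig <- extend(contig, right = TRUE)
  contig <- extend(contig, right = FALSE)
  out <- structure(list(sequence = contig, complete = NA,
                        n_reads = length(locus_reads)),
                   class = "consensus_sequence")
  if (!is.null(reference) && !is.null(locus)) {
    la <- ref_window(reference, locus$chrom, locus$tsd_end - anchor + 1L,
                     locus$tsd_end)
    ra <- ref_window(reference, locus$chrom, locus$tsd_start,
                     locus$tsd_start + anchor - 1L)
    hit <- function(ctg) {
      i <- regexpr(la, ctg, fixed = TRUE)
      if (i < 0) return(NULL)
      j <- regexpr(ra, substr(ctg, i + anchor, nchar(ctg)), fixed = TRUE)
      if (j < 0) return(NULL)
      substr(ctg, i + anchor, i + anchor + j - 2L)
    }
    el <- hit(contig)
    if (is.null(el))
      el <- hit(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(contig))))
    if (is.null(el) || !nchar(el)) {
      out$complete <- FALSE
    } else {
      out$sequence <- el
      out$complete <- TRUE
    }
  }
  out
}

# Deletions (parent coordinates) and point mutations observed when aligning
# a derived sequence back to its parent. Affine gap costs keep each excised
# interval as one contiguous gap; canonical subtypes are mapped through the
# same procedure so breakpoint comparisons are internally consistent.
observed_deletions <- function(seqs, parent) {
  pseq <- if (inherits(parent, "te_element")) parent$sequence else parent
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(seqs)), Biostrings::DNAString(pseq),
    type = "global", substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  su <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ppos <- cumsum(su != "-")
  is_del <- pa == "-" & su != "-"
  dels <- list()
  r <- rle(is_del)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k])
      dels[[length(dels) + 1L]] <- c(ppos[starts[k]], ppos[ends[k]])
  }
  mut_cols <- which(pa != "-" & su != "-" & pa != su)
  muts <- lapply(mut_cols, function(cc) list(ppos[cc], pa[cc]))
  list(deletions = dels, mutations = muts)
}

#' Assign a canonical subtype label to a consensus
#'
#' The consensus and each canonical subtype are aligned to the parent
#' element; the label is the canonical subtype whose deletion breakpoints
#' all match and whose point mutations are present. No match gives
#' `"novel"`; multiple matches are broken by fewest total differences to the
#' canonical sequence, with persistent ties labelled `"ambiguous"`.
#'
#' @param consensus a `consensus_sequence` or nucleotide string.
#' @param canonical_subtypes list of `te_subtype` objects
#'   ([canonical_mping_subtypes()]).
#' @param parent parent `te_element` (Ping16G).
#' @return list with `$label`, `$breakpoints` (observed deletions),
#'   `$mutations`.
#' @export
assign_canonical <- function(consensus, canonical_subtypes, parent) {
  seqs <- if (inherits(consensus, "consensus_sequence")) consensus$sequence
  else toupper(as.character(consensus))
  obs <- observed_deletions(seqs, parent)
  key <- function(d) paste(vapply(d, function(x) paste0(x[1], "-", x[2]), ""),
                           collapse = ";")
  obs_key <- key(obs$deletions)
  obs_muts <- vapply(obs$mutations, function(m) paste0(m[[1]], m[[2]]), "")
  hits <- character(0)
  for (cs in canonical_subtypes) {
    cobs <- observed_deletions(cs$sequence, parent)
    if (key(cobs$deletions) != obs_key) next
    cmuts <- vapply(cs$defn$point_mutations,
                    function(m) paste0(m[[1]], m[[2]]), character(1))
    if (all(cmuts %in% obs_muts)) hits <- c(hits, cs$id)
  }
  label <- if (!length(hits)) "novel" else if (length(hits) == 1L) hits else {
    d <- vapply(hits, function(h) {
      cs <- canonical_subtypes[[which(vapply(canonical_subtypes, `[[`, "",
                                             "id") == h)]]
      sum(pairwise_distance(seqs, cs$sequence))
    }, numeric(1))
    best <- hits[d == min(d)]
    if (length(best) == 1L) best else {
      message("ambiguous canonical assignment: ",
              paste(best, collapse = ", "))
      "ambiguous"
    }
  }
  list(label = label, breakpoints = obs$deletions, mutations = obs$mutations)
}

#' Detect subtypes from breakpoint-spanning reads
#'
#' Low-depth mode: reads are aligned to the canonical subtype sequences with
#' the <= 2 mismatch filter, and a subtype is reported present when at least
#' `min_reads` span its diagnostic breakpoint with `min_overhang` bases on
#' each side.
#'
#' @param reads accession reads.
#' @param canonical_subtypes list of `te_subtype` objects with breakpoints.
#' @param min_reads spanning reads required (2).
#' @param max_mismatch placement filter.
#' @param min_overhang bases required on each side of the breakpoint.
#' @return character vector of subtype ids present.
#' @export
detect_subtype_by_breakpoint_reads <- function(reads, canonical_subtypes,
                                               min_reads = 2L,
                                               max_mismatch = 2L,
                                               min_overhang = 10L) {
  reads <- as_read_chr(reads)
  if (!length(reads)) return(character(0))
  targets <- vapply(canonical_subtypes, `[[`, "", "sequence")
  names(targets) <- vapply(canonical_subtypes, `[[`, "", "id")
  present <- character(0)
  for (nm in names(targets)) {
    idx <- te_index(targets[nm], min_read_length = min(nchar(reads)))
    aln <- align_reads(reads, index = idx, max_mismatch = max_mismatch)
    cs <- canonical_subtypes[[which(names(targets) == nm)]]
    for (bp in cs$breakpoints) {
      nspan <- sum(aln$start <= bp - min_overhang + 1L &
                   aln$end >= bp + min_overhang)
      if (nspan >= min_reads) { present <- c(present, nm); break }
    }
  }
  present
}

#' Orient a sequence to match a template
#'
#' Returns the sequence or its reverse complement, whichever has the smaller
#' alignment distance to the template (insertions are simulated on either
#' strand).
#' @param seqs nucleotide string.
#' @param template orientation reference (e.g. the mPing template).
#' @export
orient_sequence <- function(seqs, template) {
  tmpl <- if (inherits(template, "te_element")) template$sequence else template
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqs)))
  if (sum(pairwise_distance(seqs, tmpl)) <=
      sum(pairwise_distance(rc, tmpl))) seqs else rc
}
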