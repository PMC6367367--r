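# Element templates, subtype definitions and known loci.
#
# Coordinates are 1-based inclusive throughout. An element template carries
# the full-length sequence, its terminal-inverted-repeat (TIR) length, the
# diagnostic internal region used to discriminate autonomous elements from
# their deletion derivatives, the base at position +16 (the G/A SNP that
# separates Ping16G from Ping16A), and the "comparable" region over which
# read-depth copy numbers are computed.

revcomp_chr <- function(x) {
  if (!length(x)) return(character(0))
  as.character(cpp_revcomp(as.character(x)))
}

#' Create and validate an element template
#'
#' @param id element name.
#' @param sequence nucleotide string (A/C/G/T).
#' @param tir_length terminal inverted repeat length in bp (15 for the
#'   mPing/Ping family); use 0 for elements without enforced TIRs.
#' @param internal_region optional `c(start, end)` of the diagnostic internal
#'   region, 1-based inclusive.
#' @param snp16_base optional expected base at position 16.
#' @param comparable_region optional `c(start, end)` used for copy-number
#'   windows.
#' @return an object of class `te_element`.
#' @export
element_template <- function(id, sequence, tir_length = 15L,
                             internal_region = NULL, snp16_base = NULL,
                             comparable_region = NULL) {
  sequence <- toupper(as.character(sequence))
  len <- nchar(sequence)
  if (len < 2L * tir_length)
    stop("element '", id, "': sequence shorter than twice the TIR length")
  if (tir_length > 0L) {
    head5 <- substr(sequence, 1L, tir_length)
    tail3 <- substr(sequence, len - tir_length + 1L, len)
    if (revcomp_chr(tail3) != head5)
      stop("element '", id, "': first ", tir_length,
           " bases are not the reverse complement of the last ", tir_length,
           " bases (TIR invariant violated)")
  }
  if (!is.null(internal_region)) {
    if (!(internal_region[1] >= 1 && internal_region[1] < internal_region[2] &&
          internal_region[2] <= len))
      stop("element '", id, "': internal region outside 1..", len,
           " (internal-region invariant violated)")
  }
  if (!is.null(snp16_base) && substr(sequence, 16L, 16L) != snp16_base)
    stop("element '", id, "': base at position 16 is not ", snp16_base)
  structure(list(id = id, sequence = sequence, length = len,
                 tir_length = as.integer(tir_length),
                 internal_region = internal_region,
                 snp16_base = snp16_base,
                 comparable_region = comparable_region),
            class = "te_element")
}

#' @export
print.te_element <- function(x, ...) {
  cat("<te_element>", x$id, "-", x$length, "bp; TIR", x$tir_length, "bp")
  if (!is.null(x$internal_region))
    cat("; internal", x$internal_region[1], "-", x$internal_region[2])
  if (!is.null(x$snp16_base)) cat("; +16", x$snp16_base)
  cat("\n")
  invisible(x)
}

random_dna <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

impose_tir <- function(seq, tir_length = 15L) {
  len <- nchar(seq)
  head5 <- substr(seq, 1L, tir_length)
  paste0(substr(seq, 1L, len - tir_length), revcomp_chr(head5))
}

#' Default element templates
#'
#' Returns templates for mPing, Ping16G, Ping16A, Pong and Stowaway. Without
#' a FASTA the sequences are parametric stand-ins generated from a fixed
#' internal seed: Ping16G is a random 5341-bp sequence with 15-bp TIRs and a
#' G at position 16; mPing (430 bp) is its internal-deletion derivative made
#' of Ping positions 1-252 and 5164-5341, so the two share both termini;
#' Ping16A differs from Ping16G only by G->A at position 16; Pong (5341 bp)
#' and Stowaway (770 bp) are independent TIR sequences. Diagnostic internal
#' regions are Ping 253-5164 and Pong 23-5320; copy-number comparable regions
#' are mPing 1-430 and Ping/Pong 260-3260.
#'
#' @param config optional path to a FASTA holding sequences named
#'   mPing/Ping16G/Ping16A/Pong/Stowaway that override the generated ones.
#' @return named list of [element_template()] objects.
#' @export
build_default_elements <- function(config = NULL) {
  if (is.null(config)) {
    seqs <- with_seed(1868L, {
      ping <- impose_tir(random_dna(5341))
      substr(ping, 16L, 16L) <- "G"
      pong <- impose_tir(random_dna(5341))
      stow <- impose_tir(random_dna(770))
      list(Ping16G = ping, Pong = pong, Stowaway = stow)
    })
    ping <- seqs$Ping16G
    ping_a <- ping
    substr(ping_a, 16L, 16L) <- "A"
    mping <- paste0(substr(ping, 1L, 252L), substr(ping, 5164L, 5341L))
    seqs <- c(list(mPing = mping, Ping16A = ping_a), seqs)
  } else {
    ss <- Biostrings::readDNAStringSet(config)
    need <- c("mPing", "Ping16G", "Ping16A", "Pong", "Stowaway")
    miss <- setdiff(need, names(ss))
    if (length(miss))
      stop("element FASTA missing sequences: ", paste(miss, collapse = ", "))
    seqs <- as.list(as.character(ss[need]))
  }
  els <- list(
    mPing = element_template("mPing", seqs$mPing, tir_length = 15L,
                             snp16_base = substr(seqs$mPing, 16, 16),
                             comparable_region = c(1L, 430L)),
    Ping16G = element_template("Ping16G", seqs$Ping16G, tir_length = 15L,
                               internal_region = c(253L, 5164L),
                               snp16_base = "G",
                               comparable_region = c(260L, 3260L)),
    Ping16A = element_template("Ping16A", seqs$Ping16A, tir_length = 15L,
                               internal_region = c(253L, 5164L),
                               snp16_base = "A",
                               comparable_region = c(260L, 3260L)),
    Pong = element_template("Pong", seqs$Pong, tir_length = 15L,
                            internal_region = c(23L, 5320L),
                            comparable_region = c(260L, 3260L)),
    Stowaway = element_template("Stowaway", seqs$Stowaway, tir_length = 15L)
  )
  d16 <- which(strsplit(els$Ping16G$sequence, "")[[1]] !=
               strsplit(els$Ping16A$sequence, "")[[1]])
  if (!identical(d16, 16L))
    stop("Ping16A and Ping16G must differ at exactly position 16")
  shared <- c(substr(els$Ping16G$sequence, 1, 252),
              substr(els$Ping16G$sequence, 5164, 5341))
  if (paste0(shared[1], shared[2]) != els$mPing$sequence &&
      !is.null(config))
    warning("mPing is not an exact terminal derivative of Ping16G in ", config)
  els
}

#' Write element templates to FASTA
#' @param elements named list of `te_element`s.
#' @param path output FASTA path.
#' @export
write_elements_fasta <- function(elements, path) {
  ss <- Biostrings::DNAStringSet(vapply(elements, `[[`, "", "sequence"))
  names(ss) <- vapply(elements, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Define a subtype as deletions plus point mutations of a parent element
#'
#' @param id subtype name (e.g. mPingA).
#' @param parent parent element id.
#' @param deletions list of `c(start, end)` 1-based inclusive intervals
#'   removed from the parent; must be disjoint.
#' @param point_mutations list of `c(position, base)` pairs (position in
#'   parent coordinates, applied after checking it survives the deletions).
#' @return object of class `subtype_definition`.
#' @export
subtype_definition <- function(id, parent, deletions = list(),
                               point_mutations = list()) {
  if (length(deletions)) {
    m <- do.call(rbind, lapply(deletions, as.integer))
    if (any(m[, 1] > m[, 2])) stop("deletion start > end")
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
      stop("overlapping deletion intervals")
    deletions <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  }
  structure(list(id = id, parent = parent, deletions = deletions,
                 point_mutations = point_mutations),
            class = "subtype_definition")
}

#' Derive a subtype sequence from its parent
#'
#' Excises the deletion intervals, applies point mutations, and records the
#' breakpoint positions (the junction base preceding each excised interval,
#' in derived coordinates) for later subtype assignment.
#'
#' @param parent a `te_element` (or nucleotide string).
#' @param defn a [subtype_definition()].
#' @return object of class `te_subtype` with `$sequence`, `$breakpoints`
#'   (derived coordinates), `$defn`.
#' @export
derive_subtype <- function(parent, defn) {
  pseq <- if (inherits(parent, "te_element")) parent$sequence else
    toupper(as.character(parent))
  plen <- nchar(pseq)
  dels <- defn$deletions
  if (length(dels)) {
    m <- do.call(rbind, lapply(dels, as.integer))
    if (any(m[, 1] < 1) || any(m[, 2] > plen))
      stop("deletion interval outside the parent sequence")
  }
  keep <- rep(TRUE, plen)
  for (d in dels) keep[d[1]:d[2]] <- FALSE
  bases <- strsplit(pseq, "")[[1]]
  for (pm in defn$point_mutations) {
    pos <- as.integer(pm[[1]])
    if (!keep[pos]) stop("point mutation at a deleted position ", pos)
    bases[pos] <- toupper(as.character(pm[[2]]))
  }
  derived <- paste(bases[keep], collapse = "")
  # breakpoint = index (derived coords) of the base just before each deletion
  cum <- cumsum(keep)
  bps <- vapply(dels, function(d) if (d[1] == 1L) 0L else cum[d[1] - 1L],
                integer(1))
  exp_len <- plen - sum(vapply(dels, function(d) d[2] - d[1] + 1L, integer(1)))
  stopifnot(nchar(derived) == exp_len)
  structure(list(id = defn$id, parent = defn$parent, sequence = derived,
                 breakpoints = as.integer(bps), defn = defn),
            class = "te_subtype")
}

#' Canonical mPing subtype definitions
#'
#' The four canonical subtypes (mPingA-D) are distinct internal-deletion
#' derivatives of Ping. Their exact breakpoints are configurable placeholders
#' here: each removes a 4911-bp interval from Ping16G (so all are 430 bp),
#' staggered by 18 bp so that any two subtypes differ by clearly more than
#' the 4-difference graph threshold. mPingC uses the 253-5163 interval,
#' which makes it identical to the default mPing template.
#'
#' @param elements element set from [build_default_elements()].
#' @param starts deletion start positions for mPingA-D.
#' @return named list of `te_subtype` objects.
#' @export
canonical_mping_subtypes <- function(elements,
                                     starts = c(mPingA = 217L, mPingB = 235L,
                                                mPingC = 253L, mPingD = 271L)) {
  parent <- elements$Ping16G
  out <- lapply(names(starts), function(nm) {
    s <- starts[[nm]]
    derive_subtype(parent, subtype_definition(nm, parent$id,
                                              list(c(s, s + 4910L))))
  })
  names(out) <- names(starts)
  out
}

#' A known element locus
#'
#' @param chrom chromosome id.
#' @param tsd_start,tsd_end 1-based inclusive target-site-duplication
#'   coordinates; swapped into ascending order if needed.
#' @param element element id at the locus.
#' @param label free-text label.
#' @export
known_locus <- function(chrom, tsd_start, tsd_end, element, label = "") {
  lo <- min(tsd_start, tsd_end); hi <- max(tsd_start, tsd_end)
  structure(list(chrom = chrom, tsd_start = as.integer(lo),
                 tsd_end = as.integer(hi), element = element, label = label),
            class = "known_locus")
}

#' Write subtype definitions to a TSV sidecar
#' @param defs list of `subtype_definition` or `te_subtype` objects.
#' @param path output path.
#' @export
write_subtypes_tsv <- function(defs, path) {
  rows <- lapply(defs, function(d) {
    if (inherits(d, "te_subtype")) d <- d$defn
    data.frame(id = d$id, parent = d$parent,
               deletions = paste(vapply(d$deletions, function(x)
                 paste0(x[1], "-", x[2]), ""), collapse = ","),
               mutations = paste(vapply(d$point_mutations, function(x)
                 paste0(x[[1]], x[[2]]), ""), collapse = ","))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
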