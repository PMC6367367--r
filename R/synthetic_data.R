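# Synthetic genomes and paired-end libraries with known element insertions.
#
# The generator emulates the study libraries: ~500-bp inserts, 100-bp reads,
# 14x coverage by default at the cohort level, genomes carrying 0-1000
# element copies, TA-rich target preference, and the nested Ping-in-Stowaway
# structure. Truth tables are kept in reference coordinates so downstream
# calls can be scored against them.

#' Simulate a reference genome
#'
#' @param n_chrom number of chromosomes.
#' @param length_per_chrom chromosome length in bp (>= 10 kb recommended).
#' @param gc_fraction target GC content.
#' @param seed RNG seed; the result is reproducible given the seed.
#' @return object of class `sim_genome` with `$ref` (named character vector
#'   of chromosome sequences), `$events` (empty truth table) and provenance.
#' @export
simulate_genome <- function(n_chrom = 1L, length_per_chrom = 100000L,
                            gc_fraction = 0.44, seed = 1L) {
  if (length_per_chrom <= 0) stop("length_per_chrom must be positive")
  if (length_per_chrom < 10000) warning("genome shorter than 10 kb")
  ref <- with_seed(seed, {
    vapply(seq_len(n_chrom), function(i) random_dna(length_per_chrom,
                                                    gc_fraction), "")
  })
  names(ref) <- paste0("chr", seq_len(n_chrom))
  structure(list(ref = ref, events = empty_events(),
                 seed = seed, gc = gc_fraction),
            class = "sim_genome")
}

empty_events <- function() {
  data.frame(chrom = character(), position = integer(), element = character(),
             strand = character(), tsd = character(), tsd_start = integer(),
             tsd_end = integer(), nested_in = character(), seq = character(),
             stringsAsFactors = FALSE)
}

element_seq_id <- function(element) {
  if (inherits(element, "te_element") || inherits(element, "te_subtype"))
    list(id = element$id, seq = element$sequence)
  else list(id = attr(element, "id") %||% "element",
            seq = toupper(as.character(element)))
}

#' Insert element copies into a simulated genome
#'
#' The element is inserted immediately after the sampled position and the
#' preceding `tsd_len` bases are duplicated (target-site duplication). Truth
#' coordinates are reported in reference coordinates, 1-based inclusive.
#' Insertion points are kept at least `min_spacing` bp apart so junction
#' evidence from distinct loci stays separable. Under `at_rich_9bp` candidate
#' sites are weighted by the AT fraction of the surrounding 9 bp, with a
#' bonus for TTA/TAA (or TA) duplications, reflecting the family's AT-rich
#' target preference.
#'
#' @param genome a `sim_genome`.
#' @param element a `te_element`, `te_subtype` or nucleotide string.
#' @param n_copies number of new insertions (>= 0).
#' @param target_model `"uniform"` or `"at_rich_9bp"`.
#' @param seed RNG seed.
#' @param tsd_len target-site duplication length; default 2 for Stowaway and
#'   3 for the mPing/Ping/Pong family.
#' @param min_spacing minimum distance between insertion points.
#' @param margin distance kept free at chromosome ends.
#' @return the updated `sim_genome`.
#' @export
insert_elements <- function(genome, element, n_copies,
                            target_model = c("uniform", "at_rich_9bp"),
                            seed = 1L, tsd_len = NULL, min_spacing = 200L,
                            margin = 600L) {
  target_model <- match.arg(target_model)
  es <- element_seq_id(element)
  if (is.null(tsd_len))
    tsd_len <- if (identical(es$id, "Stowaway")) 2L else 3L
  n_copies <- as.integer(n_copies)
  if (n_copies < 0) stop("n_copies must be >= 0")
  if (n_copies == 0L) return(genome)
  with_seed(seed, {
    lens <- nchar(genome$ref)
    picks <- vector("list", length(lens))
    chroms <- sample(names(lens), n_copies, replace = TRUE,
                     prob = lens / sum(lens))
    n_by <- table(factor(chroms, levels = names(lens)))
    new_rows <- list()
    for (ci in seq_along(lens)) {
      need <- as.integer(n_by[[ci]])
      if (need == 0L) next
      L <- lens[[ci]]
      lo <- max(margin, tsd_len + 5L); hi <- L - margin
      if (hi <= lo) stop("n_copies exceeds available target sites")
      existing <- genome$events$position[genome$events$chrom == names(lens)[ci]]
      if (target_model == "at_rich_9bp") {
        at <- as.integer(Biostrings::letterFrequencyInSlidingView(
          Biostrings::DNAString(genome$ref[[ci]]), 9L, "AT"))
        # window centred on the insertion point p covers p-4 .. p+4
        w <- numeric(L)
        w[5:(L - 4L)] <- at / 9
        w[seq_len(lo - 1L)] <- 0; if (hi < L) w[(hi + 1L):L] <- 0
        tsd_at <- substring(genome$ref[[ci]],
                            seq_len(L) - tsd_len + 1L, seq_len(L))
        pref <- if (tsd_len == 2L) c("TA") else c("TTA", "TAA")
        w <- w * ifelse(tsd_at %in% pref, 3, 1)
        cand_pool <- which(w > 0)
        if (!length(cand_pool)) stop("n_copies exceeds available target sites")
        weights <- w[cand_pool]
      } else {
        cand_pool <- lo:hi
        weights <- NULL
      }
      got <- integer(0)
      for (round in 1:60) {
        take <- min(length(cand_pool), max(4L * need, 32L))
        cand <- sample(cand_pool, take, prob = weights)
        for (p in cand) {
          if (length(got) >= need) break
          if (all(abs(c(existing, got) - p) >= min_spacing) || (
            length(existing) + length(got) == 0L))
            got <- c(got, p)
        }
        if (length(got) >= need) break
      }
      if (length(got) < need) stop("n_copies exceeds available target sites")
      picks[[ci]] <- sort(got[seq_len(need)])
      tsd <- substring(genome$ref[[ci]], picks[[ci]] - tsd_len + 1L,
                       picks[[ci]])
      new_rows[[ci]] <- data.frame(
        chrom = names(lens)[ci], position = picks[[ci]], element = es$id,
        strand = sample(c("+", "-"), need, replace = TRUE), tsd = tsd,
        tsd_start = picks[[ci]] - tsd_len + 1L, tsd_end = picks[[ci]],
        nested_in = NA_character_, seq = es$seq, stringsAsFactors = FALSE)
    }
    genome$events <- rbind(genome$events, do.call(rbind, new_rows))
    genome$events <- genome$events[order(genome$events$chrom,
                                         genome$events$position), ]
    rownames(genome$events) <- NULL
    genome
  })
}

#' Insert an element inside an already-inserted host element
#'
#' Models the Ping16A_Stow structure: an inner element (Ping16A) inserted
#' after position `inner_position` of a host (Stowaway) already present in
#' the truth table, duplicating the host's preceding `tsd_len` bases. The
#' resulting host copy reads host[1..p] + inner + host[p-tsd_len+1..p] +
#' host[p+1..end].
#'
#' @param genome a `sim_genome` whose truth contains the host.
#' @param host_locus optional [known_locus()]; defaults to the first host
#'   element insertion matching `host_element`.
#' @param inner_element element to nest (e.g. Ping16A).
#' @param inner_position host position after which the inner copy sits.
#' @param tsd_len duplication length for the inner insertion (3 for Ping).
#' @param host_element host element id used when `host_locus` is `NULL`.
#' @return the updated `sim_genome`.
#' @export
insert_nested <- function(genome, host_locus = NULL, inner_element,
                          inner_position = 305L, tsd_len = 3L,
                          host_element = "Stowaway") {
  ev <- genome$events
  idx <- if (!is.null(host_locus)) {
    which(ev$chrom == host_locus$chrom & ev$tsd_start == host_locus$tsd_start &
          ev$tsd_end == host_locus$tsd_end)
  } else {
    which(ev$element == host_element & is.na(ev$nested_in))
  }
  if (!length(idx)) stop("host locus absent from the truth table")
  idx <- idx[1]
  host <- ev[idx, ]
  es <- element_seq_id(inner_element)
  S <- host$seq
  p <- as.integer(inner_position)
  if (p < tsd_len || p >= nchar(S)) stop("inner_position outside the host")
  tsd <- substr(S, p - tsd_len + 1L, p)
  nested <- paste0(substr(S, 1L, p), es$seq, tsd,
                   substr(S, p + 1L, nchar(S)))
  genome$events$seq[idx] <- nested
  genome$events <- rbind(genome$events, data.frame(
    chrom = host$chrom, position = host$position, element = es$id,
    strand = host$strand, tsd = tsd, tsd_start = host$tsd_start,
    tsd_end = host$tsd_end,
    nested_in = paste0(host$element, ":", host$chrom, ":", host$tsd_start,
                       "-", host$tsd_end),
    seq = es$seq, stringsAsFactors = FALSE))
  rownames(genome$events) <- NULL
  genome
}

#' Materialize a simulated genome's chromosome sequences
#'
#' Applies every truth insertion (element plus duplicated target site) to the
#' reference. Length of each chromosome grows by element length + TSD length
#' per insertion.
#'
#' @param genome a `sim_genome`.
#' @return named character vector of mutated chromosome sequences.
#' @export
materialize_genome <- function(genome) {
  out <- genome$ref
  ev <- genome$events[is.na(genome$events$nested_in), , drop = FALSE]
  for (ch in unique(ev$chrom)) {
    rows <- ev[ev$chrom == ch, , drop = FALSE]
    rows <- rows[order(rows$position), , drop = FALSE]
    refseq <- genome$ref[[ch]]
    pieces <- character(2L * nrow(rows) + 1L)
    prev <- 0L
    for (i in seq_len(nrow(rows))) {
      p <- rows$position[i]
      ins <- if (rows$strand[i] == "-") revcomp_chr(rows$seq[i]) else
        rows$seq[i]
      pieces[2L * i - 1L] <- substr(refseq, prev + 1L, p)
      pieces[2L * i] <- paste0(ins, rows$tsd[i])
      prev <- p
    }
    pieces[2L * nrow(rows) + 1L] <- substr(refseq, prev + 1L, nchar(refseq))
    out[[ch]] <- paste(pieces, collapse = "")
  }
  out
}

inject_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  lens <- nchar(reads)
  nerr <- rbinom(length(reads), lens, rate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, old), 1L)
    }
  }
  reads
}

#' Simulate a paired-end library
#'
#' Draws `round(coverage * genome_length / (2 * read_length))` fragments with
#' normally distributed insert sizes, emits forward/reverse 100-bp mates by
#' default, applies per-base substitution errors, and records true origins.
#'
#' @param genome a `sim_genome` or named character vector of sequences.
#' @param coverage requested mean genome coverage (> 0).
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment-size distribution; a warning is
#'   issued when `insert_mean <= 2 * read_length` because short inserts
#'   prevent discriminating Ping/Pong from mPing.
#' @param error_rate per-base substitution rate.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @param id_prefix read-name prefix.
#' @return object of class `read_pairs` with `$r1`, `$r2`, `$id`, `$origin`.
#' @export
simulate_reads <- function(genome, coverage, read_length = 100L,
                           insert_mean = 500, insert_sd = 50,
                           error_rate = 0.001, seed = 1L,
                           id_prefix = "sim") {
  seqs <- if (inherits(genome, "sim_genome")) materialize_genome(genome) else
    genome
  if (coverage <= 0) stop("coverage must be > 0")
  if (insert_mean <= 2 * read_length)
    warning("insert_mean <= 2 * read_length: short inserts prevent ",
            "discriminating Ping and Pong insertions from mPing")
  lens <- nchar(seqs)
  total <- sum(lens)
  n_pairs <- as.integer(round(coverage * total / (2 * read_length)))
  with_seed(seed, {
    if (n_pairs == 0L) {
      return(structure(list(r1 = character(), r2 = character(),
                            id = character(), origin = NULL,
                            read_length = read_length,
                            insert_mean = insert_mean, insert_sd = insert_sd,
                            error_rate = error_rate, coverage = coverage,
                            genome_length = total), class = "read_pairs"))
    }
    chrom <- sample(names(lens), n_pairs, replace = TRUE,
                    prob = lens / total)
    flen <- pmax(read_length, round(rnorm(n_pairs, insert_mean, insert_sd)))
    flen <- pmin(flen, lens[chrom])
    start <- floor(runif(n_pairs) * (lens[chrom] - flen + 1)) + 1L
    fwd <- rev_ <- character(n_pairs)
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      fwd[sel] <- substring(seqs[[ch]], start[sel],
                            start[sel] + read_length - 1L)
      rev_[sel] <- substring(seqs[[ch]], start[sel] + flen[sel] - read_length,
                             start[sel] + flen[sel] - 1L)
    }
    rev_ <- revcomp_chr(rev_)
    fwd <- inject_errors(fwd, error_rate)
    rev_ <- inject_errors(rev_, error_rate)
    swap <- runif(n_pairs) < 0.5
    r1 <- fwd; r1[swap] <- rev_[swap]
    r2 <- rev_; r2[swap] <- fwd[swap]
    origin <- data.frame(
      chrom = chrom, frag_start = start, frag_end = start + flen - 1L,
      m1_start = ifelse(swap, start + flen - read_length, start),
      m1_strand = ifelse(swap, "-", "+"),
      m2_start = ifelse(swap, start, start + flen - read_length),
      m2_strand = ifelse(swap, "+", "-"), stringsAsFactors = FALSE)
    structure(list(r1 = r1, r2 = r2,
                   id = paste0(id_prefix, "_", seq_len(n_pairs)),
                   origin = origin, read_length = read_length,
                   insert_mean = insert_mean, insert_sd = insert_sd,
                   error_rate = error_rate, coverage = coverage,
                   genome_length = total), class = "read_pairs")
  })
}

#' All reads of a pair set as one character vector (r1 then r2)
#' @param rp a `read_pairs` object.
#' @export
all_reads <- function(rp) c(rp$r1, rp$r2)

#' Write a read pair set as paired FASTQ files
#' @param rp a `read_pairs` object.
#' @param prefix output prefix; writes `<prefix>_1.fastq`, `<prefix>_2.fastq`.
#' @param quality_char constant base-quality character (default Q30).
#' @export
write_read_pairs <- function(rp, prefix, quality_char = "?") {
  for (mate in 1:2) {
    reads <- if (mate == 1) rp$r1 else rp$r2
    ss <- Biostrings::DNAStringSet(reads)
    names(ss) <- paste0(rp$id, "/", mate)
    qual <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
    Biostrings::writeXStringSet(ss, paste0(prefix, "_", mate, ".fastq"),
                                format = "fastq", qualities = qual)
  }
  invisible(prefix)
}

#' Simulate a cohort of accessions over a shared reference
#'
#' Each accession receives its configured mPing/Ping/Pong copies (Ping as the
#' chosen 16G/16A variant), optionally the Stowaway host at a fixed shared
#' locus and the nested Ping16A_Stow structure, and a paired-end library at
#' the configured coverage. One truth table per accession plus a cohort-level
#' aggregate are returned; FASTQ and truth TSV files are written when
#' `out_dir` is given.
#'
#' @param config data frame with columns `accession`, and optionally
#'   `mping` (copies), `ping` (copies), `ping_variant` ("16G"/"16A"),
#'   `pong` (copies), `stow` ("none"/"stowaway_only"/"ping16A_stow"),
#'   `coverage`.
#' @param elements element set from [build_default_elements()].
#' @param seed master RNG seed.
#' @param genome_length,gc_fraction shared reference parameters.
#' @param read_length,insert_mean,insert_sd,error_rate library parameters.
#' @param out_dir optional output directory for FASTQ + truth TSV.
#' @return list with `$reference` (`sim_genome` of the shared reference),
#'   `$stow_locus`, `$accessions` (per-accession genome/reads/truth), and
#'   `$truth` (cohort truth table).
#' @export
simulate_cohort <- function(config, elements, seed = 1L,
                            genome_length = 150000L, gc_fraction = 0.44,
                            read_length = 100L, insert_mean = 500,
                            insert_sd = 50, error_rate = 0,
                            out_dir = NULL) {
  if (anyDuplicated(config$accession))
    stop("duplicate accession ids in cohort config")
  n <- nrow(config)
  col <- function(nm, default) if (nm %in% names(config)) config[[nm]] else
    rep(default, n)
  mping <- col("mping", 0L); ping <- col("ping", 0L)
  variant <- col("ping_variant", "16A"); pong <- col("pong", 0L)
  stow <- col("stow", "none"); coverage <- col("coverage", 14)
  ref <- simulate_genome(1L, genome_length, gc_fraction, seed = seed)
  stow_pos <- as.integer(genome_length %/% 2)
  stow_locus <- known_locus("chr1", stow_pos - 1L, stow_pos, "Stowaway",
                            "stow_host")
  accessions <- list()
  truth <- list()
  for (i in seq_len(n)) {
    acc <- as.character(config$accession[i])
    g <- ref
    sub_seed <- (seed * 131L + i * 7L) %% 2000000000L
    if (!identical(stow[i], "none")) {
      # fixed shared host locus: insert the Stowaway after stow_pos
      tsd <- substr(g$ref[[1]], stow_pos - 1L, stow_pos)
      g$events <- rbind(g$events, data.frame(
        chrom = "chr1", position = stow_pos, element = "Stowaway",
        strand = "+", tsd = tsd, tsd_start = stow_pos - 1L,
        tsd_end = stow_pos, nested_in = NA_character_,
        seq = elements$Stowaway$sequence, stringsAsFactors = FALSE))
      if (identical(stow[i], "ping16A_stow"))
        g <- insert_nested(g, stow_locus, elements$Ping16A,
                           inner_position = 305L)
    }
    if (mping[i] > 0)
      g <- insert_elements(g, elements$mPing, mping[i], seed = sub_seed + 1L)
    if (ping[i] > 0) {
      pel <- if (identical(variant[i], "16G")) elements$Ping16G else
        elements$Ping16A
      g <- insert_elements(g, pel, ping[i], seed = sub_seed + 2L)
    }
    if (pong[i] > 0)
      g <- insert_elements(g, elements$Pong, pong[i], seed = sub_seed + 3L)
    reads <- simulate_reads(g, coverage = coverage[i],
                            read_length = read_length,
                            insert_mean = insert_mean, insert_sd = insert_sd,
                            error_rate = error_rate, seed = sub_seed + 4L,
                            id_prefix = acc)
    tt <- g$events
    tt <- if (nrow(tt)) cbind(accession = acc, tt[, names(tt) != "seq"]) else
      NULL
    accessions[[acc]] <- list(genome = g, reads = reads, truth = tt)
    truth[[acc]] <- tt
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_read_pairs(reads, file.path(out_dir, acc))
      if (!is.null(tt))
        write.table(tt, file.path(out_dir, paste0(acc, "_truth.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  truth <- do.call(rbind, truth[lengths(truth) > 0])
  if (!is.null(out_dir) && !is.null(truth))
    write.table(truth, file.path(out_dir, "cohort_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  list(reference = ref, stow_locus = stow_locus, accessions = accessions,
       truth = truth, config = config)
}
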