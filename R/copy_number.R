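# Window read-depth copy-number estimation.
#
# The element's comparable region (mPing 1-430; Ping/Pong 260-3260) is tiled
# with 50-bp windows overlapping by 40 bp. Each window's copy number is its
# mean per-position depth divided by the genome-wide mean depth, and the
# element copy number is the mean over windows. A one-sample t-test compares
# window depths with the genome mean.

#' Window specification over an element region
#' @param region_start,region_end 1-based inclusive element coordinates.
#' @param width window width (50 bp).
#' @param step distance between window starts (10 bp = 40 bp overlap).
#' @export
window_spec <- function(region_start, region_end, width = 50L, step = 10L) {
  if (!(width > step && step > 0)) stop("need width > step > 0")
  if (region_end - region_start + 1L < width)
    stop("region shorter than the window width")
  structure(list(region_start = as.integer(region_start),
                 region_end = as.integer(region_end),
                 width = as.integer(width), step = as.integer(step)),
            class = "window_spec")
}

#' Enumerate the windows of a specification
#'
#' Windows start at `region_start`, `region_start + step`, ...; when the last
#' grid window ends before `region_end`, one extra end-anchored window
#' `(region_end - width + 1, region_end)` is appended so every position is
#' covered.
#'
#' @param spec a [window_spec()].
#' @return data frame with columns `start`, `end`.
#' @export
make_windows <- function(spec) {
  starts <- seq(spec$region_start, spec$region_end - spec$width + 1L,
                by = spec$step)
  ends <- starts + spec$width - 1L
  if (ends[length(ends)] < spec$region_end) {
    starts <- c(starts, spec$region_end - spec$width + 1L)
    ends <- c(ends, spec$region_end)
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' One-sample t-test of window depths against the genome mean
#'
#' Degenerate zero-variance inputs short-circuit: t is +/-Inf with p = 0 when
#' the window mean differs from the genome mean, and t = 0 with p = 1 when
#' all windows equal it.
#'
#' @param window_depths per-window mean depths (>= 2 windows).
#' @param genome_mean genome-wide mean depth.
#' @return list with `t_statistic` and `p_value`.
#' @export
depth_ttest <- function(window_depths, genome_mean) {
  if (length(window_depths) < 2L) stop("need at least 2 windows")
  if (sd(window_depths) == 0) {
    m <- mean(window_depths)
    if (m == genome_mean) return(list(t_statistic = 0, p_value = 1))
    message("degenerate t-test: zero variance in window depths")
    return(list(t_statistic = sign(m - genome_mean) * Inf, p_value = 0))
  }
  tt <- t.test(window_depths, mu = genome_mean)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Estimate element copy number from a pileup profile
#'
#' @param profile `pileup_profile` over the element.
#' @param spec [window_spec()]; defaults to the element's comparable region.
#' @param genome_mean genome-wide mean depth (> 0).
#' @param element optional `te_element` supplying the default region.
#' @return object of class `copy_number_estimate` with `$value` (mean window
#'   ratio), `$rounded` (half away from zero), per-window values and the
#'   t-test.
#' @export
estimate_copy_number <- function(profile, spec = NULL, genome_mean,
                                 element = NULL) {
  if (genome_mean <= 0) stop("genome_mean must be > 0")
  if (is.null(spec)) {
    cr <- element$comparable_region %||% c(1L, profile$length)
    cr[2] <- min(cr[2], profile$length)
    spec <- window_spec(cr[1], cr[2])
  }
  w <- make_windows(spec)
  wd <- vapply(seq_len(nrow(w)), function(i)
    mean(profile$depth[w$start[i]:w$end[i]]), numeric(1))
  ratios <- wd / genome_mean
  tt <- depth_ttest(wd, genome_mean)
  value <- mean(ratios)
  structure(list(element = profile$target, value = value,
                 rounded = round_half_away(value, 0L),
                 window_values = ratios, window_depths = wd,
                 t_statistic = tt$t_statistic, p_value = tt$p_value,
                 n_windows = nrow(w), genome_mean = genome_mean),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat("<copy_number_estimate>", x$element, "=", signif(x$value, 4),
      "(", x$n_windows, "windows; t =", signif(x$t_statistic, 4),
      ", p =", format(x$p_value, digits = 3), ")\n")
  invisible(x)
}

#' Evaluate the read-depth estimator over a simulation grid
#'
#' Simulates genomes carrying known element copy numbers, paired-end
#' libraries at a range of depths, and re-estimates the copy number with the
#' window method, reporting the relative error per cell. The study grid is
#' copies {1,10,100,1000} x depths {1,2,3,4,5,10,20,40} x 3 replicates; the
#' defaults here reproduce it (call with reduced vectors for desk-scale
#' runs).
#'
#' @param copies true copy numbers to simulate.
#' @param depths sequencing depths.
#' @param replicates replicates per cell.
#' @param seed master seed.
#' @param genome_length reference length (single chromosome).
#' @param elements element set; the `element` id is inserted and estimated.
#' @param element element id to simulate (default mPing).
#' @param read_length,insert_mean,insert_sd,error_rate library parameters.
#' @param depth_cap pileup cap (the validation runs used a high cap).
#' @param verbose print per-cell progress.
#' @return data frame (copies, depth, replicate, estimate, rounded,
#'   rel_error, p_value).
#' @export
evaluate_simulation_grid <- function(copies = c(1, 10, 100, 1000),
                                     depths = c(1, 2, 3, 4, 5, 10, 20, 40),
                                     replicates = 3L, seed = 1L,
                                     genome_length = 1000000L,
                                     elements = build_default_elements(),
                                     element = "mPing", read_length = 100L,
                                     insert_mean = 500, insert_sd = 50,
                                     error_rate = 0.001, depth_cap = 100000L,
                                     verbose = FALSE) {
  el <- elements[[element]]
  spec <- window_spec(el$comparable_region[1], el$comparable_region[2])
  base <- simulate_genome(1L, genome_length, 0.44, seed = seed)
  gidx <- te_index(base$ref)
  rows <- list()
  counter <- 0L
  for (cp in copies) for (rep_ in seq_len(replicates)) {
    counter <- counter + 1L
    g <- insert_elements(base, el, cp,
                         seed = (seed * 977L + counter * 13L) %% 2e9)
    seqs <- materialize_genome(g)
    for (d in depths) {
      counter <- counter + 1L
      rp <- simulate_reads(seqs, coverage = d, read_length = read_length,
                           insert_mean = insert_mean, insert_sd = insert_sd,
                           error_rate = error_rate,
                           seed = (seed * 613L + counter * 29L) %% 2e9)
      gm <- genome_mean_depth(rp, gidx)
      prof <- element_profile(rp, el, depth_cap = depth_cap)
      est <- estimate_copy_number(prof, spec, genome_mean = gm)
      rows[[length(rows) + 1L]] <- data.frame(
        copies = cp, depth = d, replicate = rep_, estimate = est$value,
        rounded = est$rounded, rel_error = abs(est$value - cp) / cp,
        p_value = est$p_value)
      if (verbose)
        message(sprintf("copies=%d depth=%g rep=%d -> %.2f", cp, d, rep_,
                        est$value))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a simulation-grid table per cell
#' @param grid output of [evaluate_simulation_grid()].
#' @return per-cell mean/sd of the estimate and mean relative error.
#' @export
summarize_grid <- function(grid) {
  agg <- aggregate(cbind(estimate, rel_error) ~ copies + depth, grid, mean)
  s <- aggregate(estimate ~ copies + depth, grid, sd)
  names(agg)[3:4] <- c("mean_estimate", "mean_rel_error")
  agg$sd_estimate <- s$estimate
  agg[order(agg$copies, agg$depth), ]
}
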