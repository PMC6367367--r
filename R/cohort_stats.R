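# Cohort-level statistics: method correlation, Ping16A_Stow association,
# one-way ANOVA with Tukey HSD, yeast transposition-rate arithmetic, and
# report percentages.

#' Round half away from zero
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Round half toward zero
#' @inheritParams round_half_away
#' @export
round_half_toward_zero <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * ceiling(abs(x) * m - 0.5) / m
}

#' Percentage of a count, under both half-rounding conventions
#'
#' Reports k/n as a percentage to one decimal. When the two conventions
#' disagree (the fraction's second decimal is exactly 5) both values are
#' retained and the row is flagged.
#'
#' @param k numerator count.
#' @param n denominator count.
#' @param digits decimal places (1).
#' @return data frame with `fraction`, `pct_half_away`, `pct_half_toward`,
#'   `convention_differs`.
#' @export
percent_both <- function(k, n, digits = 1L) {
  frac <- ifelse(n > 0, k / n, NA_real_)
  pa <- round_half_away(100 * frac, digits)
  pt <- round_half_toward_zero(100 * frac, digits)
  data.frame(k = k, n = n, fraction = frac, pct_half_away = pa,
             pct_half_toward = pt, convention_differs = pa != pt)
}

#' Pearson correlation between discovery counts and depth estimates
#'
#' @param summaries accession summary data frame.
#' @param element element id; uses columns `<element>_count` and
#'   `<element>_estimate` (or supply `counts`/`estimates` directly).
#' @param counts,estimates optional numeric vectors overriding `summaries`.
#' @return list with `r`, `p_value`, `n`; `r` is `NA` with
#'   `status = "not-applicable"` when either vector has zero variance.
#' @export
correlate_methods <- function(summaries = NULL, element = "mPing",
                              counts = NULL, estimates = NULL) {
  if (is.null(counts)) counts <- summaries[[paste0(element, "_count")]]
  if (is.null(estimates))
    estimates <- summaries[[paste0(element, "_estimate")]]
  ok <- stats::complete.cases(counts, estimates)
  counts <- counts[ok]; estimates <- estimates[ok]
  if (length(counts) < 3) stop("need >= 3 accessions with both measurements")
  if (sd(counts) == 0 || sd(estimates) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(counts),
                status = "not-applicable"))
  ct <- cor.test(counts, estimates, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(counts),
       status = "ok")
}

# Two-tailed rank-sum p by full enumeration of the C(n, n1) group-1 rank
# assignments (handles ties through midranks).
rank_sum_exact <- function(x, y) {
  ranks <- rank(c(x, y))
  n1 <- length(x); n <- length(ranks)
  w_obs <- sum(ranks[seq_len(n1)])
  splits <- combn(n, n1)
  w_all <- colSums(matrix(ranks[splits], nrow = n1))
  eps <- 1e-9
  p_le <- mean(w_all <= w_obs + eps)
  p_ge <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact enumeration of all rank splits for combined n <= `exact_limit`
#' (ties handled through midranks); otherwise the normal approximation with
#' tie correction and continuity correction. Two-tailed.
#'
#' @param x,y the two groups (non-empty).
#' @param exact_limit largest combined n for exact mode (16).
#' @return list with `statistic` (group-1 rank sum W), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_limit = 16L) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  ranks <- rank(c(x, y))
  w <- sum(ranks[seq_len(n1)])
  if (n <= exact_limit)
    return(list(statistic = w, p_value = rank_sum_exact(x, y),
                method = "exact"))
  mu <- n1 * (n + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  list(statistic = w, p_value = min(1, 2 * pnorm(-abs(z))),
       method = "normal")
}

#' Association of Ping16A_Stow with mPing copy number
#'
#' Rank-sum test of mPing copy numbers between accessions with and without
#' the nested Ping16A_Stow structure.
#'
#' @param summaries data frame with columns `stow_status`
#'   (`"ping16A_stow"` vs anything else) and `mping` (copy number; falls
#'   back to `mPing_estimate`/`mPing_count`).
#' @return the [rank_sum_test()] result plus group sizes.
#' @export
test_stow_association <- function(summaries) {
  v <- summaries$mping %||% summaries$mPing_estimate %||%
    summaries$mPing_count
  has <- summaries$stow_status == "ping16A_stow"
  if (!any(has) || all(has)) stop("both groups must be non-empty")
  res <- rank_sum_test(v[has], v[!has])
  res$n_with <- sum(has); res$n_without <- sum(!has)
  res
}

#' One-way ANOVA with Tukey HSD
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   observations).
#' @return list with `F`, `df` (between), `df_resid`, `p_value`, and the
#'   Tukey pairwise table (`diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs >= 2 observations")
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups) %||% seq_along(groups), lengths(groups))))
  gm <- mean(df$y)
  ssb <- sum(tapply(df$y, df$g, function(v) length(v) * (mean(v) - gm)^2))
  if (ssb == 0 && all(tapply(df$y, df$g, sd) == 0))
    return(list(F = 0, df = length(groups) - 1L,
                df_resid = nrow(df) - length(groups), p_value = 1,
                tukey = NULL))
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  colnames(tk) <- c("diff", "lwr", "upr", "p_adj")
  list(F = an[["F value"]][1], df = an[["Df"]][1], df_resid = an[["Df"]][2],
       p_value = an[["Pr(>F)"]][1], tukey = as.data.frame(tk))
}

#' Yeast transposition frequency
#'
#' Total cells plated on the selective plate are back-calculated from the
#' reference (YPD) plate count at the given dilution (default 1e-4) scaled
#' by the plated-volume ratio; the rate is the galactose colony count over
#' total cells, reported per million and optionally normalized to the
#' control construct.
#'
#' @param gal_count colonies on the selective (galactose) plate.
#' @param ref_count colonies on the reference plate (> 0).
#' @param dilution reference-plate dilution factor in (0, 1].
#' @param vol_selective,vol_reference plated volumes (same units).
#' @param control_per_million optional control rate for normalization
#'   (must be non-zero when supplied).
#' @return data frame with `total_cells`, `per_million`, `normalized`.
#' @export
transposition_frequency <- function(gal_count, ref_count, dilution = 1e-4,
                                    vol_selective = 100, vol_reference = 100,
                                    control_per_million = NULL) {
  if (any(ref_count <= 0)) stop("reference-plate count must be > 0")
  if (any(dilution <= 0 | dilution > 1)) stop("dilution must be in (0, 1]")
  total <- ref_count / dilution * (vol_selective / vol_reference)
  per_million <- gal_count / total * 1e6
  normalized <- rep(NA_real_, length(per_million))
  if (!is.null(control_per_million)) {
    if (control_per_million == 0)
      stop("control frequency is zero; normalization undefined")
    normalized <- per_million / control_per_million
  }
  data.frame(total_cells = total, per_million = per_million,
             normalized = normalized)
}

#' Mean and standard deviation of per-accession copy numbers
#'
#' @param values numeric copy numbers (one per accession).
#' @param digits rounding for the reported summary (2, matching the
#'   printed precision of cohort summaries).
#' @return list with `n`, `mean`, `sd` (rounded half away from zero).
#' @export
summarize_copy_numbers <- function(values, digits = 2L) {
  values <- values[!is.na(values)]
  list(n = length(values), mean = round_half_away(mean(values), digits),
       sd = round_half_away(sd(values), digits))
}

#' Cohort report tables
#'
#' Presence counts and percentages (both rounding conventions), Ping variant
#' tallies, Ping16A_Stow tallies and per-subgroup mean copy numbers.
#'
#' @param summaries accession summary data frame; recognised columns:
#'   `accession`, `subgroup`, `mping`/`ping`/`pong` (copy numbers),
#'   `ping_variant`, `stow_status`.
#' @return list of data frames (`presence`, `variants`, `stow`,
#'   `subgroup_means`).
#' @export
report_tables <- function(summaries) {
  n <- nrow(summaries)
  pres <- NULL
  for (el in c("mping", "ping", "pong")) {
    if (is.null(summaries[[el]])) next
    k <- sum(summaries[[el]] > 0, na.rm = TRUE)
    row <- cbind(element = el, percent_both(k, n))
    pres <- rbind(pres, row)
  }
  variants <- if (!is.null(summaries$ping_variant))
    as.data.frame(table(variant = summaries$ping_variant)) else NULL
  stow <- if (!is.null(summaries$stow_status))
    as.data.frame(table(status = summaries$stow_status)) else NULL
  sub_means <- if (!is.null(summaries$subgroup) && !is.null(summaries$mping))
    aggregate(mping ~ subgroup, summaries, mean) else NULL
  list(presence = pres, variants = variants, stow = stow,
       subgroup_means = sub_means)
}
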