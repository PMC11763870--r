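#' Per-patient coverage statistics from per-amplicon read counts
#'
#' For amplicon sequencing the per-amplicon read count approximates the
#' depth over that amplicon. Mean depth is the length-weighted mean
#' (total on-target bases over total target length); uniformity is the
#' percent of target bases at or above 0.2x the mean depth (the platform's
#' uniformity convention).
#'
#' @param per_amplicon_reads Named list mapping patient id to a numeric
#'   vector of per-amplicon read counts.
#' @param target_lengths Positive numeric vector of amplicon lengths
#'   (recycled check: must match each patient's count vector length).
#' @param raw_read_totals Optional named numeric vector of total raw reads
#'   per patient, used to compute `on_target_pct`.
#' @return data.frame: `patient_id`, `mean_depth`, `total_reads`,
#'   `reads_depth_ratio`, `uniformity_pct`, `on_target_pct`.
#' @export
coverage_stats <- function(per_amplicon_reads, target_lengths,
                           raw_read_totals = NULL) {
  if (any(target_lengths <= 0)) stop("target lengths must be positive")
  total_len <- sum(target_lengths)
  if (total_len <= 0) stop("zero total target length")
  out <- lapply(names(per_amplicon_reads), function(pid) {
    reads <- per_amplicon_reads[[pid]]
    if (length(reads) != length(target_lengths)) {
      stop("read-count vector length mismatch for patient ", pid)
    }
    if (any(reads < 0)) stop("negative read count for patient ", pid)
    mean_depth <- sum(reads * target_lengths) / total_len
    uniform <- if (mean_depth > 0) {
      100 * sum(target_lengths[reads >= 0.2 * mean_depth]) / total_len
    } else 100
    on_target <- NA_real_
    if (!is.null(raw_read_totals) && pid %in% names(raw_read_totals)) {
      on_target <- 100 * sum(reads) / raw_read_totals[[pid]]
    }
    data.frame(patient_id = pid, mean_depth = mean_depth,
               total_reads = sum(reads),
               reads_depth_ratio = ifelse(mean_depth > 0,
                                          sum(reads) / mean_depth, NA_real_),
               uniformity_pct = uniform, on_target_pct = on_target)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Robust FDR-controlled outlier detection (ROUT, location model)
#'
#' Specialisation of the ROUT procedure to a single-location model: the
#' center is the median, the robust scale (RSDR) is the 68.27th percentile
#' of absolute residuals times `n/(n-1)`, each point gets a two-tailed t
#' probability at `n-1` degrees of freedom, and outliers are declared by a
#' step-up false-discovery scan from the most extreme point inward at rate
#' `Q`. Identical values (zero robust spread) yield no outliers.
#'
#' @param values Numeric vector, `length(values) >= 3`.
#' @param Q Maximum desired false-discovery rate, in percent (default 1).
#' @return Integer indices of outliers (possibly empty).
#' @export
#' @examples
#' rout_outliers(c(10, 11, 9, 10, 12, 10, 1000))  # index of 1000
rout_outliers <- function(values, Q = 1) {
  n <- length(values)
  if (n < 3) stop("ROUT needs at least 3 values")
  if (Q <= 0 || Q >= 100) stop("Q must be in (0, 100) percent")
  resid <- values - stats::median(values)
  p68 <- stats::quantile(abs(resid), 0.6827, names = FALSE, type = 7)
  rsdr <- p68 * n / (n - 1)
  if (rsdr <= 0) return(integer(0))
  tstat <- abs(resid) / rsdr
  pvals <- 2 * stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  ord <- order(pvals)  # most extreme first
  thresh <- (Q / 100) * seq_len(n) / n
  below <- which(pvals[ord] <= thresh)
  if (!length(below)) return(integer(0))
  sort(ord[seq_len(max(below))])
}

#' Ordinary least-squares fit with Pearson correlation
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; `x` not constant.
#' @return List: `slope`, `intercept`, `pearson_r`, `p_value` (two-sided
#'   test of zero correlation).
#' @export
linear_fit <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need n >= 3 paired observations")
  if (stats::var(x) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = unname(ct$estimate),
       p_value = ct$p.value)
}

#' Bland-Altman limits of agreement for paired VAF measurements
#'
#' Differences are `A - B`; limits are the mean difference plus/minus
#' 1.96 sample standard deviations (n-1).
#'
#' @param vaf_a,vaf_b Numeric vectors of paired measurements, `n >= 2`.
#' @return List: `mean_diff`, `loa_low`, `loa_high`, `differences`,
#'   `averages`.
#' @export
bland_altman <- function(vaf_a, vaf_b) {
  n <- length(vaf_a)
  if (n < 2 || length(vaf_b) != n) stop("need n >= 2 pairs")
  d <- vaf_a - vaf_b
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       differences = d, averages = (vaf_a + vaf_b) / 2)
}

#' 2x2 concordance table between two calling methods
#'
#' @param pos_pos,pos_neg,neg_pos,neg_neg Non-negative cell counts; the
#'   first index is method A, the second the reference method B
#'   (`pos_neg` = positive in A, negative in B).
#' @return A `concordance_table`.
#' @export
concordance_table <- function(pos_pos, pos_neg, neg_pos, neg_neg) {
  cells <- c(pos_pos, pos_neg, neg_pos, neg_neg)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  structure(list(pos_pos = pos_pos, pos_neg = pos_neg,
                 neg_pos = neg_pos, neg_neg = neg_neg,
                 total = sum(cells)),
            class = "concordance_table")
}

#' Cohen's kappa, sensitivity and specificity for a 2x2 table
#'
#' Kappa is `(p_o - p_e) / (1 - p_e)` with the usual observed and expected
#' agreement; perfect agreement with degenerate margins (`p_e == 1`) is
#' reported as kappa 1. With method B as reference, sensitivity is
#' `pos_pos / (pos_pos + neg_pos)` and specificity
#' `neg_neg / (neg_neg + pos_neg)` (in percent); the A-as-reference
#' direction is also returned. An empty reference class makes that metric
#' `NA`, never 0. Agreement bands: weak below 0.4, moderate 0.4-0.8,
#' strong above 0.8.
#'
#' @param table A [concordance_table()].
#' @return List: `kappa`, `kappa_band`, `sensitivity`, `specificity`
#'   (B as reference), `sensitivity_a_ref`, `specificity_a_ref`.
#' @export
#' @examples
#' agreement(concordance_table(8, 0, 0, 1))  # kappa 1, 100/100, STRONG
agreement <- function(table) {
  stopifnot(inherits(table, "concordance_table"))
  a <- table$pos_pos; b <- table$pos_neg
  c_ <- table$neg_pos; d <- table$neg_neg
  n <- table$total
  if (n == 0) stop("empty table")
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  kappa <- if (p_e == 1) {
    if (p_o == 1) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  band <- if (kappa < 0.4) "WEAK" else if (kappa <= 0.8) "MODERATE" else "STRONG"
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(
    kappa = kappa, kappa_band = band,
    sensitivity = rate(a, a + c_), specificity = rate(d, d + b),
    sensitivity_a_ref = rate(a, a + b), specificity_a_ref = rate(d, d + c_)
  )
}

#' Concordance percentage between two call sets over a comparison universe
#'
#' Counts every compared item as concordant unless it appears in exactly one
#' of the two call sets (shared negatives within the universe are
#' concordant). Display conventions: `"round"` rounds half-up to `digits`
#' decimals; `"truncate"` truncates, the convention under which 103 of 104
#' concordant prints as 99.03.
#'
#' @param calls_a,calls_b Character vectors (sets) of positive calls.
#' @param universe Total number of compared items, at least
#'   `length(union(calls_a, calls_b))`.
#' @param digits Decimals for the printed value.
#' @param convention `"round"` or `"truncate"`.
#' @return Concordance percent at the requested precision.
#' @export
#' @examples
#' validation_concordance(letters[1:10], letters[2:11], 11)  # 91
validation_concordance <- function(calls_a, calls_b, universe, digits = 0,
                                   convention = c("round", "truncate")) {
  convention <- match.arg(convention)
  if (universe <= 0) stop("universe must be positive")
  discordant <- length(setdiff(calls_a, calls_b)) +
    length(setdiff(calls_b, calls_a))
  if (universe < length(union(calls_a, calls_b))) {
    stop("universe smaller than the union of calls")
  }
  pct <- 100 * (universe - discordant) / universe
  if (convention == "round") {
    round_half_up(pct, digits)
  } else {
    trunc(pct * 10^digits) / 10^digits
  }
}
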