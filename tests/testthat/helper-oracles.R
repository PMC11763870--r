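# Independent oracles: deliberately naive implementations used to
# cross-check the package's code paths. None of these call package internals.

# Cohen's kappa / sensitivity / specificity by direct arithmetic on a 2x2
oracle_agreement <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  kappa <- if (p_e == 1) {
    if (p_o == 1) 1 else 0
  } else (p_o - p_e) / (1 - p_e)
  list(kappa = kappa,
       sensitivity = if (a + c_ == 0) NA_real_ else 100 * a / (a + c_),
       specificity = if (d + b == 0) NA_real_ else 100 * d / (d + b))
}

# product-limit estimator by explicit loop over distinct event times
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])          # events precede censorings at ties
    d_i <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(times = ts, survival = surv)
}

# two-group log-rank by direct 2x2 summation at each event time
oracle_logrank <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in ts) {
    n <- sum(time >= tt)
    n1 <- sum(time >= tt & grp == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O - E)^2 / V
  list(chi_square = chi,
       p_value = pchisq(chi, df = 1, lower.tail = FALSE))
}

# SNP table for one patient/chromosome with explicit per-locus VAFs
snp_rows <- function(vafs, chrom = "3", patient = "PT1", depth = 500,
                     arm = NULL) {
  n <- length(vafs)
  if (is.null(arm)) arm <- rep(c("p", "q"), length.out = n)
  if (n == 0) {
    return(data.frame(patient_id = character(0), rsid = character(0),
                      chrom = character(0), arm = character(0),
                      pos = numeric(0), total_depth = numeric(0),
                      alt_depth = numeric(0), vaf = numeric(0)))
  }
  data.frame(
    patient_id = patient, rsid = sprintf("rs%s%03d", chrom, seq_len(n)),
    chrom = chrom, arm = arm, pos = seq_len(n) * 1e6,
    total_depth = depth, alt_depth = round(vafs / 100 * depth),
    vaf = vafs, stringsAsFactors = FALSE
  )
}

# minimal valid variant row(s) for filter-chain tests
variant_rows <- function(n = 1, patient = "PT1", gene = "GNAQ", vaf = 45,
                         depth = 500, qual = 80, pvalue = 1e-9,
                         consequence = "MISSENSE", clin_class = "PATHOGENIC") {
  data.frame(
    patient_id = patient, gene = gene, chrom = "9",
    pos = seq_len(n) + 8e7, ref = "A", alt = "C",
    total_depth = depth, alt_depth = round(vaf / 100 * depth), vaf = vaf,
    qual = qual, pvalue = pvalue, consequence = consequence,
    clin_class = clin_class, hgvs_p = NA_character_,
    stringsAsFactors = FALSE
  )
}
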