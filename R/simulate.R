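#' Simulation configuration for synthetic uveal-melanoma cohorts
#'
#' Defaults encode the stated world the generator emulates: tumor purity
#' uniform on 85-95%, amplicon depth negative-binomial with mean 500 and
#' CV about 0.3, clonal drivers (cancer-cell fraction 1), per-gene mutation
#' frequencies matching the published 44-patient cohort rates (with
#' GNAQ/GNA11 mutual exclusivity enforced by a single categorical draw),
#' per-chromosome imbalance frequencies of 50% / 66% / 56.8% for
#' chromosomes 1 / 3 / 8, and exponential survival whose hazard is scaled
#' by stratum (BAP1-mutant, chromosome-3 imbalance).
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param purity_range Tumor-cellularity range (proportion).
#' @param depth_mean,depth_size Negative-binomial depth parameters
#'   (`size = 11.1` gives CV close to 0.3 at mean 500).
#' @param ccf Cancer-cell fraction of somatic drivers.
#' @param het_prob Germline heterozygosity probability of a panel SNP locus.
#' @param gene_frequencies Named per-gene mutation probabilities; GNAQ and
#'   GNA11 must sum to at most 1.
#' @param imbalance_frequencies Named (`"1"`, `"3"`, `"8"`) imbalance
#'   probabilities.
#' @param hazard_ratios Named hazard ratios applied multiplicatively
#'   (`BAP1` for BAP1-mutant, `CHR3` for chromosome-3 imbalance).
#' @param base_median_months Baseline overall-survival median (months).
#' @param censor_range Administrative censoring window (months).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 44, seed = 1,
                       purity_range = c(0.85, 0.95),
                       depth_mean = 500, depth_size = 11.1,
                       ccf = 1, het_prob = 0.5,
                       gene_frequencies = c(
                         GNAQ = 0.591, GNA11 = 0.296, BAP1 = 0.41,
                         SF3B1 = 0.182, FOXO1 = 0.136, RPL5 = 0.114,
                         EIF1AX = 0.114, HIF1A = 0.091, CENPE = 0.068,
                         SRSF2 = 0.068, PLCB4 = 0.046, TP53 = 0.046,
                         BRAF = 0.023, CDKN2A = 0.023, CYSLTR2 = 0.023),
                       imbalance_frequencies = c("1" = 0.50, "3" = 0.66,
                                                 "8" = 0.568),
                       hazard_ratios = c(BAP1 = 2.5, CHR3 = 3.0),
                       base_median_months = 100,
                       censor_range = c(24, 150)) {
  stopifnot(n_patients >= 1, length(purity_range) == 2,
            purity_range[1] > 0, purity_range[2] <= 1,
            purity_range[1] <= purity_range[2],
            all(gene_frequencies >= 0 & gene_frequencies <= 1),
            all(imbalance_frequencies >= 0 & imbalance_frequencies <= 1),
            all(hazard_ratios > 0))
  if (gene_frequencies[["GNAQ"]] + gene_frequencies[["GNA11"]] > 1) {
    stop("GNAQ + GNA11 frequencies exceed 1; mutual exclusivity infeasible")
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    purity_range = purity_range, depth_mean = depth_mean,
    depth_size = depth_size, ccf = ccf, het_prob = het_prob,
    gene_frequencies = gene_frequencies,
    imbalance_frequencies = imbalance_frequencies,
    hazard_ratios = hazard_ratios,
    base_median_months = base_median_months,
    censor_range = censor_range
  ), class = "sim_config")
}

#' Expected alternate-allele dosage of a germline-heterozygous SNP
#'
#' Mixes tumor and normal allele copies at tumor purity `p`. Copy states:
#' `disomy` (dosage 1/2); `loss` of one chromosome copy, giving
#' `(1-p)/(2-p)` when the alternate allele was lost and `1/(2-p)` when it
#' was retained; single-copy `gain`, giving `(1+p)/(2+p)` when the
#' alternate allele was duplicated and `1/(2+p)` otherwise.
#'
#' @param copy_state `"disomy"`, `"loss"` or `"gain"` (vectorised).
#' @param purity Tumor purity in (0, 1].
#' @param alt_affected Logical: whether the alternate allele is the one
#'   lost (under `loss`) or duplicated (under `gain`).
#' @return Expected VAF as a proportion.
#' @export
dosage_prob <- function(copy_state, purity, alt_affected) {
  n <- max(length(copy_state), length(purity), length(alt_affected))
  copy_state <- rep_len(copy_state, n)
  purity <- rep_len(purity, n)
  alt_affected <- rep_len(alt_affected, n)
  out <- rep(0.5, n)
  i <- copy_state == "loss"
  out[i] <- ifelse(alt_affected[i], (1 - purity[i]) / (2 - purity[i]),
                   1 / (2 - purity[i]))
  i <- copy_state == "gain"
  out[i] <- ifelse(alt_affected[i], (1 + purity[i]) / (2 + purity[i]),
                   1 / (2 + purity[i]))
  out
}

# depth draw guarded away from zero (a zero-depth amplicon has no VAF)
rdepth <- function(n, cfg) {
  pmax(1L, stats::rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_size))
}

# caller-style significance: one-sided binomial tail vs a 1% error null
caller_pvalue <- function(alt, depth) {
  stats::pbinom(alt - 1, depth, 0.01, lower.tail = FALSE)
}

sim_gene_meta <- function() {
  data.frame(
    gene = c("GNAQ", "GNA11", "CYSLTR2", "PLCB4", "BAP1", "EIF1AX", "SF3B1",
             "SRSF2", "CDKN2A", "CENPE", "FOXO1", "HIF1A", "RPL5", "TP53",
             "BRAF"),
    consequence = c("MISSENSE", "MISSENSE", "MISSENSE", "MISSENSE",
                    "FRAMESHIFT", "MISSENSE", "MISSENSE", "MISSENSE",
                    "NONSENSE", "MISSENSE", "MISSENSE", "MISSENSE",
                    "MISSENSE", "MISSENSE", "MISSENSE"),
    clin_class = c("PATHOGENIC", "PATHOGENIC", "PATHOGENIC", "PATHOGENIC",
                   "PATHOGENIC", "PATHOGENIC", "PATHOGENIC", "PATHOGENIC",
                   "VUS", "NOVEL", "NOVEL", "NOVEL", "NOVEL", "PATHOGENIC",
                   "VUS"),
    hgvs_p = c("p.Q209P", "p.Q209L", "p.L129Q", "p.D630Y", "p.E31fs",
               "p.G8R", "p.R625H", "p.P95H", "p.R80*", "p.K792N", "p.S205T",
               "p.P582S", "p.A55V", "p.R248Q", "p.G466V"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Generates the four tables the pipeline consumes — a variant table (true
#' somatic drivers plus rejectable noise: synonymous, sub-threshold-VAF
#' artifacts and benign germline polymorphisms), a SNP allele-count table
#' under the copy-state dosage model, a clinical table and a survival
#' table — plus a ground-truth object that the pipeline under test must
#' never consume.
#'
#' @param cfg A [sim_config()].
#' @param panel A `panel_definition`; default the bundled panel.
#' @return A `sim_cohort` list: `variants`, `snps`, `clinical`, `survival`
#'   (data.frames) and `truth` (list with per-patient mutation sets, copy
#'   states, purity and stratum labels).
#' @export
simulate_cohort <- function(cfg = sim_config(),
                            panel = load_panel(bundled_panel_path())) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "panel_definition"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  purity <- stats::runif(n, cfg$purity_range[1], cfg$purity_range[2])

  # --- mutation ground truth -------------------------------------------
  meta <- sim_gene_meta()
  genes <- meta$gene
  freq <- cfg$gene_frequencies[genes]
  mut <- matrix(FALSE, n, length(genes), dimnames = list(ids, genes))
  u <- stats::runif(n)  # single categorical draw: GNAQ xor GNA11 xor neither
  mut[, "GNAQ"] <- u < freq[["GNAQ"]]
  mut[, "GNA11"] <- u >= freq[["GNAQ"]] &
    u < freq[["GNAQ"]] + freq[["GNA11"]]
  for (g in setdiff(genes, c("GNAQ", "GNA11"))) {
    mut[, g] <- stats::runif(n) < freq[[g]]
  }

  # --- chromosome copy-state ground truth ------------------------------
  state_for <- c("1" = "loss", "3" = "loss", "8" = "gain")
  copy_state <- sapply(c("1", "3", "8"), function(ch) {
    ifelse(stats::runif(n) < cfg$imbalance_frequencies[[ch]],
           state_for[[ch]], "disomy")
  })
  rownames(copy_state) <- ids

  # --- somatic driver variants -----------------------------------------
  hit <- which(mut, arr.ind = TRUE)
  gi <- hit[, 2]
  region1 <- panel$regions[match(genes[gi], panel$regions$gene), ]
  depth <- rdepth(nrow(hit), cfg)
  alt <- stats::rbinom(nrow(hit), depth,
                       purity[hit[, 1]] * cfg$ccf / 2)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(hit), replace = TRUE)
  altb <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  variants <- data.frame(
    patient_id = ids[hit[, 1]],
    gene = genes[gi],
    chrom = region1$chrom,
    pos = floor(stats::runif(nrow(hit), region1$start, region1$end + 1)),
    ref = ref, alt = altb,
    total_depth = depth, alt_depth = alt,
    vaf = 100 * alt / depth,
    qual = round(stats::runif(nrow(hit), 60, 99), 1),
    pvalue = caller_pvalue(alt, depth),
    consequence = meta$consequence[gi],
    clin_class = meta$clin_class[gi],
    hgvs_p = meta$hgvs_p[gi],
    somatic_truth = TRUE,
    stringsAsFactors = FALSE
  )

  # --- rejectable noise variants ---------------------------------------
  n_noise <- stats::rpois(n, 2)
  pat <- rep(seq_len(n), n_noise)
  m <- length(pat)
  if (m) {
    kind <- sample(c("synonymous", "artifact", "germline"), m,
                   replace = TRUE)
    ngene <- sample(genes, m, replace = TRUE)
    region <- panel$regions[match(ngene, panel$regions$gene), ]
    ndepth <- rdepth(m, cfg)
    nprob <- ifelse(kind == "artifact",
                    stats::runif(m, 0.01, 0.08), 0.5)
    nalt <- stats::rbinom(m, ndepth, nprob)
    nref <- sample(bases, m, replace = TRUE)
    naltb <- vapply(nref, function(r) sample(setdiff(bases, r), 1),
                    character(1))
    noise <- data.frame(
      patient_id = ids[pat], gene = ngene, chrom = region$chrom,
      pos = floor(stats::runif(m, region$start, region$end + 1)),
      ref = nref, alt = naltb,
      total_depth = ndepth, alt_depth = nalt, vaf = 100 * nalt / ndepth,
      qual = round(stats::runif(m, 45, 99), 1),
      pvalue = caller_pvalue(nalt, ndepth),
      consequence = ifelse(kind == "synonymous", "SYNONYMOUS", "MISSENSE"),
      clin_class = ifelse(kind == "germline",
                          sample(c("BENIGN", "COMMON_SNP"), m, replace = TRUE),
                          "NOVEL"),
      hgvs_p = NA_character_, somatic_truth = FALSE,
      stringsAsFactors = FALSE
    )
    variants <- rbind(variants, noise)
  }
  variants <- variants[order(variants$patient_id, variants$gene,
                             variants$pos), ]
  rownames(variants) <- NULL

  # --- SNP allele counts under the dosage model ------------------------
  L <- nrow(panel$snps)
  spat <- rep(seq_len(n), each = L)
  sloc <- rep(seq_len(L), times = n)
  geno_u <- stats::runif(n * L)
  geno <- ifelse(geno_u < cfg$het_prob, "het",
                 ifelse(geno_u < cfg$het_prob + (1 - cfg$het_prob) / 2,
                        "hom_ref", "hom_alt"))
  st <- copy_state[cbind(spat, match(panel$snps$chrom[sloc],
                                     c("1", "3", "8")))]
  alt_affected <- stats::runif(n * L) < 0.5  # which haplotype is lost/gained
  err <- 0.002
  prob <- ifelse(geno == "het", dosage_prob(st, purity[spat], alt_affected),
                 ifelse(geno == "hom_ref", err, 1 - err))
  sdepth <- rdepth(n * L, cfg)
  salt <- stats::rbinom(n * L, sdepth, prob)
  snps <- data.frame(
    patient_id = ids[spat],
    rsid = panel$snps$rsid[sloc],
    chrom = panel$snps$chrom[sloc],
    arm = panel$snps$arm[sloc],
    pos = panel$snps$pos[sloc],
    total_depth = sdepth, alt_depth = salt,
    vaf = 100 * salt / sdepth,
    stringsAsFactors = FALSE
  )

  # --- clinical table ---------------------------------------------------
  lat_u <- stats::runif(n)
  clinical <- data.frame(
    patient_id = ids,
    sex = ifelse(stats::runif(n) < 0.523, "M", "F"),
    laterality = ifelse(lat_u < 0.341, "L",
                        ifelse(lat_u < 0.955, "R", NA)),
    tumor_size_mm = round(stats::runif(n, 2, 30), 1),
    site = ifelse(stats::runif(n) < 0.977, "CHOROID", "CHOROID_CILIARY"),
    stringsAsFactors = FALSE
  )

  # --- survival ---------------------------------------------------------
  bap1_mut <- mut[, "BAP1"]
  imb3 <- copy_state[, "3"] != "disomy"
  rate <- log(2) / cfg$base_median_months *
    ifelse(bap1_mut, cfg$hazard_ratios[["BAP1"]], 1) *
    ifelse(imb3, cfg$hazard_ratios[["CHR3"]], 1)
  t_death <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, cfg$censor_range[1], cfg$censor_range[2])
  survival_tab <- data.frame(
    patient_id = ids,
    time = round(pmax(0.1, pmin(t_death, t_cens)), 2),
    event = as.integer(t_death <= t_cens),
    stringsAsFactors = FALSE
  )

  truth <- list(
    patient_id = ids,
    purity = stats::setNames(purity, ids),
    mutations = apply(mut, 1, function(r) genes[r], simplify = FALSE),
    copy_state = copy_state,
    bap1_mutated = stats::setNames(bap1_mut, ids),
    chr3_imbalanced = stats::setNames(imb3, ids)
  )
  structure(list(variants = variants, snps = snps, clinical = clinical,
                 survival = survival_tab, truth = truth, config = cfg),
            class = "sim_cohort")
}

#' Simulate a balanced (aberration-free) reference SNP table
#'
#' Emulates a normal diploid reference genome: every locus is either
#' heterozygous (expected VAF 50%) or homozygous (VAF near 0 or 100), the
#' negative control for the imbalance caller.
#'
#' @param cfg A [sim_config()] (`seed`, `depth_mean`, `depth_size`,
#'   `het_prob` are used).
#' @param panel A `panel_definition`.
#' @param sample_id Identifier for the reference sample.
#' @return SNP data.frame in the same dialect as [simulate_cohort()].
#' @export
simulate_balanced_reference <- function(cfg = sim_config(),
                                        panel = load_panel(bundled_panel_path()),
                                        sample_id = "REF_DIPLOID") {
  set.seed(cfg$seed)
  L <- nrow(panel$snps)
  geno_u <- stats::runif(L)
  geno <- ifelse(geno_u < cfg$het_prob, "het",
                 ifelse(geno_u < cfg$het_prob + (1 - cfg$het_prob) / 2,
                        "hom_ref", "hom_alt"))
  err <- 0.002
  prob <- ifelse(geno == "het", 0.5, ifelse(geno == "hom_ref", err, 1 - err))
  depth <- rdepth(L, cfg)
  alt <- stats::rbinom(L, depth, prob)
  data.frame(
    patient_id = sample_id,
    rsid = panel$snps$rsid, chrom = panel$snps$chrom, arm = panel$snps$arm,
    pos = panel$snps$pos, total_depth = depth, alt_depth = alt,
    vaf = 100 * alt / depth,
    stringsAsFactors = FALSE
  )
}
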