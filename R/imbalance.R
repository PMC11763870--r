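#' Zygosity band configuration
#'
#' The published thresholds band a SNP's VAF into homozygous-reference
#' (0-5%), heterozygous (45-55%) and homozygous-alternate (95-100%) ranges;
#' anything else is a deviant VAF indicating allelic imbalance. All interval
#' ends are inclusive, matching the printed ranges.
#'
#' @param hom_low,het,hom_high Two-element numeric ranges in VAF percent.
#' @return A `band_config`.
#' @export
band_config <- function(hom_low = c(0, 5), het = c(45, 55),
                        hom_high = c(95, 100)) {
  stopifnot(length(hom_low) == 2, length(het) == 2, length(hom_high) == 2,
            hom_low[1] <= hom_low[2], het[1] <= het[2],
            hom_high[1] <= hom_high[2],
            hom_low[2] < het[1], het[2] < hom_high[1])  # disjoint
  structure(list(hom_low = hom_low, het = het, hom_high = hom_high),
            class = "band_config")
}

#' Band a SNP VAF into a zygosity class
#'
#' @param vaf VAF in percent, in `[0, 100]` (vectorised).
#' @param cfg A [band_config()].
#' @return Character vector: `HOM_REF`, `HET`, `HOM_ALT` or `DEVIANT`.
#' @export
#' @examples
#' band_snp(c(50, 2, 30, 45))  # HET HOM_REF DEVIANT HET
band_snp <- function(vaf, cfg = band_config()) {
  stopifnot(inherits(cfg, "band_config"))
  if (any(is.na(vaf)) || any(vaf < 0 | vaf > 100)) {
    stop("vaf must lie in [0, 100]")
  }
  out <- rep("DEVIANT", length(vaf))
  out[vaf >= cfg$hom_low[1] & vaf <= cfg$hom_low[2]] <- "HOM_REF"
  out[vaf >= cfg$het[1] & vaf <= cfg$het[2]] <- "HET"
  out[vaf >= cfg$hom_high[1] & vaf <= cfg$hom_high[2]] <- "HOM_ALT"
  out
}

# shared aggregation: counts -> status
imbalance_status <- function(n_het, n_deviant, min_informative,
                             deviant_fraction) {
  informative <- n_het + n_deviant
  if (informative < min_informative) return("NON_INFORMATIVE")
  if (n_deviant >= min_informative &&
      n_deviant / informative >= deviant_fraction) "IMBALANCED" else "BALANCED"
}

#' Call chromosomal imbalance from one patient's SNPs on one chromosome
#'
#' Homozygous SNPs are uninformative (a lost or gained allele cannot shift a
#' 0% or 100% VAF); informative SNPs are those banding HET or DEVIANT. The
#' chromosome is `NON_INFORMATIVE` with fewer than `min_informative`
#' informative SNPs, `IMBALANCED` when at least `min_informative` SNPs are
#' deviant and deviant SNPs make up at least `deviant_fraction` of the
#' informative ones, and `BALANCED` otherwise.
#'
#' @param snps data.frame with columns `patient_id`, `chrom`, `arm`,
#'   `total_depth`, `alt_depth` (and optionally `vaf`), all rows sharing one
#'   patient and chromosome. May have zero rows.
#' @param cfg A [band_config()].
#' @param min_informative Minimum informative SNPs for a call (default 2).
#' @param deviant_fraction Minimum deviant share among informative SNPs
#'   (default 0.5).
#' @return One-row data.frame: `patient_id`, `chrom`, `n_snps`,
#'   `n_homozygous`, `n_het`, `n_deviant`, `status`, plus an `arms` attribute
#'   holding the same counts per chromosome arm.
#' @export
call_chromosome <- function(snps, cfg = band_config(), min_informative = 2,
                            deviant_fraction = 0.5) {
  stopifnot(min_informative >= 1, deviant_fraction > 0, deviant_fraction <= 1)
  if (nrow(snps) == 0) {
    out <- data.frame(patient_id = NA_character_, chrom = NA_character_,
                      n_snps = 0L, n_homozygous = 0L, n_het = 0L,
                      n_deviant = 0L, status = "NON_INFORMATIVE")
    attr(out, "arms") <- NULL
    return(out)
  }
  if (length(unique(snps$chrom)) > 1L) {
    stop("call_chromosome expects SNPs from a single chromosome")
  }
  if (length(unique(snps$patient_id)) > 1L) {
    stop("call_chromosome expects SNPs from a single patient")
  }
  vaf <- if ("vaf" %in% names(snps)) snps$vaf else
    compute_vaf(snps$alt_depth, snps$total_depth)
  band <- band_snp(vaf, cfg)
  tally <- function(b) {
    c(hom = sum(b %in% c("HOM_REF", "HOM_ALT")),
      het = sum(b == "HET"), dev = sum(b == "DEVIANT"))
  }
  tl <- tally(band)
  out <- data.frame(
    patient_id = snps$patient_id[1], chrom = as.character(snps$chrom[1]),
    n_snps = length(band), n_homozygous = unname(tl["hom"]),
    n_het = unname(tl["het"]), n_deviant = unname(tl["dev"]),
    status = imbalance_status(tl["het"], tl["dev"], min_informative,
                              deviant_fraction)
  )
  if ("arm" %in% names(snps)) {
    arms <- do.call(rbind, lapply(split(band, snps$arm), function(b) {
      t <- tally(b)
      data.frame(n_snps = length(b), n_homozygous = unname(t["hom"]),
                 n_het = unname(t["het"]), n_deviant = unname(t["dev"]),
                 status = imbalance_status(t["het"], t["dev"],
                                           min_informative, deviant_fraction))
    }))
    arms$arm <- rownames(arms)
    rownames(arms) <- NULL
    attr(out, "arms") <- arms[, c("arm", "n_snps", "n_homozygous", "n_het",
                                  "n_deviant", "status")]
  }
  out
}

#' Call imbalance on chromosomes 1, 3 and 8 for one patient
#'
#' Loci not in the panel's SNP set are dropped with a warning; a chromosome
#' with no data yields `NON_INFORMATIVE`.
#'
#' @param snps data.frame of one patient's SNP observations (`patient_id`,
#'   `rsid`, `chrom`, `arm`, `total_depth`, `alt_depth`).
#' @param panel A `panel_definition` (default: bundled panel); pass `NULL`
#'   to skip locus validation.
#' @inheritParams call_chromosome
#' @return data.frame with one row per chromosome in `c("1","3","8")`.
#' @export
call_patient_imbalances <- function(snps, panel = NULL, cfg = band_config(),
                                    min_informative = 2,
                                    deviant_fraction = 0.5) {
  stopifnot(is.data.frame(snps))
  pid <- unique(snps$patient_id)
  if (length(pid) > 1L) stop("expected SNPs for a single patient")
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "panel_definition"))
    off <- !(snps$rsid %in% panel$snps$rsid)
    if (any(off)) {
      warning(sum(off), " SNP observation(s) at loci outside the panel ignored: ",
              paste(utils::head(unique(snps$rsid[off]), 5), collapse = ", "))
      snps <- snps[!off, , drop = FALSE]
    }
  }
  snps$chrom <- as.character(snps$chrom)
  calls <- lapply(c("1", "3", "8"), function(ch) {
    sub <- snps[snps$chrom == ch, , drop = FALSE]
    call <- call_chromosome(sub, cfg, min_informative, deviant_fraction)
    call$patient_id <- if (length(pid)) pid else NA_character_
    call$chrom <- ch
    call
  })
  do.call(rbind, calls)
}

#' Call imbalances for every patient in a cohort SNP table
#'
#' @param snps data.frame of SNP observations for one or more patients.
#' @inheritParams call_patient_imbalances
#' @return data.frame with three rows (chromosomes 1, 3, 8) per patient.
#' @export
call_cohort_imbalances <- function(snps, panel = NULL, cfg = band_config(),
                                   min_informative = 2,
                                   deviant_fraction = 0.5) {
  parts <- split(snps, snps$patient_id)
  out <- do.call(rbind, lapply(parts, call_patient_imbalances, panel = panel,
                               cfg = cfg, min_informative = min_informative,
                               deviant_fraction = deviant_fraction))
  rownames(out) <- NULL
  out
}
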