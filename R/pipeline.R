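#' Run-level configuration for the end-to-end pipeline
#'
#' @param variants,snps,clinical,survival Input file paths (clinical and
#'   survival may be `NULL`; the corresponding stages degrade gracefully).
#' @param panel Path to a panel-definition file (default: bundled panel).
#' @param out Output directory.
#' @param filter A [filter_config()].
#' @param bands A [band_config()].
#' @param min_informative,deviant_fraction Imbalance aggregation parameters.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters for [simulate_cohort()] upstream).
#' @return A `run_config` list.
#' @export
run_config <- function(variants, snps, clinical = NULL, survival = NULL,
                       panel = bundled_panel_path(), out = "umprofiler_out",
                       filter = filter_config(), bands = band_config(),
                       min_informative = 2, deviant_fraction = 0.5,
                       seed = 1L) {
  structure(list(variants = variants, snps = snps, clinical = clinical,
                 survival = survival, panel = panel, out = out,
                 filter = filter, bands = bands,
                 min_informative = min_informative,
                 deviant_fraction = deviant_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Execute the full analysis pipeline
#'
#' Stages: variant filtering, chromosome imbalance calling, per-patient
#' profiling, cohort summary, stratification, and survival comparison.
#' Every stage output is written under `cfg$out` and listed, with an md5
#' checksum, in `manifest.json`; identical inputs and configuration give
#' identical checksums. Required input files are checked before any stage
#' runs; a missing optional file skips only its dependent stages and is
#' flagged in the manifest.
#'
#' @param cfg A [run_config()].
#' @return The manifest (named list), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (f in c(cfg$variants, cfg$snps, cfg$panel)) {
    if (!file.exists(f)) stop("pipeline input missing: ", f)
  }
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out, name)
    write_table_checked(df, p)
    outputs[[name]] <<- p
    p
  }

  panel <- load_panel(cfg$panel)

  # stage 1: filter chain
  variants <- read_variants(cfg$variants)
  filt <- apply_filter_chain(variants, cfg$filter)
  emit(filt$kept, "filtered_variants.tsv")
  emit(filt$rejected, "rejected_variants.tsv")
  message(sprintf("[filter] %d in, %d kept, %d rejected",
                  nrow(variants), nrow(filt$kept), nrow(filt$rejected)))

  # stage 2: imbalance calling
  snps <- read_snps(cfg$snps)
  imb <- call_cohort_imbalances(snps, panel, cfg$bands,
                                cfg$min_informative, cfg$deviant_fraction)
  emit(imb, "imbalance_calls.tsv")
  message(sprintf("[imbalance] %d chromosome calls across %d patients",
                  nrow(imb), length(unique(imb$patient_id))))

  # stage 3: profiles
  clinical <- if (!is.null(cfg$clinical) && file.exists(cfg$clinical)) {
    read_clinical(cfg$clinical)
  }
  profiles <- build_cohort_profiles(filt$kept, imb, clinical)
  prof_json <- file.path(cfg$out, "profiles.json")
  jsonlite::write_json(
    lapply(profiles, function(p) {
      p$mutations <- NULL  # variant rows live in filtered_variants.tsv
      unclass(p)
    }),
    prof_json, auto_unbox = TRUE, digits = NA, na = "null")
  outputs[["profiles.json"]] <- prof_json

  # stage 4: cohort summary
  summ <- summarize_cohort(profiles)
  emit(summ$gene_rates, "cohort_gene_rates.tsv")
  emit(summ$chrom_rates, "cohort_chrom_rates.tsv")

  # stages 5-6: strata + survival comparison
  surv <- if (!is.null(cfg$survival) && file.exists(cfg$survival)) {
    read_survival(cfg$survival)
  }
  strata_report <- lapply(c("BAP1", "CHR1", "CHR3", "CHR8"), function(sc) {
    st <- stratify(profiles, sc)
    rep <- list(scheme = sc, label_a = st$label_a, label_b = st$label_b,
                group_a = st$group_a, group_b = st$group_b,
                excluded = st$excluded)
    if (!is.null(surv)) {
      cmp <- compare_strata(profiles, surv, sc)
      rep$n_survival <- as.list(cmp$n)
      if (!is.null(cmp$test)) {
        rep$log_rank_chi_square <- cmp$test$chi_square
        rep$log_rank_p <- cmp$test$p_value
      }
      if (!is.null(cmp$km_a)) {
        rep$km_a <- cmp$km_a[c("times", "survival", "at_risk")]
      }
      if (!is.null(cmp$km_b)) {
        rep$km_b <- cmp$km_b[c("times", "survival", "at_risk")]
      }
    }
    rep
  })
  strata_json <- file.path(cfg$out, "strata_survival.json")
  jsonlite::write_json(strata_report, strata_json, auto_unbox = TRUE,
                       digits = NA, na = "null")
  outputs[["strata_survival.json"]] <- strata_json

  manifest <- list(
    seed = cfg$seed,
    inputs = list(variants = cfg$variants, snps = cfg$snps,
                  clinical = cfg$clinical, survival = cfg$survival,
                  panel = cfg$panel),
    skipped = c(if (is.null(clinical)) "clinical",
                if (is.null(surv)) "survival"),
    n_patients = summ$n_patients,
    gnaq_gna11_exclusive = summ$gnaq_gna11_exclusive,
    outputs = lapply(outputs, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}
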