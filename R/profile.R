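# half-up rounding (base round() is banker's); used for printed percentages
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

percent_of <- function(count, n, digits = 1) {
  round_half_up(100 * count / n, digits)
}

#' Build a per-patient molecular profile
#'
#' Groups a patient's kept (filtered) variants by gene category, attaches
#' chromosome imbalance calls and clinical fields, and derives BAP1 status.
#' Missing clinical fields become `NA`; patients are never dropped.
#'
#' @param patient_id Patient identifier.
#' @param kept_variants data.frame of the patient's variants that survived
#'   [apply_filter_chain()] (may have zero rows).
#' @param imbalance_calls data.frame from [call_patient_imbalances()] for
#'   this patient (or `NULL`).
#' @param clinical_row One-row data.frame (or `NULL`) with any of `sex`,
#'   `laterality`, `tumor_size_mm`, `site`.
#' @return A `patient_profile` list.
#' @export
build_profile <- function(patient_id, kept_variants = NULL,
                          imbalance_calls = NULL, clinical_row = NULL) {
  genes <- character(0)
  if (!is.null(kept_variants) && nrow(kept_variants)) {
    if (length(unique(kept_variants$patient_id)) > 1L) {
      stop("kept_variants spans multiple patients")
    }
    genes <- sort(unique(kept_variants$gene))
  }
  cats <- gene_categories()
  category_hits <- lapply(cats, function(members) intersect(genes, members))
  stray <- setdiff(genes, unlist(cats))
  if (length(stray)) stop("variant in non-panel gene: ",
                          paste(stray, collapse = ", "))

  imb <- c("1" = "NON_INFORMATIVE", "3" = "NON_INFORMATIVE",
           "8" = "NON_INFORMATIVE")
  if (!is.null(imbalance_calls) && nrow(imbalance_calls)) {
    k <- as.character(imbalance_calls$chrom)
    imb[k[k %in% names(imb)]] <-
      imbalance_calls$status[k %in% names(imb)]
  }
  clin <- function(field) {
    if (!is.null(clinical_row) && field %in% names(clinical_row)) {
      clinical_row[[field]][1]
    } else NA
  }
  structure(list(
    patient_id = patient_id,
    sex = clin("sex"), laterality = clin("laterality"),
    tumor_size_mm = clin("tumor_size_mm"), site = clin("site"),
    mutations = kept_variants,
    mutated_genes = genes,
    category_hits = category_hits,
    imbalances = imb,
    bap1_status = if ("BAP1" %in% genes) "MUTATED" else "WT"
  ), class = "patient_profile")
}

#' Build profiles for a whole cohort
#'
#' @param kept_variants Filtered variant table for the cohort.
#' @param imbalance_calls Output of [call_cohort_imbalances()].
#' @param clinical data.frame with a `patient_id` column, or `NULL`.
#' @param patient_ids Patients to profile; defaults to the union of ids seen
#'   in the three tables (so variant-free patients are kept).
#' @return List of `patient_profile`, named by patient id.
#' @export
build_cohort_profiles <- function(kept_variants, imbalance_calls,
                                  clinical = NULL, patient_ids = NULL) {
  if (is.null(patient_ids)) {
    patient_ids <- unique(c(kept_variants$patient_id,
                            imbalance_calls$patient_id,
                            clinical$patient_id))
  }
  patient_ids <- sort(patient_ids)
  out <- lapply(patient_ids, function(pid) {
    build_profile(
      pid,
      kept_variants[kept_variants$patient_id == pid, , drop = FALSE],
      imbalance_calls[imbalance_calls$patient_id == pid, , drop = FALSE],
      if (!is.null(clinical)) {
        clinical[clinical$patient_id == pid, , drop = FALSE]
      }
    )
  })
  stats::setNames(out, patient_ids)
}

#' Cohort-level mutation and imbalance rates
#'
#' A gene counts as mutated once per patient regardless of how many variants
#' it carries; a chromosome counts only when `IMBALANCED` (non-informative
#' chromosomes count toward neither rate's numerator). Percentages are
#' half-up rounded to one decimal.
#'
#' @param profiles List of `patient_profile`.
#' @return A `cohort_summary` list with `n_patients`, `gene_rates`
#'   (data.frame gene/count/pct), `chrom_rates`, and
#'   `gnaq_gna11_exclusive` (TRUE iff no patient carries both).
#' @export
summarize_cohort <- function(profiles) {
  if (length(profiles) == 0) stop("empty cohort")
  n <- length(profiles)
  gene_sets <- lapply(profiles, `[[`, "mutated_genes")
  genes <- panel_genes()
  gcount <- vapply(genes, function(g) {
    sum(vapply(gene_sets, function(s) g %in% s, logical(1)))
  }, integer(1))
  gene_rates <- data.frame(gene = genes, count = unname(gcount),
                           pct = percent_of(unname(gcount), n))
  ccount <- vapply(c("1", "3", "8"), function(ch) {
    sum(vapply(profiles, function(p) p$imbalances[[ch]] == "IMBALANCED",
               logical(1)))
  }, integer(1))
  chrom_rates <- data.frame(chrom = c("1", "3", "8"), count = unname(ccount),
                            pct = percent_of(unname(ccount), n))
  both <- vapply(gene_sets, function(s) all(c("GNAQ", "GNA11") %in% s),
                 logical(1))
  structure(list(
    n_patients = n, gene_rates = gene_rates, chrom_rates = chrom_rates,
    gnaq_gna11_exclusive = !any(both)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n_patients))
  top <- x$gene_rates[order(-x$gene_rates$count), ]
  top <- top[top$count > 0, ]
  if (nrow(top)) {
    cat("Mutated genes (patients, %):\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %-8s %3d  %5.1f%%\n", top$gene[i], top$count[i],
                  top$pct[i]))
    }
  }
  cat("Chromosomal imbalance (patients, %):\n")
  for (i in 1:3) {
    cat(sprintf("  chr%-5s %3d  %5.1f%%\n", x$chrom_rates$chrom[i],
                x$chrom_rates$count[i], x$chrom_rates$pct[i]))
  }
  cat(sprintf("GNAQ/GNA11 mutually exclusive: %s\n", x$gnaq_gna11_exclusive))
  invisible(x)
}

#' Split a cohort into two prognostic strata
#'
#' Schemes: `"BAP1"` contrasts BAP1-mutant vs BAP1 wild-type patients.
#' `"CHR1"`, `"CHR3"`, `"CHR8"` contrast patients imbalanced for that
#' chromosome against a chromosome-3-disomy baseline; for chromosomes 1 and 8
#' the baseline additionally requires balance on the comparison chromosome,
#' so the baseline size differs per scheme. Patients whose status for the
#' scheme's chromosome is `NON_INFORMATIVE` are excluded and reported, as are
#' balanced-k/imbalanced-3 patients that fit neither group.
#'
#' @param profiles List of `patient_profile`.
#' @param scheme One of `"BAP1"`, `"CHR1"`, `"CHR3"`, `"CHR8"`.
#' @return A `risk_strata` list: `scheme`, `label_a`/`label_b`, `group_a` /
#'   `group_b` (patient id vectors) and `excluded`.
#' @export
stratify <- function(profiles, scheme = c("BAP1", "CHR1", "CHR3", "CHR8")) {
  scheme <- match.arg(scheme)
  ids <- vapply(profiles, `[[`, character(1), "patient_id")
  if (scheme == "BAP1") {
    bap1 <- vapply(profiles, `[[`, character(1), "bap1_status")
    res <- list(scheme = scheme, label_a = "BAP1_MUT", label_b = "BAP1_WT",
                group_a = unname(ids[bap1 == "MUTATED"]),
                group_b = unname(ids[bap1 == "WT"]),
                excluded = character(0))
  } else {
    k <- sub("CHR", "", scheme)
    st_k <- vapply(profiles, function(p) p$imbalances[[k]], character(1))
    st_3 <- vapply(profiles, function(p) p$imbalances[["3"]], character(1))
    in_a <- st_k == "IMBALANCED"
    in_b <- st_3 == "BALANCED" & (k == "3" | st_k == "BALANCED")
    in_b <- in_b & !in_a  # imbalance membership takes precedence
    res <- list(scheme = scheme, label_a = paste0("IMB", k), label_b = "D3",
                group_a = unname(ids[in_a]), group_b = unname(ids[in_b]),
                excluded = unname(ids[!in_a & !in_b]))
  }
  if (length(intersect(res$group_a, res$group_b))) {
    stop("internal error: strata overlap")  # unreachable by construction
  }
  structure(res, class = "risk_strata")
}
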