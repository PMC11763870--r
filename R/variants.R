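#' Variant allele frequency in percent
#'
#' @param alt_depth Reads supporting the alternate allele.
#' @param total_depth Total reads at the position. Must be positive.
#' @return `100 * alt_depth / total_depth` (vectorised).
#' @export
#' @examples
#' compute_vaf(103, 515)  # 20
compute_vaf <- function(alt_depth, total_depth) {
  if (any(total_depth <= 0)) stop("VAF undefined: total_depth must be > 0")
  if (any(alt_depth < 0 | alt_depth > total_depth)) {
    stop("alt_depth must satisfy 0 <= alt_depth <= total_depth")
  }
  100 * alt_depth / total_depth
}

#' Filter-chain configuration
#'
#' Defaults follow the published chain: VAF cut-off 10% (inclusive), read
#' depth > 100, Phred quality > 40 and caller p-value < 0.01, with removal of
#' synonymous variants and of variants annotated benign or common SNP.
#'
#' @param vaf_min Minimum VAF in percent (kept when `vaf >= vaf_min`).
#' @param depth_min Depth threshold (kept when `total_depth > depth_min`).
#' @param qual_min Phred threshold (kept when `qual > qual_min`).
#' @param p_max Caller significance threshold (kept when `pvalue < p_max`).
#' @return A `filter_config` list.
#' @export
filter_config <- function(vaf_min = 10, depth_min = 100, qual_min = 40,
                          p_max = 0.01) {
  stopifnot(vaf_min >= 0, vaf_min <= 100, depth_min >= 0, p_max > 0, p_max <= 1)
  structure(list(vaf_min = vaf_min, depth_min = depth_min,
                 qual_min = qual_min, p_max = p_max),
            class = "filter_config")
}

variant_consequences <- function() {
  c("SYNONYMOUS", "MISSENSE", "NONSENSE", "FRAMESHIFT", "SPLICE", "OTHER")
}

clin_classes <- function() {
  c("PATHOGENIC", "VUS", "CIP", "NOVEL", "BENIGN", "COMMON_SNP")
}

# columns a variant table must carry for the filter chain
variant_required_cols <- function() {
  c("patient_id", "gene", "vaf", "total_depth", "qual", "pvalue",
    "consequence", "clin_class")
}

#' Apply the variant filter chain
#'
#' A variant is kept iff `vaf >= vaf_min` AND `total_depth > depth_min` AND
#' `qual > qual_min` AND `pvalue < p_max` AND the consequence is not
#' synonymous AND the clinical class is neither benign nor common SNP.
#' Rejected variants carry the first failing rule's reason code, evaluated in
#' the order VAF, depth, quality, p-value, synonymous, benign/common. Rows
#' with missing required fields are rejected with reason `MALFORMED`.
#'
#' @param variants data.frame of variant calls (see
#'   [simulate_cohort()] for the column dialect).
#' @param cfg A [filter_config()].
#' @return List with data.frames `kept` and `rejected`; `rejected` gains a
#'   `reason` column. `nrow(kept) + nrow(rejected) == nrow(variants)`.
#' @export
apply_filter_chain <- function(variants, cfg = filter_config()) {
  stopifnot(is.data.frame(variants), inherits(cfg, "filter_config"))
  missing_cols <- setdiff(variant_required_cols(), names(variants))
  if (length(missing_cols)) {
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(variants)
  reason <- rep(NA_character_, n)
  if (n) {
    malformed <- Reduce(`|`, lapply(
      variants[variant_required_cols()],
      function(col) is.na(col)
    ))
    # first failing rule wins; later assignments must not overwrite earlier ones
    set_reason <- function(cond, code) {
      hit <- !malformed & is.na(reason) & cond
      reason[hit] <<- code
    }
    reason[malformed] <- "MALFORMED"
    set_reason(variants$vaf < cfg$vaf_min, "VAF_BELOW_CUTOFF")
    set_reason(variants$total_depth <= cfg$depth_min, "LOW_DEPTH")
    set_reason(variants$qual <= cfg$qual_min, "LOW_QUALITY")
    set_reason(variants$pvalue >= cfg$p_max, "P_VALUE")
    set_reason(variants$consequence == "SYNONYMOUS", "SYNONYMOUS")
    set_reason(variants$clin_class %in% c("BENIGN", "COMMON_SNP"),
               "BENIGN_OR_COMMON")
  }
  keep <- is.na(reason)
  rejected <- variants[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = variants[keep, , drop = FALSE], rejected = rejected)
}

#' Build an offline clinical-annotation lookup table
#'
#' Lookups are keyed genomically (`chrom:pos:ref:alt`) with a protein-level
#' fallback (`gene:hgvs_p`); variants absent from the table classify as
#' `NOVEL`.
#'
#' @param df data.frame with columns `clin_class` plus either
#'   `chrom`,`pos`,`ref`,`alt` or `gene`,`hgvs_p` (or both).
#' @return An `annotation_table`.
#' @export
annotation_table <- function(df) {
  stopifnot(is.data.frame(df), "clin_class" %in% names(df))
  if (!all(df$clin_class %in% clin_classes())) {
    stop("clin_class must be one of: ", paste(clin_classes(), collapse = ", "))
  }
  genomic <- character(0)
  protein <- character(0)
  if (all(c("chrom", "pos", "ref", "alt") %in% names(df))) {
    k <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
    genomic <- stats::setNames(df$clin_class, k)[!is.na(df$chrom)]
  }
  if (all(c("gene", "hgvs_p") %in% names(df))) {
    ok <- !is.na(df$hgvs_p) & nzchar(df$hgvs_p)
    protein <- stats::setNames(df$clin_class[ok],
                               paste(df$gene[ok], df$hgvs_p[ok], sep = ":"))
  }
  structure(list(genomic = genomic, protein = protein),
            class = "annotation_table")
}

#' Classify variants against an annotation table
#'
#' @param variants data.frame with `chrom`,`pos`,`ref`,`alt` and/or
#'   `gene`,`hgvs_p` columns.
#' @param ann An [annotation_table()].
#' @return Character vector of clinical classes; `NOVEL` when unlisted.
#' @export
classify_variant <- function(variants, ann) {
  stopifnot(inherits(ann, "annotation_table"), is.data.frame(variants))
  n <- nrow(variants)
  out <- rep("NOVEL", n)
  if (all(c("gene", "hgvs_p") %in% names(variants)) && length(ann$protein)) {
    k <- paste(variants$gene, variants$hgvs_p, sep = ":")
    hit <- k %in% names(ann$protein)
    out[hit] <- unname(ann$protein[k[hit]])
  }
  if (all(c("chrom", "pos", "ref", "alt") %in% names(variants)) &&
      length(ann$genomic)) {
    k <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = ":")
    hit <- k %in% names(ann$genomic)
    out[hit] <- unname(ann$genomic[k[hit]])  # genomic key takes precedence
  }
  out
}
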