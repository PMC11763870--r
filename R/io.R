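# table dialects: tab-separated with header, no quoting, NA as "NA".
# chromosome names are stored without a "chr" prefix; both accepted on read.

strip_chr <- function(x) sub("^chr", "", as.character(x))

#' Read / write the package's TSV and CSV table dialects
#'
#' All interchange tables (variant, SNP, imbalance, coverage) are
#' tab-separated with a header row; clinical and survival tables are CSV.
#' Writing then reading any table is lossless for the column types used.
#'
#' @param path File path.
#' @param required Character vector of columns that must be present.
#' @return data.frame.
#' @export
read_table_checked <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE,
                          quote = "", comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(basename(path), " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  if ("chrom" %in% names(df)) df$chrom <- strip_chr(df$chrom)
  df
}

#' @rdname read_table_checked
#' @param df data.frame to write.
#' @export
write_table_checked <- function(df, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant table (TSV dialect)
#' @param path Path to a variant TSV.
#' @return data.frame with at least the filter-chain columns; `vaf` is
#'   recomputed from depths when absent.
#' @export
read_variants <- function(path) {
  df <- read_table_checked(path, c("patient_id", "gene", "total_depth",
                                   "alt_depth", "qual", "pvalue",
                                   "consequence", "clin_class"))
  if (!"vaf" %in% names(df)) {
    df$vaf <- compute_vaf(df$alt_depth, df$total_depth)
  }
  df
}

#' Read a SNP observation table (TSV dialect)
#' @param path Path to a SNP TSV.
#' @return data.frame; `vaf` recomputed from depths when absent.
#' @export
read_snps <- function(path) {
  df <- read_table_checked(path, c("patient_id", "rsid", "chrom", "arm",
                                   "total_depth", "alt_depth"))
  if (!"vaf" %in% names(df)) {
    df$vaf <- compute_vaf(df$alt_depth, df$total_depth)
  }
  df
}

#' Read clinical and survival tables (CSV dialect)
#' @param path Path to a CSV file.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  read_table_checked(path, "patient_id")
}

#' @rdname read_clinical
#' @export
read_survival <- function(path) {
  df <- read_table_checked(path, c("patient_id", "time", "event"))
  if (any(df$time <= 0)) stop("survival times must be positive")
  df
}

#' Read variant calls from a VCF file
#'
#' Uses `VariantAnnotation::readVcf`. Depths come from the `AD` genotype
#' field (ref,alt) or `DP`+`AO`; gene, consequence, clinical class, caller
#' p-value and protein notation come from the INFO keys `GENE`, `CONSEQ`,
#' `CLIN`, `PVAL`, `HGVSP` when present (a sidecar annotation table can
#' supply `clin_class` afterwards via [classify_variant()]).
#'
#' @param path Path to a VCF (4.x) file.
#' @param patient_id Patient identifier; defaults to the first sample name.
#' @return Variant data.frame in the package dialect.
#' @export
read_vcf <- function(path, patient_id = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  if (n == 0) stop("VCF contains no records: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  info <- VariantAnnotation::info(vcf)
  if (is.null(patient_id)) {
    smp <- colnames(vcf)
    patient_id <- if (length(smp)) smp[1] else "SAMPLE"
  }
  get_info <- function(key, default = NA) {
    if (key %in% names(info)) {
      v <- info[[key]]
      if (!is.atomic(v)) v <- vapply(as.list(v), function(e) {
        if (length(e)) as.character(e[1]) else NA_character_
      }, character(1))
      v
    } else rep(default, n)
  }
  alt_depth <- total_depth <- rep(NA_real_, n)
  if ("AD" %in% names(geno)) {
    ad <- geno$AD
    for (i in seq_len(n)) {
      v <- ad[i, 1][[1]]
      if (length(v) >= 2) {
        alt_depth[i] <- v[2]
        total_depth[i] <- sum(v)
      }
    }
  }
  if (anyNA(total_depth) && "DP" %in% names(geno)) {
    dp <- as.numeric(geno$DP[, 1])
    total_depth[is.na(total_depth)] <- dp[is.na(total_depth)]
  }
  if (anyNA(alt_depth) && "AO" %in% names(info)) {
    ao <- suppressWarnings(as.numeric(get_info("AO")))
    alt_depth[is.na(alt_depth)] <- ao[is.na(alt_depth)]
  }
  if (anyNA(alt_depth) || anyNA(total_depth)) {
    stop("VCF lacks usable depth fields (need genotype AD, or DP with INFO AO)")
  }
  alt_char <- vapply(seq_len(n), function(i) {
    as.character(rr$ALT[[i]][1])
  }, character(1))
  data.frame(
    patient_id = patient_id,
    gene = get_info("GENE", NA_character_),
    chrom = strip_chr(as.character(GenomicRanges::seqnames(rr))),
    pos = BiocGenerics::start(rr),
    ref = as.character(rr$REF),
    alt = alt_char,
    total_depth = total_depth,
    alt_depth = alt_depth,
    vaf = compute_vaf(alt_depth, total_depth),
    qual = as.numeric(rr$QUAL),
    pvalue = suppressWarnings(as.numeric(get_info("PVAL", NA))),
    consequence = get_info("CONSEQ", "OTHER"),
    clin_class = get_info("CLIN", "NOVEL"),
    hgvs_p = get_info("HGVSP", NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Write a simulated cohort to a directory of interchange files
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    variants = file.path(dir, "variants.tsv"),
    snps = file.path(dir, "snps.tsv"),
    clinical = file.path(dir, "clinical.csv"),
    survival = file.path(dir, "survival.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_table_checked(cohort$variants, paths[["variants"]])
  write_table_checked(cohort$snps, paths[["snps"]])
  write_table_checked(cohort$clinical, paths[["clinical"]])
  write_table_checked(cohort$survival, paths[["survival"]])
  truth <- cohort$truth
  truth$copy_state <- as.data.frame(truth$copy_state)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
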