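#' Gene categories of the 15-gene uveal melanoma panel
#'
#' The panel recognises 15 genes grouped into four pairwise-disjoint
#' categories: Galpha-q pathway initiating drivers, second-hit prognostic
#' genes, emergent biomarkers, and a positive-control gene not expected to be
#' mutated in uveal melanoma.
#'
#' @return Named list of character vectors with elements `INITIATING`,
#'   `PROGNOSTIC`, `EMERGENT` and `CONTROL`.
#' @export
#' @examples
#' gene_categories()$INITIATING
gene_categories <- function() {
  list(
    INITIATING = c("CYSLTR2", "GNA11", "GNAQ", "PLCB4"),
    PROGNOSTIC = c("BAP1", "EIF1AX", "SF3B1", "SRSF2"),
    EMERGENT   = c("CDKN2A", "CENPE", "FOXO1", "HIF1A", "RPL5", "TP53"),
    CONTROL    = "BRAF"
  )
}

#' All 15 panel gene symbols
#' @return Character vector of the panel's gene symbols, sorted.
#' @export
panel_genes <- function() {
  sort(unname(unlist(gene_categories())))
}

# genes targeted over their whole coding sequence vs hotspot exons
full_cds_genes <- function() {
  c("BAP1", "CDKN2A", "CENPE", "FOXO1", "HIF1A", "RPL5", "SRSF2", "TP53")
}

hotspot_genes <- function() {
  c("BRAF", "CYSLTR2", "EIF1AX", "GNA11", "GNAQ", "PLCB4", "SF3B1")
}

#' Category of a panel gene
#'
#' @param gene Gene symbol (one of the 15 panel genes).
#' @return One of `"INITIATING"`, `"PROGNOSTIC"`, `"EMERGENT"`, `"CONTROL"`.
#' @export
#' @examples
#' category_of("GNAQ")  # INITIATING
#' category_of("BAP1")  # PROGNOSTIC
category_of <- function(gene) {
  stopifnot(is.character(gene), length(gene) >= 1L)
  cats <- gene_categories()
  lookup <- rep(names(cats), lengths(cats))
  names(lookup) <- unlist(cats)
  unknown <- setdiff(gene, names(lookup))
  if (length(unknown)) {
    stop("not a panel gene: ", paste(unknown, collapse = ", "))
  }
  unname(lookup[gene])
}

#' Path to the bundled reconstructed panel definition
#'
#' The coordinates in this file are a synthetic reconstruction (approximate
#' hg19 gene intervals and invented rs-numbered SNP positions); the structure
#' — 15 genes, 55 SNP loci on both arms of chromosomes 1, 3 and 8, and 418
#' amplicons in two primer pools — matches the reference panel.
#'
#' @return File path to the bundled panel TSV.
#' @export
bundled_panel_path <- function() {
  system.file("extdata", "panel_synthetic_reference.tsv",
              package = "umprofiler", mustWork = TRUE)
}

#' Load and validate a panel definition
#'
#' The panel file is a two-section TSV: a `[regions]` section (chrom, start,
#' end, gene, pool, mode) and a `[snps]` section (rsid, chrom, arm, pos).
#' Comment lines start with `#`; a `# coords=bed` header marks region
#' coordinates as 0-based half-open (BED), converted to 1-based inclusive on
#' load. A `# amplicon_count=N` header records the panel's amplicon total.
#'
#' @param path Path to a panel-definition file.
#' @return Object of class `panel_definition` with elements `regions`
#'   (data.frame), `snps` (data.frame) and `amplicon_count` (integer).
#' @export
#' @examples
#' pan <- load_panel(bundled_panel_path())
#' nrow(pan$snps)  # 55
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  coords <- "1-based"
  amplicon_count <- NA_integer_
  for (h in grep("^#", lines, value = TRUE)) {
    if (grepl("coords=bed", h, fixed = TRUE)) coords <- "bed"
    m <- regmatches(h, regexec("amplicon_count=([0-9]+)", h))[[1]]
    if (length(m) == 2L) amplicon_count <- as.integer(m[2])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  ri <- which(body == "[regions]")
  si <- which(body == "[snps]")
  if (length(ri) != 1L || length(si) != 1L || si <= ri) {
    stop("panel file must contain a [regions] section followed by a [snps] section")
  }
  parse_section <- function(txt, what) {
    if (length(txt) < 2L) stop("empty ", what, " section")
    utils::read.delim(text = paste(txt, collapse = "\n"),
                      stringsAsFactors = FALSE, check.names = TRUE)
  }
  regions <- parse_section(body[(ri + 1L):(si - 1L)], "regions")
  snps <- parse_section(body[(si + 1L):length(body)], "snps")

  need_r <- c("chrom", "start", "end", "gene", "pool", "mode")
  if (!all(need_r %in% names(regions))) {
    stop("regions section must have columns: ", paste(need_r, collapse = ", "))
  }
  need_s <- c("rsid", "chrom", "arm", "pos")
  if (!all(need_s %in% names(snps))) {
    stop("snps section must have columns: ", paste(need_s, collapse = ", "))
  }

  regions$start <- suppressWarnings(as.numeric(regions$start))
  regions$end <- suppressWarnings(as.numeric(regions$end))
  bad <- which(is.na(regions$start) | is.na(regions$end))
  if (length(bad)) {
    stop("malformed region coordinates at regions row ", bad[1])
  }
  if (coords == "bed") {
    regions$start <- regions$start + 1  # 0-based half-open -> 1-based inclusive
  }
  bad <- which(regions$start > regions$end)
  if (length(bad)) {
    stop(sprintf("region start > end for gene %s (regions row %d)",
                 regions$gene[bad[1]], bad[1]))
  }
  unknown <- setdiff(unique(regions$gene), panel_genes())
  if (length(unknown)) {
    stop("unknown gene symbol in panel: ", paste(unknown, collapse = ", "))
  }
  if (!all(regions$mode %in% c("FULL_CDS", "HOTSPOT"))) {
    stop("region mode must be FULL_CDS or HOTSPOT")
  }
  if (!all(regions$pool %in% c(1L, 2L))) stop("pool must be 1 or 2")

  snps$chrom <- as.character(snps$chrom)
  if (!all(snps$chrom %in% c("1", "3", "8"))) {
    stop("SNP loci must lie on chromosomes 1, 3 or 8")
  }
  if (!all(snps$arm %in% c("p", "q"))) stop("SNP arm must be 'p' or 'q'")
  snps$pos <- as.integer(snps$pos)
  if (anyNA(snps$pos)) stop("malformed SNP position")
  if (anyDuplicated(snps$rsid)) stop("duplicated SNP rsid")

  structure(
    list(regions = regions, snps = snps, amplicon_count = amplicon_count),
    class = "panel_definition"
  )
}

#' Write a panel definition back to its two-section TSV format
#'
#' `load_panel(write_panel(pan, f))` round-trips regions and SNP loci.
#'
#' @param panel A `panel_definition`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_definition"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# umprofiler panel definition",
    sprintf("# amplicon_count=%d", panel$amplicon_count),
    "[regions]"
  ), con)
  utils::write.table(panel$regions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("[snps]", con)
  utils::write.table(panel$snps, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf(
    "Panel definition: %d genes, %d regions, %d SNP loci, %s amplicons\n",
    length(unique(x$regions$gene)), nrow(x$regions), nrow(x$snps),
    ifelse(is.na(x$amplicon_count), "?", x$amplicon_count)
  ))
  invisible(x)
}
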