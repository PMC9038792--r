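## Tabular interchange. TSV is the primary on-disk format; coordinates are
## 1-based inclusive on disk and 0-based half-open internally. A minimal
## VCF (AD/DP) is accepted as a convenience SNP input via VariantAnnotation.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    abort(paste0(what, " is missing required column(s): ",
                 paste(miss, collapse = ", ")),
          "lohscape_error_schema")
  invisible(df)
}

#' Read a per-sample alteration call table
#'
#' TSV with columns `sample`, `gene`, `alt_class`, `pathogenicity`. Rows
#' whose pathogenicity is not `known` or `likely` (variants of unknown
#' significance) are dropped, with the drop count reported; an alteration
#' class outside the closed vocabulary is an error naming the offending
#' line(s).
#'
#' @param path TSV path.
#' @return data.frame of kept records; attribute `n_dropped` counts excluded
#'   rows.
#' @export
read_alteration_table <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("sample", "gene", "alt_class", "pathogenicity"),
                  "alteration table")
  bad <- which(!df$alt_class %in% alteration_classes())
  if (length(bad))
    abort(paste0("unknown alt_class at line(s) ",
                 paste(bad + 1L, collapse = ", "), " of ", path),
          "lohscape_error_schema")
  keep <- df$pathogenicity %in% c("known", "likely")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " row(s) excluded (variants of unknown significance)")
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_drop
  out
}

#' Write the cohort's alteration indicators as a long call table
#'
#' @param cohort an `lms_cohort`.
#' @param path output TSV.
#' @param pathogenicity value written for every call (default "known").
#' @return the path, invisibly.
#' @export
write_alteration_table <- function(cohort, path, pathogenicity = "known") {
  M <- as_alteration_matrix(cohort)
  idx <- which(M != 0, arr.ind = TRUE)
  keys <- colnames(M)[idx[, 2]]
  df <- data.frame(sample = cohort$samples$sample[idx[, 1]],
                   gene = key_gene(keys), alt_class = key_class(keys),
                   pathogenicity = pathogenicity)
  df <- df[order(df$sample, df$gene), ]
  write_tsv(df, path)
}

#' Assemble an alteration indicator matrix from long call records
#'
#' @param samples character vector of sample ids (row order of the matrix).
#' @param records data.frame from [read_alteration_table()].
#' @return binary matrix, one column per observed "GENE:class" key.
#' @export
alteration_matrix <- function(samples, records) {
  keys <- sort(unique(alt_key(records$gene, records$alt_class)))
  M <- matrix(0L, length(samples), length(keys),
              dimnames = list(NULL, keys))
  ri <- match(records$sample, samples)
  ok <- !is.na(ri)
  M[cbind(ri[ok], match(alt_key(records$gene, records$alt_class)[ok], keys))] <- 1L
  M
}

#' Read SNP observations from TSV or minimal VCF
#'
#' TSV columns: `sample` (optional), `chrom`, `pos` (1-based), `depth`,
#' `alt_count`, optional `ref_depth`. A `.vcf` file is parsed with
#' VariantAnnotation and must carry per-sample `AD` (and optionally `DP`)
#' FORMAT fields. Non-autosomal records are skipped with a reported count;
#' positions are converted to the internal 0-based convention.
#'
#' @param path input file; format chosen by extension (`.vcf` vs TSV).
#' @return data.frame `chrom` (integer), `pos` (0-based), `depth`,
#'   `alt_count` (+ `ref_depth`, `sample` when available); attribute
#'   `n_skipped` counts non-autosome records.
#' @export
read_snp_observations <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    return(read_snp_vcf(path))
  df <- read_tsv(path)
  require_columns(df, c("chrom", "pos", "depth", "alt_count"),
                  "SNP observation table")
  chrom <- suppressWarnings(as.integer(df$chrom))
  auto <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  named <- grepl("^(chr)?([0-9XYM]+)$", as.character(df$chrom))
  if (any(!named))
    abort(paste0("malformed chromosome at line(s) ",
                 paste(which(!named)[1:min(5, sum(!named))] + 1L,
                       collapse = ", "), " of ", path),
          "lohscape_error_parse")
  pos <- suppressWarnings(as.numeric(df$pos))
  if (anyNA(pos) || any(pos < 1))
    abort(paste0("malformed coordinate at line(s) ",
                 paste(which(is.na(pos) | pos < 1)[1] + 1L, collapse = ", "),
                 " of ", path),
          "lohscape_error_parse")
  n_skip <- sum(!auto)
  if (n_skip > 0) message(n_skip, " non-autosome record(s) skipped")
  out <- df[auto, , drop = FALSE]
  out$chrom <- chrom[auto]
  out$pos <- pos[auto] - 1 # to 0-based
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skip
  out
}

read_snp_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    abort("reading VCF requires the VariantAnnotation package",
          "lohscape_error_missing_dependency")
  vcf <- VariantAnnotation::readVcf(path)
  chrom_chr <- as.character(GenomeInfoDb::seqnames(
    SummarizedExperiment::rowRanges(vcf)))
  pos1 <- BiocGenerics::start(SummarizedExperiment::rowRanges(vcf))
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad))
    abort("VCF has no AD FORMAT field", "lohscape_error_schema")
  ad1 <- ad[, 1] # first sample
  ref_n <- vapply(ad1, function(v) as.numeric(v[1]), numeric(1))
  alt_n <- vapply(ad1, function(v) as.numeric(v[2]), numeric(1))
  dp <- VariantAnnotation::geno(vcf)$DP
  depth <- if (!is.null(dp)) as.numeric(dp[, 1]) else ref_n + alt_n
  chrom <- suppressWarnings(as.integer(sub("^chr", "", chrom_chr)))
  auto <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  n_skip <- sum(!auto)
  if (n_skip > 0) message(n_skip, " non-autosome record(s) skipped")
  out <- data.frame(chrom = chrom[auto], pos = pos1[auto] - 1,
                    depth = depth[auto], alt_count = alt_n[auto])
  attr(out, "n_skipped") <- n_skip
  out
}

#' Write SNP observations as TSV
#'
#' @param obs observation data.frame (internal 0-based positions).
#' @param path output TSV (positions written 1-based).
#' @param sample_id sample label written in the `sample` column.
#' @return the path, invisibly.
#' @export
write_snp_obs <- function(obs, path, sample_id = "sample") {
  df <- data.frame(sample = sample_id, chrom = obs$chrom, pos = obs$pos + 1,
                   depth = obs$depth, alt_count = obs$alt_count)
  if (!is.null(obs$ref_depth)) df$ref_depth <- obs$ref_depth
  write_tsv(df, path)
}

#' Write SNP observations as a minimal VCF (GT:AD:DP)
#'
#' @inheritParams write_snp_obs
#' @return the path, invisibly.
#' @export
write_snp_vcf <- function(obs, path, sample_id = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample_id)), con)
  ref_n <- obs$depth - obs$alt_count
  writeLines(sprintf("%d\t%d\t.\tA\tC\t.\tPASS\t.\tGT:AD:DP\t0/1:%d,%d:%d",
                     obs$chrom, obs$pos + 1, ref_n, obs$alt_count, obs$depth),
             con)
  invisible(path)
}

#' Write a scored segment table as SEG-like TSV
#'
#' @param segs `cn_segments` with states and exclusion flags.
#' @param path output TSV; `start`/`end` written 1-based inclusive.
#' @param sample_id sample label.
#' @return the path, invisibly.
#' @export
write_seg <- function(segs, path, sample_id = "sample") {
  df <- data.frame(sample = sample_id, chrom = segs$chrom,
                   start = segs$start + 1, end = segs$end,
                   n_snps = segs$n_snps,
                   log_ratio = round(segs$mean_log_ratio, 4),
                   Ci = segs$Ci, Mi = segs$Mi, is_loh = segs$is_loh,
                   excluded = segs$excluded,
                   reason = segs$exclusion_reason)
  write_tsv(df, path)
}

#' Read a SEG-like segment table back to internal coordinates
#'
#' @param path TSV written by [write_seg()] (or equivalent 1-based table).
#' @return data.frame with 0-based half-open `start`/`end`.
#' @export
read_seg <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("chrom", "start", "end"), "segment table")
  df$start <- df$start - 1
  df
}

#' Write / read a cohort sample table
#' @param cohort an `lms_cohort`.
#' @param path TSV path.
#' @return the path (writer) or a data.frame (reader).
#' @export
write_cohort_tsv <- function(cohort, path) {
  write_tsv(cohort$samples, path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("sample", "gloh"), "cohort table")
  df
}
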