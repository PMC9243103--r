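# Writers/readers for the plain-text interchange formats the pipeline uses:
# summary-statistics TSV, dosage TSV, minimal VCF with a DS FORMAT field,
# BED-like gene models (1-based inclusive), GMT gene sets, and an ATC
# drug-target table. Reading is gzip-transparent (base connections).

#' Write summary statistics to TSV
#' @param sumstats data.frame with the canonical columns
#'   SNP CHR BP A1 A2 FRQ BETA SE P N_CASES N_CONTROLS INFO.
#' @param path Output file (".gz" suffix writes gzip).
#' @export
write_sumstats <- function(sumstats, path) {
  write_tsv(sumstats, path)
  invisible(path)
}

#' Write a dosage matrix to TSV (variants x individuals after transpose)
#' @param panel A \code{reference_panel} or a \code{sim_cohort}.
#' @param path Output file.
#' @export
write_dosage_tsv <- function(panel, path) {
  g <- panel$genotypes
  df <- data.frame(SNP = colnames(g), t(g), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("SNP", sprintf("IND%04d", seq_len(nrow(g))))
  write_tsv(df, path)
  invisible(path)
}

#' Write panel genotypes as a minimal VCF with dosages in the DS field
#' @param panel A \code{reference_panel}.
#' @param path Output file.
#' @export
write_vcf_dosage <- function(panel, path) {
  v <- panel$variants
  g <- panel$genotypes
  con <- file_conn(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT",
                       sprintf("IND%04d", seq_len(nrow(g)))),
                     collapse = "\t")), con)
  body <- vapply(seq_len(nrow(v)), function(j)
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$a2[j], v$a1[j], ".", "PASS",
            ".", "DS", format(g[, j])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write gene models to a BED-like TSV (1-based inclusive coordinates)
#' @param genes data.frame GENE CHR START END STRAND.
#' @param path Output file.
#' @export
write_gene_models <- function(genes, path) {
  write_tsv(genes, path)
  invisible(path)
}

#' Read gene models from a BED-like TSV
#' @param path Input file.
#' @return data.frame GENE CHR START END STRAND.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("GENE", "CHR", "START", "END", "STRAND")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop_param("gene model file missing column(s): %s",
               paste(miss, collapse = ", "))
  if (!all(df$STRAND %in% c("+", "-")))
    stop_param("unknown strand symbol in gene models (must be + or -)")
  df
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors of gene ids.
#' @param path Output file.
#' @param description Second GMT column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  con <- file_conn(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read gene sets from GMT format
#' @param path Input file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  con <- file_conn(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_param("malformed GMT line: %s", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write a drug-target/ATC table
#' @param atc data.frame DRUG ATC_CODE GENE.
#' @param path Output file.
#' @export
write_atc_table <- function(atc, path) {
  write_tsv(atc, path)
  invisible(path)
}

#' Read a drug-target/ATC table
#' @param path Input file.
#' @return data.frame DRUG ATC_CODE GENE.
#' @export
read_atc_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("DRUG", "ATC_CODE", "GENE"), colnames(df))
  if (length(miss))
    stop_param("ATC table missing column(s): %s", paste(miss, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  con <- file_conn(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

# gzip-transparent connection by extension
file_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}
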