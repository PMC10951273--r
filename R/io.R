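# Interchange readers/writers. Canonical formats are headed CSV/TSV:
# pedigree CSV (id,sire,dam,birth_year; 0/empty = unknown parent), genotype
# TSV (rows = individuals, columns = markers, NA = missing), map TSV
# (marker,chrom,pos in cM), phenotype CSV (hybrid,block,year,location,
# trait,value). VCF is supported on ingestion only.

#' Read a pedigree CSV
#'
#' Rows may appear in any order; the result is topologically sorted and
#' fully validated (duplicates, self-parentage, cycles).
#'
#' @param path CSV with header id,sire,dam,birth_year.
#' @param complete add missing parents as founder records (default TRUE).
#' @export
read_pedigree <- function(path, complete = TRUE) {
  pedigree(read.csv(path, colClasses = "character"), complete = complete)
}

#' Write a pedigree CSV
#' @param ped a [pedigree()].
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"; df$dam[is.na(df$dam)] <- "0"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dosage matrix (TSV or VCF)
#'
#' TSV: individuals in rows (first column id), markers in columns, values
#' 0/1/2 with `NA` for missing. VCF (via the vcfR package): biallelic
#' records only, GT mapped 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, ./. ->
#' missing; multiallelic records are skipped with a message.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return raw dosage matrix (pass to [qc_genotypes()]).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    bad <- m[!is.na(m)]
    assert(all(bad == round(bad) & bad %in% 0:2), "non-integer or out-of-range dosage")
    return(m)
  }
  assert(requireNamespace("vcfR", quietly = TRUE), "reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  multi <- grepl(",", vcfR::getFIX(v)[, "ALT"])
  if (any(multi)) {
    message("skipping ", sum(multi), " multiallelic VCF record(s)")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    ifelse(g %in% c("0/0"), 0, ifelse(g %in% c("0/1", "1/0"), 1,
      ifelse(g %in% c("1/1"), 2, NA)))
  }
  m <- t(apply(gt, 2, code))
  colnames(m) <- rownames(gt)
  m
}

#' Write a dosage matrix as TSV
#' @param m dosage matrix (rows named by individual).
#' @param path output path.
#' @export
write_genotypes <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genetic map TSV (marker, chrom, pos)
#' @param path input path.
#' @export
read_map <- function(path) {
  df <- read.delim(path)
  genetic_map(df$marker, df$chrom, df$pos)
}

#' Write a genetic map TSV
#' @param map a [genetic_map()].
#' @param path output path.
#' @export
write_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read long-format trial phenotypes (CSV)
#' @param path CSV with header hybrid,block,year,location,trait,value.
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path)
  assert(all(c("hybrid", "block", "year", "value") %in% names(df)),
         "phenotype file needs columns hybrid, block, year, value")
  df
}

#' Write long-format trial phenotypes (CSV)
#' @param df phenotype data frame.
#' @param path output path.
#' @export
write_phenotypes <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a GEBV table (CSV)
#' @param gebv data frame from [fit_ssblup()].
#' @param path output path.
#' @export
write_gebv <- function(gebv, path) {
  write.csv(gebv, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GEBV table (CSV)
#' @param path input path.
#' @export
read_gebv <- function(path) read.csv(path)

#' Write a relationship matrix as id-indexed TSV
#' @param M a `relmatrix`.
#' @param path output path.
#' @export
write_relmatrix <- function(M, path) {
  df <- data.frame(id = rownames(M), unclass(M), check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a relationship matrix TSV
#' @param path input path.
#' @param kind matrix kind label ("A", "G" or "H").
#' @export
read_relmatrix <- function(path, kind = "A") {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  new_relmatrix(m, kind)
}
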