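#' Read and write genotype matrices as TSV
#'
#' The matrix file is lines x markers with a leading `line` column and
#' `-1/0/1` calls (`NA` for missing). Marker map and line metadata travel
#' in sidecar TSVs (`<path>.map.tsv`: `marker`, `chrom`, `pos_cm`;
#' `<path>.lines.tsv`: `line`, `population`, `parent1`, `parent2`), written
#' and read automatically.
#'
#' @param geno A [geno_matrix()].
#' @param path Path of the matrix TSV.
#' @return `write_geno_tsv()` returns `path` invisibly; `read_geno_tsv()`
#'   returns a [geno_matrix()].
#' @export
write_geno_tsv <- function(geno, path) {
  m <- geno_calls(geno)
  df <- data.frame(line = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(marker_map(geno), paste0(path, ".map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(line_info(geno), paste0(path, ".lines.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  map <- as_tibble(read.table(paste0(path, ".map.tsv"), header = TRUE,
                              sep = "\t"))
  lines <- as_tibble(read.table(paste0(path, ".lines.tsv"), header = TRUE,
                                sep = "\t", na.strings = c("NA", "")))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$line
  geno_matrix(m, map, lines)
}

#' Write genotypes as a minimal VCF 4.2 file
#'
#' One record per marker with `GT` calls (`0/0`, `0/1`, `1/1`, `./.` for
#' coded `-1/0/+1/NA`), contigs from the map's chromosomes, and 1-based
#' positions derived from map positions (`round(pos_cm * 1e4) + 1`). The
#' REF/ALT alleles are placeholders (`A`/`T`): the coding, not the
#' nucleotides, carries the information.
#'
#' @param geno A [geno_matrix()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_geno_vcf <- function(geno, path) {
  m <- geno_calls(geno)
  map <- marker_map(geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=soygs",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s>", unique(paste0("chr", map$chrom)))
  ), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(m)), collapse = "\t"), con)
  gt <- matrix("./.", nrow = ncol(m), ncol = nrow(m))
  codes <- c(`-1` = "0/0", `0` = "0/1", `1` = "1/1")
  for (v in c(-1, 0, 1)) gt[t(m) == v] <- codes[[as.character(v)]]
  body <- paste0(
    "chr", map$chrom, "\t", as.integer(round(map$pos_cm * 1e4)) + 1L, "\t",
    map$marker, "\tA\tT\t.\tPASS\t.\tGT\t",
    apply(gt, 1, paste, collapse = "\t")
  )
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from a VCF written by [write_geno_vcf()]
#'
#' Uses the vcfR package. Line metadata is not stored in VCF; supply it (or
#' it defaults to a single unknown population).
#'
#' @param path VCF path.
#' @param line_info Optional tibble `line`, `population`, `parent1`,
#'   `parent2`.
#' @return A [geno_matrix()]; `pos_cm` is recovered as `(POS - 1) / 1e4`.
#' @export
read_geno_vcf <- function(path, line_info = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_geno_vcf() needs the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  code <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt == "0/0"] <- -1
  code[gt == "0/1" | gt == "1/0"] <- 0
  code[gt == "1/1"] <- 1
  fix <- vcfR::getFIX(v)
  map <- tibble(
    marker = fix[, "ID"],
    chrom = as.integer(sub("^chr", "", fix[, "CHROM"])),
    pos_cm = (as.numeric(fix[, "POS"]) - 1) / 1e4
  )
  if (is.null(line_info)) {
    line_info <- tibble(line = colnames(gt), population = "unknown",
                        parent1 = NA_character_, parent2 = NA_character_)
  }
  geno_matrix(t(code), map, line_info)
}

#' Read/write the long-format phenotype and BLUP tables
#'
#' Phenotype CSV header: `line,env,set,block,dtm_class,trait,value`.
#' BLUP CSV header: `line,trait,blup`.
#'
#' @param pheno,blups The tibbles to write.
#' @param path CSV path.
#' @return Writers return `path` invisibly; readers return a tibble.
#' @export
write_pheno_csv <- function(pheno, path) {
  cols <- c("line", "env", "set", "block", "dtm_class", "trait", "value")
  stopifnot(all(cols %in% names(pheno)))
  utils::write.csv(pheno[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pheno_csv
#' @export
read_pheno_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_pheno_csv
#' @export
write_blup_csv <- function(blups, path) {
  stopifnot(all(c("line", "trait", "blup") %in% names(blups)))
  utils::write.csv(blups[c("line", "trait", "blup")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pheno_csv
#' @export
read_blup_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
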