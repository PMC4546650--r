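# Readers and writers. Canonical tabular dialect: UTF-8 TSV, '.' decimal,
# 'NA' missing; every writer stamps the generating seed in a '#' comment
# header so artifacts are self-describing.

seed_header <- function(con, what, seed) {
  if (!is.null(seed))
    writeLines(sprintf("# demostrat %s seed=%s", what, seed), con)
}

#' Write a pedigree as a PLINK-FAM-style file
#'
#' Whitespace-delimited, six columns: family id, individual id, father id,
#' mother id, sex (1 = M, 2 = W), phenotype placeholder (-9). Absent
#' parents are written as 0. A `#` comment header carries the seed.
#'
#' @param ped pedigree data frame.
#' @param path output path.
#' @param seed seed to stamp in the header (optional).
#' @export
write_pedigree <- function(ped, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  seed_header(con, "pedigree", seed)
  fam <- data.frame(
    family_id = ped$family_id, id = ped$id,
    father_id = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother_id = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "M", 1L, 2L), phenotype = -9L)
  write.table(fam, con, quote = FALSE, sep = " ", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a PLINK-FAM-style pedigree
#'
#' Accepts any whitespace delimiter and `#` comment lines; order of rows is
#' irrelevant (children may precede their parents). Sex codes 1/2 map to
#' M/W; a parent id of 0 means absent. Generation is inferred
#' topologically: founders are generation 1 and each child is one
#' generation below its parents; married-in founders cannot be
#' distinguished from lineage founders by the FAM format alone.
#'
#' @param path input path.
#' @return A `pedigree` data frame (without birth years or biospecimen
#'   ages, which the FAM format does not carry).
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  data_ln <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  fields <- strsplit(trimws(lines[data_ln]), "\\s+")
  bad <- which(lengths(fields) < 6)
  if (length(bad))
    stop("pedigree parse error at line ", data_ln[bad[1]],
         ": expected 6 whitespace-delimited fields", call. = FALSE)
  m <- do.call(rbind, fields)
  dup <- which(duplicated(m[, 2]))
  if (length(dup))
    stop("pedigree parse error at line ", data_ln[dup[1]],
         ": duplicate individual id '", m[dup[1], 2], "'", call. = FALSE)
  if (!all(m[, 5] %in% c("1", "2")))
    stop("pedigree parse error: sex codes must be 1 (M) or 2 (W)",
         call. = FALSE)
  ped <- data.frame(
    id = m[, 2], family_id = m[, 1],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = ifelse(m[, 5] == "1", "M", "W"),
    stringsAsFactors = FALSE)
  for (col in c("father_id", "mother_id")) {
    known <- is.na(ped[[col]]) | ped[[col]] %in% ped$id
    if (!all(known)) {
      i <- which(!known)[1]
      stop("pedigree parse error at line ", data_ln[i], ": unknown ",
           col, " '", ped[[col]][i], "'", call. = FALSE)
    }
  }
  # topological depth; a cycle leaves unresolved individuals
  depth <- ifelse(is.na(ped$father_id) & is.na(ped$mother_id), 1L,
                  NA_integer_)
  fa <- match(ped$father_id, ped$id); mo <- match(ped$mother_id, ped$id)
  for (iter in seq_len(nrow(ped))) {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    pd <- pmax(depth[fa[todo]], depth[mo[todo]])
    depth[todo] <- pd + 1L
  }
  if (anyNA(depth))
    stop("pedigree parse error: cyclic parentage involving '",
         ped$id[which(is.na(depth))[1]], "'", call. = FALSE)
  ped$generation <- depth
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Write / read the long-format phenotype table
#'
#' Tab-delimited with header, `NA` for missing, seed stamped in a comment
#' line. The write-read round trip is the identity for all fields.
#'
#' @param pheno phenotype data frame.
#' @param path file path.
#' @param seed optional seed stamp.
#' @export
write_phenotypes <- function(pheno, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  seed_header(con, "phenotypes", seed)
  write.table(pheno, con, quote = FALSE, sep = "\t", row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  pheno <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
  if ("tc_mgdl" %in% names(pheno)) {
    if (!is.numeric(pheno$tc_mgdl))
      stop("phenotype parse error: non-numeric tc_mgdl", call. = FALSE)
    if (any(pheno$tc_mgdl <= 0, na.rm = TRUE))
      stop("phenotype parse error: tc_mgdl must be > 0", call. = FALSE)
  }
  dup <- duplicated(pheno[, c("individual_id", "exam_index")])
  if (any(dup))
    stop("phenotype parse error: duplicate (individual, exam) record",
         call. = FALSE)
  pheno
}

#' Write / read a genotype dosage matrix as TSV
#'
#' First column `individual_id`, one column per SNP with minor-allele
#' dosages 0/1/2 (`NA` missing).
#'
#' @param geno dosage matrix with row names = individual ids.
#' @param path file path.
#' @param seed optional seed stamp.
#' @export
write_genotypes <- function(geno, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  seed_header(con, "genotypes", seed)
  df <- data.frame(individual_id = rownames(geno), geno,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  geno <- as.matrix(df[, -1, drop = FALSE])
  rownames(geno) <- df$individual_id
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop("genotype parse error: dosages must be 0, 1, 2 or NA",
         call. = FALSE)
  storage.mode(geno) <- "integer"
  geno
}

#' Read genotype dosages from a VCF
#'
#' Derives dosages from the GT field as the count of ALT alleles (the
#' files this package writes and expects encode the minor allele as ALT);
#' missing genotypes (`./.`) give missing dosage. Requires the vcfR
#' package.
#'
#' @param path VCF path (plain or gzipped).
#' @return Integer dosage matrix, rows = individuals, columns = SNP ids.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    if (is.na(g) || grepl("\\.", g)) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  }
  geno <- apply(gt, c(1, 2), count_alt)
  t(geno)
}

#' Write a cell scan as TSV
#'
#' Fixed column order mirroring the supplementary association tables:
#' snp, sex, generation, stratum, n, beta, se, p, class.
#'
#' @param scan a `cell_scan`.
#' @param path file path.
#' @param seed optional seed stamp.
#' @export
write_scan <- function(scan, path, seed = NULL) {
  cols <- c("snp_id", "sex", "generation", "age_stratum", "n_individuals",
            "n_records", "beta", "se", "p_value", "class", "model_level",
            "scale", "error")
  con <- file(path, "w")
  on.exit(close(con))
  seed_header(con, "scan", seed)
  write.table(scan[, cols], con, quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(path)
}
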