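#' Genotype, expression and map readers/writers
#'
#' Genotypes are held as a plain numeric matrix of alt-allele dosages
#' (samples x SNPs, values 0/1/2 or NA for missing) with sample and SNP
#' ids as dimnames, plus a SNP map data frame (`snp_id`, `chromosome`,
#' `position_bp`; both NA when the position is unknown).
#'
#' @name genotype-io
NULL

#' Read genotypes from PLINK-text or VCF
#'
#' For VCF the dosage counts the ALT allele. PLINK .ped/.map files carry
#' no ref/alt designation, so the counted allele is the minor allele
#' observed at read time (ties broken to the alphabetically smaller
#' allele) and is recorded in the returned `alleles` table; the
#' association tests downstream are invariant to this 0/2 relabelling.
#' Multi-allelic VCF records are skipped with a warning; malformed lines
#' are a hard error naming the line.
#'
#' @param path VCF file, or PLINK prefix / .ped path.
#' @param format `"plink_text"` or `"vcf"`.
#' @return list with `dosage` (samples x SNPs), `map`, and for PLINK an
#'   `alleles` data frame (`snp_id`, `counted`, `other`).
#' @export
read_genotypes <- function(path, format = c("plink_text", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") .read_vcf_dosage(path) else .read_plink_text(path)
}

.read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  allele1 <- substr(gt, 1L, 1L)
  allele2 <- substr(gt, 3L, 3L)
  dos <- (allele1 == "1") + (allele2 == "1")
  dos[allele1 == "." | is.na(gt)] <- NA_real_
  dosage <- t(dos)
  colnames(dosage) <- ids
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  unknown <- is.na(chrom) | chrom %in% c("0", ".")
  chrom[unknown] <- NA_character_
  pos[unknown] <- NA_integer_
  map <- data.frame(snp_id = ids, chromosome = chrom, position_bp = pos,
                    stringsAsFactors = FALSE)
  rownames(map) <- NULL
  list(dosage = dosage, map = map)
}

.read_plink_text <- function(path) {
  prefix <- sub("\\.ped$", "", path)
  ped_f <- paste0(prefix, ".ped")
  map_f <- paste0(prefix, ".map")
  if (!file.exists(ped_f)) stop("no such file: ", ped_f, call. = FALSE)
  if (!file.exists(map_f)) stop("no such file: ", map_f, call. = FALSE)
  mp <- utils::read.table(map_f, colClasses = "character")
  if (ncol(mp) < 4L) stop("malformed .map: expected 4 columns",
                          call. = FALSE)
  names(mp)[1:4] <- c("chromosome", "snp_id", "cm", "position_bp")
  n_snp <- nrow(mp)
  lines <- readLines(ped_f)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  dosage <- matrix(NA_real_, n, n_snp)
  sample_ids <- character(n)
  a_mat <- matrix(NA_character_, 2L * n, n_snp)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) != 6L + 2L * n_snp)
      stop("malformed .ped line ", i, ": expected ", 6L + 2L * n_snp,
           " fields, got ", length(f), call. = FALSE)
    sample_ids[i] <- f[2L]
    al <- f[-(1:6)]
    a_mat[2L * i - 1L, ] <- al[seq(1L, by = 2L, length.out = n_snp)]
    a_mat[2L * i, ] <- al[seq(2L, by = 2L, length.out = n_snp)]
  }
  counted <- character(n_snp)
  other <- character(n_snp)
  for (j in seq_len(n_snp)) {
    al <- a_mat[, j]
    al[al == "0"] <- NA_character_
    tab <- sort(table(al))
    if (length(tab) > 2L)
      stop("more than two alleles at SNP ", mp$snp_id[j], call. = FALSE)
    if (length(tab) == 0L) { counted[j] <- NA_character_; next }
    # minor allele counted; tie -> alphabetically smaller
    if (length(tab) == 2L && tab[1L] == tab[2L])
      tab <- tab[order(names(tab))]
    counted[j] <- names(tab)[1L]
    other[j] <- if (length(tab) == 2L) names(tab)[2L] else NA_character_
    cj <- matrix(al == counted[j], nrow = 2L)
    dosage[, j] <- colSums(cj)
  }
  rownames(dosage) <- sample_ids
  colnames(dosage) <- mp$snp_id
  chrom <- mp$chromosome
  pos <- suppressWarnings(as.integer(mp$position_bp))
  unknown <- chrom %in% c("0", "", ".") | is.na(pos) | pos <= 0L
  chrom[unknown] <- NA_character_
  pos[unknown] <- NA_integer_
  map <- data.frame(snp_id = mp$snp_id, chromosome = chrom,
                    position_bp = pos, stringsAsFactors = FALSE)
  list(dosage = dosage, map = map,
       alleles = data.frame(snp_id = mp$snp_id, counted = counted,
                            other = other, stringsAsFactors = FALSE))
}

#' Write genotypes as PLINK .ped/.map
#'
#' Dosage 0/1/2 is written as allele pairs `A A` / `A B` / `B B` (`B` the
#' counted allele), missing as `0 0`. Unknown positions get chromosome 0.
#'
#' @param dosage samples x SNPs matrix.
#' @param map SNP map (`snp_id`, `chromosome`, `position_bp`).
#' @param prefix output path prefix (writes `prefix.ped`, `prefix.map`).
#' @export
write_plink <- function(dosage, map, prefix) {
  map <- map[match(colnames(dosage), map$snp_id), ]
  chrom <- map$chromosome
  pos <- map$position_bp
  chrom[is.na(chrom)] <- "0"
  pos[is.na(pos)] <- 0L
  utils::write.table(
    data.frame(chrom, map$snp_id, 0, pos),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  code <- c("A A", "A B", "B B")
  n <- nrow(dosage)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- dosage[i, ]
    al <- ifelse(is.na(g), "0 0", code[g + 1L])
    lines[i] <- paste(c("FAM", rownames(dosage)[i], "0", "0", "0", "-9", al),
                      collapse = " ")
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Write genotypes as a minimal VCF 4.2
#'
#' REF is `A`, ALT is `B`; dosage counts ALT. SNPs with unknown position
#' are written with CHROM 0 and POS 0.
#'
#' @inheritParams write_plink
#' @param path output .vcf path.
#' @export
write_vcf <- function(dosage, map, path) {
  map <- map[match(colnames(dosage), map$snp_id), ]
  chrom <- ifelse(is.na(map$chromosome), "0", map$chromosome)
  pos <- ifelse(is.na(map$position_bp), 0L, map$position_bp)
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=rankqtl",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(dosage)), collapse = "\t"))
  body <- vapply(seq_len(ncol(dosage)), function(j) {
    g <- dosage[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(chrom[j], pos[j], colnames(dosage)[j], "A", "B", ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write an expression matrix TSV
#'
#' Layout: one header row, first column `sample_id`, one column per
#' transcript; used for both raw and de-correlated expression.
#'
#' @param path TSV file.
#' @return numeric matrix, samples x transcripts.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(sample_id = "character"))
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$sample_id
  storage.mode(M) <- "double"
  if (any(!is.finite(M)))
    stop("expression matrix contains missing/non-finite values",
         call. = FALSE)
  M
}

#' @rdname read_expression
#' @param M matrix to write.
#' @export
write_expression <- function(M, path) .write_matrix_tsv(M, path)

#' Read a covariate CSV (`sample_id`, `season_class`, `age_days`)
#' @param path CSV file.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character"))
  stopifnot(all(c("sample_id", "season_class", "age_days") %in% names(df)))
  df$season_class <- as.character(df$season_class)
  df
}

#' Read a SNP or gene position map TSV
#'
#' SNP maps have columns `snp_id`, `chromosome`, `position_bp`; gene maps
#' `transcript_id`, `gene_id`, `chromosome`, `start`. Chromosome `"0"` or
#' empty means the position is unknown.
#'
#' @param path TSV file.
#' @export
read_snp_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("snp_id", "chromosome", "position_bp") %in% names(df)))
  pos <- suppressWarnings(as.integer(df$position_bp))
  unknown <- df$chromosome %in% c("0", "", ".") | is.na(pos)
  df$chromosome[unknown] <- NA_character_
  pos[unknown] <- NA_integer_
  df$position_bp <- pos
  df
}

#' @rdname read_snp_map
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("transcript_id", "chromosome", "start") %in% names(df)))
  df$start <- as.integer(df$start)
  if (is.null(df$gene_id)) df$gene_id <- df$transcript_id
  df
}
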