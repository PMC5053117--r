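#' Genotype quality control
#'
#' Missingness and minor-allele-frequency filters with the boundary
#' semantics "more than 10 % missing" (strict >) and "MAF less than 5 %"
#' (strict <), and trio/duo Mendelian-consistency checks against the
#' pedigree.
#'
#' @name genotype-qc
NULL

#' Filter samples and SNPs by missingness and MAF
#'
#' Samples are filtered first (missing fraction across SNPs strictly
#' greater than `max_missing`); SNP missingness and MAF are then computed
#' on the surviving samples' non-missing calls. A SNP survives when its
#' missing fraction is <= `max_missing` and its MAF is >= `min_maf`
#' (monomorphic SNPs have MAF 0 and are excluded for any positive
#' `min_maf`). The filter is idempotent.
#'
#' @param dosage samples x SNPs matrix (0/1/2/NA).
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return list with `dosage` (filtered matrix) and `report` (data frame
#'   `type`, `id`, `reason`, `value` with one row per exclusion).
#' @export
filter_samples_and_snps <- function(dosage, max_missing = 0.10,
                                    min_maf = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  miss_s <- rowMeans(is.na(dosage))
  drop_s <- miss_s > max_missing
  report <- data.frame(type = character(0), id = character(0),
                       reason = character(0), value = numeric(0),
                       stringsAsFactors = FALSE)
  if (any(drop_s))
    report <- rbind(report, data.frame(
      type = "sample", id = rownames(dosage)[drop_s],
      reason = "missing_fraction", value = miss_s[drop_s],
      stringsAsFactors = FALSE))
  d <- dosage[!drop_s, , drop = FALSE]

  miss_v <- colMeans(is.na(d))
  n_called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(p, 1 - p)
  maf[n_called == 0L] <- 0
  drop_miss <- miss_v > max_missing
  drop_maf <- !drop_miss & maf < min_maf
  if (any(drop_miss))
    report <- rbind(report, data.frame(
      type = "snp", id = colnames(d)[drop_miss],
      reason = "missing_fraction", value = miss_v[drop_miss],
      stringsAsFactors = FALSE))
  if (any(drop_maf))
    report <- rbind(report, data.frame(
      type = "snp", id = colnames(d)[drop_maf], reason = "maf",
      value = maf[drop_maf], stringsAsFactors = FALSE))
  keep <- !(drop_miss | drop_maf)
  if (!any(keep)) stop("all SNPs excluded by QC filters", call. = FALSE)
  rownames(report) <- NULL
  list(dosage = d[, keep, drop = FALSE], report = report)
}

#' Mendelian consistency check
#'
#' Per-trio incompatibility test on dosages: with both parents genotyped
#' the offspring dosage must lie between the number of parents that can
#' only transmit the alternate allele and the number that can transmit
#' it at all; with one genotyped parent only opposing homozygotes
#' (|parent - offspring| = 2) are impossible. Sites with a missing
#' genotype are skipped. This is the O(1)-per-trio screen appropriate at
#' F2-trio pedigree depth, not a full likelihood-based elimination.
#'
#' @param dosage samples x SNPs matrix covering offspring and (some)
#'   parents.
#' @param ped validated pedigree.
#' @return data frame `snp_id`, `animal`, `sire`, `dam`, `dosage_animal`,
#'   `dosage_sire`, `dosage_dam`; zero rows when consistent.
#' @export
mendelian_check <- function(dosage, ped) {
  stopifnot(inherits(ped, "pedigree"))
  ids <- rownames(dosage)
  out <- list()
  for (i in seq_len(nrow(ped))) {
    an <- ped$animal[i]
    if (!an %in% ids) next
    s <- ped$sire[i]
    d <- ped$dam[i]
    gs <- if (!is.na(s) && s %in% ids) dosage[s, ] else rep(NA_real_,
                                                            ncol(dosage))
    gd <- if (!is.na(d) && d %in% ids) dosage[d, ] else rep(NA_real_,
                                                            ncol(dosage))
    go <- dosage[an, ]
    both <- !is.na(go) & !is.na(gs) & !is.na(gd)
    lo <- (gs == 2) + (gd == 2)
    hi <- (gs >= 1) + (gd >= 1)
    bad_trio <- both & (go < lo | go > hi)
    sire_only <- !is.na(go) & !is.na(gs) & is.na(gd) & abs(go - gs) == 2
    dam_only <- !is.na(go) & is.na(gs) & !is.na(gd) & abs(go - gd) == 2
    bad <- which(bad_trio | sire_only | dam_only)
    if (length(bad))
      out[[length(out) + 1L]] <- data.frame(
        snp_id = colnames(dosage)[bad], animal = an,
        sire = if (is.na(s)) NA_character_ else s,
        dam = if (is.na(d)) NA_character_ else d,
        dosage_animal = go[bad], dosage_sire = gs[bad],
        dosage_dam = gd[bad], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(snp_id = character(0), animal = character(0),
                      sire = character(0), dam = character(0),
                      dosage_animal = numeric(0), dosage_sire = numeric(0),
                      dosage_dam = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intersect two genotype matrices on SNP id
#'
#' Utility for merging genotype sets typed on different chip versions:
#' keeps the SNPs present in both matrices and stacks the samples.
#'
#' @param g1,g2 samples x SNPs dosage matrices.
#' @return combined matrix over the shared SNPs.
#' @export
intersect_snps <- function(g1, g2) {
  shared <- intersect(colnames(g1), colnames(g2))
  if (!length(shared)) stop("no shared SNPs", call. = FALSE)
  rbind(g1[, shared, drop = FALSE], g2[, shared, drop = FALSE])
}
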