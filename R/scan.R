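#' Genome-wide eQTL scan
#'
#' Tests every SNP x transcript pair with the adaptive linear rank test on
#' de-correlated expression, adjusts for multiple testing with the
#' Benjamini-Hochberg step-up over all performed tests, and classifies
#' significant associations as cis (SNP and gene on the same chromosome),
#' trans (different chromosomes) or unknown (SNP position unknown).
#'
#' @name eqtl-scan
NULL

#' Scan configuration
#'
#' @param alpha_fdr global BH false-discovery level (default 0.1).
#' @param min_group_count genotype classes with fewer members are dropped
#'   from a pair's test (default 3).
#' @param min_groups minimum surviving genotype classes for a pair to be
#'   tested at all (default 2); pairs below this are skipped and counted
#'   but contribute nothing to the number of performed tests m.
#' @param selector_scope `"per_pair"` (selector on the analysed subsample
#'   of each pair) or `"per_transcript"` (selector once per transcript on
#'   the full residual vector).
#' @param emit_companion_tests also report plain Kruskal-Wallis and
#'   one-way ANOVA p-values per pair (default TRUE).
#' @param rules selector decision table ([default_selector_rules()]).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(alpha_fdr = 0.1, min_group_count = 3L,
                        min_groups = 2L,
                        selector_scope = c("per_pair", "per_transcript"),
                        emit_companion_tests = TRUE,
                        rules = default_selector_rules()) {
  stopifnot(alpha_fdr > 0, alpha_fdr < 1, min_group_count >= 1,
            min_groups >= 2)
  cfg <- list(alpha_fdr = alpha_fdr,
              min_group_count = as.integer(min_group_count),
              min_groups = as.integer(min_groups),
              selector_scope = match.arg(selector_scope),
              emit_companion_tests = isTRUE(emit_companion_tests),
              rules = rules)
  class(cfg) <- "scan_config"
  cfg
}

#' Benjamini-Hochberg adjustment over m performed tests
#'
#' Step-up adjusted p-values `adj_(k) = min_{j >= k} (m * p_(j) / j)`
#' capped at 1, computed against the total number of performed tests `m`,
#' which may exceed the length of `p` when results are processed in
#' chunks. Delegates to [stats::p.adjust()] with `n = m`.
#'
#' @param p raw p-values in `[0,1]`.
#' @param m total number of performed tests (`m >= length(p)`).
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, m = length(p)) {
  stopifnot(m >= length(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH", n = m)
}

#' Classify a SNP-gene pair as cis, trans or unknown
#'
#' cis = SNP and gene on the same chromosome (the wide, chromosome-level
#' notion appropriate for an F2 cross with long-range linkage
#' disequilibrium), trans = different chromosomes, unknown = SNP position
#' unknown. The gene's chromosome must be known.
#'
#' @param snp_chrom SNP chromosome (NA if unknown), vectorised.
#' @param gene_chrom gene chromosome.
#' @return character vector `"cis"`/`"trans"`/`"unknown"`.
#' @export
classify_association <- function(snp_chrom, gene_chrom) {
  if (any(is.na(gene_chrom)))
    stop("gene chromosome unknown", call. = FALSE)
  ifelse(is.na(snp_chrom), "unknown",
         ifelse(snp_chrom == gene_chrom, "cis", "trans"))
}

#' Distance between SNP and gene start
#'
#' `|snp_pos - gene_start|` in bp when SNP and gene share a chromosome,
#' NA otherwise.
#'
#' @param snp_pos,gene_start 1-based positions (vectorised).
#' @param same_chromosome logical.
#' @return integer-valued numeric vector.
#' @export
snp_gene_distance <- function(snp_pos, gene_start, same_chromosome) {
  ifelse(same_chromosome & !is.na(snp_pos) & !is.na(gene_start),
         abs(as.numeric(snp_pos) - as.numeric(gene_start)), NA_real_)
}

#' Equivalent FDR level for a test subset
#'
#' The genome-wide BH procedure at level `alpha` over `m_total` tests
#' rejects at the per-test threshold `k * alpha / m_total`; restricted to
#' a subset of `m_sub` tests the same per-test threshold corresponds to
#' BH at level `alpha * m_sub / m_total` (the rejection count k cancels).
#'
#' @param alpha global FDR level.
#' @param m_sub number of tests in the subset.
#' @param m_total total number of performed tests.
#' @return equivalent FDR level in `(0, alpha]`.
#' @examples
#' equivalent_fdr(0.1, 13e6, 374e6) # ~0.0035
#' @export
equivalent_fdr <- function(alpha, m_sub, m_total) {
  stopifnot(alpha > 0, m_sub > 0, m_sub <= m_total)
  alpha * m_sub / m_total
}

#' Raw-p threshold implied by a BH rejection count
#'
#' With k rejections out of m tests at FDR level alpha, the BH step-up
#' boundary for unadjusted p-values is `k * alpha / m`.
#'
#' @param k number of rejections.
#' @param m number of performed tests.
#' @param alpha FDR level.
#' @return per-test raw p-value threshold.
#' @examples
#' threshold_from_rejections(505, 374e6, 0.1) # ~1.35e-7
#' @export
threshold_from_rejections <- function(k, m, alpha) {
  stopifnot(k >= 1, k <= m, alpha > 0)
  k * alpha / m
}

#' Run the genome-wide scan
#'
#' Tests each SNP x transcript pair. Samples with a missing genotype at
#' the tested SNP are dropped pair-wise; genotype classes with fewer than
#' `min_group_count` members are dropped, and the pair is skipped (and
#' counted) when fewer than `min_groups` classes survive. `m`, the number
#' of performed tests, feeds the BH adjustment. When no sample is dropped
#' for a pair the per-transcript selector/scores are reused across SNPs,
#' which makes the dense case fast.
#'
#' @param residuals de-correlated expression matrix (samples x
#'   transcripts) from [decorrelate_expression()].
#' @param dosage genotype matrix (samples x SNPs).
#' @param snp_map data frame `snp_id`, `chromosome`, `position_bp`.
#' @param gene_map data frame `transcript_id`, `gene_id`, `chromosome`,
#'   `start`.
#' @param cfg a [scan_config()].
#' @return object of class `eqtl_scan`: list with `records` (one row per
#'   performed test: snp/transcript ids and positions, chosen test,
#'   p_adaptive, p_kw, p_anova, p_bh, significant, assoc_class,
#'   distance_bp), `m`, `n_skipped`, `alpha_fdr`.
#' @export
run_scan <- function(residuals, dosage, snp_map, gene_map,
                     cfg = scan_config()) {
  stopifnot(inherits(cfg, "scan_config"))
  shared <- intersect(rownames(residuals), rownames(dosage))
  if (!length(shared)) stop("no overlapping samples", call. = FALSE)
  R <- residuals[shared, , drop = FALSE]
  D <- dosage[shared, , drop = FALSE]
  n <- nrow(R)
  nt <- ncol(R)
  ns <- ncol(D)
  tids <- colnames(R)
  gm <- gene_map[match(tids, gene_map$transcript_id), , drop = FALSE]
  if (anyNA(gm$transcript_id))
    stop("gene map missing transcripts: ",
         paste(setdiff(tids, gene_map$transcript_id), collapse = ", "),
         call. = FALSE)
  sm <- snp_map[match(colnames(D), snp_map$snp_id), , drop = FALSE]

  # per-transcript cache for the complete-sample fast path
  full_scores <- vector("list", nt)
  full_chosen <- character(nt)
  full_fallback <- logical(nt)
  full_mean <- numeric(nt)
  full_var <- numeric(nt)
  get_full <- function(t) {
    if (is.null(full_scores[[t]])) {
      y <- R[, t]
      sel <- if (length(unique(y)) > 1L) selector_statistics(y) else
        structure(list(degenerate = TRUE), class = "selector_stats")
      full_fallback[t] <<- isTRUE(sel$degenerate)
      full_chosen[t] <<- select_test(sel, cfg$rules)
      a <- .observation_scores(y, full_chosen[t])
      full_scores[[t]] <<- a
      full_mean[t] <<- mean(a)
      full_var[t] <<- sum((a - mean(a))^2) / (n - 1)
    }
    invisible(NULL)
  }
  kw_scores <- NULL
  kw_mean <- NULL
  kw_var <- NULL

  recs <- vector("list", ns)
  n_skipped <- 0L
  for (j in seq_len(ns)) {
    g_raw <- D[, j]
    ok <- !is.na(g_raw)
    tb <- table(g_raw[ok])
    keep_classes <- names(tb)[tb >= cfg$min_group_count]
    use <- ok & g_raw %in% keep_classes
    k <- length(keep_classes)
    if (k < cfg$min_groups) { n_skipped <- n_skipped + nt; next }
    complete <- all(use)
    g <- factor(g_raw[use])
    ng <- as.integer(table(g))
    Gind <- stats::model.matrix(~ g - 1)

    if (complete) {
      # dense fast path: reuse per-transcript selector/scores across SNPs
      for (t in seq_len(nt)) get_full(t)
      S <- do.call(cbind, full_scores)
      Ag <- crossprod(S, Gind)                       # nt x k
      dev <- Ag - outer(full_mean, ng)
      Tstat <- rowSums(dev^2 / matrix(ng, nt, k, byrow = TRUE)) / full_var
      Tstat[!is.finite(Tstat) | full_var <= 0] <- 0
      chosen <- full_chosen
      fallback <- full_fallback
    } else {
      # subsetted sample: ranks and scores recomputed on the analysed
      # subsample; the selector follows cfg$selector_scope
      Tstat <- numeric(nt)
      chosen <- character(nt)
      fallback <- logical(nt)
      for (t in seq_len(nt)) {
        if (cfg$selector_scope == "per_transcript") {
          get_full(t)
          chosen[t] <- full_chosen[t]
          fallback[t] <- full_fallback[t]
          lr <- linear_rank_statistic(R[use, t], g, chosen[t])
          Tstat[t] <- lr$statistic
        } else {
          res <- adaptive_rank_test(R[use, t], g, rules = cfg$rules)
          Tstat[t] <- res$statistic
          chosen[t] <- res$chosen_test
          fallback[t] <- res$fallback
        }
      }
    }
    p_adapt <- stats::pchisq(Tstat, k - 1L, lower.tail = FALSE)

    p_kw <- rep(NA_real_, nt)
    p_anova <- rep(NA_real_, nt)
    if (cfg$emit_companion_tests) {
      if (complete) {
        if (is.null(kw_scores)) {
          kw_scores <- apply(R, 2L, .observation_scores, "kruskal_wallis")
          kw_mean <- colMeans(kw_scores)
          kw_var <- apply(kw_scores, 2L, function(a)
            sum((a - mean(a))^2) / (n - 1))
        }
        Agk <- crossprod(kw_scores, Gind)
        devk <- Agk - outer(kw_mean, ng)
        Hk <- rowSums(devk^2 / matrix(ng, nt, k, byrow = TRUE)) / kw_var
        Hk[!is.finite(Hk)] <- 0
        p_kw <- stats::pchisq(Hk, k - 1L, lower.tail = FALSE)
        # one-way ANOVA, vectorised over transcripts
        Rm <- R
        gs <- crossprod(Rm, Gind)
        mu_g <- gs / matrix(ng, nt, k, byrow = TRUE)
        mu <- colMeans(Rm)
        ssb <- rowSums(matrix(ng, nt, k, byrow = TRUE) * (mu_g - mu)^2)
        sst <- colSums(Rm^2) - n * mu^2
        ssw <- pmax(sst - ssb, 0)
        Fv <- (ssb / (k - 1)) / (ssw / (n - k))
        p_anova <- stats::pf(Fv, k - 1, n - k, lower.tail = FALSE)
        p_anova[ssw <= 0] <- ifelse(ssb[ssw <= 0] > 0, 0, 1)
      } else {
        for (t in seq_len(nt)) {
          lr <- linear_rank_statistic(R[use, t], g, "kruskal_wallis")
          p_kw[t] <- lr$p_value
          p_anova[t] <- anova_f_test(R[use, t], g)
        }
      }
    }

    recs[[j]] <- data.frame(
      snp_id = colnames(D)[j], snp_chrom = sm$chromosome[j],
      snp_pos = sm$position_bp[j],
      transcript_id = tids, gene_id = gm$gene_id,
      gene_chrom = gm$chromosome, gene_start = as.integer(gm$start),
      chosen_test = chosen, n_groups = k,
      p_adaptive = p_adapt, p_kw = p_kw, p_anova = p_anova,
      selector_fallback = fallback,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  if (is.null(records)) stop("no testable SNP-transcript pairs",
                             call. = FALSE)
  m <- nrow(records)
  records$p_bh <- bh_adjust(records$p_adaptive, m)
  records$significant <- records$p_bh <= cfg$alpha_fdr
  records$assoc_class <- classify_association(records$snp_chrom,
                                              records$gene_chrom)
  records$distance_bp <- snp_gene_distance(records$snp_pos,
                                           records$gene_start,
                                           records$assoc_class == "cis")
  rownames(records) <- NULL
  out <- list(records = records, m = m, n_skipped = n_skipped,
              alpha_fdr = cfg$alpha_fdr)
  class(out) <- "eqtl_scan"
  out
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat("eQTL scan:", x$m, "performed tests,", x$n_skipped, "skipped pairs\n")
  cat(sprintf("  %d significant at BH-FDR %.3g\n",
              sum(x$records$significant), x$alpha_fdr))
  invisible(x)
}

#' Summarise significant associations
#'
#' Counts total associations, unique SNPs and transcripts, the
#' cis/trans/unknown split by the chromosome rule, per-chromosome cis and
#' trans counts (by SNP chromosome), a window-based re-classification
#' (within `w` bp of the gene start on the same chromosome = cis;
#' everything else with known position = trans; unknown excluded) and the
#' cis distance distribution.
#'
#' @param records data frame of (significant) `eqtl_scan` records, or an
#'   `eqtl_scan` object (its significant records are used).
#' @param windows window sizes in bp (default 1 Mb and 5 Mb).
#' @return list of class `eqtl_summary`.
#' @export
summarize_scan <- function(records, windows = c(1e6, 5e6)) {
  if (inherits(records, "eqtl_scan"))
    records <- records$records[records$records$significant, , drop = FALSE]
  cls <- records$assoc_class
  per_chrom <- if (nrow(records)) {
    tab <- table(chromosome = records$snp_chrom[cls != "unknown"],
                 class = cls[cls != "unknown"])
    as.data.frame(tab, stringsAsFactors = FALSE)
  } else data.frame(chromosome = character(0), class = character(0),
                    Freq = integer(0))
  win <- lapply(windows, function(w) {
    known <- cls != "unknown"
    cis_w <- known & !is.na(records$distance_bp) & records$distance_bp < w
    list(window_bp = w, cis = sum(cis_w), trans = sum(known & !cis_w),
         unknown = sum(!known))
  })
  names(win) <- paste0("window_", format(windows, scientific = FALSE,
                                         trim = TRUE))
  out <- list(
    n_associations = nrow(records),
    n_snps = length(unique(records$snp_id)),
    n_transcripts = length(unique(records$transcript_id)),
    n_cis = sum(cls == "cis"),
    n_trans = sum(cls == "trans"),
    n_unknown = sum(cls == "unknown"),
    per_chromosome = per_chrom,
    windows = win,
    cis_distances = records$distance_bp[cls == "cis" &
                                          !is.na(records$distance_bp)]
  )
  class(out) <- "eqtl_summary"
  out
}

#' @export
print.eqtl_summary <- function(x, ...) {
  cat(sprintf(
    "%d associations (%d SNPs, %d transcripts): %d cis, %d trans, %d unknown\n",
    x$n_associations, x$n_snps, x$n_transcripts, x$n_cis, x$n_trans,
    x$n_unknown))
  for (w in x$windows)
    cat(sprintf("  window %s bp: %d cis / %d trans (%d unknown excluded)\n",
                format(w$window_bp, big.mark = ",", scientific = FALSE),
                w$cis, w$trans, w$unknown))
  invisible(x)
}

#' Plot an eQTL scan summary
#'
#' Two base-graphics panels: cis/trans association counts per chromosome,
#' and the histogram of SNP-to-gene-start distances for cis associations.
#'
#' @param x an `eqtl_summary`.
#' @param ... ignored.
#' @export
plot.eqtl_summary <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  pc <- x$per_chromosome
  if (nrow(pc)) {
    tab <- stats::xtabs(Freq ~ class + chromosome, data = pc)
    graphics::barplot(tab, beside = TRUE, col = c("firebrick", "steelblue"),
                      legend.text = rownames(tab), xlab = "chromosome",
                      ylab = "associations")
  }
  if (length(x$cis_distances))
    graphics::hist(x$cis_distances / 1e6, breaks = 30,
                   main = "cis associations",
                   xlab = "SNP to gene start (Mb)", col = "grey")
  invisible(x)
}

#' Write / read the eQTL record table as TSV
#' @param records `eqtl_scan` object or its records data frame.
#' @param path TSV path.
#' @export
write_eqtl_table <- function(records, path) {
  if (inherits(records, "eqtl_scan")) records <- records$records
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_eqtl_table
#' @export
read_eqtl_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(snp_id = "character"))
}
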