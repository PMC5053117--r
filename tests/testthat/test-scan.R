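scan_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- tiny_cross()
      dc <- decorrelate_expression(sim$expression, sim$covariates,
                                   sim$pedigree)
      cache <<- list(sim = sim, residuals = dc$residuals)
    }
    cache
  }
})

test_that("the scan produces one record per performed test", {
  fx <- scan_fixture()
  r3 <- fx$residuals[, 1:2]
  d3 <- fx$sim$dosage_f2[, 1:3]
  sc <- run_scan(r3, d3, fx$sim$snp_map, fx$sim$gene_map)
  expect_equal(sc$m, nrow(sc$records))
  expect_lte(sc$m, 6)
  expect_equal(sc$m + sc$n_skipped, 6)
})

test_that("sparse genotype classes are dropped per the group-size rule", {
  fx <- scan_fixture()
  res <- fx$residuals[, 1:4]
  n <- nrow(res)
  D <- cbind(
    ok3 = rep(c(0, 1, 2), length.out = n),
    two = c(rep(0, n - 5), rep(1, 5)),          # {n-5, 5, 0}: 2 groups
    near = c(rep(0, n - 2), rep(1, 2)),         # {n-2, 2}: 1 group left
    mono = rep(1, n))
  rownames(D) <- rownames(res)
  map <- data.frame(snp_id = colnames(D), chromosome = "1",
                    position_bp = 1:4, stringsAsFactors = FALSE)
  sc <- run_scan(res, D, map, fx$sim$gene_map,
                 scan_config(min_group_count = 3))
  expect_setequal(unique(sc$records$snp_id), c("ok3", "two"))
  expect_equal(unique(sc$records$n_groups[sc$records$snp_id == "two"]), 2)
  expect_equal(sc$n_skipped, 8) # near + mono, 4 transcripts each
  expect_equal(sc$m, 8)
  expect_error(run_scan(res, D[1:3, ][0, , drop = FALSE], map,
                        fx$sim$gene_map), "overlapping")
})

test_that("missing genotypes are dropped pair-wise and ranks recomputed", {
  fx <- scan_fixture()
  res <- fx$residuals[, 1:3]
  D <- fx$sim$dosage_f2[, 1:2]
  D[1:4, 1] <- NA
  sc <- run_scan(res, D, fx$sim$snp_map, fx$sim$gene_map)
  rec <- sc$records[sc$records$snp_id == colnames(D)[1], ]
  # reference: direct adaptive test on the complete cases
  keep <- !is.na(D[, 1])
  ref <- adaptive_rank_test(res[keep, 2], D[keep, 1])
  expect_equal(rec$p_adaptive[rec$transcript_id == colnames(res)[2]],
               ref$p_value, tolerance = 1e-12)
})

test_that("fast vectorised path equals the one-pair reference tests", {
  fx <- scan_fixture()
  sc <- run_scan(fx$residuals, fx$sim$dosage_f2, fx$sim$snp_map,
                 fx$sim$gene_map)
  set.seed(70)
  take <- sample(nrow(sc$records), 25)
  for (i in take) {
    rec <- sc$records[i, ]
    g <- fx$sim$dosage_f2[, rec$snp_id]
    y <- fx$residuals[, rec$transcript_id]
    # reference applies the same small-class rule as the scan
    tb <- table(g)
    use <- !is.na(g) & g %in% as.numeric(names(tb)[tb >= 3])
    ref <- adaptive_rank_test(y[use], g[use])
    expect_identical(rec$chosen_test, ref$chosen_test)
    expect_equal(rec$p_adaptive, ref$p_value, tolerance = 1e-10)
    kw <- kruskal.test(y[use], factor(g[use]))
    expect_equal(rec$p_kw, kw$p.value, tolerance = 1e-10)
    expect_equal(rec$p_anova, anova_f_test(y[use], g[use]),
                 tolerance = 1e-10)
  }
})

test_that("scan output is deterministic and round-trips through TSV", {
  fx <- scan_fixture()
  sc1 <- run_scan(fx$residuals[, 1:5], fx$sim$dosage_f2[, 1:10],
                  fx$sim$snp_map, fx$sim$gene_map)
  sc2 <- run_scan(fx$residuals[, 1:5], fx$sim$dosage_f2[, 1:10],
                  fx$sim$snp_map, fx$sim$gene_map)
  expect_identical(sc1$records, sc2$records)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "eqtl.tsv")
  write_eqtl_table(sc1, f)
  back <- read_eqtl_table(f)
  expect_equal(back$p_adaptive, sc1$records$p_adaptive, tolerance = 1e-12)
  expect_identical(back$assoc_class, sc1$records$assoc_class)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.04, 0.9), 4),
               c(0.004, 0.04, 0.16 / 3, 0.9), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(1, 5), 5), rep(1, 5))
  expect_equal(bh_adjust(0.3, 1), 0.3)
  set.seed(71)
  for (i in 1:50) {
    k <- sample(1:40, 1)
    p <- runif(k)^sample(1:3, 1)
    m <- k + sample(0:10, 1)
    expect_lt(max(abs(bh_adjust(p, m) - bh_brute_force(p, m))), 1e-12)
    # monotone in raw p
    o <- order(p)
    expect_true(all(diff(bh_adjust(p, m)[o]) >= -1e-12))
  }
})

test_that("cis/trans/unknown classification is exhaustive", {
  expect_identical(classify_association(c("5", "2", NA), c("5", "7", "3")),
                   c("cis", "trans", "unknown"))
  expect_error(classify_association("1", NA), "gene chromosome")
  fx <- scan_fixture()
  sc <- run_scan(fx$residuals, fx$sim$dosage_f2, fx$sim$snp_map,
                 fx$sim$gene_map)
  cls <- sc$records$assoc_class
  expect_equal(sum(cls == "cis") + sum(cls == "trans") +
                 sum(cls == "unknown"), nrow(sc$records))
})

test_that("snp-gene distance follows the same-chromosome rule", {
  expect_equal(snp_gene_distance(1e6, 3.5e6, TRUE), 2.5e6)
  expect_equal(snp_gene_distance(42, 42, TRUE), 0)
  expect_true(is.na(snp_gene_distance(1e6, 3.5e6, FALSE)))
})

test_that("summaries count the toy example and empty set correctly", {
  toy <- data.frame(
    snp_id = paste0("s", 1:5),
    snp_chrom = c("1", "1", "1", "1", "2"),
    snp_pos = c(1e6, 2e6, 3e6, 40e6, 5e6),
    transcript_id = paste0("t", 1:5),
    gene_chrom = c("1", "1", "1", "1", "3"),
    gene_start = c(1.5e6, 2.2e6, 3.9e6, 10e6, 1e6),
    stringsAsFactors = FALSE)
  toy$assoc_class <- classify_association(toy$snp_chrom, toy$gene_chrom)
  toy$distance_bp <- snp_gene_distance(toy$snp_pos, toy$gene_start,
                                       toy$assoc_class == "cis")
  s <- summarize_scan(toy, windows = 1e6)
  expect_equal(s$n_cis, 4)          # chromosome rule
  expect_equal(s$n_trans, 1)
  expect_equal(s$windows[[1]]$cis, 3)   # 1 Mb window rule
  expect_equal(s$windows[[1]]$trans, 2)

  empty <- toy[0, ]
  s0 <- summarize_scan(empty)
  expect_equal(s0$n_associations, 0)
  expect_equal(s0$n_cis + s0$n_trans + s0$n_unknown, 0)
})

test_that("threshold arithmetic follows the BH step-up identities", {
  expect_equal(equivalent_fdr(0.1, 5, 10), 0.05)
  expect_equal(equivalent_fdr(0.1, 10, 10), 0.1)
  expect_equal(threshold_from_rejections(1, 10, 0.1), 0.01)
  expect_equal(threshold_from_rejections(10, 10, 0.1), 0.1)
})

test_that("null scan p-values are near-uniform", {
  # unlinked SNPs, no planted effects; the chi-square approximation is
  # slightly conservative at n = 145, so assert closeness to uniformity
  # rather than a literal KS rejection threshold
  cfg <- sim_config(n_transcripts = 50, n_cis_eqtl = 0, n_trans_eqtl = 0,
                    n_chromosomes = 50, snps_per_chromosome = 1,
                    residual_family = "mixed", seed = 72)
  sim <- simulate_cross(cfg)
  dc <- decorrelate_expression(sim$expression, sim$covariates, sim$pedigree)
  sc <- run_scan(dc$residuals, sim$dosage_f2, sim$snp_map, sim$gene_map)
  p <- sc$records$p_adaptive
  expect_gte(length(p), 2000)
  D <- suppressWarnings(ks.test(p, "punif")$statistic)
  expect_lt(D, 0.03)
  expect_gt(mean(p), 0.48)
  expect_lt(mean(p), 0.54)
  expect_lt(mean(p <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(p)))
})

test_that("planted effects are recovered and BH keeps the FDP in check", {
  cfg <- sim_config(n_transcripts = 60, n_cis_eqtl = 8, n_trans_eqtl = 2,
                    effect_size = 1.5, residual_family = "mixed", seed = 73)
  sim <- simulate_cross(cfg)
  dc <- decorrelate_expression(sim$expression, sim$covariates, sim$pedigree)
  sc <- run_scan(dc$residuals, sim$dosage_f2, sim$snp_map, sim$gene_map)
  tr <- sim$truth$eqtl
  rec <- sc$records
  planted <- merge(tr, rec, by = c("snp_id", "transcript_id"))
  expect_gte(mean(planted$p_adaptive[planted$class == "cis"] < 1e-4), 0.8)
  # discoveries on a chromosome carrying a causal SNP for that transcript
  # count as true (F2 LD makes linked SNPs genuinely associated)
  sig <- rec[rec$significant, ]
  causal_chr <- sim$snp_map$chromosome[match(tr$snp_id, sim$snp_map$snp_id)]
  truth_key <- paste(tr$transcript_id, causal_chr)
  fdp <- mean(!(paste(sig$transcript_id, sig$snp_chrom) %in% truth_key))
  expect_lte(fdp, 0.1 + 3 * sqrt(0.1 * 0.9 / max(nrow(sig), 1)))
})
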