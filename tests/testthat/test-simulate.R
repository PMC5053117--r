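test_that("default pedigree matches the study design counts", {
  ped <- generate_pedigree(sim_config())
  expect_equal(sum(ped$generation == "F2"), 145)
  expect_equal(sum(ped$generation == "F1"), 52)
  expect_equal(sum(ped$generation == "P0"), 38)
  # five P0 sires, each heading one family line
  sires <- unique(ped$sire[ped$generation == "F1"])
  expect_equal(sort(sires), sprintf("S%d", 1:5))
  # family sizes by F1 sire
  fam <- table(ped$sire[ped$generation == "F2"])
  expect_setequal(as.integer(fam), c(49, 35, 52, 8, 1))
  # every F2 has two known F1 parents
  f2 <- ped[ped$generation == "F2", ]
  expect_false(anyNA(f2$sire) || anyNA(f2$dam))
})

test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(n_transcripts = 5, n_cis_eqtl = 1, n_trans_eqtl = 1,
                    n_chromosomes = 2, snps_per_chromosome = 8,
                    family_sizes = c(4, 4, 4, 2, 1), seed = 77)
  s1 <- simulate_cross(cfg)
  s2 <- simulate_cross(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$dosage_f2, s2$dosage_f2)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$truth, s2$truth)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_simulation(s1, dir1)
  write_simulation(s2, dir2)
  for (f in list.files(dir1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
})

test_that("loci at zero map distance co-segregate in every gamete", {
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 6,
                    chromosome_length_morgans = 0,
                    founder_freq_divergence = 1,
                    family_sizes = c(10, 10, 10, 5, 5),
                    n_transcripts = 1, n_cis_eqtl = 0, n_trans_eqtl = 0,
                    seed = 41)
  ped <- generate_pedigree(cfg)
  G <- simulate_genotypes(ped, cfg)
  # with fully diverged founders and no recombination, every SNP carries
  # the same dosage vector up to which breed got the alternate allele
  same <- apply(G$dosage, 2, function(cc)
    all(cc == G$dosage[, 1]) || all(cc == 2 - G$dosage[, 1]))
  expect_true(all(same))
})

test_that("fully diverged founders give heterozygous F1 and 1:2:1 F2", {
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 2,
                    founder_freq_divergence = 1,
                    family_sizes = c(1000, 1000, 1000, 1000, 1000),
                    n_f1 = 52, n_transcripts = 1, n_cis_eqtl = 0,
                    n_trans_eqtl = 0, seed = 43)
  ped <- generate_pedigree(cfg)
  G <- simulate_genotypes(ped, cfg)
  f1 <- ped$animal[ped$generation == "F1"]
  expect_true(all(G$dosage[f1, ] == 1))
  f2 <- ped$animal[ped$generation == "F2"]
  counts <- table(factor(G$dosage[f2, 1], levels = 0:2))
  # 5000 F2 = 10,000 gametes; Mendelian segregation gives 1:2:1
  p <- chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.001)
})

test_that("linkage disequilibrium decays with map distance", {
  cfg0 <- sim_config(n_chromosomes = 1, snps_per_chromosome = 13,
                     chromosome_length_morgans = 1.2,
                     founder_freq_divergence = 1,
                     family_sizes = c(30, 30, 30, 30, 25),
                     n_transcripts = 1, n_cis_eqtl = 0, n_trans_eqtl = 0)
  bins <- c(0, 0.15, 0.35, 0.7, 1.3)
  acc <- matrix(0, 50, length(bins) - 1)
  for (rep in 1:50) {
    cfg <- cfg0; cfg$seed <- 1000 + rep
    ped <- generate_pedigree(cfg)
    G <- simulate_genotypes(ped, cfg)
    f2 <- ped$animal[ped$generation == "F2"]
    D <- G$dosage[f2, ]
    pos <- G$map$position_morgans
    pr <- t(combn(ncol(D), 2))
    dist <- abs(pos[pr[, 1]] - pos[pr[, 2]])
    r2 <- vapply(seq_len(nrow(pr)), function(i)
      suppressWarnings(cor(D[, pr[i, 1]], D[, pr[i, 2]]))^2, numeric(1))
    bin <- cut(dist, bins, include.lowest = TRUE)
    acc[rep, ] <- tapply(r2, bin, mean, na.rm = TRUE)
  }
  avg <- colMeans(acc, na.rm = TRUE)
  expect_true(all(diff(avg) < 0))
})

test_that("degenerate config gives iid residuals after removing covariates", {
  cfg <- sim_config(n_transcripts = 200, n_cis_eqtl = 0, n_trans_eqtl = 0,
                    sigma2_a = 0, sigma2_e = 1, season_effect_sd = 0,
                    age_beta = 0, residual_family = "normal", seed = 51)
  sim <- simulate_cross(cfg)
  E <- sim$expression - cfg$grand_mean
  # per-transcript variance concentrates around sigma2_e
  v <- apply(E, 2, var)
  expect_lt(abs(mean(v) - 1), 0.05)
  # pooled values pass a normality check at this sample size
  expect_gt(shapiro.test(as.vector(E[, 1:5]))$p.value, 0.001)
})

test_that("planted effects shift genotype-group means by the effect size", {
  cfg <- sim_config(n_transcripts = 10, n_cis_eqtl = 3, n_trans_eqtl = 0,
                    effect_size = 2, sigma2_a = 0.2, sigma2_e = 0.5,
                    seed = 52)
  sim <- simulate_cross(cfg)
  tr <- sim$truth$eqtl
  for (e in seq_len(nrow(tr))) {
    g <- sim$dosage_f2[, tr$snp_id[e]]
    y <- sim$expression[, tr$transcript_id[e]]
    mg <- tapply(y, g, mean)
    present <- as.integer(names(mg))
    if (length(mg) < 2) next
    slope <- coef(lm(mg ~ present))[2]
    expect_lt(abs(slope - tr$effect_per_allele[e]), 0.75)
  }
})

test_that("truth-table classes agree with classify_association", {
  sim <- tiny_cross()
  tr <- sim$truth$eqtl
  snp_chr <- sim$snp_map$chromosome[match(tr$snp_id, sim$snp_map$snp_id)]
  gene_chr <- sim$gene_map$chromosome[match(tr$transcript_id,
                                            sim$gene_map$transcript_id)]
  expect_identical(classify_association(snp_chr, gene_chr), tr$class)
})

test_that("residual families are exactly variance-calibrated", {
  cfg <- sim_config(n_transcripts = 40, n_cis_eqtl = 0, n_trans_eqtl = 0,
                    sigma2_a = 0, sigma2_e = 2, season_effect_sd = 0,
                    age_beta = 0, residual_family = "mixed",
                    family_sizes = c(200, 200, 200, 200, 200), seed = 53)
  sim <- simulate_cross(cfg)
  fams <- sim$truth$transcripts$residual_family
  expect_setequal(unique(fams),
                  c("normal", "lognormal_shifted", "student_t", "uniform"))
  v <- apply(sim$expression, 2, var)
  for (f in c("normal", "lognormal_shifted", "uniform")) {
    expect_lt(abs(mean(v[fams == f]) - 2), 0.35, label = f)
  }
  # skew direction of the lognormal family
  sk <- apply(sim$expression[, fams == "lognormal_shifted"], 2,
              function(x) mean((x - mean(x))^3) / sd(x)^3)
  expect_gt(mean(sk), 0.5)
})

test_that("simulation round-trips through the on-disk formats", {
  sim <- tiny_cross()
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, format = "vcf")
  g <- read_genotypes(file.path(dir, "genotypes.vcf"), format = "vcf")
  expect_equal(g$dosage[rownames(sim$dosage_f2), colnames(sim$dosage_f2)],
               sim$dosage_f2)
  E <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(E, sim$expression, tolerance = 1e-12)
  cov <- read_covariates(file.path(dir, "covariates.csv"))
  expect_identical(cov$sample_id, sim$covariates$sample_id)
  m <- read_snp_map(file.path(dir, "snp_map.tsv"))
  expect_identical(m$snp_id, sim$snp_map$snp_id)
  gm <- read_gene_map(file.path(dir, "gene_map.tsv"))
  expect_identical(gm$transcript_id, sim$gene_map$transcript_id)
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_identical(sort(ped$animal), sort(sim$pedigree$animal))
})
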