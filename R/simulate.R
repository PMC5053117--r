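#' Synthetic F2 cross with planted eQTL
#'
#' The simulator emulates a two-breed F2 resource population: purebred
#' sires of one breed crossed to purebred dams of another, F1 intercrossed
#' (via MOET-style full-sib flushes) to give five full/half-sib F2
#' families. Genotypes arise by gamete dropping founder haplotypes through
#' the pedigree with Haldane recombination; expression arises from the
#' generative form of the sire-dam model (year-season class effects, an
#' age slope, parental additive effects with pedigree covariance
#' `sigma2_a * A`, planted per-allele eQTL effects, and residuals from a
#' configurable, exactly variance-calibrated distribution family). A truth
#' table records every planted effect for parameter-recovery tests.
#'
#' @name synthetic-cross
NULL

#' Simulation configuration
#'
#' Defaults reproduce the shape of the study population: 5 purebred sires,
#' five F2 families of 49/35/52/8/1 cows (145 F2), 52 F1 and 38 P0
#' animals, 25 year-season classes. Genome size defaults are scaled down
#' (5 chromosomes x 60 SNPs, 1 Morgan each at 1 cM/Mb) so simulated scans
#' stay cheap; all sizes are configurable.
#'
#' @param n_sires number of purebred P0 sires (one F2 family line each).
#' @param family_sizes F2 cows per family; length must equal `n_sires`.
#' @param n_f1 total F1 animals (sires of families plus F1 dams).
#' @param n_p0_dams purebred P0 dams.
#' @param n_chromosomes,snps_per_chromosome,chromosome_length_morgans
#'   genome shape; physical positions use 1 cM = 1 Mb.
#' @param founder_freq_divergence in `[0,1]`: 0 = breeds share the
#'   Beta(2,2) allele-frequency prior, 1 = breeds fixed for alternate
#'   alleles (all F1 heterozygous).
#' @param n_transcripts number of expression traits.
#' @param n_cis_eqtl,n_trans_eqtl planted effects (cis: gene near the SNP
#'   on the same chromosome; trans: gene on a different chromosome).
#' @param effect_size_sd SD of normally drawn per-allele effects
#'   (expression units); ignored when `effect_size` is given.
#' @param effect_size optional fixed per-allele effect magnitude (random
#'   sign), for calibrated power studies.
#' @param sigma2_a,sigma2_e polygenic and residual variance per transcript.
#' @param residual_family one of `"normal"`, `"lognormal_shifted"` (right
#'   skew), `"student_t"` (df 3, heavy tails), `"uniform"` (short tails),
#'   or `"mixed"` (cycle the four across transcripts). All are centred and
#'   scaled so the residual variance is exactly `sigma2_e`.
#' @param n_seasons number of year-season classes, assigned cyclically.
#' @param age_beta fixed age-at-slaughter slope (expression units/day).
#' @param age_range uniform range for age at slaughter in days.
#' @param season_effect_sd SD of the per-transcript season class effects.
#' @param grand_mean baseline expression (log2 RMA scale).
#' @param seed integer seed; every output is a deterministic function of
#'   the configuration including the seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 5,
                       family_sizes = c(49, 35, 52, 8, 1),
                       n_f1 = 52,
                       n_p0_dams = 33,
                       n_chromosomes = 5,
                       snps_per_chromosome = 60,
                       chromosome_length_morgans = 1,
                       founder_freq_divergence = 0.6,
                       n_transcripts = 100,
                       n_cis_eqtl = 10,
                       n_trans_eqtl = 5,
                       effect_size_sd = 0.5,
                       effect_size = NULL,
                       sigma2_a = 0.5,
                       sigma2_e = 1,
                       residual_family = "normal",
                       n_seasons = 25,
                       age_beta = 0.002,
                       age_range = c(950, 1250),
                       season_effect_sd = 0.5,
                       grand_mean = 8,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$family_sizes) == cfg$n_sires,
            all(cfg$family_sizes >= 0),
            cfg$founder_freq_divergence >= 0,
            cfg$founder_freq_divergence <= 1,
            cfg$sigma2_a >= 0, cfg$sigma2_e >= 0,
            cfg$n_seasons >= 1,
            cfg$n_f1 > cfg$n_sires)
  ok_fam <- c("normal", "lognormal_shifted", "student_t", "uniform", "mixed")
  if (!cfg$residual_family %in% ok_fam)
    stop("residual_family must be one of: ", paste(ok_fam, collapse = ", "),
         call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the three-generation pedigree
#'
#' P0 sires of breed A and P0 dams of breed B produce the F1; each family
#' line is headed by one F1 sire (son of the corresponding P0 sire) mated
#' to F1 dams sired by the *other* P0 sires (avoiding half-sib matings),
#' with F2 cows arriving in full-sib flushes of up to three per F1 dam.
#' The construction is deterministic.
#'
#' @param cfg a [sim_config()].
#' @return validated `pedigree` with a `generation` column (P0/F1/F2).
#' @export
generate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sires <- sprintf("S%d", seq_len(cfg$n_sires))
  dams0 <- sprintf("H%02d", seq_len(cfg$n_p0_dams))
  p0 <- data.frame(animal = c(sires, dams0), sire = NA_character_,
                   dam = NA_character_, generation = "P0",
                   stringsAsFactors = FALSE)

  # one F1 sire per family, remaining F1 are dams
  f1_sires <- sprintf("F1S%d", seq_len(cfg$n_sires))
  n_f1_dams <- cfg$n_f1 - cfg$n_sires
  f1_dams <- sprintf("F1D%02d", seq_len(n_f1_dams))
  dam_cycle <- function(i) dams0[(i - 1L) %% cfg$n_p0_dams + 1L]
  f1 <- rbind(
    data.frame(animal = f1_sires, sire = sires,
               dam = dam_cycle(seq_len(cfg$n_sires)),
               generation = "F1", stringsAsFactors = FALSE),
    data.frame(animal = f1_dams,
               sire = sires[(seq_len(n_f1_dams) - 1L) %% cfg$n_sires + 1L],
               dam = dam_cycle(cfg$n_sires + seq_len(n_f1_dams)),
               generation = "F1", stringsAsFactors = FALSE))

  # allocate F1 dams to families proportionally to family size
  alloc <- pmax(1L, round(cfg$family_sizes / sum(cfg$family_sizes) *
                            n_f1_dams))
  while (sum(alloc) > n_f1_dams) alloc[which.max(alloc)] <-
    alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_f1_dams) alloc[which.min(alloc)] <-
    alloc[which.min(alloc)] + 1L
  dam_pool <- split(f1_dams, rep(seq_len(cfg$n_sires), alloc))

  f2 <- list()
  for (k in seq_len(cfg$n_sires)) {
    nk <- cfg$family_sizes[k]
    if (nk == 0) next
    pool <- dam_pool[[as.character(k)]]
    # avoid half-sib matings: drop dams sired by this family's P0 sire
    safe <- pool[f1$sire[match(pool, f1$animal)] != sires[k]]
    if (!length(safe)) safe <- pool
    dams_k <- rep(safe, each = 3L, length.out = nk)
    f2[[k]] <- data.frame(
      animal = sprintf("F2_%d_%03d", k, seq_len(nk)),
      sire = f1_sires[k], dam = dams_k, generation = "F2",
      stringsAsFactors = FALSE)
  }
  validate_pedigree(rbind(p0, f1, do.call(rbind, f2)))
}

#' Drop gametes through the pedigree
#'
#' Founder haplotypes are drawn per breed from SNP-specific allele
#' frequencies (Beta(2,2) priors pushed apart by
#' `founder_freq_divergence`); each meiosis recombines the parental
#' haplotypes as a Markov chain along the chromosome with Haldane
#' crossover probability `r = (1 - exp(-2 d)) / 2` between adjacent SNPs
#' at map distance d Morgans (no interference).
#'
#' @param ped validated pedigree (founders used as sires are breed A,
#'   founders used as dams breed B).
#' @param cfg a [sim_config()]; the seed determines all randomness.
#' @return list with `dosage` (animals x SNPs alt-allele counts in 0:2),
#'   `map` (data frame `snp_id`, `chromosome`, `position_bp`,
#'   `position_morgans`, `freq_breed_a`, `freq_breed_b`) and `haplotypes`
#'   (list of two 0/1 matrices, for diagnostics).
#' @export
simulate_genotypes <- function(ped, cfg) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n_chr <- cfg$n_chromosomes
  m <- cfg$snps_per_chromosome
  L <- cfg$chromosome_length_morgans
  pos_m <- if (m == 1L) L / 2 else L * (seq_len(m) - 1L) / (m - 1L)
  map <- data.frame(
    snp_id = sprintf("snp_c%d_%03d", rep(seq_len(n_chr), each = m),
                     rep(seq_len(m), n_chr)),
    chromosome = as.character(rep(seq_len(n_chr), each = m)),
    position_bp = rep(round(pos_m * 1e8) + 1L, n_chr),
    position_morgans = rep(pos_m, n_chr),
    stringsAsFactors = FALSE)
  n_snp <- nrow(map)

  delta <- cfg$founder_freq_divergence
  qa <- stats::rbeta(n_snp, 2, 2)
  qb <- stats::rbeta(n_snp, 2, 2)
  flip <- stats::runif(n_snp) < 0.5
  pa <- (1 - delta) * qa + delta * ifelse(flip, 1, 0)
  pb <- (1 - delta) * qb + delta * ifelse(flip, 0, 1)
  map$freq_breed_a <- pa
  map$freq_breed_b <- pb

  n_ind <- nrow(ped)
  idx <- seq_len(n_ind); names(idx) <- ped$animal
  H1 <- matrix(0L, n_ind, n_snp, dimnames = list(ped$animal, map$snp_id))
  H2 <- H1
  founder <- is.na(ped$sire) & is.na(ped$dam)
  breed_a <- founder & ped$animal %in% ped$sire   # used as sires
  # per-interval recombination fractions; chromosome independence comes
  # from restarting the chain per chromosome
  dd <- diff(pos_m)
  r_intra <- (1 - exp(-2 * dd)) / 2

  gamete <- function(h1, h2) {
    out <- integer(n_snp)
    for (c in seq_len(n_chr)) {
      o <- (c - 1L) * m
      state <- integer(m)
      state[1L] <- stats::rbinom(1L, 1L, 0.5)
      if (m > 1L) {
        sw <- stats::rbinom(m - 1L, 1L, r_intra)
        state <- (state[1L] + c(0L, cumsum(sw))) %% 2L
      }
      rows <- o + seq_len(m)
      out[rows] <- ifelse(state == 0L, h1[rows], h2[rows])
    }
    out
  }

  for (i in seq_len(n_ind)) {
    if (founder[i]) {
      p <- if (breed_a[i]) pa else pb
      H1[i, ] <- stats::rbinom(n_snp, 1L, p)
      H2[i, ] <- stats::rbinom(n_snp, 1L, p)
    } else {
      si <- idx[ped$sire[i]]
      di <- idx[ped$dam[i]]
      H1[i, ] <- gamete(H1[si, ], H2[si, ])
      H2[i, ] <- gamete(H1[di, ], H2[di, ])
    }
  }
  list(dosage = H1 + H2, map = map, haplotypes = list(H1, H2))
}

# centred, exactly variance-calibrated residual draw
.draw_residuals <- function(n, family, sigma2_e) {
  s <- sqrt(sigma2_e)
  switch(family,
    normal = stats::rnorm(n, 0, s),
    lognormal_shifted = {
      sl <- 0.8
      x <- stats::rlnorm(n, 0, sl)
      (x - exp(sl^2 / 2)) / sqrt((exp(sl^2) - 1) * exp(sl^2)) * s
    },
    student_t = stats::rt(n, df = 3) / sqrt(3) * s,
    uniform = stats::runif(n, -sqrt(3), sqrt(3)) * s,
    stop("unknown residual family: ", family, call. = FALSE)
  )
}

#' Simulate expression with planted eQTL
#'
#' Runs the sire-dam model generatively per transcript: season class
#' effects, an age slope, parental additive effects with covariance
#' `sigma2_a * A` over the F2 parents, planted eQTL effects added as
#' `effect_per_allele * dosage`, and centred residuals of the configured
#' family with variance exactly `sigma2_e`.
#'
#' @param G output of [simulate_genotypes()].
#' @param ped validated pedigree.
#' @param A relationship matrix over all pedigree members
#'   ([build_relationship_matrix()]).
#' @param cfg a [sim_config()].
#' @return list with `expression` (F2 samples x transcripts),
#'   `covariates` (`sample_id`, `season_class`, `age_days`), `gene_map`
#'   (`transcript_id`, `gene_id`, `chromosome`, `start`), and `truth`
#'   (list: `eqtl` data frame with `snp_id`, `transcript_id`,
#'   `effect_per_allele`, `class`; `transcripts` data frame with the
#'   per-transcript variance components, age slope and residual family;
#'   `season_effects` matrix).
#' @export
simulate_expression <- function(G, ped, A, cfg) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  f2 <- ped$animal[!is.na(ped$generation) & ped$generation == "F2"]
  n <- length(f2)
  nt <- cfg$n_transcripts
  n_snp <- nrow(G$map)
  n_eqtl <- cfg$n_cis_eqtl + cfg$n_trans_eqtl
  if (n_eqtl > 0 && n_snp == 0)
    stop("planted eQTL requested but no SNPs available", call. = FALSE)
  if (cfg$n_trans_eqtl > 0 && cfg$n_chromosomes < 2)
    stop("trans eQTL need at least 2 chromosomes", call. = FALSE)
  if (n_eqtl > nt)
    stop("more planted eQTL than transcripts", call. = FALSE)

  tids <- sprintf("tr%04d", seq_len(nt))
  covariates <- data.frame(
    sample_id = f2,
    season_class = sprintf("ys%02d", (seq_len(n) - 1L) %% cfg$n_seasons + 1L),
    age_days = round(stats::runif(n, cfg$age_range[1], cfg$age_range[2])),
    stringsAsFactors = FALSE)

  chr_levels <- as.character(seq_len(cfg$n_chromosomes))
  chr_len_bp <- round(cfg$chromosome_length_morgans * 1e8) + 1L
  gene_map <- data.frame(
    transcript_id = tids,
    gene_id = paste0("gene_", tids),
    chromosome = sample(chr_levels, nt, replace = TRUE),
    start = sample.int(chr_len_bp, nt, replace = TRUE),
    stringsAsFactors = FALSE)

  # plant eQTL on the first n_eqtl transcripts; causal SNPs without
  # replacement so every planted pair is distinct
  eqtl <- NULL
  if (n_eqtl > 0) {
    causal <- sample.int(n_snp, n_eqtl)
    cls <- rep(c("cis", "trans"), c(cfg$n_cis_eqtl, cfg$n_trans_eqtl))
    eff <- if (!is.null(cfg$effect_size)) {
      sample(c(-1, 1), n_eqtl, replace = TRUE) * cfg$effect_size
    } else stats::rnorm(n_eqtl, 0, cfg$effect_size_sd)
    for (e in seq_len(n_eqtl)) {
      snp_chr <- G$map$chromosome[causal[e]]
      snp_pos <- G$map$position_bp[causal[e]]
      if (cls[e] == "cis") {
        gene_map$chromosome[e] <- snp_chr
        gene_map$start[e] <- max(1L, snp_pos +
                                   round(stats::runif(1, -5e5, 5e5)))
      } else {
        gene_map$chromosome[e] <- sample(setdiff(chr_levels, snp_chr), 1L)
        gene_map$start[e] <- sample.int(chr_len_bp, 1L)
      }
    }
    eqtl <- data.frame(snp_id = G$map$snp_id[causal], transcript_id =
                         tids[seq_len(n_eqtl)],
                       effect_per_allele = eff, class = cls,
                       stringsAsFactors = FALSE)
  }

  Z <- parent_incidence(ped, f2)
  A_par <- A[colnames(Z), colnames(Z), drop = FALSE]
  ea <- eigen((A_par + t(A_par)) / 2, symmetric = TRUE)
  Lh <- ea$vectors %*% diag(sqrt(pmax(ea$values, 0)), nrow(A_par))

  fam_cycle <- c("normal", "lognormal_shifted", "student_t", "uniform")
  fams <- if (cfg$residual_family == "mixed") {
    fam_cycle[(seq_len(nt) - 1L) %% 4L + 1L]
  } else rep(cfg$residual_family, nt)

  season_levels <- sort(unique(covariates$season_class))
  season_eff <- matrix(stats::rnorm(length(season_levels) * nt, 0,
                                    cfg$season_effect_sd),
                       nrow = nt,
                       dimnames = list(tids, season_levels))
  si <- match(covariates$season_class, season_levels)
  dose_f2 <- G$dosage[f2, , drop = FALSE]

  E <- matrix(NA_real_, n, nt, dimnames = list(f2, tids))
  for (t in seq_len(nt)) {
    a_par <- sqrt(cfg$sigma2_a) * (Lh %*% stats::rnorm(nrow(A_par)))[, 1L]
    y <- cfg$grand_mean + season_eff[t, si] +
      cfg$age_beta * covariates$age_days + (Z %*% a_par)[, 1L] +
      .draw_residuals(n, fams[t], cfg$sigma2_e)
    if (!is.null(eqtl)) {
      hit <- which(eqtl$transcript_id == tids[t])
      for (e in hit)
        y <- y + eqtl$effect_per_allele[e] * dose_f2[, eqtl$snp_id[e]]
    }
    E[, t] <- y
  }
  truth_tr <- data.frame(transcript_id = tids, sigma2_a = cfg$sigma2_a,
                         sigma2_e = cfg$sigma2_e, beta_age = cfg$age_beta,
                         residual_family = fams, stringsAsFactors = FALSE)
  list(expression = E, covariates = covariates, gene_map = gene_map,
       truth = list(eqtl = eqtl, transcripts = truth_tr,
                    season_effects = season_eff))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: pedigree, relationship matrix, genotypes and
#' expression in one call.
#'
#' @param cfg a [sim_config()].
#' @return list with `pedigree`, `A`, `genotypes` (dosage over all
#'   animals), `dosage_f2`, `snp_map`, `expression`, `covariates`,
#'   `gene_map`, `truth`.
#' @export
simulate_cross <- function(cfg = sim_config()) {
  ped <- generate_pedigree(cfg)
  A <- build_relationship_matrix(ped)
  G <- simulate_genotypes(ped, cfg)
  ex <- simulate_expression(G, ped, A, cfg)
  f2 <- rownames(ex$expression)
  list(pedigree = ped, A = A, genotypes = G$dosage,
       dosage_f2 = G$dosage[f2, , drop = FALSE], snp_map = G$map,
       expression = ex$expression, covariates = ex$covariates,
       gene_map = ex$gene_map, truth = ex$truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the same plain-text formats the pipeline reads: PLINK-text or
#' VCF genotypes, TSV expression and maps, CSV pedigree and covariates,
#' and `truth.tsv`.
#'
#' @param sim output of [simulate_cross()].
#' @param dir output directory (created if needed).
#' @param format `"plink"` or `"vcf"`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, format = c("plink", "vcf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  ped_out <- sim$pedigree
  ped_out$sire[is.na(ped_out$sire)] <- "0"
  ped_out$dam[is.na(ped_out$dam)] <- "0"
  utils::write.csv(as.data.frame(ped_out), fp("pedigree.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$covariates, fp("covariates.csv"),
                   row.names = FALSE, quote = FALSE)
  .write_matrix_tsv(sim$expression, fp("expression.tsv"))
  utils::write.table(sim$snp_map[, c("snp_id", "chromosome", "position_bp")],
                     fp("snp_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$gene_map, fp("gene_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (format == "plink") {
    write_plink(sim$dosage_f2, sim$snp_map, fp("genotypes"))
  } else {
    write_vcf(sim$dosage_f2, sim$snp_map, fp("genotypes.vcf"))
  }
  if (!is.null(sim$truth$eqtl))
    utils::write.table(sim$truth$eqtl, fp("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}

.write_matrix_tsv <- function(M, path, id_col = "sample_id") {
  df <- data.frame(rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
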