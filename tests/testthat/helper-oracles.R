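# Shared fixtures and independent oracles for the test suite.

# Small pedigrees -----------------------------------------------------------

trio_pedigree <- function() {
  validate_pedigree(data.frame(
    animal = c("O", "S", "D"), sire = c("S", NA, NA),
    dam = c("D", NA, NA), stringsAsFactors = FALSE))
}

# offspring of two half sibs: F = 0.125, diagonal 1.125
halfsib_mating_pedigree <- function() {
  validate_pedigree(data.frame(
    animal = c("P", "M1", "M2", "H1", "H2", "O"),
    sire = c(NA, NA, NA, "P", "P", "H1"),
    dam = c(NA, NA, NA, "M1", "M2", "H2"),
    stringsAsFactors = FALSE))
}

# Monte-Carlo gene-dropping estimate of additive relationships --------------
# Founders get unique allele labels; alleles drop through the pedigree, and
# A_ij is estimated as twice the IBD probability of randomly drawn alleles.
gene_drop_relationship <- function(ped, pairs, nrep = 1e5, seed = 99) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  a1 <- matrix(0L, n, nrep)
  a2 <- matrix(0L, n, nrep)
  lab <- 0L
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s)) {
      lab <- lab + 1L; a1[i, ] <- lab
    } else {
      si <- idx[s]
      pick <- stats::runif(nrep) < 0.5
      a1[i, ] <- ifelse(pick, a1[si, ], a2[si, ])
    }
    if (is.na(d)) {
      lab <- lab + 1L; a2[i, ] <- lab
    } else {
      di <- idx[d]
      pick <- stats::runif(nrep) < 0.5
      a2[i, ] <- ifelse(pick, a2[di, ], a1[di, ])
    }
  }
  do.call(rbind, lapply(pairs, function(pr) {
    i <- idx[pr[1]]; j <- idx[pr[2]]
    phi <- if (i == j) {
      (2 + 2 * (a1[i, ] == a2[i, ])) / 4
    } else {
      ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
         (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
    }
    data.frame(i = pr[1], j = pr[2], a_mc = 2 * mean(phi),
               se = 2 * stats::sd(phi) / sqrt(nrep),
               stringsAsFactors = FALSE)
  }))
}

# Brute-force BH step-up: adj_(k) = min_{j>=k} m p_(j)/j, capped at 1 -------
bh_brute_force <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  k <- length(p)
  adj <- numeric(k)
  for (i in seq_len(k))
    adj[i] <- min(1, min(m * ps[i:k] / (i:k)))
  out <- numeric(k)
  out[o] <- adj
  out
}

# Dense-matrix REML reference (no shared eigendecomposition) ---------------
reml_dense_reference <- function(y, X, Z, A, lambda_max = 1e3) {
  n <- length(y); p <- ncol(X)
  K <- Z %*% A %*% t(Z)
  ll <- function(l) {
    V <- diag(n) + l * K
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
    -0.5 * ((n - p) * log(s2) +
              as.numeric(determinant(V)$modulus) +
              as.numeric(determinant(XtViX)$modulus) + (n - p))
  }
  o <- stats::optimize(ll, c(0, lambda_max), maximum = TRUE, tol = 1e-8)
  l <- if (ll(0) >= o$objective) 0 else o$maximum
  V <- diag(n) + l * K
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- l * A %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(lambda = l, ll = ll,
       resid = as.numeric(y - X %*% b - Z %*% u))
}

# Exhaustive permutation p-value by brute force over group assignments ------
exact_p_brute_force <- function(values, groups, score_type) {
  g <- factor(groups)
  N <- length(values)
  stat0 <- linear_rank_statistic(values, g, score_type)$statistic
  lev <- levels(g)
  hits <- 0L; tot <- 0L
  rec <- function(lab, remaining, pos) {
    if (pos > N) {
      s <- linear_rank_statistic(values, factor(lab, levels = lev),
                                 score_type)$statistic
      tot <<- tot + 1L
      if (s >= stat0 - 1e-12) hits <<- hits + 1L
      return(invisible(NULL))
    }
    for (gi in seq_along(remaining)) {
      if (remaining[gi] == 0L) next
      remaining[gi] <- remaining[gi] - 1L
      lab[pos] <- lev[gi]
      rec(lab, remaining, pos + 1L)
      remaining[gi] <- remaining[gi] + 1L
    }
  }
  rec(character(N), as.integer(table(g)), 1L)
  hits / tot
}

# Small simulated dataset shared by several test files ---------------------
tiny_cross <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cross(sim_config(
        n_transcripts = 20, n_cis_eqtl = 3, n_trans_eqtl = 2,
        n_chromosomes = 3, snps_per_chromosome = 15,
        family_sizes = c(12, 9, 13, 4, 2), seed = 42))
    cache
  }
})

# Synthetic reconstruction of the published supplementary eQTL table -------
# The real table is not bundled; this builds, in code, a table with the same
# printed marginal structure (505 associations: 482 same-chromosome of which
# 343 lie < 5 Mb and 314 < 1 Mb from the gene start; 17 cross-chromosome;
# 6 with unknown SNP position; chromosome 23 carrying 55 SNPs / 11
# transcripts) so the summary machinery can be exercised at full scale.
synthetic_supplementary_table <- function() {
  n_cis <- 482; n_trans <- 17; n_unk <- 6
  # distances: 314 within 1 Mb, 29 in [1,5) Mb, 139 at >= 5 Mb
  d <- c(seq(1e4, 9.9e5, length.out = 314),
         seq(1.1e6, 4.9e6, length.out = 29),
         seq(5.1e6, 3.0e7, length.out = 139))
  d <- round(d)
  # chromosome 23 gets 55 of the cis SNPs across 11 transcripts
  chrom <- c(rep("23", 55), rep(as.character(rep(1:22, length.out = 427)),
                                1))
  gene_start <- rep(5e7, n_cis)
  cis <- data.frame(
    snp_id = sprintf("ss%03d", seq_len(n_cis)),
    snp_chrom = chrom, snp_pos = gene_start + d,
    transcript_id = c(sprintf("t23_%02d", rep(1:11, length.out = 55)),
                      sprintf("tc%03d", 56:482)),
    gene_chrom = chrom, gene_start = gene_start,
    stringsAsFactors = FALSE)
  trans <- data.frame(
    snp_id = sprintf("st%03d", seq_len(n_trans)),
    snp_chrom = as.character(rep(1:17)), snp_pos = 1e6,
    transcript_id = sprintf("tt%03d", seq_len(n_trans)),
    gene_chrom = as.character(rep(2:18)), gene_start = 2e6,
    stringsAsFactors = FALSE)
  unk <- data.frame(
    snp_id = sprintf("su%03d", seq_len(n_unk)),
    snp_chrom = NA_character_, snp_pos = NA_real_,
    transcript_id = sprintf("tu%03d", seq_len(n_unk)),
    gene_chrom = "1", gene_start = 3e6,
    stringsAsFactors = FALSE)
  tab <- rbind(cis, trans, unk)
  tab$assoc_class <- classify_association(tab$snp_chrom, tab$gene_chrom)
  tab$distance_bp <- snp_gene_distance(tab$snp_pos, tab$gene_start,
                                       tab$assoc_class == "cis")
  tab
}
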