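#' Sire-dam animal model and expression decorrelation
#'
#' Per-transcript mixed model
#' \deqn{y_i = s_j + \beta x_i + 0.5 (a_{if} + a_{im}) + e_i}
#' where `s_j` is a fixed year-season class effect, `x_i` the age at
#' slaughter in days, `a_if`, `a_im` the additive-genetic effects of the
#' animal's sire and dam with covariance `sigma2_a * A` (A the pedigree
#' numerator relationship matrix over the parents), and `e_i` an
#' uncorrelated residual with variance `sigma2_e`. The residuals absorb
#' the Mendelian-sampling deviation and are used downstream as
#' de-correlated expression values.
#'
#' Variance components are estimated by REML, profiling the ratio
#' `lambda = sigma2_a / sigma2_e`. Because the fixed design X and the
#' parent incidence Z are shared by all transcripts, a single
#' eigendecomposition of `Z A Z'` turns every per-transcript fit into a
#' one-dimensional bounded optimisation over lambda with O(n) likelihood
#' evaluations.
#'
#' @name sire-dam-model
NULL

#' Precompute the shared model basis
#'
#' Builds the fixed-effect design (intercept, year-season dummies with the
#' first non-empty level as reference, age), the parent incidence Z, and
#' the eigendecomposition of `Z A_par Z'` shared by all transcripts.
#'
#' @param covariates data frame with columns `sample_id`, `season_class`,
#'   `age_days`; one row per phenotyped sample.
#' @param Z parent incidence matrix from [parent_incidence()], rows in the
#'   same sample order as `covariates`.
#' @param A_par numerator relationship sub-matrix over the parents (the
#'   columns of Z), from [build_relationship_matrix()].
#' @return object of class `sire_dam_basis`.
#' @export
sire_dam_basis <- function(covariates, Z, A_par) {
  stopifnot(all(c("sample_id", "season_class", "age_days") %in%
                  names(covariates)))
  if (!identical(colnames(Z), rownames(A_par)) ||
      !identical(colnames(Z), colnames(A_par)))
    stop("columns of Z must match rows/columns of A_par", call. = FALSE)
  if (nrow(Z) != nrow(covariates))
    stop("Z and covariates disagree on the number of samples", call. = FALSE)
  season <- droplevels(factor(covariates$season_class))
  age <- as.numeric(covariates$age_days)
  if (anyNA(age)) stop("missing age_days", call. = FALSE)
  X <- if (nlevels(season) > 1L) {
    stats::model.matrix(~ season + age,
                        data = data.frame(season = season, age = age))
  } else {
    cbind("(Intercept)" = 1, age = age)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("singular fixed-effect design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  K <- Z %*% A_par %*% t(Z)
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  out <- list(
    sample_ids = as.character(covariates$sample_id),
    X = X, Z = Z, A_par = A_par,
    season_levels = levels(season),
    U = U, d = d,
    Xr = crossprod(U, X),          # rotated design, shared by transcripts
    n = nrow(X), p = ncol(X)
  )
  class(out) <- "sire_dam_basis"
  out
}

# Restricted log-likelihood at ratio lambda (profiled over sigma2_e),
# up to an additive constant. Returns the pieces needed downstream.
.reml_at_lambda <- function(lambda, basis, yr) {
  w <- 1 + lambda * basis$d
  fit <- stats::lm.wfit(basis$Xr, yr, w = 1 / w)
  rss <- sum(fit$residuals^2 / w)
  np <- basis$n - basis$p
  sigma2_e <- rss / np
  XtWX <- crossprod(basis$Xr / w, basis$Xr)
  ldet_xwx <- determinant(XtWX, logarithm = TRUE)$modulus
  ll <- -0.5 * (np * log(sigma2_e) + sum(log(w)) + as.numeric(ldet_xwx) + np)
  list(ll = ll, beta = fit$coefficients, sigma2_e = sigma2_e, w = w,
       resid_rot = fit$residuals)
}

#' Fit the sire-dam model to one transcript
#'
#' REML estimation of `(sigma2_a, sigma2_e)` by bounded one-dimensional
#' optimisation of the restricted likelihood over
#' `lambda = sigma2_a / sigma2_e` in `[0, lambda_max]`, generalised
#' least-squares fixed effects at the optimum, parent effects as BLUPs,
#' and residuals `y - X beta - Z u`. A boundary solution `lambda = 0`
#' (no detectable polygenic variance; the fit degenerates to OLS) is
#' allowed and reported. A constant response is flagged `degenerate` with
#' zero residuals.
#'
#' @param y numeric response, aligned with the basis sample order.
#' @param basis a [sire_dam_basis()] object.
#' @param transcript_id optional label stored in the fit.
#' @param lambda_max upper bound for the variance ratio (default 1e3).
#' @param tol optimisation tolerance on lambda (default 1e-8).
#' @return object of class `sire_dam_fit` with components `beta_age`,
#'   `season_effects`, `sigma2_a`, `sigma2_e`, `h2`, `lambda`,
#'   `parent_blups`, `residuals`, `fitted`, `coefficients`,
#'   `log_likelihood` (restricted, up to a constant), `converged`,
#'   `degenerate`.
#' @export
fit_sire_dam <- function(y, basis, transcript_id = NA_character_,
                         lambda_max = 1e3, tol = 1e-8) {
  stopifnot(inherits(basis, "sire_dam_basis"))
  y <- as.numeric(y)
  if (length(y) != basis$n) stop("length(y) != n samples", call. = FALSE)
  if (anyNA(y)) stop("missing expression values", call. = FALSE)

  if (stats::var(y) == 0) {
    out <- list(transcript_id = transcript_id,
                coefficients = c("(Intercept)" = y[1]),
                beta_age = 0, season_effects = numeric(0),
                sigma2_a = 0, sigma2_e = 0, h2 = NA_real_, lambda = 0,
                parent_blups = stats::setNames(rep(0, ncol(basis$Z)),
                                               colnames(basis$Z)),
                residuals = stats::setNames(rep(0, basis$n),
                                            basis$sample_ids),
                fitted = stats::setNames(y, basis$sample_ids),
                log_likelihood = NA_real_,
                converged = FALSE, degenerate = TRUE)
    class(out) <- "sire_dam_fit"
    return(out)
  }

  yr <- crossprod(basis$U, y)[, 1L]
  obj <- function(l) .reml_at_lambda(l, basis, yr)$ll
  opt <- stats::optimize(obj, interval = c(0, lambda_max), maximum = TRUE,
                         tol = tol)
  lambda <- opt$maximum
  ll <- opt$objective
  # optimize() never returns an endpoint exactly; accept the boundary when
  # it is at least as good as the interior candidate
  ll0 <- obj(0)
  if (ll0 >= ll) { lambda <- 0; ll <- ll0 }
  at <- .reml_at_lambda(lambda, basis, yr)
  sigma2_e <- at$sigma2_e
  sigma2_a <- lambda * sigma2_e
  beta <- at$beta

  # residuals e = U diag(1/w) U'(y - X beta); BLUPs u = lambda A Z' e / 1
  r_marg <- y - basis$X %*% beta
  e_rot <- crossprod(basis$U, r_marg)[, 1L] / at$w
  e_hat <- basis$U %*% e_rot
  u_hat <- lambda * (basis$A_par %*% crossprod(basis$Z, e_hat))[, 1L]
  resid <- (y - basis$X %*% beta - basis$Z %*% u_hat)[, 1L]

  cf <- stats::setNames(as.numeric(beta), colnames(basis$X))
  seas <- cf[grep("^season", names(cf))]
  names(seas) <- sub("^season", "", names(seas))
  converged <- is.finite(ll)
  out <- list(transcript_id = transcript_id,
              coefficients = cf,
              beta_age = unname(cf["age"]),
              season_effects = seas,
              sigma2_a = sigma2_a, sigma2_e = sigma2_e,
              h2 = sigma2_a / (sigma2_a + sigma2_e),
              lambda = lambda,
              parent_blups = stats::setNames(u_hat, colnames(basis$Z)),
              residuals = stats::setNames(resid, basis$sample_ids),
              fitted = stats::setNames(y - resid, basis$sample_ids),
              log_likelihood = ll,
              converged = converged, degenerate = FALSE)
  class(out) <- "sire_dam_fit"
  out
}

#' @export
print.sire_dam_fit <- function(x, ...) {
  cat("Sire-dam mixed model fit",
      if (!is.na(x$transcript_id)) paste0(" [", x$transcript_id, "]"), "\n")
  if (x$degenerate) {
    cat("  degenerate fit (constant response)\n")
    return(invisible(x))
  }
  cat(sprintf("  sigma2_a = %.4g, sigma2_e = %.4g, h2 = %.3f%s\n",
              x$sigma2_a, x$sigma2_e, x$h2,
              if (x$lambda == 0) " (boundary: OLS)" else ""))
  cat(sprintf("  beta_age = %.4g; %d season levels; %d parents\n",
              x$beta_age, length(x$season_effects) + 1L,
              length(x$parent_blups)))
  invisible(x)
}

#' @export
summary.sire_dam_fit <- function(object, ...) {
  print(object)
  cat("  residual quartiles:",
      paste(signif(stats::quantile(object$residuals), 3), collapse = " "),
      "\n")
  invisible(object)
}

#' @export
coef.sire_dam_fit <- function(object, ...) object$coefficients

#' @export
residuals.sire_dam_fit <- function(object, ...) object$residuals

#' @export
fitted.sire_dam_fit <- function(object, ...) object$fitted

#' @export
logLik.sire_dam_fit <- function(object, ...) {
  structure(object$log_likelihood, class = "logLik",
            df = length(object$coefficients) + 2L)
}

#' Decorrelate an expression matrix
#'
#' Fits the sire-dam model to every transcript (sharing one
#' eigendecomposition) and returns the residual matrix as de-correlated
#' expression, together with a per-transcript fit report. Per-transcript
#' failures are flagged in the report, never abort the batch.
#'
#' @param expr numeric matrix, samples x transcripts, with sample ids as
#'   row names and transcript ids as column names.
#' @param covariates data frame `sample_id`, `season_class`, `age_days`.
#' @param ped validated pedigree covering the samples and their parents.
#' @param lambda_max,tol passed to [fit_sire_dam()].
#' @return list with `residuals` (matrix, same shape and dimnames as
#'   `expr`) and `report` (data frame: transcript, sigma2_a, sigma2_e, h2,
#'   beta_age, lambda, converged, degenerate).
#' @export
decorrelate_expression <- function(expr, covariates, ped,
                                   lambda_max = 1e3, tol = 1e-8) {
  expr <- as.matrix(expr)
  ids <- rownames(expr)
  if (is.null(ids)) stop("expr needs sample row names", call. = FALSE)
  cov <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
  if (anyNA(cov$sample_id))
    stop("samples without covariates: ",
         paste(setdiff(ids, covariates$sample_id), collapse = ", "),
         call. = FALSE)
  Z <- parent_incidence(ped, ids)
  A_par <- build_relationship_matrix(ped, ids = colnames(Z))
  basis <- sire_dam_basis(cov, Z, A_par)

  nt <- ncol(expr)
  res <- matrix(NA_real_, nrow(expr), nt, dimnames = dimnames(expr))
  rep_rows <- vector("list", nt)
  for (t in seq_len(nt)) {
    tid <- colnames(expr)[t]
    fit <- tryCatch(
      fit_sire_dam(expr[, t], basis, transcript_id = tid,
                   lambda_max = lambda_max, tol = tol),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rep_rows[[t]] <- data.frame(
        transcript = tid, sigma2_a = NA_real_, sigma2_e = NA_real_,
        h2 = NA_real_, beta_age = NA_real_, lambda = NA_real_,
        converged = FALSE, degenerate = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    res[, t] <- fit$residuals
    rep_rows[[t]] <- data.frame(
      transcript = tid, sigma2_a = fit$sigma2_a, sigma2_e = fit$sigma2_e,
      h2 = fit$h2, beta_age = fit$beta_age, lambda = fit$lambda,
      converged = fit$converged, degenerate = fit$degenerate,
      stringsAsFactors = FALSE)
  }
  list(residuals = res, report = do.call(rbind, rep_rows))
}
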