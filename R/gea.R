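#' Per-genotype presence encoding
#'
#' Splits a biallelic dosage column into three binary presence indicators,
#' one per genotype class (hom-ref = 0, het = 1, hom-alt = 2). Missing stays
#' missing; a class absent from the data yields an all-zero vector and is
#' flagged non-testable.
#'
#' @param snp_column integer vector of dosages in `{0, 1, 2, NA}`.
#' @return list with `y` (n x 3 binary matrix, columns `hom_ref`, `het`,
#'   `hom_alt`) and `testable` (logical length 3: both classes present).
#' @export
encode_genotypes <- function(snp_column) {
  y <- cbind(hom_ref = as.integer(snp_column == 0L),
             het = as.integer(snp_column == 1L),
             hom_alt = as.integer(snp_column == 2L))
  ones <- colSums(y, na.rm = TRUE)
  n_obs <- sum(!is.na(snp_column))
  list(y = y, testable = ones > 0 & ones < n_obs)
}

#' Number of candidate association models
#'
#' One model per (environmental variable, genotype class, SNP) triple.
#'
#' @param n_env,n_snps positive integers.
#' @return `n_env * 3 * n_snps`.
#' @export
count_models <- function(n_env, n_snps) {
  stopifnot(n_env >= 1, n_snps >= 1)
  as.numeric(n_env) * 3 * as.numeric(n_snps)
}

# Batched IRLS for logistic regression with a shared design matrix and many
# response columns. Y may contain NA (listwise weight 0). Returns, per
# column: coefficients, deviance, standard errors, iteration count and a
# status code. Predictors are assumed already standardized by the caller
# when separation detection (|beta| > sep_bound) is to be meaningful.
logistic_irls_batch <- function(Y, X, maxit = 100, tol = 1e-8,
                                sep_bound = 50) {
  n <- nrow(Y); L <- ncol(Y); p <- ncol(X)
  M <- !is.na(Y)
  Y0 <- Y; Y0[!M] <- 0
  B <- matrix(0, p, L)
  dev <- rep(NA_real_, L)
  se <- matrix(NA_real_, p, L)
  iter <- integer(L)
  status <- rep("ok", L)
  nobs <- colSums(M)
  ones <- colSums(Y0)
  degen <- ones == 0 | ones == nobs
  status[degen] <- "degenerate_response"
  active <- !degen
  prev <- rep(Inf, L)
  for (it in seq_len(maxit)) {
    idx <- which(active)
    if (!length(idx)) break
    Eta <- X %*% B[, idx, drop = FALSE]
    Mu <- 1 / (1 + exp(-Eta))
    W <- Mu * (1 - Mu) * M[, idx, drop = FALSE]
    R <- (Y0[, idx, drop = FALSE] - Mu) * M[, idx, drop = FALSE]
    d <- -2 * colSums(M[, idx, drop = FALSE] *
                        (Y0[, idx, drop = FALSE] * log(pmax(Mu, 1e-300)) +
                         (1 - Y0[, idx, drop = FALSE]) *
                           log(pmax(1 - Mu, 1e-300))))
    conv <- abs(d - prev[idx]) < tol * (abs(d) + 0.1)
    prev[idx] <- d
    dev[idx] <- d
    iter[idx] <- it
    for (k in seq_along(idx)) {
      l <- idx[k]
      if (conv[k]) { active[l] <- FALSE; next }
      XtWX <- crossprod(X, W[, k] * X)
      g <- crossprod(X, R[, k])
      step <- tryCatch(solve(XtWX, g), error = function(e) NULL)
      if (is.null(step)) { status[l] <- "singular"; active[l] <- FALSE; next }
      B[, l] <- B[, l] + step
      if (max(abs(B[, l])) > sep_bound) {
        status[l] <- "separation"; active[l] <- FALSE
      }
    }
  }
  status[active] <- "no_convergence"
  for (l in which(status == "ok")) {
    w <- plogis(X %*% B[, l]); w <- as.vector(w * (1 - w)) * M[, l]
    vc <- tryCatch(solve(crossprod(X, w * X)), error = function(e) NULL)
    if (is.null(vc)) { status[l] <- "singular"; next }
    se[, l] <- sqrt(pmax(diag(vc), 0))
  }
  list(coef = B, se = se, deviance = dev, iter = iter, status = status,
       n = nobs)
}

#' Fit one genotype-environment logistic association model
#'
#' Maximum-likelihood logistic regression of a binary genotype-presence
#' vector on one environmental variable, optionally adjusted for
#' population-structure covariates: `logit P(y = 1) = alpha + beta env +
#' gamma cov`. Two significance scores are reported: the likelihood-ratio
#' G score `G = 2 (ll_full - ll_null)` where the null retains the
#' covariates but drops the environmental term, and the Wald score
#' `W = (beta / se(beta))^2`; both are referred to chi-square with 1 df.
#' Predictors are standardized internally for numerical stability (max 100
#' IRLS iterations, tolerance 1e-8 on the deviance; separation flagged when
#' a standardized coefficient exceeds 50); coefficients are reported on the
#' original scale. Rows with missing response, environment or covariate are
#' dropped listwise.
#'
#' @param y binary response (genotype presence), may contain `NA`.
#' @param env numeric environmental variable.
#' @param covariates optional numeric matrix of structure covariates.
#' @return list of class `association_model`: `alpha`, `beta`, `gamma`,
#'   `G`, `W`, `p_G`, `p_W`, `n`, `status` (`"ok"` or the failure mode; no
#'   p-values are emitted unless `"ok"`).
#' @export
fit_logistic <- function(y, env, covariates = NULL) {
  if (stats::var(env, na.rm = TRUE) == 0 || anyNA(env) && all(is.na(env)))
    stop("degenerate predictor: environmental variable has no variance")
  keep <- !is.na(env)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & !apply(covariates, 1, anyNA)
  }
  y <- y[keep]; env <- env[keep]
  C <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
  fit <- gea_scan_env(matrix(y, ncol = 1), env, C)
  out <- as.list(fit[1, c("alpha", "beta", "G", "W", "p_G", "p_W", "n")])
  out$gamma <- unlist(fit[1, grep("^gamma", names(fit)), drop = TRUE])
  out$status <- fit$status[1]
  if (out$status != "ok") out[c("G", "W", "p_G", "p_W")] <- NA_real_
  class(out) <- "association_model"
  out
}

# Core batched scan for one environmental variable: Y = n x L binary
# presence matrix; returns one row per column of Y with coefficients on the
# original predictor scale.
gea_scan_env <- function(Y, env, covariates = NULL, maxit = 100,
                         tol = 1e-8) {
  n <- length(env)
  stopifnot(nrow(Y) == n)
  mu_e <- mean(env); sd_e <- stats::sd(env)
  if (sd_e == 0) stop("degenerate predictor: environmental variable has no variance")
  Xe <- (env - mu_e) / sd_e
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    mu_c <- colMeans(C); sd_c <- apply(C, 2, stats::sd)
    sd_c[sd_c == 0] <- 1
    Cs <- sweep(sweep(C, 2, mu_c), 2, sd_c, "/")
    Xf <- cbind(1, Xe, Cs)
    Xn <- cbind(1, Cs)
  } else {
    Cs <- NULL
    Xf <- cbind(1, Xe)
    Xn <- matrix(1, n, 1)
  }
  full <- logistic_irls_batch(Y, Xf, maxit, tol)
  null <- logistic_irls_batch(Y, Xn, maxit, tol)
  G <- pmax(null$deviance - full$deviance, 0)
  bz <- full$coef[2, ]; sez <- full$se[2, ]
  W <- (bz / sez)^2
  ok <- full$status == "ok" & null$status == "ok"
  p_G <- ifelse(ok, stats::pchisq(G, 1, lower.tail = FALSE), NA_real_)
  p_W <- ifelse(ok, stats::pchisq(W, 1, lower.tail = FALSE), NA_real_)
  # back-transform to the original predictor scale
  beta <- bz / sd_e
  alpha <- full$coef[1, ] - bz * mu_e / sd_e
  out <- data.frame(alpha = alpha, beta = beta, G = ifelse(ok, G, NA),
                    W = ifelse(ok, W, NA), p_G = p_G, p_W = p_W,
                    n = full$n, status = ifelse(ok, full$status,
                                                ifelse(full$status != "ok",
                                                       full$status,
                                                       null$status)))
  if (!is.null(covariates)) {
    Gm <- full$coef[-(1:2), , drop = FALSE] / sd_c
    alpha_shift <- colSums(Gm * mu_c)
    out$alpha <- out$alpha - alpha_shift
    for (j in seq_len(nrow(Gm))) out[[paste0("gamma", j)]] <- Gm[j, ]
  }
  out
}

#' Genotype-environment association scan
#'
#' Fits every (environmental variable, genotype class, SNP) logistic model
#' and corrects G and Wald p-values for multiple testing with Storey
#' q-values, by default within each environmental variable's batch of
#' models (so one variable's q-values do not depend on the other
#' variables' batches).
#'
#' @param gm a [genotype_matrix()].
#' @param features data frame of environmental variables at the individuals
#'   (one row per individual, aligned with `gm$ind`).
#' @param covariates optional structure covariate matrix.
#' @param batch `"per_env"` (default) or `"global"` q-value batches.
#' @param qvalue_method forwarded to [qvalues()].
#' @return data frame, one row per model: `snp`, `class`, `env`,
#'   coefficients, `G`, `W`, `p_G`, `p_W`, `q_G`, `q_W`, `n`, `status`.
#' @export
gea_scan <- function(gm, features, covariates = NULL,
                     batch = c("per_env", "global"),
                     qvalue_method = "storey") {
  batch <- match.arg(batch)
  stopifnot(nrow(features) == nrow(gm$geno))
  classes <- c("hom_ref", "het", "hom_alt")
  Ybig <- matrix(NA_integer_, nrow(gm$geno), 3 * ncol(gm$geno))
  for (j in seq_len(ncol(gm$geno))) {
    e <- encode_genotypes(gm$geno[, j])
    Ybig[, 3 * (j - 1) + 1:3] <- e$y
  }
  snp_of <- rep(colnames(gm$geno), each = 3)
  cls_of <- rep(classes, ncol(gm$geno))
  res <- vector("list", ncol(features))
  for (v in seq_len(ncol(features))) {
    fit <- gea_scan_env(Ybig, features[[v]], covariates)
    fit$snp <- snp_of
    fit$class <- cls_of
    fit$env <- names(features)[v]
    if (batch == "per_env") {
      fit$q_G <- NA_real_; fit$q_W <- NA_real_
      ok <- !is.na(fit$p_G)
      if (any(ok)) {
        fit$q_G[ok] <- qvalues(fit$p_G[ok], qvalue_method)
        fit$q_W[ok] <- qvalues(fit$p_W[ok], qvalue_method)
      }
    }
    res[[v]] <- fit
  }
  res <- do.call(rbind, res)
  if (batch == "global") {
    res$q_G <- NA_real_; res$q_W <- NA_real_
    ok <- !is.na(res$p_G)
    res$q_G[ok] <- qvalues(res$p_G[ok], qvalue_method)
    res$q_W[ok] <- qvalues(res$p_W[ok], qvalue_method)
  }
  front <- c("snp", "class", "env")
  res[, c(front, setdiff(names(res), front))]
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the proportion of true nulls `pi0`
#' estimated on a lambda grid (0.05 to 0.95 by 0.05) with a smoothing
#' spline (df = 3) evaluated at the largest lambda, clamped to (0, 1].
#' With `method = "bh"`, `pi0` is fixed at 1 and the result equals
#' Benjamini-Hochberg adjusted p-values. q is monotone nondecreasing in p.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param method `"storey"` or `"bh"`.
#' @return q-values in the order of `p`.
#' @export
qvalues <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (method == "storey") {
    lambda <- seq(0.05, 0.95, 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- if (length(unique(pi0_l)) == 1) pi0_l[1] else {
      sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(sp, x = max(lambda))$y
    }
    pi0 <- min(max(pi0, 1e-8), 1)
  } else pi0 <- 1
  o <- order(p, decreasing = TRUE)
  q <- pi0 * p[o] * m / (m - seq_len(m) + 1)
  q <- cummin(pmin(q, 1))
  q[order(o)]
}

#' Select significant genotype-environment associations (SGEA)
#'
#' Keeps models with `q_G < q` and `q_W < q` (dual rule); when a SNP is
#' significant with several environmental variables, only the best model by
#' G is retained, with deterministic tie-breaks (lower `p_W`, then
#' environmental-variable name).
#'
#' @param models data frame from [gea_scan()].
#' @param q significance threshold on both q-values.
#' @return the retained subset, at most one row per SNP.
#' @export
select_sgea <- function(models, q = 0.01) {
  sig <- models[!is.na(models$q_G) & !is.na(models$q_W) &
                  models$q_G < q & models$q_W < q, , drop = FALSE]
  if (!nrow(sig)) return(sig)
  sig <- sig[order(sig$snp, -sig$G, sig$p_W, sig$env), , drop = FALSE]
  out <- sig[!duplicated(sig$snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
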