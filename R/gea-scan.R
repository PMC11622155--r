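# Shared helpers and the result container for the three genome scans.

# expand a site x variable env table to one row per individual, in the
# order of the genotype matrix, standardising each variable
env_by_individual <- function(x, env, standardize = TRUE) {
  env <- as.data.frame(env)
  miss <- setdiff(unique(x$ind_meta$site), rownames(env))
  if (length(miss)) {
    stop("no environmental values for site(s): ", paste(miss, collapse = ", "))
  }
  E <- env[x$ind_meta$site, , drop = FALSE]
  if (standardize) E[] <- lapply(E, function(v) as.numeric(scale(v)))
  rownames(E) <- NULL
  E
}

require_imputed <- function(x, fn) {
  if (anyNA(x$calls)) {
    stop(fn, " requires a complete matrix; run impute_nearest_neighbour() first")
  }
}

new_gea_scan <- function(method, statistic, p, p_adj, outliers,
                         per_variable = NULL, calibration = list(), ...) {
  structure(
    list(method = method, statistic = statistic, p = p, p_adj = p_adj,
         outliers = outliers, per_variable = per_variable,
         calibration = calibration, ...),
    class = "gea_scan"
  )
}

#' @export
print.gea_scan <- function(x, ...) {
  cat(sprintf("gea_scan [%s]: %d loci tested, %d outliers\n",
              x$method, length(x$statistic), length(x$outliers)))
  if (!is.null(x$calibration$gif)) {
    cat(sprintf("  genomic inflation factor: %s\n",
                paste(sprintf("%.3f", x$calibration$gif), collapse = ", ")))
  }
  if (!is.null(x$per_variable)) {
    cat("  outliers per environmental variable:\n")
    print(x$per_variable)
  }
  invisible(x)
}

#' Redundancy-analysis loading outlier scan
#'
#' Fits the constrained ordination of centred genotypes on the
#' (standardised) environmental predictors, takes per-locus loadings on
#' each constrained axis, and flags loci whose loading lies beyond
#' `mean +/- sd_cutoff * SD` of that axis's loading distribution
#' (2.5 SD corresponds to a two-tailed normal p of 0.0005). Model
#' significance is assessed by permutation of the environmental rows
#' (pseudo-F on the constrained variance); sequential per-axis tests are
#' available via `by_axis`.
#'
#' @param x an imputed [genotype_matrix()]
#' @param env site x variable environmental table (rows = site names)
#' @param sd_cutoff loading outlier cutoff in axis SD units (default 2.5)
#' @param n_permutations permutations for the significance tests
#'   (default 999; 0 skips them)
#' @param seed integer seed for the permutations
#' @param axes constrained axes to scan (default: all)
#' @param pool_axes pool loadings of all scanned axes into one
#'   distribution instead of applying the rule per axis
#' @param by_axis also run sequential per-axis permutation tests
#'   (slower; default FALSE)
#' @return a `gea_scan`; `statistic` is the per-locus maximum |z| across
#'   scanned axes, `p` its two-tailed normal p-value. Each outlier locus
#'   is attributed to the environmental variable it correlates with most
#'   strongly (`per_variable` counts). `calibration` records the SD
#'   cutoff, GIF, overall permutation p and (optionally) per-axis p.
#' @export
rda_scan <- function(x, env, sd_cutoff = 2.5, n_permutations = 999,
                     seed = 1L, axes = NULL, pool_axes = FALSE,
                     by_axis = FALSE) {
  require_imputed(x, "rda_scan")
  env <- as.data.frame(env)
  if (ncol(env) >= nrow(env)) {
    stop("more environmental predictors than sites; prune predictors first")
  }
  E <- env_by_individual(x, env)
  G <- x$calls
  mod <- vegan::rda(G ~ ., data = E)
  v <- mod$CCA$v
  if (is.null(axes)) axes <- seq_len(ncol(v))
  v <- v[, axes, drop = FALSE]

  if (pool_axes) {
    z <- (v - mean(v)) / stats::sd(v)
  } else {
    z <- scale(v)
  }
  out_mask <- rowSums(abs(z) > sd_cutoff) > 0
  zmax <- apply(abs(z), 1, max)
  p <- 2 * stats::pnorm(-zmax)
  names(p) <- names(zmax) <- x$locus_meta$id
  outliers <- x$locus_meta$id[out_mask]

  anova_p <- axis_p <- NULL
  if (n_permutations > 0) {
    set.seed(seed)
    an <- vegan::anova.cca(mod, permutations = n_permutations)
    anova_p <- an[["Pr(>F)"]][1]
    if (by_axis) {
      axis_an <- vegan::anova.cca(mod, by = "axis",
                                  permutations = n_permutations)
      axis_p <- axis_an[["Pr(>F)"]][seq_along(axes)]
    }
  }

  per_variable <- NULL
  if (length(outliers)) {
    Em <- as.matrix(E)
    r <- stats::cor(G[, out_mask, drop = FALSE], Em)
    assigned <- colnames(Em)[max.col(abs(r), ties.method = "first")]
    per_variable <- table(factor(assigned, levels = colnames(Em)))
  }
  # per-axis calibration: standardised loadings behave as z-scores under
  # the null, so median(z^2) over the chi-square-1 median indexes
  # residual inflation axis by axis
  gif <- apply(z, 2, function(col) stats::median(col^2)) /
    stats::qchisq(0.5, 1)
  names(gif) <- paste0("RDA", axes)

  new_gea_scan(
    "rda", zmax, p, stats::p.adjust(p, "BH"), outliers, per_variable,
    calibration = list(sd_cutoff = sd_cutoff, gif = gif,
                       permutation_p = anova_p, axis_p = axis_p,
                       n_permutations = n_permutations),
    loadings = v, model = mod
  )
}

#' Principal-component Mahalanobis outlier scan
#'
#' Regresses each binomially scaled locus on the top `K` principal
#' component score vectors, collects the K-vector of per-locus z-scores,
#' and measures each locus's robust Mahalanobis distance from the bulk
#' (covariance by a robust estimator). Distances are divided by the
#' genomic inflation factor (median distance over the chi-square-K
#' median) before conversion to chi-square p-values.
#'
#' @param x an imputed [genotype_matrix()]
#' @param K number of principal components capturing background structure
#'   (default 5)
#' @param alpha significance level on the adjusted scale (default 0.1)
#' @param mode `"qvalue"` (Benjamini-Hochberg step-up, default) or
#'   `"bonferroni"`
#' @param seed seed for the robust covariance subsampling
#' @return a `gea_scan`; `statistic` is the calibrated Mahalanobis
#'   distance.
#' @export
pcadapt_scan <- function(x, K = 5, alpha = 0.1,
                         mode = c("qvalue", "bonferroni"), seed = 1L) {
  mode <- match.arg(mode)
  require_imputed(x, "pcadapt_scan")
  pc <- pca_scores(x, K)
  g <- x$calls[, pc$kept_loci, drop = FALSE]
  p_hat <- colMeans(g) / 2
  Z <- sweep(sweep(g, 2, 2 * p_hat), 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  S <- pc$scores
  n <- nrow(Z)

  StS <- crossprod(S)
  B <- solve(StS, crossprod(S, Z))              # K x L
  rss <- colSums(Z^2) - colSums(B * (StS %*% B))
  df <- n - K - 1
  sigma2 <- pmax(rss, 0) / df
  se <- sqrt(outer(diag(solve(StS)), sigma2))   # K x L
  zs <- t(B / se)                               # L x K

  old <- globalenv()$.Random.seed
  set.seed(seed)
  rob <- tryCatch(MASS::cov.rob(zs, method = "mcd"),
                  error = function(e) list(center = apply(zs, 2, stats::median),
                                           cov = stats::cov(zs)))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  d <- stats::mahalanobis(zs, rob$center, rob$cov)
  gif <- stats::median(d) / stats::qchisq(0.5, K)
  d_cal <- d / gif
  p <- stats::pchisq(d_cal, df = K, lower.tail = FALSE)
  ids <- x$locus_meta$id[pc$kept_loci]
  names(p) <- names(d_cal) <- ids

  p_adj <- stats::p.adjust(p, if (mode == "qvalue") "BH" else "bonferroni")
  outliers <- ids[p_adj < alpha]

  new_gea_scan(
    "pcadapt", d_cal, p, p_adj, outliers, NULL,
    calibration = list(K = K, gif = gif, mode = mode, alpha = alpha),
    zscores = zs
  )
}

#' Latent-factor ridge regression scan
#'
#' For each environmental variable: latent factors are the top-K left
#' singular vectors of the genotype matrix after regressing the variable
#' out, per-locus effects come from least squares of genotypes on the
#' variable plus the factors with a ridge penalty on the factor loadings,
#' z-scores are recalibrated by the genomic inflation factor, and
#' outliers must satisfy both the Benjamini-Hochberg FDR threshold and a
#' raw p-value ceiling.
#'
#' @param x an imputed [genotype_matrix()]
#' @param env site x variable environmental table
#' @param K number of latent factors (default 8)
#' @param fdr Benjamini-Hochberg FDR threshold (default 0.05)
#' @param p_threshold raw p-value ceiling (default 0.001)
#' @param ridge ridge penalty scale on the factor loadings, as a fraction
#'   of the mean diagonal of the design cross-product (default 1e-4)
#' @param use_fdr,use_p switch either arm of the conjunction off
#' @return a `gea_scan`; method-level `outliers` is the union over
#'   variables (each locus counted once), `per_variable` the per-variable
#'   outlier counts, `by_variable` the per-variable detail (z, p,
#'   adjusted p, outlier ids, GIF).
#' @export
lfmm_scan <- function(x, env, K = 8, fdr = 0.05, p_threshold = 0.001,
                      ridge = 1e-4, use_fdr = TRUE, use_p = TRUE) {
  require_imputed(x, "lfmm_scan")
  E <- env_by_individual(x, env)
  G <- scale(x$calls, center = TRUE, scale = FALSE)
  n <- nrow(G)
  ids <- x$locus_meta$id
  by_variable <- list()
  for (v in colnames(E)) {
    xv <- E[[v]]
    if (K > 0) {
      resid <- G - cbind(xv) %*% t(crossprod(G, xv)) / sum(xv^2)
      sv <- svd(resid, nu = K, nv = 0)
      A <- cbind(xv, sv$u)
    } else {
      A <- cbind(xv)
    }
    AtA <- crossprod(A)
    delta <- ridge * mean(diag(AtA))
    M <- AtA + diag(c(0, rep(delta, ncol(A) - 1)), ncol(A))
    Minv <- solve(M)
    B <- Minv %*% crossprod(A, G)
    fitted_ss <- colSums(B * (AtA %*% B))
    rss <- pmax(colSums(G^2) - 2 * colSums(B * crossprod(A, G)) + fitted_ss, 0)
    df <- n - ncol(A) - 1
    sigma2 <- rss / df
    cov_unscaled <- (Minv %*% AtA %*% Minv)[1, 1]
    z <- B[1, ] / sqrt(sigma2 * cov_unscaled)
    gif <- stats::median(z^2) / stats::qchisq(0.5, 1)
    p <- stats::pchisq(z^2 / gif, df = 1, lower.tail = FALSE)
    names(z) <- names(p) <- ids
    p_adj <- stats::p.adjust(p, "BH")
    sel <- rep(TRUE, length(p))
    if (use_fdr) sel <- sel & p_adj < fdr
    if (use_p) sel <- sel & p < p_threshold
    by_variable[[v]] <- list(z = z, p = p, p_adj = p_adj,
                             outliers = ids[sel], gif = gif)
  }
  outliers <- unique(unlist(lapply(by_variable, `[[`, "outliers")))
  per_variable <- vapply(by_variable, function(b) length(b$outliers), 0L)
  pmin_all <- do.call(pmin, lapply(by_variable, `[[`, "p"))
  zmax <- do.call(pmax, lapply(by_variable, function(b) abs(b$z)))
  new_gea_scan(
    "lfmm", zmax, pmin_all, NULL, outliers, per_variable,
    calibration = list(K = K, fdr = fdr, p_threshold = p_threshold,
                       gif = vapply(by_variable, `[[`, 0, "gif")),
    by_variable = by_variable
  )
}

#' Multi-method consensus of outlier loci
#'
#' A locus enters the consensus when it appears in the outlier set of at
#' least `min_methods` scans (a locus counts once per method regardless
#' of how many environmental variables flagged it).
#'
#' @param results list of `gea_scan` objects (>= 2)
#' @param min_methods minimum number of methods (default 2)
#' @return a `candidate_set`: `per_method` (named list of outlier id
#'   vectors), `consensus`, `min_methods`.
#' @export
consensus <- function(results, min_methods = 2) {
  if (length(results) < 2) stop("need at least two scan results")
  per_method <- lapply(results, `[[`, "outliers")
  names(per_method) <- vapply(results, `[[`, "", "method")
  counts <- table(unlist(lapply(per_method, unique)))
  cons <- names(counts)[counts >= min_methods]
  structure(
    list(per_method = per_method, consensus = cons,
         min_methods = min_methods),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %s -> %d consensus loci (>= %d methods)\n",
              paste(sprintf("%s=%d", names(x$per_method),
                            lengths(x$per_method)), collapse = ", "),
              length(x$consensus), x$min_methods))
  invisible(x)
}
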