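#' Sparse non-negative matrix factorisation of ancestry
#'
#' Factorises the genotype matrix `G` (0/1/2) as `G/2 ~ Q F` where `Q`
#' (individuals x K) holds ancestry coefficients constrained to the
#' probability simplex and `F` (K x loci) holds ancestral allele
#' frequencies in `[0, 1]`, by alternating least squares with a ridge
#' penalty `alpha` on `F` and exact row-wise simplex projection of `Q`.
#' A random `mask_fraction` of observed entries is held out; the masked
#' cross-entropy (mean negative binomial log-likelihood of held-out calls
#' under `Binomial(2, (QF)_ij)`) is the model-choice criterion used by
#' [choose_K()]. Missing calls are treated like masked entries (excluded
#' from the fit, soft-imputed from the current factorisation) but do not
#' enter the cross-entropy.
#'
#' @param x a [genotype_matrix()]
#' @param K number of ancestral populations (>= 1)
#' @param alpha ridge penalty on `F` (default 10)
#' @param mask_fraction fraction of observed entries held out (default 0.05)
#' @param seed integer seed (initialisation and mask)
#' @param max_iter,tol convergence controls: stop when the relative loss
#'   change falls below `tol` (1e-6) or after `max_iter` (200) iterations
#' @return an `ancestry_fit` list: `Q`, `F`, `alpha`, `cross_entropy`,
#'   `loss`, `iterations`, `K`, `seed`.
#' @export
fit_snmf <- function(x, K, alpha = 10, mask_fraction = 0.05, seed = 1L,
                     max_iter = 200L, tol = 1e-6) {
  g <- x$calls
  n <- nrow(g)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K cannot exceed the number of individuals")
  set.seed(seed)
  Y <- g / 2
  obs <- !is.na(Y)
  mask <- obs & (matrix(stats::runif(length(Y)), n) < mask_fraction)
  train <- obs & !mask
  heldout_g <- g[mask]

  colmean <- colSums(Y * train) / pmax(colSums(train), 1)
  fill <- !train
  Y[fill] <- matrix(colmean, n, ncol(Y), byrow = TRUE)[fill]

  Q <- matrix(stats::runif(n * K), n, K)
  Q <- Q / rowSums(Q)
  loss_old <- Inf
  Fmat <- NULL
  for (it in seq_len(max_iter)) {
    Fmat <- solve(crossprod(Q) + diag(alpha, K), crossprod(Q, Y))
    Fmat[Fmat < 0] <- 0
    Fmat[Fmat > 1] <- 1
    # simplex-constrained row-wise least squares for Q by projected
    # gradient (warm-started); an unconstrained solve + projection is not
    # the constrained optimum and fails on degenerate frequency rows
    FFt <- tcrossprod(Fmat)
    YFt <- Y %*% t(Fmat)
    Q <- project_simplex_rows(YFt %*% solve(FFt + diag(1e-8, K)))
    Lg <- max(eigen(FFt, symmetric = TRUE, only.values = TRUE)$values) + 1e-9
    for (s in 1:3) {
      Q <- project_simplex_rows(Q - (Q %*% FFt - YFt) / Lg)
    }
    P <- Q %*% Fmat
    # refresh held-out / missing cells from the current model
    Y[fill] <- P[fill]
    loss <- sum(((Y - P) * train)^2) + alpha * sum(Fmat^2)
    if (is.finite(loss_old) &&
        abs(loss_old - loss) <= tol * max(loss_old, .Machine$double.eps)) {
      loss_old <- loss
      break
    }
    loss_old <- loss
  }
  P <- Q %*% Fmat
  eps <- 1e-6
  p_held <- pmin(pmax(P[mask], eps), 1 - eps)
  ce <- if (length(heldout_g)) {
    -mean(stats::dbinom(heldout_g, 2L, p_held, log = TRUE))
  } else NA_real_
  structure(
    list(Q = Q, F = Fmat, alpha = alpha, cross_entropy = ce,
         loss = loss_old, iterations = it, K = K, seed = seed,
         mask_fraction = mask_fraction),
    class = "ancestry_fit"
  )
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat(sprintf("ancestry_fit: K = %d, cross-entropy = %.4f (%d iterations)\n",
              x$K, x$cross_entropy, x$iterations))
  invisible(x)
}

# exact Euclidean projection of each row onto the probability simplex
project_simplex_rows <- function(X) {
  .proj_simplex_rows_cpp(X)
}

#' Select the number of ancestral populations by masked cross-entropy
#'
#' Runs `repetitions` seeded [fit_snmf()] fits per K and selects the K
#' whose best (lowest) cross-entropy is smallest. `statistic = "median"`
#' uses the per-K median instead.
#'
#' @param x a [genotype_matrix()]
#' @param K_range integer vector of K values (e.g. `1:13`)
#' @param repetitions fits per K (default 100)
#' @param statistic `"min"` (default) or `"median"` summary per K
#' @param seed base seed; fit r of K uses a seed derived from it
#' @param ... passed to [fit_snmf()]
#' @return list `K_star`, `summary` (named per-K summary statistic),
#'   `cross_entropy` (repetitions x K matrix).
#' @export
choose_K <- function(x, K_range, repetitions = 100L, statistic = c("min", "median"),
                     seed = 1L, ...) {
  statistic <- match.arg(statistic)
  if (!length(K_range)) stop("K_range must be non-empty")
  ce <- matrix(NA_real_, repetitions, length(K_range),
               dimnames = list(NULL, paste0("K", K_range)))
  for (j in seq_along(K_range)) {
    for (r in seq_len(repetitions)) {
      f <- fit_snmf(x, K = K_range[j],
                    seed = (seed * 1009L + 131L * K_range[j] + r) %% 2147483587L,
                    ...)
      ce[r, j] <- f$cross_entropy
    }
  }
  s <- apply(ce, 2, if (statistic == "min") min else stats::median)
  list(K_star = K_range[which.min(s)], summary = s, cross_entropy = ce)
}

#' Principal component scores of a genotype matrix
#'
#' Loci are centred on twice their allele frequency and scaled by the
#' binomial standard deviation `sqrt(2 p (1 - p))`; monomorphic loci are
#' excluded. The top-K truncated decomposition is returned.
#'
#' @param x an imputed [genotype_matrix()] (no missing calls)
#' @param K number of components
#' @return list `scores` (n x K), `loadings` (loci x K), `explained`
#'   (variance per component), `total_variance`, `kept_loci` (indices of
#'   polymorphic loci).
#' @export
pca_scores <- function(x, K) {
  g <- x$calls
  if (anyNA(g)) stop("pca_scores requires an imputed matrix; see impute_nearest_neighbour()")
  p <- colMeans(g) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all loci are monomorphic")
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(g, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  if (K > min(dim(Z))) stop("K exceeds the usable rank")
  s <- svd(Z, nu = K, nv = K)
  n <- nrow(Z)
  list(
    scores = s$u %*% diag(s$d[seq_len(K)], K),
    loadings = s$v,
    explained = s$d[seq_len(K)]^2 / (n - 1),
    total_variance = sum(s$d^2) / (n - 1),
    kept_loci = which(keep)
  )
}
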