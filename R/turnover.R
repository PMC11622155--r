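#' Gradient-forest model of allelic turnover
#'
#' Fits one regression random forest (bootstrap rows, random predictor
#' subset per split, variance-reduction splitting) per candidate locus,
#' with environmental predictors on their natural scales as features and
#' genotypes (0/1/2; or site allele frequencies) as the response. Each
#' split's impurity reduction is logged against its predictor and
#' threshold. Per predictor, split importances are standardised by the
#' density of observed split opportunities (equal-width bins over the
#' predictor's observed range), weighted by the locus out-of-bag R^2, and
#' accumulated along the sorted threshold axis into a monotone cumulative
#' importance ("turnover") curve. Only loci with positive out-of-bag R^2
#' contribute.
#'
#' @param x a [genotype_matrix()] restricted (or restrictable via
#'   `loci`) to candidate loci; must be imputed
#' @param env site x variable environmental table (rows = site names),
#'   natural units
#' @param loci optional locus ids/indices to model (default: all in `x`)
#' @param n_trees trees per locus forest (default 500)
#' @param seed integer seed
#' @param response `"genotype"` (individual-level 0/1/2, default) or
#'   `"frequency"` (per-site alternate allele frequency)
#' @param min_leaf minimum node size (default 5; consider 2 for the
#'   13-row frequency mode)
#' @param mtry predictors tried per split (default `ceiling(p/3)`)
#' @param n_bins equal-width bins for the split-density standardisation
#'   (default 200)
#' @return a `turnover_model`: `predictors`, `importance` (total
#'   aggregated importance per predictor, the curve endpoint),
#'   `mean_importance` (R^2-weighted mean across contributing loci),
#'   `r_squared` (per-locus OOB R^2), `contributing` (ids with R^2 > 0),
#'   `curves` (per predictor: sorted thresholds, standardised
#'   importances), `density` (per predictor binned split-opportunity
#'   density), `n_trees`, `seed`.
#' @export
fit_turnover <- function(x, env, loci = NULL, n_trees = 500L, seed = 1L,
                         response = c("genotype", "frequency"),
                         min_leaf = 5L, mtry = NULL, n_bins = 200L) {
  response <- match.arg(response)
  require_imputed(x, "fit_turnover")
  if (!is.null(loci)) x <- subset_genotypes(x, loci = loci)
  env <- as.data.frame(env)

  if (response == "genotype") {
    X <- as.matrix(env_by_individual(x, env, standardize = FALSE))
    Y <- x$calls
  } else {
    sites <- sort(unique(x$ind_meta$site))
    miss <- setdiff(sites, rownames(env))
    if (length(miss)) stop("no env values for site(s): ",
                           paste(miss, collapse = ", "))
    X <- as.matrix(env[sites, , drop = FALSE])
    Y <- do.call(rbind, lapply(sites, function(s) {
      allele_freq(subset_genotypes(x, individuals = which(x$ind_meta$site == s)))
    }))
  }
  usable <- apply(X, 2, function(v) length(unique(v)) >= 2)
  if (!all(usable)) {
    warning("dropping predictor(s) with fewer than 2 distinct values: ",
            paste(colnames(X)[!usable], collapse = ", "))
    X <- X[, usable, drop = FALSE]
  }
  preds <- colnames(X)
  p <- ncol(X)
  if (p < 1) stop("no usable predictors")
  if (is.null(mtry)) mtry <- ceiling(p / 3)

  n_loci_used <- ncol(Y)
  ids <- x$locus_meta$id
  r2 <- stats::setNames(rep(NA_real_, n_loci_used), ids)
  split_tab <- vector("list", n_loci_used)
  perm_imp <- matrix(0, n_loci_used, p)
  for (l in seq_len(n_loci_used)) {
    y <- as.numeric(Y[, l])
    if (stats::var(y) == 0) {
      r2[l] <- 0
      next
    }
    fit <- .rf_fit_cpp(X, y, as.integer(n_trees), as.integer(mtry),
                       as.integer(min_leaf),
                       as.integer((seed + 7L * l) %% 2147483629L))
    has_oob <- fit$oob_n > 0
    if (!any(has_oob)) {
      r2[l] <- 0
      next
    }
    pred <- fit$oob_sum[has_oob] / fit$oob_n[has_oob]
    mse <- mean((y[has_oob] - pred)^2)
    r2[l] <- 1 - mse / stats::var(y)
    perm_imp[l, ] <- fit$perm_importance
    if (length(fit$var)) {
      split_tab[[l]] <- data.frame(locus = l, var = fit$var,
                                   threshold = fit$threshold,
                                   gain = fit$gain)
    }
  }

  contributing <- which(r2 > 0)
  curves <- stats::setNames(vector("list", p), preds)
  density <- stats::setNames(vector("list", p), preds)
  breaks_of <- lapply(seq_len(p), function(j) {
    rng <- range(X[, j])
    seq(rng[1], rng[2], length.out = n_bins + 1)
  })
  for (j in seq_len(p)) {
    h <- graphics::hist(X[, j], breaks = breaks_of[[j]], plot = FALSE)
    density[[j]] <- h$counts
  }

  # each contributing locus carries total importance R^2_l, partitioned
  # across predictors by OOB permutation importance (so predictors whose
  # splits do not validate out-of-bag earn ~nothing) and distributed
  # along each predictor's threshold axis by the in-bag split gains
  agg <- list()
  for (l in contributing) {
    st <- split_tab[[l]]
    if (is.null(st)) next
    w <- pmax(perm_imp[l, ], 0)
    if (sum(w) > 0) {
      w <- w / sum(w)
    } else {
      gsum <- vapply(seq_len(p), function(j) sum(st$gain[st$var == j]), 0)
      w <- gsum / sum(gsum)
    }
    st$imp <- 0
    for (j in unique(st$var)) {
      sel <- st$var == j
      gv <- st$gain[sel]
      if (sum(gv) > 0) st$imp[sel] <- gv / sum(gv) * w[j] * r2[l]
    }
    agg[[length(agg) + 1]] <- st
  }
  agg <- if (length(agg)) do.call(rbind, agg) else NULL

  importance <- stats::setNames(numeric(p), preds)
  mean_importance <- stats::setNames(numeric(p), preds)
  for (j in seq_len(p)) {
    sj <- if (is.null(agg)) NULL else agg[agg$var == j, , drop = FALSE]
    if (is.null(sj) || nrow(sj) == 0) {
      curves[[j]] <- data.frame(threshold = numeric(0), importance = numeric(0))
      next
    }
    if (sum(sj$imp) <= 0) {
      curves[[j]] <- data.frame(threshold = numeric(0), importance = numeric(0))
      next
    }
    bin <- findInterval(sj$threshold, breaks_of[[j]],
                        rightmost.closed = TRUE, all.inside = TRUE)
    w <- 1 / pmax(density[[j]][bin], 1)
    imp_std <- sj$imp * w
    # rescale so density standardisation redistributes but conserves mass
    imp_std <- imp_std * sum(sj$imp) / sum(imp_std)
    o <- order(sj$threshold)
    thr <- sj$threshold[o]
    iv <- imp_std[o]
    grp <- cumsum(!duplicated(thr))
    curves[[j]] <- data.frame(
      threshold = thr[!duplicated(thr)],
      importance = as.numeric(tapply(iv, grp, sum))
    )
    importance[j] <- sum(iv)
    mean_importance[j] <- sum(iv) / length(contributing)
  }

  structure(
    list(predictors = preds, importance = importance,
         mean_importance = mean_importance, r_squared = r2,
         contributing = ids[contributing], curves = curves,
         density = density, breaks = stats::setNames(breaks_of, preds),
         n_trees = n_trees, seed = seed, response = response,
         x_range = apply(X, 2, range)),
    class = "turnover_model"
  )
}

#' @export
print.turnover_model <- function(x, ...) {
  cat(sprintf(
    "turnover_model: %d/%d loci contributing (OOB R^2 > 0), %d trees/locus\n",
    length(x$contributing), length(x$r_squared), x$n_trees))
  imp <- predictor_importance(x)
  if (nrow(imp)) print(utils::head(imp, 10))
  invisible(x)
}

#' Ranked predictor importance
#'
#' @param model a `turnover_model`
#' @return data.frame `predictor`, `importance` (total aggregated
#'   importance, the cumulative-curve endpoint), descending; ties broken
#'   lexicographically. Empty when no locus contributed.
#' @export
predictor_importance <- function(model) {
  imp <- model$importance[model$importance > 0]
  if (!length(imp)) {
    return(data.frame(predictor = character(0), importance = numeric(0)))
  }
  o <- order(-imp, names(imp))
  data.frame(predictor = names(imp)[o], importance = unname(imp[o]),
             stringsAsFactors = FALSE)
}

#' Evaluate a cumulative importance curve
#'
#' Right-continuous non-decreasing step curve: the value at `x` is the
#' summed standardised importance of all splits with threshold <= `x`.
#'
#' @param model a `turnover_model`
#' @param predictor predictor name
#' @param grid numeric evaluation points
#' @return data.frame `x`, `cumulative_importance`.
#' @export
cumulative_curve <- function(model, predictor, grid) {
  if (!predictor %in% model$predictors) {
    stop("unknown predictor: ", predictor)
  }
  cv <- model$curves[[predictor]]
  cum <- cumsum(cv$importance)
  idx <- findInterval(grid, cv$threshold)
  val <- c(0, cum)[idx + 1]
  data.frame(x = grid, cumulative_importance = val)
}
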