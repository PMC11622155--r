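#' Replicate-based sequencing error rate
#'
#' For each technical-replicate pair, the bitwise distance (proportion of
#' differing genotype calls over jointly non-missing loci). Pairs whose
#' distance exceeds `threshold` (default 0.9%) are flagged as exceeding
#' the sequencing-error budget.
#'
#' @param x a [genotype_matrix()]
#' @param pairs two-column matrix/data.frame of individual ids; defaults to
#'   the pairs recorded in `ind_meta$replicate_of`.
#' @param threshold flag distance above this value
#' @param per_allele see [bitwise_distance()]
#' @return data.frame with one row per pair: `a`, `b`, `n_shared`,
#'   `distance`, `flagged`; attribute `max_distance`.
#' @export
replicate_error_rate <- function(x, pairs = replicate_pairs(x),
                                 threshold = 0.009, per_allele = FALSE) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) stop("no replicate pairs supplied or recorded")
  ia <- match(pairs[, 1], x$ind_meta$id)
  ib <- match(pairs[, 2], x$ind_meta$id)
  if (anyNA(ia) || anyNA(ib)) stop("pair references an unknown individual")
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    ga <- x$calls[ia[k], ]
    gb <- x$calls[ib[k], ]
    both <- !is.na(ga) & !is.na(gb)
    n <- sum(both)
    if (n == 0) {
      stop(sprintf("pair %s/%s shares no non-missing locus",
                   pairs[k, 1], pairs[k, 2]))
    }
    d <- if (per_allele) sum(abs(ga[both] - gb[both])) / 2 / n
         else sum(ga[both] != gb[both]) / n
    data.frame(a = pairs[k, 1], b = pairs[k, 2], n_shared = n, distance = d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$flagged <- out$distance > threshold
  attr(out, "max_distance") <- max(out$distance)
  attr(out, "threshold") <- threshold
  out
}

#' Drop technical replicates (and optionally clones)
#'
#' Replicates are removed after error screening; clonal resamples are kept
#' by default because outlier scans are run on the complete dataset
#' (somatic variation in clonal material can carry adaptive signal).
#'
#' @param x a `genotype_matrix`
#' @param clones also drop individuals marked as clonal copies
#' @return a `genotype_matrix`
#' @export
drop_replicates <- function(x, clones = FALSE) {
  keep <- is.na(x$ind_meta$replicate_of)
  if (clones) keep <- keep & is.na(x$ind_meta$clone_of)
  subset_genotypes(x, individuals = which(keep))
}

#' Sequential SNP quality-control filtering
#'
#' Applies the standard DArT-style filter sequence: locus call rate,
#' individual call rate, locus call rate recomputed over the retained
#' individuals, reproducibility, mean read depth window, and minor allele
#' frequency (computed over non-missing calls of retained individuals).
#'
#' @param x a [genotype_matrix()]
#' @param locus_callrate keep loci with call rate >= this (default 0.67)
#' @param ind_callrate keep individuals with call rate >= this (0.25)
#' @param reproducibility keep loci with reproducibility >= this (0.99)
#' @param depth_min,depth_max keep loci with mean read depth in this
#'   window (2--50)
#' @param maf keep loci with minor allele frequency >= this (0.01)
#' @return list `matrix` (filtered `genotype_matrix`) and `report`
#'   (a `qc_report` data.frame of per-step retained counts).
#' @export
filter_pipeline <- function(x, locus_callrate = 0.67, ind_callrate = 0.25,
                            reproducibility = 0.99, depth_min = 2,
                            depth_max = 50, maf = 0.01) {
  steps <- list()
  note <- function(step, m) {
    steps[[length(steps) + 1]] <<- data.frame(
      step = step, loci = ncol(m$calls), individuals = nrow(m$calls),
      stringsAsFactors = FALSE
    )
    if (ncol(m$calls) == 0 || nrow(m$calls) == 0) {
      stop(sprintf("no data left after step '%s'", step))
    }
    m
  }
  m <- note("input", x)

  cr <- colMeans(!is.na(m$calls))
  m <- note("locus_callrate", subset_genotypes(m, loci = which(cr >= locus_callrate)))

  icr <- rowMeans(!is.na(m$calls))
  m <- note("ind_callrate", subset_genotypes(m, individuals = which(icr >= ind_callrate)))

  # call rates change once individuals are dropped; re-apply the locus rule
  cr2 <- colMeans(!is.na(m$calls))
  m <- note("locus_callrate_recomputed",
            subset_genotypes(m, loci = which(cr2 >= locus_callrate)))

  m <- note("reproducibility",
            subset_genotypes(m, loci = which(m$locus_meta$reproducibility >= reproducibility)))

  dep <- m$locus_meta$depth
  m <- note("read_depth",
            subset_genotypes(m, loci = which(dep >= depth_min & dep <= depth_max)))

  m <- note("maf", subset_genotypes(m, loci = which(minor_allele_freq(m) >= maf)))

  report <- do.call(rbind, steps)
  attr(report, "thresholds") <- list(
    locus_callrate = locus_callrate, ind_callrate = ind_callrate,
    reproducibility = reproducibility, depth_min = depth_min,
    depth_max = depth_max, maf = maf
  )
  class(report) <- c("qc_report", class(report))
  list(matrix = m, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC report (sequential filters)\n")
  print.data.frame(x)
  invisible(x)
}

#' Nearest-neighbour imputation of missing genotypes
#'
#' Each missing call is replaced by the call of the nearest individual
#' (smallest bitwise distance over jointly non-missing loci) that has a
#' non-missing call at that locus; when the nearest neighbour is itself
#' missing there, the search falls through to the next nearest. Ties are
#' broken by lowest individual index. Non-missing calls are never altered.
#'
#' @param x a [genotype_matrix()]
#' @return a `genotype_matrix` with no missing values.
#' @export
impute_nearest_neighbour <- function(x) {
  g <- x$calls
  if (!anyNA(g)) return(x)
  all_missing <- colSums(!is.na(g)) == 0
  if (any(all_missing)) {
    stop(sprintf("locus %s is missing in every individual",
                 x$locus_meta$id[which(all_missing)[1]]))
  }
  d <- bitwise_distance(x)
  diag(d) <- Inf
  d[is.nan(d)] <- Inf
  n <- nrow(g)
  for (i in seq_len(n)) {
    miss <- which(is.na(g[i, ]))
    if (!length(miss)) next
    ord <- order(d[i, ], seq_len(n))  # ties -> lowest index
    for (j in ord) {
      if (!length(miss)) break
      have <- !is.na(x$calls[j, miss])
      if (any(have)) {
        g[i, miss[have]] <- x$calls[j, miss[have]]
        miss <- miss[!have]
      }
    }
    if (length(miss)) {
      stop("could not impute all loci for individual ", x$ind_meta$id[i])
    }
  }
  genotype_matrix(g, x$ind_meta, x$locus_meta)
}
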