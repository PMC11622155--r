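#' Construct a genotype matrix object
#'
#' The central container of the package: biallelic SNP calls coded
#' 0 (reference homozygote), 1 (heterozygote), 2 (alternate homozygote)
#' with `NA` as the missing sentinel, plus per-individual and per-locus
#' metadata of the kind a DArT-style reduced-representation pipeline
#' reports (call rate, reproducibility, mean read depth).
#'
#' @param calls integer matrix, individuals x loci, values in
#'   `c(0L, 1L, 2L, NA)`. Row names are individual ids, column names locus
#'   ids of the form `"<cloneid>-<pos>-<ref>/<alt>"`.
#' @param ind_meta data.frame with one row per individual: columns `id`,
#'   `site`, and optionally `replicate_of` and `clone_of` (character, `NA`
#'   when the individual is not a technical replicate / clonal resample).
#' @param locus_meta data.frame with one row per locus: columns `id`,
#'   `ref`, `alt`, `call_rate`, `reproducibility`, `depth`. `call_rate` is
#'   recomputed from `calls` so it always equals 1 minus the missing
#'   fraction.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, ind_meta, locus_meta) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  if (nrow(ind_meta) != nrow(calls)) {
    stop("ind_meta must have one row per individual")
  }
  if (nrow(locus_meta) != ncol(calls)) {
    stop("locus_meta must have one row per locus")
  }
  if (anyDuplicated(locus_meta$id)) {
    stop("locus ids must be unique")
  }
  if (is.null(ind_meta$replicate_of)) ind_meta$replicate_of <- NA_character_
  if (is.null(ind_meta$clone_of)) ind_meta$clone_of <- NA_character_
  rownames(calls) <- ind_meta$id
  colnames(calls) <- locus_meta$id
  locus_meta$call_rate <- colMeans(!is.na(calls))
  rownames(ind_meta) <- NULL
  rownames(locus_meta) <- NULL
  structure(
    list(calls = calls, ind_meta = ind_meta, locus_meta = locus_meta),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d loci, %.1f%% missing, %d sites\n",
    nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls)),
    length(unique(x$ind_meta$site))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of individuals / loci
#' @param x a `genotype_matrix`
#' @return integer count.
#' @export
n_individuals <- function(x) nrow(x$calls)

#' @rdname n_individuals
#' @export
n_loci <- function(x) ncol(x$calls)

#' Subset a genotype matrix
#'
#' Keeps metadata in step with the call matrix.
#'
#' @param x a `genotype_matrix`
#' @param individuals,loci logical, integer or character index vectors;
#'   `NULL` keeps everything.
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(x, individuals = NULL, loci = NULL) {
  ii <- if (is.null(individuals)) seq_len(nrow(x$calls)) else individuals
  jj <- if (is.null(loci)) seq_len(ncol(x$calls)) else loci
  if (is.character(ii)) ii <- match(ii, x$ind_meta$id)
  if (is.character(jj)) jj <- match(jj, x$locus_meta$id)
  genotype_matrix(
    x$calls[ii, jj, drop = FALSE],
    x$ind_meta[ii, , drop = FALSE],
    x$locus_meta[jj, , drop = FALSE]
  )
}

#' Pairwise bitwise distance between individuals
#'
#' Proportion of differing genotype calls over jointly non-missing loci,
#' the distance used both for technical-replicate error screening and
#' nearest-neighbour imputation. With `per_allele = TRUE` a heterozygote vs
#' homozygote difference counts half (per-allele rather than
#' genotype-state counting).
#'
#' @param x a `genotype_matrix`
#' @param per_allele logical; count allele differences (0/1/2 scale halved)
#'   instead of genotype-state differences.
#' @return a symmetric matrix of distances; `NaN` where two individuals
#'   share no non-missing locus.
#' @export
bitwise_distance <- function(x, per_allele = FALSE) {
  g <- x$calls
  obs <- !is.na(g)
  mode(obs) <- "numeric"
  shared <- tcrossprod(obs)
  if (per_allele) {
    gz <- g
    gz[is.na(gz)] <- 0L
    gz <- gz / 2
    # |gi - gj| summed over shared loci, via the identity built from
    # per-state indicators (3 states -> exact)
    d <- matrix(0, nrow(g), nrow(g))
    for (a in 0:2) for (b in 0:2) {
      if (a == b) next
      A <- (g == a) & obs
      B <- (g == b) & obs
      mode(A) <- "numeric"; mode(B) <- "numeric"
      d <- d + abs(a - b) / 2 * tcrossprod(A, B)
    }
    diff <- d
  } else {
    eq <- matrix(0, nrow(g), nrow(g))
    for (a in 0:2) {
      A <- (g == a) & obs
      mode(A) <- "numeric"
      eq <- eq + tcrossprod(A)
    }
    diff <- shared - eq
  }
  out <- diff / shared
  dimnames(out) <- list(x$ind_meta$id, x$ind_meta$id)
  out
}

#' Per-locus alternate allele frequencies
#'
#' @param x a `genotype_matrix`
#' @return numeric vector over loci, computed over non-missing calls.
#' @export
allele_freq <- function(x) {
  colMeans(x$calls, na.rm = TRUE) / 2
}

#' Minor allele frequency per locus
#' @param x a `genotype_matrix`
#' @return numeric vector over loci.
#' @export
minor_allele_freq <- function(x) {
  p <- allele_freq(x)
  pmin(p, 1 - p)
}

#' Compose DArT-style locus ids
#' @param cloneid,pos,ref,alt vectors recycled to common length
#' @return character vector `"<cloneid>-<pos>-<ref>/<alt>"`.
#' @export
make_locus_id <- function(cloneid, pos, ref, alt) {
  sprintf("%s-%s-%s/%s", cloneid, pos, ref, alt)
}
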