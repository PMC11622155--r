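#' Generate admixed genotype data with known truth
#'
#' Draws deme allele frequencies around shared ancestral frequencies using
#' the Balding--Nichols beta parameterisation
#' `p_i ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` so a single `fst` knob controls
#' differentiation, then draws diploid calls `Binomial(2, p_i)` per
#' individual per locus. Defaults mirror a 13-estuary survey design:
#' thirteen demes of 26 individuals, 3000 loci, F_ST = 0.10.
#'
#' Each locus column is drawn from its own seeded stream (derived from
#' `seed` and the locus index) so that [plant_env_effects()] can re-draw
#' individual loci reproducibly.
#'
#' @param n_pops number of demes (>= 1)
#' @param n_per_pop individuals per deme (scalar or length `n_pops`)
#' @param n_loci number of biallelic loci
#' @param fst target differentiation in `[0, 1)`; 0 gives panmixia
#' @param seed integer seed
#' @param site_names optional deme labels (default `pop01`, ...)
#' @param maf_range range of ancestral allele frequencies (uniform draw);
#'   wide enough that MAF filters have work to do.
#'
#' @return list with elements `matrix` (a [genotype_matrix()]) and `truth`
#'   (a `synthetic_truth` list: `k_true`, `fst`, `adaptive_loci` (empty
#'   until [plant_env_effects()]), `beta`, `seed`, `ancestral_freq`,
#'   `deme_freq` (n_pops x n_loci), `deme_of` (deme index per individual)).
#' @export
gen_admixed_genotypes <- function(n_pops = 13L, n_per_pop = 26L,
                                  n_loci = 3000L, fst = 0.10, seed = 1L,
                                  site_names = NULL,
                                  maf_range = c(0.05, 0.95)) {
  if (n_pops < 1 || any(n_per_pop < 1) || n_loci < 1) {
    stop("n_pops, n_per_pop and n_loci must be positive")
  }
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (length(n_per_pop) == 1) n_per_pop <- rep(n_per_pop, n_pops)
  if (is.null(site_names)) site_names <- sprintf("pop%02d", seq_len(n_pops))

  set.seed(seed)
  p_anc <- stats::runif(n_loci, maf_range[1], maf_range[2])
  if (fst > 0) {
    a <- p_anc * (1 - fst) / fst
    b <- (1 - p_anc) * (1 - fst) / fst
    deme_freq <- matrix(stats::rbeta(n_pops * n_loci, rep(a, each = n_pops),
                                     rep(b, each = n_pops)),
                        nrow = n_pops, ncol = n_loci)
  } else {
    deme_freq <- matrix(rep(p_anc, each = n_pops), nrow = n_pops)
  }

  deme_of <- rep(seq_len(n_pops), times = n_per_pop)
  n_ind <- length(deme_of)
  calls <- matrix(NA_integer_, n_ind, n_loci)
  for (l in seq_len(n_loci)) {
    set.seed(locus_seed(seed, l))
    calls[, l] <- stats::rbinom(n_ind, 2L, deme_freq[deme_of, l])
  }

  alleles <- draw_alleles(seed, n_loci)
  locus_meta <- data.frame(
    id = make_locus_id(100000000L + seq_len(n_loci), alleles$pos,
                       alleles$ref, alleles$alt),
    ref = alleles$ref, alt = alleles$alt,
    call_rate = 1, reproducibility = alleles$repro, depth = alleles$depth,
    stringsAsFactors = FALSE
  )
  ind_meta <- data.frame(
    id = sprintf("%s_%03d", site_names[deme_of], stats::ave(deme_of, deme_of,
                                                            FUN = seq_along)),
    site = site_names[deme_of],
    stringsAsFactors = FALSE
  )
  truth <- structure(
    list(k_true = n_pops, fst = fst, adaptive_loci = integer(0),
         beta = numeric(0), seed = seed, ancestral_freq = p_anc,
         deme_freq = deme_freq, deme_of = deme_of,
         site_names = site_names),
    class = "synthetic_truth"
  )
  list(matrix = genotype_matrix(calls, ind_meta, locus_meta), truth = truth)
}

# per-locus RNG seed kept below 2^31
locus_seed <- function(seed, l) {
  (as.integer(seed) %% 1000003L) * 2011L + 7L * as.integer(l) %% 1999993L
}

# technical locus metadata: reproducibility near 1 with a thin lower tail,
# mean read depth log-normal around ~7x
draw_alleles <- function(seed, n_loci) {
  set.seed(locus_seed(seed, 0L) + 1L)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_loci, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  list(
    pos = sample(5:69, n_loci, replace = TRUE),
    ref = ref, alt = unname(alt),
    repro = pmin(1, 1 - stats::rexp(n_loci, rate = 400)),
    depth = stats::rlnorm(n_loci, meanlog = log(7), sdlog = 0.45)
  )
}

#' Plant environmental effects at chosen loci
#'
#' Creates the structure a genotype--environment scan should detect: at
#' each adaptive locus the deme allele frequency is shifted on the logit
#' scale by `beta * z(env)` where `z(env)` is the standardised deme-level
#' environmental covariate, and those locus columns are re-drawn. With
#' `beta = 0` the re-draw reproduces the input matrix exactly (same
#' per-locus seeds).
#'
#' @param mat a [genotype_matrix()] from [gen_admixed_genotypes()]
#' @param truth the matching `synthetic_truth`
#' @param env_values one environmental value per deme
#' @param adaptive_loci locus indices to make adaptive
#' @param beta effect on logit allele frequency per SD of env (scalar or
#'   per-locus)
#' @param seed optional; defaults to the generator seed so the same stream
#'   is reused
#' @return list `matrix`, `truth` with `adaptive_loci`, `beta` and
#'   `deme_freq` updated.
#' @export
plant_env_effects <- function(mat, truth, env_values, adaptive_loci,
                              beta, seed = truth$seed) {
  n_pops <- truth$k_true
  if (length(env_values) != n_pops) {
    stop("need one env value per deme")
  }
  if (any(adaptive_loci < 1 | adaptive_loci > ncol(mat$calls))) {
    stop("adaptive_loci out of range")
  }
  beta <- rep_len(beta, length(adaptive_loci))
  # population-SD standardisation so two demes at +/-e give z = +/-1
  z <- env_values - mean(env_values)
  z <- z / sqrt(mean(z^2))
  calls <- mat$calls
  deme_freq <- truth$deme_freq
  for (k in seq_along(adaptive_loci)) {
    l <- adaptive_loci[k]
    p <- truth$deme_freq[, l]
    p <- stats::plogis(stats::qlogis(p) + beta[k] * z)
    deme_freq[, l] <- p
    set.seed(locus_seed(seed, l))
    calls[, l] <- stats::rbinom(nrow(calls), 2L, p[truth$deme_of])
  }
  truth$adaptive_loci <- as.integer(adaptive_loci)
  truth$beta <- beta
  truth$deme_freq <- deme_freq
  truth$env_values <- env_values
  list(matrix = genotype_matrix(calls, mat$ind_meta, mat$locus_meta),
       truth = truth)
}

#' Degrade a clean genotype matrix
#'
#' Emulates the blemishes of real reduced-representation data: entries set
#' missing independently at `missing_rate`; technical-replicate pairs
#' (copied individuals whose calls flip to a different valid call with
#' probability `replicate_error`); clonal resamples (exact copies). Locus
#' call-rate metadata is recomputed.
#'
#' @param mat a [genotype_matrix()]
#' @param missing_rate per-entry missingness probability in `[0, 1]`
#' @param replicate_pairs number of technical replicate pairs to append
#' @param replicate_error per-call flip probability for replicates
#' @param clone_pairs number of exact clonal copies to append
#' @param seed integer seed
#' @return a `genotype_matrix` with appended replicate/clone individuals
#'   (marked in `ind_meta$replicate_of` / `ind_meta$clone_of`).
#' @export
degrade <- function(mat, missing_rate = 0.2, replicate_pairs = 6L,
                    replicate_error = 0.002, clone_pairs = 0L, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            replicate_error >= 0, replicate_error <= 1)
  set.seed(seed + 57L)
  calls <- mat$calls
  ind_meta <- mat$ind_meta
  n <- nrow(calls)

  pick <- sample(n, replicate_pairs + clone_pairs)
  rep_src <- pick[seq_len(replicate_pairs)]
  clone_src <- pick[replicate_pairs + seq_len(clone_pairs)]

  add_rows <- function(src, suffix, err, slot) {
    for (i in src) {
      row <- calls[i, ]
      if (err > 0) {
        flip <- which(stats::runif(length(row)) < err & !is.na(row))
        if (length(flip)) {
          row[flip] <- vapply(row[flip],
                              function(g) sample(setdiff(0:2, g), 1L), 0L)
        }
      }
      meta <- ind_meta[1, ]
      meta$id <- paste0(mat$ind_meta$id[i], suffix)
      meta$site <- mat$ind_meta$site[i]
      meta$replicate_of <- NA_character_
      meta$clone_of <- NA_character_
      meta[[slot]] <- mat$ind_meta$id[i]
      calls <<- rbind(calls, row)
      ind_meta <<- rbind(ind_meta, meta)
    }
  }
  add_rows(rep_src, "_rep", replicate_error, "replicate_of")
  add_rows(clone_src, "_clone", 0, "clone_of")

  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(calls)) < missing_rate,
                   nrow(calls), ncol(calls))
    calls[drop] <- NA_integer_
  }
  genotype_matrix(calls, ind_meta, mat$locus_meta)
}

#' Technical replicate pairs of a genotype matrix
#'
#' @param x a `genotype_matrix`
#' @return two-column matrix of individual ids (original, replicate).
#' @export
replicate_pairs <- function(x) {
  i <- which(!is.na(x$ind_meta$replicate_of))
  cbind(original = x$ind_meta$replicate_of[i], replicate = x$ind_meta$id[i])
}

#' Environmental summaries for 13 NSW Posidonia australis meadows
#'
#' The canonical 13 meadow x 9 variable table of warm-season environmental
#' summaries (AvTemp, MaxTemp, TempRange in degrees C; pHRange, MinpH in pH
#' units; MaxSal, AvSal in PSU; TurbRange, MinTurb in NTU) used throughout
#' the package's examples and tests, shipped as a plain-CSV fixture.
#'
#' @return data.frame with row names = meadow names and 9 numeric columns.
#' @export
load_meadow_env <- function() {
  path <- system.file("extdata", "nsw_meadow_env.csv",
                      package = "seagrassGEA", mustWork = TRUE)
  read_env_csv(path)
}
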