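# Shared test fixtures and independent oracles, all built in code.

# quick genotype_matrix from a plain matrix
make_gm <- function(calls, sites = rep("siteA", nrow(calls)),
                    depth = 10, repro = 1) {
  n <- nrow(calls)
  L <- ncol(calls)
  genotype_matrix(
    calls,
    ind_meta = data.frame(id = sprintf("ind%02d", seq_len(n)), site = sites,
                          stringsAsFactors = FALSE),
    locus_meta = data.frame(
      id = make_locus_id(seq_len(L) + 100L, 25L, "G", "C"),
      ref = "G", alt = "C", call_rate = 1,
      reproducibility = rep_len(repro, L), depth = rep_len(depth, L),
      stringsAsFactors = FALSE)
  )
}

# Weir & Cockerham (1984) multilocus theta, written directly from the
# variance-components definitions as an oracle independent of the
# generator and of any package code path
wc_fst <- function(calls, pops) {
  pops <- as.factor(pops)
  r <- nlevels(pops)
  a_sum <- b_sum <- c_sum <- 0
  for (l in seq_len(ncol(calls))) {
    g <- calls[, l]
    ok <- !is.na(g)
    ni <- tapply(ok, pops, sum)
    if (any(ni < 2)) next
    pi <- tapply(g[ok], pops[ok], mean) / 2
    hi <- tapply(g[ok] == 1, pops[ok], mean)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    b_sum <- b_sum + b
    c_sum <- c_sum + cc
  }
  a_sum / (a_sum + b_sum + c_sum)
}

meadow_env <- load_meadow_env()

published_registry <- utils::read.csv(
  system.file("extdata", "nsw_donor_registry_published.csv",
              package = "seagrassGEA"),
  stringsAsFactors = FALSE
)
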