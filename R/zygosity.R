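#' Per-meadow zygosity proportions at candidate loci
#'
#' For each meadow x locus cell, the proportions of reference homozygotes
#' (call 0), heterozygotes (1) and alternate homozygotes (2) over
#' non-missing calls — the data behind stacked-histogram maps of adaptive
#' allele distributions. "Reference" is a labelling convention (the
#' designated reference allele of the locus record), not an inference
#' about ancestry.
#'
#' @param x a [genotype_matrix()]
#' @param candidate_loci locus ids or indices
#' @param site_labels per-individual meadow labels (default
#'   `ind_meta$site`)
#' @return data.frame (class `zygosity_profile`): `meadow`, `locus`,
#'   `n` (non-missing calls), `p_ref_hom`, `p_het`, `p_alt_hom`,
#'   `flagged` (TRUE when a cell has zero non-missing calls and the
#'   proportions are undefined).
#' @export
zygosity_proportions <- function(x, candidate_loci,
                                 site_labels = x$ind_meta$site) {
  if (is.character(candidate_loci)) {
    jj <- match(candidate_loci, x$locus_meta$id)
    if (anyNA(jj)) {
      stop("candidate loci not in matrix: ",
           paste(candidate_loci[is.na(jj)], collapse = ", "))
    }
  } else {
    jj <- candidate_loci
  }
  meadows <- unique(site_labels)
  rows <- list()
  for (m in meadows) {
    sub <- x$calls[site_labels == m, jj, drop = FALSE]
    n <- colSums(!is.na(sub))
    for (k in seq_along(jj)) {
      g <- sub[, k]
      if (n[k] == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          meadow = m, locus = x$locus_meta$id[jj[k]], n = 0L,
          p_ref_hom = NA_real_, p_het = NA_real_, p_alt_hom = NA_real_,
          flagged = TRUE, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          meadow = m, locus = x$locus_meta$id[jj[k]], n = n[k],
          p_ref_hom = sum(g == 0, na.rm = TRUE) / n[k],
          p_het = sum(g == 1, na.rm = TRUE) / n[k],
          p_alt_hom = sum(g == 2, na.rm = TRUE) / n[k],
          flagged = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("zygosity_profile", class(out))
  out
}

#' Order zygosity profiles along an environmental gradient
#'
#' Sorts meadows by the chosen variable's value (ties: stable
#' alphabetical order by meadow name) and annotates every profile row
#' with its gradient position so the stacked histograms can be aligned
#' with a turnover curve.
#'
#' @param profiles output of [zygosity_proportions()]
#' @param env site x variable environmental table
#' @param variable variable name present in `env`
#' @return the profiles with a `gradient_value` column, meadows ordered
#'   by the gradient; attribute `meadow_order`.
#' @export
order_by_gradient <- function(profiles, env, variable) {
  env <- as.data.frame(env)
  if (!variable %in% colnames(env)) {
    stop("variable not in env table: ", variable)
  }
  unknown <- setdiff(unique(profiles$meadow), rownames(env))
  if (length(unknown)) {
    stop("unknown meadow(s): ", paste(unknown, collapse = ", "))
  }
  meadows <- intersect(rownames(env), unique(profiles$meadow))
  vals <- env[meadows, variable]
  ord <- meadows[order(vals, meadows)]
  profiles$gradient_value <- env[profiles$meadow, variable]
  out <- profiles[order(match(profiles$meadow, ord)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "meadow_order") <- ord
  attr(out, "variable") <- variable
  out
}

#' Export zygosity profiles as TSV
#'
#' Columns meadow, locus, gradient value and the three zygosity
#' proportions — the data behind a stacked-histogram figure.
#'
#' @param profiles output of [order_by_gradient()]
#' @param file path
#' @return `file`, invisibly.
#' @export
write_zygosity_tsv <- function(profiles, file) {
  cols <- intersect(c("meadow", "locus", "gradient_value", "p_ref_hom",
                      "p_het", "p_alt_hom"), colnames(profiles))
  utils::write.table(profiles[, cols], file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
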