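#' Write genotypes to VCF
#'
#' Minimal diploid VCF: one contig, positions are 1-based locus indices,
#' GT-only FORMAT, missing calls encoded `./.`.
#'
#' @param x a [genotype_matrix()]
#' @param file output path; `.vcf.gz` is appended gz-compressed by vcfR.
#' @return `file`, invisibly.
#' @export
write_vcf <- function(x, file) {
  g <- t(x$calls)
  gt_str <- matrix(c("0/0", "0/1", "1/1", "./.")[ifelse(is.na(g), 4L, g + 1L)],
                   nrow(g), ncol(g))
  fix <- cbind(
    CHROM = "1", POS = as.character(seq_len(ncol(x$calls))),
    ID = x$locus_meta$id, REF = x$locus_meta$ref, ALT = x$locus_meta$alt,
    QUAL = ".", FILTER = "PASS", INFO = "."
  )
  gt <- cbind(FORMAT = "GT", gt_str)
  colnames(gt) <- c("FORMAT", x$ind_meta$id)
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = c("##fileformat=VCFv4.2", "##contig=<ID=1>"),
                    fix = fix, gt = gt)
  vcfR::write.vcf(v, file)
  invisible(file)
}

#' Read genotypes from VCF
#'
#' Inverse of [write_vcf()]. Site labels and technical metadata are not
#' part of VCF; they can be supplied, otherwise every individual gets site
#' `"unknown"` and loci get call-rate-only metadata.
#'
#' @param file VCF path (optionally gzipped)
#' @param ind_meta,locus_meta optional metadata data.frames (see
#'   [genotype_matrix()]); ids must match the file.
#' @return a `genotype_matrix`
#' @export
read_vcf <- function(file, ind_meta = NULL, locus_meta = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  calls <- t(code)
  fix <- vcfR::getFIX(v)
  if (is.null(locus_meta)) {
    locus_meta <- data.frame(
      id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
      call_rate = 1, reproducibility = 1, depth = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(ind_meta)) {
    ind_meta <- data.frame(id = colnames(gt), site = "unknown",
                           stringsAsFactors = FALSE)
  }
  genotype_matrix(calls, ind_meta, locus_meta)
}

#' Write / read genotype CSV
#'
#' Individuals as rows, loci as columns, a header row of locus ids, a
#' leading `id` and `site` column, missing calls written `NA`.
#'
#' @param x a `genotype_matrix`
#' @param file path
#' @return `file` (writer, invisibly) or a `genotype_matrix` (reader).
#' @export
write_genotype_csv <- function(x, file) {
  df <- data.frame(id = x$ind_meta$id, site = x$ind_meta$site,
                   x$calls, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, na = "NA")
  invisible(file)
}

#' @rdname write_genotype_csv
#' @param locus_meta optional locus metadata; reconstructed from ids when
#'   absent.
#' @export
read_genotype_csv <- function(file, locus_meta = NULL) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  calls <- as.matrix(df[, -(1:2), drop = FALSE])
  ids <- colnames(calls)
  if (is.null(locus_meta)) {
    parts <- regmatches(ids, regexec("^(.*)-(\\d+)-([ACGT])/([ACGT])$", ids))
    ref <- vapply(parts, function(p) if (length(p) == 5) p[4] else "A", "")
    alt <- vapply(parts, function(p) if (length(p) == 5) p[5] else "C", "")
    locus_meta <- data.frame(id = ids, ref = ref, alt = alt, call_rate = 1,
                             reproducibility = 1, depth = NA_real_,
                             stringsAsFactors = FALSE)
  }
  genotype_matrix(calls,
                  data.frame(id = df$id, site = df$site,
                             stringsAsFactors = FALSE),
                  locus_meta)
}

#' Write / read a site-by-variable environmental table
#'
#' Sites as rows (first column `meadow`), variables as numeric columns.
#'
#' @param env data.frame with row names = site names
#' @param file path
#' @return `file` (writer, invisibly) or a data.frame with site row names
#'   (reader).
#' @export
write_env_csv <- function(env, file) {
  df <- data.frame(meadow = rownames(env), env, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_env_csv
#' @export
read_env_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  out <- df[, -1, drop = FALSE]
  rownames(out) <- df[[1]]
  out
}
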