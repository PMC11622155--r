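#' Project an environmental value forward at a constant annual rate
#'
#' `projected = current + rate * (target_year - base_year)`. Display
#' rounding is half-up to 2 decimals; the unrounded value is what
#' downstream matching uses.
#'
#' @param current current value
#' @param rate change per year (same units)
#' @param base_year,target_year integers, `target_year >= base_year`
#' @return unrounded projected value (vectorised); see [round_half_up()]
#'   for display.
#' @export
project <- function(current, rate, base_year, target_year) {
  if (any(target_year < base_year)) stop("target_year must be >= base_year")
  current + rate * (target_year - base_year)
}

#' Round half-up to a fixed number of decimals
#'
#' Display rounding for projections (base R `round` rounds half to even).
#'
#' @param x numeric
#' @param digits decimals (default 2)
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-9) / scale
}

#' Find a pre-adapted donor meadow for a projected condition
#'
#' Rule `"min_above"` (default): among meadows whose current value is at
#' least the target, return the one with the smallest current value
#' (ties: alphabetical); `NA` when none qualifies. Rule `"nearest"`:
#' the meadow minimising `|current - target|`, ties preferring the
#' above-target meadow. Comparisons use a small tolerance (default
#' 0.005) so values that agree at the printed 2-decimal precision are
#' treated as satisfying `>=`.
#'
#' @param env site x variable environmental table
#' @param variable variable name
#' @param target_value projected value to meet or exceed
#' @param rule `"min_above"` or `"nearest"`
#' @param exclude meadow name(s) never returned (e.g. the recipient
#'   itself)
#' @param tol comparison tolerance (default 0.005)
#' @return donor meadow name, or `NA_character_`.
#' @export
find_donor <- function(env, variable, target_value,
                       rule = c("min_above", "nearest"), exclude = NULL,
                       tol = 0.005) {
  rule <- match.arg(rule)
  env <- as.data.frame(env)
  if (!variable %in% colnames(env)) stop("unknown variable: ", variable)
  meadows <- setdiff(rownames(env), exclude)
  if (!length(meadows)) return(NA_character_)
  cur <- env[meadows, variable]
  o <- order(cur, meadows)
  meadows <- meadows[o]
  cur <- cur[o]
  if (rule == "min_above") {
    ok <- cur >= target_value - tol
    if (!any(ok)) return(NA_character_)
    meadows[which(ok)[1]]
  } else {
    d <- abs(cur - target_value)
    best <- min(d)
    cand <- which(d <= best + tol / 10)
    above <- cand[cur[cand] >= target_value - tol]
    if (length(above)) cand <- above
    meadows[cand[1]]
  }
}

#' Build the climate-projection donor registry
#'
#' For every meadow x variable x horizon cell: project the current value
#' forward at the variable's annual rate from `base_year` and match a
#' donor meadow whose *current* conditions already meet or exceed the
#' projection (climate-adjusted provenancing). Self-matching is
#' disallowed by default.
#'
#' @param env site x variable environmental table (rows = meadows)
#' @param variables variables to project (default AvTemp and MaxTemp)
#' @param rates named per-variable change per year (default +0.2 for
#'   both temperatures)
#' @param base_year projection base (default 2024)
#' @param horizons target years (default 2030, 2040, 2050)
#' @param rule donor matching rule, see [find_donor()]
#' @param allow_self allow recipient == donor
#' @param tol comparison tolerance (default 0.005)
#' @return a `registry_table` data.frame: `meadow`, `variable`,
#'   `horizon`, `current`, `rate`, `projected` (unrounded),
#'   `projected_2dp`, `donor` (`NA` when no meadow qualifies).
#' @export
build_registry <- function(env,
                           variables = c("AvTemp", "MaxTemp"),
                           rates = c(AvTemp = 0.2, MaxTemp = 0.2),
                           base_year = 2024,
                           horizons = c(2030, 2040, 2050),
                           rule = c("min_above", "nearest"),
                           allow_self = FALSE, tol = 0.005) {
  rule <- match.arg(rule)
  env <- as.data.frame(env)
  if (any(horizons < base_year)) stop("horizons must not precede base_year")
  if (!all(variables %in% names(rates))) {
    stop("rates must be given for every projected variable")
  }
  rows <- list()
  for (v in variables) {
    for (m in rownames(env)) {
      cur <- env[m, v]
      for (h in horizons) {
        proj <- project(cur, rates[[v]], base_year, h)
        donor <- find_donor(env, v, proj, rule = rule,
                            exclude = if (allow_self) NULL else m,
                            tol = tol)
        rows[[length(rows) + 1]] <- data.frame(
          meadow = m, variable = v, horizon = h, current = cur,
          rate = rates[[v]], projected = proj,
          projected_2dp = round_half_up(proj), donor = donor,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rule") <- rule
  attr(out, "base_year") <- base_year
  attr(out, "tol") <- tol
  class(out) <- c("registry_table", class(out))
  out
}

#' Compare a computed registry with a published one
#'
#' Cell-by-cell comparison of projections and donors against a reference
#' table (columns `meadow`, `variable`, `horizon`, `projected`, `donor`,
#' donor `NA` meaning no pre-adapted material). Cells are classified as
#' `agree`, `valid_not_emitted` (the reference donor satisfies the `>=`
#' rule but is not the one the matching rule selects) or
#' `violates_rule` (the reference donor's current value falls short of
#' the projected target — no rule choice can reproduce it).
#'
#' @param registry a `registry_table` from [build_registry()]
#' @param published reference data.frame
#' @param env the environmental table the registry was built from
#' @param tol comparison tolerance (default 0.005)
#' @return list: `cells` (merged table with `match_projected` and
#'   `classification`), `n_agree`, `disagreements` (rows not classified
#'   `agree`).
#' @export
compare_registry <- function(registry, published, env, tol = 0.005) {
  env <- as.data.frame(env)
  merged <- merge(registry, published,
                  by = c("meadow", "variable", "horizon"),
                  suffixes = c("", "_published"))
  if (nrow(merged) != nrow(registry)) {
    warning("published table does not cover every registry cell")
  }
  merged$match_projected <-
    abs(merged$projected_2dp - merged$projected_published) <= tol
  cls <- character(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    ours <- merged$donor[i]
    ref <- merged$donor_published[i]
    if (identical(is.na(ours), is.na(ref)) &&
        (is.na(ours) || ours == ref)) {
      cls[i] <- "agree"
    } else if (is.na(ref)) {
      cls[i] <- "published_na_but_donor_exists"
    } else if (!is.na(ref) &&
               env[ref, merged$variable[i]] >= merged$projected[i] - tol) {
      cls[i] <- "valid_not_emitted"
    } else {
      cls[i] <- "violates_rule"
    }
  }
  merged$classification <- cls
  list(cells = merged, n_agree = sum(cls == "agree"),
       disagreements = merged[cls != "agree", , drop = FALSE])
}

#' @export
print.registry_table <- function(x, ...) {
  cat(sprintf(
    "registry_table: %d cells (%d meadows x %d variables x %d horizons), rule '%s'\n",
    nrow(x), length(unique(x$meadow)), length(unique(x$variable)),
    length(unique(x$horizon)), attr(x, "rule")))
  cat(sprintf("  donors found for %d cells, none for %d\n",
              sum(!is.na(x$donor)), sum(is.na(x$donor))))
  invisible(x)
}
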