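#' Diatom valve-count matrix
#'
#' Samples (dated) by taxa matrix of non-negative integer valve counts.
#' Row totals are conventionally 300 valves per sample; the print method
#' reports departures from that convention.
#'
#' @param dates Sample dates (`Date` or ISO-8601 character).
#' @param counts Integer matrix or data frame, one column per taxon code,
#'   one row per sample.
#' @return Object of class `"count_matrix"`: list with `dates`, `taxa` and
#'   the integer `counts` matrix (rownames = ISO dates).
#' @export
count_matrix <- function(dates, counts) {
  dates <- as.Date(dates)
  counts <- as.matrix(counts)
  if (anyNA(dates)) stop("sample dates must parse as dates")
  if (nrow(counts) != length(dates))
    stop("`counts` must have one row per sample date")
  if (is.null(colnames(counts))) stop("`counts` needs taxon codes as column names")
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) <= 0))
    stop("empty sample (zero total count) at ",
         paste(format(dates[rowSums(counts) <= 0]), collapse = ", "))
  rownames(counts) <- format(dates)
  structure(list(dates = dates, taxa = colnames(counts), counts = counts),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tot <- rowSums(x$counts)
  cat(sprintf("Valve-count matrix: %d samples x %d taxa (%s to %s)\n",
              nrow(x$counts), ncol(x$counts), min(x$dates), max(x$dates)))
  off <- sum(tot != 300)
  cat(sprintf("  row totals: %s (300-valve convention%s)\n",
              paste(range(tot), collapse = "-"),
              if (off) sprintf("; %d sample(s) differ", off) else ""))
  invisible(x)
}

#' Read a valve-count matrix from CSV
#'
#' First column `date` (ISO-8601), remaining columns taxon codes with
#' integer cells.
#'
#' @param path CSV file path.
#' @return A [count_matrix()].
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  count_matrix(df[[1L]], df[, -1L, drop = FALSE])
}

#' Write a valve-count matrix to CSV
#' @param x A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(x, path) {
  df <- data.frame(date = format(x$dates), x$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Taxon trait table
#'
#' Validates a table of per-taxon nutrient-sensitivity scores `s` in
#' `[1, 5]`, indicator weights `v` in `[1, 3]` and growth-form guilds, the
#' inputs of the weighted-average quality index.
#'
#' @param path CSV with columns `taxon,sensitivity,indicator_weight,guild`.
#' @return Validated data frame.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("taxon", "sensitivity", "indicator_weight", "guild")
  if (!all(req %in% names(df)))
    stop("trait table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$taxon)) stop("taxon codes must be unique")
  if (any(df$sensitivity < 1 | df$sensitivity > 5))
    stop("sensitivity scores must lie in [1, 5]")
  if (any(df$indicator_weight < 1 | df$indicator_weight > 3))
    stop("indicator weights must lie in [1, 3]")
  guilds <- c("low_profile", "high_profile", "motile", "planktic", "unknown")
  if (!all(df$guild %in% guilds))
    stop("guild must be one of: ", paste(guilds, collapse = ", "))
  df
}

#' Bundled synthetic trait table
#'
#' Illustrative sensitivity/weight scores for twelve common river benthic
#' diatom taxa. These are synthetic values for demonstration and testing;
#' they are not the coefficient set of any regulatory tool. Any user table
#' in the same CSV layout can be used instead.
#'
#' @return Trait data frame (see [read_trait_table()]).
#' @export
default_trait_table <- function() {
  read_trait_table(system.file("extdata", "trait_table_synthetic.csv",
                               package = "seasdhr", mustWork = TRUE))
}

#' Relative abundances
#'
#' Converts valve counts to within-sample proportions; each row sums to 1.
#'
#' @param counts A [count_matrix()] or a numeric matrix.
#' @return Proportion matrix of the same shape.
#' @export
relative_abundance <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    bad <- rownames(m)[tot <= 0]
    stop("empty sample (zero total count) at ",
         paste(if (is.null(bad)) which(tot <= 0) else bad, collapse = ", "))
  }
  m / tot
}

#' Dominance ratio of two taxa
#'
#' Per-sample ratio `count_a / count_b`. Samples where taxon `b` was not
#' recorded are undefined: they are returned as `NA`, flagged, and logged
#' with a warning so downstream series can exclude them.
#'
#' @param counts A [count_matrix()].
#' @param taxon_a,taxon_b Taxon codes (columns of the matrix).
#' @return Data frame `date`, `ratio`, `undefined`.
#' @export
dominance_ratio <- function(counts, taxon_a, taxon_b) {
  stopifnot(inherits(counts, "count_matrix"))
  for (tx in c(taxon_a, taxon_b))
    if (!tx %in% counts$taxa) stop("unknown taxon code: ", tx)
  a <- counts$counts[, taxon_a]
  b <- counts$counts[, taxon_b]
  undef <- b == 0
  ratio <- ifelse(undef, NA_real_, a / b)
  if (any(undef))
    warning(sprintf("dominance ratio undefined (zero %s count) for %d sample(s): %s",
                    taxon_b, sum(undef),
                    paste(format(counts$dates[undef]), collapse = ", ")))
  data.frame(date = counts$dates, ratio = ratio, undefined = undef)
}

#' Abundance-weighted mean sensitivity
#'
#' The weighted-average core of trophic-index style metrics:
#' \deqn{WMS = \sum_j a_j s_j v_j / \sum_j a_j v_j}
#' over taxa with trait coverage, where \eqn{a_j} is relative abundance,
#' \eqn{s_j} the sensitivity score and \eqn{v_j} the indicator weight.
#'
#' @param proportions Named numeric vector of one sample's relative
#'   abundances (taxon codes as names).
#' @param traits A trait table (see [read_trait_table()]).
#' @return List with `wms` and `coverage` (fraction of counted valves
#'   belonging to trait-covered taxa).
#' @export
weighted_mean_sensitivity <- function(proportions, traits) {
  if (is.null(names(proportions))) stop("`proportions` must be named by taxon code")
  idx <- match(names(proportions), traits$taxon)
  cov_mask <- !is.na(idx) & proportions > 0
  coverage <- sum(proportions[cov_mask])
  if (coverage <= 0)
    stop("no taxa in this sample are covered by the trait table")
  a <- proportions[cov_mask]
  s <- traits$sensitivity[idx[cov_mask]]
  v <- traits$indicator_weight[idx[cov_mask]]
  list(wms = sum(a * s * v) / sum(a * v), coverage = unname(coverage))
}

#' Index on the 0-100 scale from a weighted mean sensitivity
#'
#' `index = (WMS - 1) * 25`, mapping sensitivity scores in `[1, 5]` onto
#' `[0, 100]` (higher index = more nutrient-tolerant assemblage).
#'
#' @param wms Weighted mean sensitivity value(s).
#' @return Index value(s) on 0-100.
#' @export
index_from_wms <- function(wms) (wms - 1) * 25

#' Ecological Quality Ratio
#'
#' `eqr = (100 - observed) / (100 - expected)`; higher is cleaner. Values
#' above 1 indicate a community better than the reference expectation; the
#' ratio is capped at `cap` (default 1.25) and capped samples are flagged
#' with a warning.
#'
#' @param observed_index Observed index on 0-100.
#' @param expected_index Reference-condition expected index (0-100,
#'   strictly below 100).
#' @param cap Upper cap applied to the ratio.
#' @return Numeric EQR value(s), with attribute `"capped"` (logical).
#' @export
eqr <- function(observed_index, expected_index, cap = 1.25) {
  if (any(observed_index < 0 | observed_index > 100))
    stop("observed index must lie in [0, 100]")
  if (any(expected_index < 0 | expected_index >= 100))
    stop("degenerate reference: expected index must lie in [0, 100)")
  e <- (100 - observed_index) / (100 - expected_index)
  capped <- e > cap
  if (any(capped))
    warning(sprintf("EQR capped at %.3g for %d value(s) above the reference expectation",
                    cap, sum(capped)))
  e <- pmin(e, cap)
  attr(e, "capped") <- capped
  e
}

#' Ecological status band from an EQR
#'
#' Boundaries (high/good 0.8, good/moderate 0.6, moderate/poor 0.4,
#' poor/bad 0.2); a boundary value belongs to the upper class, so an EQR of
#' exactly 0.8 is `high`.
#'
#' @param eqr Non-negative EQR value(s).
#' @return Ordered factor with levels `bad < poor < moderate < good < high`.
#' @export
#' @examples
#' classify_status(c(0.85, 0.8, 0.6, 0.05))
classify_status <- function(eqr) {
  eqr <- as.numeric(eqr)
  if (any(!is.finite(eqr)) || any(eqr < 0))
    stop("EQR values must be finite and >= 0")
  lv <- c("bad", "poor", "moderate", "good", "high")
  cut(eqr, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
      labels = lv, right = FALSE, ordered_result = TRUE)
}

#' EQR series from counts and traits
#'
#' Chains [relative_abundance()] -> [weighted_mean_sensitivity()] ->
#' [index_from_wms()] -> [eqr()] -> [classify_status()] per sample, and
#' emits an [irregular_series()] of EQR values (sample dates converted to
#' decimal years) ready for [asdhr()]. Samples that fail (no trait
#' coverage) are logged with a warning and excluded, never imputed.
#'
#' @param counts A [count_matrix()].
#' @param traits Trait table; defaults to [default_trait_table()].
#' @param expected_index Site reference expected index (scalar, 0-100).
#' @param cap EQR cap, passed to [eqr()].
#' @return List with `table` (per-sample data frame: date, wms, coverage,
#'   index, eqr, capped, status) and `series` (an `irregular_series`).
#' @export
eqr_series <- function(counts, traits = default_trait_table(),
                       expected_index, cap = 1.25) {
  stopifnot(inherits(counts, "count_matrix"))
  props <- relative_abundance(counts)
  n <- nrow(props)
  wms <- coverage <- rep(NA_real_, n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    p_i <- stats::setNames(props[i, ], colnames(props))
    res <- tryCatch(weighted_mean_sensitivity(p_i, traits),
                    error = function(e) NULL)
    if (is.null(res)) {
      ok[i] <- FALSE
      next
    }
    wms[i] <- res$wms
    coverage[i] <- res$coverage
  }
  if (any(!ok))
    warning(sprintf("excluded %d sample(s) with no trait coverage: %s",
                    sum(!ok), paste(format(counts$dates[!ok]), collapse = ", ")))
  if (!any(ok)) stop("no sample could be indexed against the trait table")
  idx <- index_from_wms(wms[ok])
  ev <- withCallingHandlers(eqr(idx, expected_index, cap = cap),
                            warning = function(w) invokeRestart("muffleWarning"))
  capped <- attr(ev, "capped")
  tab <- data.frame(date = counts$dates[ok], wms = wms[ok],
                    coverage = coverage[ok], index = idx,
                    eqr = as.numeric(ev), capped = capped,
                    status = classify_status(as.numeric(ev)))
  if (any(capped))
    warning(sprintf("EQR capped for %d sample(s): %s", sum(capped),
                    paste(format(tab$date[capped]), collapse = ", ")))
  list(table = tab,
       series = irregular_series(decimal_year(tab$date), tab$eqr, "EQR"))
}
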