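# Pearson screen over all marker-probe x miRNA pairs.
#
# The selection rule couples a minimum absolute correlation with a
# two-sided t-test significance level; both are configurable because at a
# given n the |r| cutoff and the alpha cutoff are close but not identical.

#' Screening thresholds for the correlation filter
#'
#' The screen keeps a (probe, miRNA) pair when its Pearson correlation is
#' large enough and/or significant enough, depending on `mode`:
#' `"both"` (the default) requires `|r| >= r_min` AND `p <= alpha`,
#' `"alpha_only"` requires only the p-value condition, `"r_only"` only the
#' magnitude condition.
#'
#' The default `r_min = 0.258` pins the published screening profile. Note
#' that inverting the t transform at n = 57, alpha = 0.05 gives
#' `critical_r(57, 0.05)` ~ 0.261, slightly above 0.258; the two conditions
#' are therefore not redundant and `mode = "both"` applies the conjunction
#' literally.
#'
#' @param alpha Two-sided significance level in (0, 1).
#' @param r_min Minimum absolute Pearson correlation in [0, 1).
#' @param mode `"both"`, `"alpha_only"` or `"r_only"`.
#' @param adjust_gate If `TRUE`, gate significance on the
#'   Benjamini-Hochberg adjusted p instead of the raw p. Default `FALSE`:
#'   the published screen applied no multiplicity correction, so `adj_p` is
#'   reported alongside but does not gate.
#' @return An object of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(alpha = 0.05, r_min = 0.258,
                                mode = c("both", "alpha_only", "r_only"),
                                adjust_gate = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(r_min), length(r_min) == 1L, r_min >= 0, r_min < 1)
  structure(list(alpha = alpha, r_min = r_min, mode = mode,
                 adjust_gate = adjust_gate),
            class = "analysis_thresholds")
}

#' Pearson product-moment correlation of two vectors
#'
#' Pairs where either value is missing are dropped (pairwise-complete). A
#' constant vector has no defined correlation and raises an error rather
#' than passing NaN downstream.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("fewer than 3 complete pairs (", n, "); correlation undefined")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in at least one vector; correlation undefined")
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with
#' `n - 2` degrees of freedom. `|r| = 1` returns an exact 0 carrying
#' attribute `exact = TRUE`.
#'
#' @param r Correlation coefficient in [-1, 1].
#' @param n Pairwise-complete sample count (>= 3).
#' @return Two-sided p-value.
#' @export
correlation_pvalue <- function(r, n) {
  stopifnot(is.numeric(r), is.numeric(n))
  if (any(n < 3)) stop("n must be >= 3")
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  p <- rep(NA_real_, length(r))
  exact <- abs(r) == 1
  p[exact] <- 0
  i <- !exact
  if (any(i)) {
    tt <- r[i] * sqrt(n - 2) / sqrt(1 - r[i]^2)
    p[i] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  if (any(exact)) attr(p, "exact") <- exact
  p
}

#' Smallest |r| significant at a given level
#'
#' Inverts the t transform at the two-sided `alpha` quantile with `n - 2`
#' degrees of freedom: the returned value is the smallest magnitude of a
#' Pearson correlation whose p-value is <= `alpha` at sample size `n`.
#'
#' @param n Sample count (>= 3).
#' @param alpha Two-sided significance level.
#' @return The critical |r|.
#' @export
critical_r <- function(n, alpha = 0.05) {
  stopifnot(n >= 3, alpha > 0, alpha < 1)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}

significance_flag <- function(r, p, adj_p, th) {
  gate_p <- if (isTRUE(th$adjust_gate)) adj_p else p
  pass_p <- !is.na(gate_p) & gate_p <= th$alpha
  pass_r <- !is.na(r) & abs(r) >= th$r_min
  switch(th$mode,
         both = pass_p & pass_r,
         alpha_only = pass_p,
         r_only = pass_r)
}

#' Correlate every marker probe with every miRNA in a matched cohort
#'
#' Computes the full probe x miRNA grid of Pearson correlations with
#' pairwise-complete handling of missing values, the t-transform p-value,
#' Benjamini-Hochberg adjusted p across the grid, and the significance flag
#' under `thresholds`. Pairs with fewer than 3 complete samples are
#' excluded from the result and listed in the `"skipped"` attribute; pairs
#' where either vector is constant are kept as explicit undefined records
#' (`r = NA`, `significant = FALSE`).
#'
#' @param cohort A `matched_cohort` from [match_samples()] or
#'   [simulate_cohort()].
#' @param marker_probes Probe ids to screen (rows of `cohort$mrna`);
#'   default all probes.
#' @param thresholds An [analysis_thresholds()] object.
#' @return A data.frame with one row per (miRNA, probe) pair and columns
#'   `mirna_id`, `probe_id`, `gene_symbol`, `r`, `n`, `t`, `p`, `adj_p`,
#'   `significant`.
#' @export
correlate_pairs <- function(cohort, marker_probes = NULL,
                            thresholds = analysis_thresholds()) {
  stopifnot(inherits(cohort, "matched_cohort"),
            inherits(thresholds, "analysis_thresholds"))
  X <- cohort$mrna$values
  if (is.null(marker_probes)) marker_probes <- rownames(X)
  unknown <- setdiff(marker_probes, rownames(X))
  if (length(unknown))
    stop("unknown probe id(s): ", paste(unknown, collapse = ", "))
  X <- X[marker_probes, , drop = FALSE]
  Y <- cohort$mirna$values
  if (nrow(X) == 0L || nrow(Y) == 0L) {
    out <- data.frame(mirna_id = character(), probe_id = character(),
                      gene_symbol = character(), r = numeric(),
                      n = integer(), t = numeric(), p = numeric(),
                      adj_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- out[, c("mirna_id", "probe_id", "n")]
    return(out)
  }
  # pairwise-complete n for every pair, then r via stats::cor
  okX <- !is.na(X); okY <- !is.na(Y)
  N <- okX %*% t(okY)                              # probes x miRNAs
  R <- suppressWarnings(
    stats::cor(t(X), t(Y), use = "pairwise.complete.obs"))
  long <- expand.grid(probe_id = rownames(X), mirna_id = rownames(Y),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$r <- as.vector(R)
  long$n <- as.integer(as.vector(N))
  skip <- long$n < 3L
  skipped <- long[skip, c("mirna_id", "probe_id", "n")]
  rownames(skipped) <- NULL
  long <- long[!skip, , drop = FALSE]
  long$t <- long$r * sqrt(long$n - 2) / sqrt(pmax(1 - long$r^2, 0))
  long$t[abs(long$r) == 1 & !is.na(long$r)] <- Inf * sign(long$r[abs(long$r) == 1 & !is.na(long$r)])
  long$p <- ifelse(is.na(long$r), NA_real_,
                   ifelse(abs(long$r) == 1, 0,
                          2 * stats::pt(-abs(long$t), df = long$n - 2)))
  long$adj_p <- stats::p.adjust(long$p, method = "BH")
  long$significant <- significance_flag(long$r, long$p, long$adj_p, thresholds)
  sym <- cohort$mrna$gene_symbol
  long$gene_symbol <- if (is.null(sym)) NA_character_ else
    sym[match(long$probe_id, rownames(cohort$mrna$values))]
  out <- long[, c("mirna_id", "probe_id", "gene_symbol", "r", "n", "t",
                  "p", "adj_p", "significant")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Keep the correlation results that pass the screening rule
#'
#' Re-evaluates the significance rule under `thresholds` and returns the
#' passing subset in stable (input) order. Undefined correlations
#' (`r = NA`) never pass.
#'
#' @param results Data.frame as returned by [correlate_pairs()].
#' @param thresholds An [analysis_thresholds()] object.
#' @return The retained subset of `results`, with `significant`
#'   recomputed.
#' @export
filter_significant <- function(results, thresholds = analysis_thresholds()) {
  stopifnot(inherits(thresholds, "analysis_thresholds"))
  if (nrow(results) == 0L) return(results)
  sig <- significance_flag(results$r, results$p, results$adj_p, thresholds)
  out <- results[sig, , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a correlation table in the canonical TSV layout
#'
#' @param results Data.frame from [correlate_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
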