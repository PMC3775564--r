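# Wet-lab quantification arithmetic.
#
# Relative expression by the Livak 2^-ddCt method, densitometric relative
# protein levels normalized to a loading control and a reference condition,
# tumor-vs-normal fold changes with unpaired t-tests, and the decision rule
# that calls a predicted gene a confirmed target.

#' Read a qPCR Ct table
#'
#' @param path TSV with columns `replicate_id`, `condition`, `gene`, `ct`.
#' @param max_cycles Assay cycle ceiling (default 40); Ct values at the
#'   ceiling are at the detection limit and flagged `censored`.
#' @return The validated data.frame with an added logical `censored`
#'   column.
#' @export
read_ct_table <- function(path, max_cycles = 40) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ct_table(df, max_cycles)
}

#' Validate a Ct table and flag detection-limit values
#'
#' @param df Data.frame with columns `replicate_id`, `condition`, `gene`,
#'   `ct`.
#' @param max_cycles Assay cycle ceiling.
#' @return `df` with a logical `censored` column added.
#' @export
validate_ct_table <- function(df, max_cycles = 40) {
  need <- c("replicate_id", "condition", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$ct <= 0 | df$ct > max_cycles))
    stop("Ct values must lie in (0, ", max_cycles, "]")
  df$censored <- df$ct >= max_cycles
  df
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = Ct(target) - Ct(endogenous control)`; dCt is
#' averaged per condition, `ddCt = mean dCt(treated) - mean dCt(control)`,
#' and `fold = 2^-ddCt`. The p-value is an unpaired two-sided t-test over
#' the replicate dCt sets (Welch by default; `pooled = TRUE` for the
#' equal-variance test). With a single replicate per condition the fold is
#' still returned and `p` is `NA`.
#'
#' If any contributing Ct sits at the detection limit the result is
#' flagged `censored` and the fold is a bound, not a point estimate.
#'
#' @param ct Ct data.frame (see [read_ct_table()]; a `censored` column is
#'   added if absent, assuming `max_cycles = 40`).
#' @param target_gene Gene being quantified.
#' @param control_gene Endogenous control gene (e.g. `"UBC"` for mRNA,
#'   `"U47"` for miRNA).
#' @param treated_condition,control_condition Condition labels; the
#'   control is typically the scrambled-miRNA negative control
#'   (`"miR-scr"`).
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return A one-row data.frame: `gene`, `condition`,
#'   `delta_ct_treated`, `delta_ct_control`, `delta_delta_ct`, `fold`,
#'   `p`, `n_replicates`, `censored`.
#' @export
delta_delta_ct <- function(ct, target_gene, control_gene,
                           treated_condition, control_condition,
                           pooled = FALSE) {
  if (is.null(ct$censored)) ct <- validate_ct_table(ct)
  cell <- function(cond, gene) {
    sub <- ct[ct$condition == cond & ct$gene == gene, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no Ct values for condition '", cond, "', gene '", gene, "'")
    sub
  }
  dct_for <- function(cond) {
    tg <- cell(cond, target_gene)
    cg <- cell(cond, control_gene)
    # pair replicate-wise on replicate_id when possible
    shared <- intersect(tg$replicate_id, cg$replicate_id)
    if (length(shared)) {
      d <- tg$ct[match(shared, tg$replicate_id)] -
        cg$ct[match(shared, cg$replicate_id)]
      cen <- tg$censored[match(shared, tg$replicate_id)] |
        cg$censored[match(shared, cg$replicate_id)]
    } else {
      d <- mean(tg$ct) - mean(cg$ct)   # unpaired plates: difference of means
      cen <- any(tg$censored) || any(cg$censored)
    }
    list(dct = d, censored = any(cen))
  }
  tr <- dct_for(treated_condition)
  co <- dct_for(control_condition)
  ddct <- mean(tr$dct) - mean(co$dct)
  p <- if (length(tr$dct) >= 2 && length(co$dct) >= 2) {
    # constant replicates (e.g. a noiseless simulation) leave p undefined
    tryCatch(stats::t.test(tr$dct, co$dct, var.equal = pooled)$p.value,
             error = function(e) NA_real_)
  } else NA_real_
  data.frame(
    gene = target_gene, condition = treated_condition,
    delta_ct_treated = mean(tr$dct), delta_ct_control = mean(co$dct),
    delta_delta_ct = ddct, fold = 2^(-ddct), p = p,
    n_replicates = min(length(tr$dct), length(co$dct)),
    censored = tr$censored || co$censored,
    stringsAsFactors = FALSE)
}

#' Read a western-blot band-intensity table
#'
#' @param path TSV with columns `protein`, `condition`, `raw_intensity`,
#'   `loading_control_intensity`.
#' @return The validated data.frame.
#' @export
read_band_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "condition", "raw_intensity",
            "loading_control_intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("band table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Relative protein level from band densitometry
#'
#' Each band is normalized to its lane's loading control (e.g. tubulin)
#' and then expressed relative to the reference condition (the scrambled
#' negative control): `relative_level = (raw/loading) /
#' (raw/loading)[reference]`. `percent_change = 100 * (1 -
#' relative_level)` is the percent downregulation (negative for
#' upregulation). Replicate lanes of the same (protein, condition) are
#' averaged on the normalized scale before the ratio.
#'
#' @param bands Band-intensity data.frame (see [read_band_table()]).
#' @param reference_condition Condition used as denominator, e.g.
#'   `"miR-scr"`.
#' @return A data.frame with columns `protein`, `condition`,
#'   `relative_level`, `percent_change`; the reference condition's own
#'   relative level is exactly 1.
#' @export
relative_protein_level <- function(bands, reference_condition = "miR-scr") {
  if (any(bands$raw_intensity <= 0) ||
      any(bands$loading_control_intensity <= 0))
    stop("band intensities must be strictly positive")
  bands$norm <- bands$raw_intensity / bands$loading_control_intensity
  agg <- stats::aggregate(norm ~ protein + condition, data = bands,
                          FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$protein), function(sub) {
    ref <- sub$norm[sub$condition == reference_condition]
    if (length(ref) != 1L)
      stop("reference condition '", reference_condition,
           "' missing for protein ", sub$protein[1L])
    data.frame(protein = sub$protein, condition = sub$condition,
               relative_level = sub$norm / ref,
               stringsAsFactors = FALSE)
  }))
  out$percent_change <- 100 * (1 - out$relative_level)
  rownames(out) <- NULL
  out
}

#' Confirmation thresholds for the mRNA-or-protein decision rule
#'
#' @param mrna_alpha Significance level for the replicate-level mRNA
#'   downregulation t-test (default 0.05).
#' @param protein_down_min Minimum fractional protein decrease relative to
#'   the negative control (default 0.15, i.e. at least 15% down).
#' @return An object of class `confirmation_thresholds`.
#' @export
confirmation_thresholds <- function(mrna_alpha = 0.05,
                                    protein_down_min = 0.15) {
  stopifnot(mrna_alpha > 0, mrna_alpha < 1,
            protein_down_min > 0, protein_down_min < 1)
  structure(list(mrna_alpha = mrna_alpha,
                 protein_down_min = protein_down_min),
            class = "confirmation_thresholds")
}

#' Call a predicted gene a confirmed target
#'
#' A predicted gene is confirmed when its mRNA is significantly
#' downregulated (fold < 1 with t-test p <= `mrna_alpha`) OR its protein
#' is downregulated by at least `protein_down_min` (fractional) relative
#' to the negative control. Either assay may be absent (e.g. no specific
#' antibody), but not both.
#'
#' @param mrna One-row [delta_delta_ct()] result, or `NULL`.
#' @param protein One row of a [relative_protein_level()] result, or
#'   `NULL`.
#' @param thresholds A [confirmation_thresholds()] object.
#' @param gene,mirna Optional labels carried into the call.
#' @return A one-row data.frame: `gene`, `mirna`,
#'   `mrna_down_significant`, `protein_down_meets_threshold`, `confirmed`.
#' @export
confirm_target <- function(mrna = NULL, protein = NULL,
                           thresholds = confirmation_thresholds(),
                           gene = NA_character_, mirna = NA_character_) {
  stopifnot(inherits(thresholds, "confirmation_thresholds"))
  if (is.null(mrna) && is.null(protein))
    stop("at least one of the mRNA or protein results must be provided")
  mrna_sig <- if (is.null(mrna)) FALSE else {
    !is.na(mrna$p) && mrna$fold < 1 && mrna$p <= thresholds$mrna_alpha
  }
  prot_down <- if (is.null(protein)) FALSE else {
    protein$percent_change >= 100 * thresholds$protein_down_min
  }
  if (is.na(gene)) {
    if (!is.null(mrna)) gene <- mrna$gene
    else if (!is.null(protein)) gene <- protein$protein
  }
  data.frame(gene = gene, mirna = mirna,
             mrna_down_significant = mrna_sig,
             protein_down_meets_threshold = prot_down,
             confirmed = mrna_sig || prot_down,
             stringsAsFactors = FALSE)
}

#' Tumor-vs-normal fold change of one feature with an unpaired t-test
#'
#' The fold is the ratio of group means on the linear scale (log2-scale
#' matrices are back-transformed for the ratio); the two-sided unpaired
#' t-test runs on the matrix's own analysis scale.
#'
#' @param x An `expr_matrix`.
#' @param meta Sample metadata (`sample_id`, `group` with levels tumor /
#'   normal) covering the matrix samples.
#' @param feature_id Feature (probe or miRNA) to test.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return A one-row data.frame: `feature_id`, `fold`
#'   (tumor / normal), `p`, `n_tumor`, `n_normal`.
#' @export
group_fold_change <- function(x, meta, feature_id, pooled = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!feature_id %in% rownames(x$values))
    stop("feature '", feature_id, "' not present")
  v <- x$values[feature_id, ]
  grp <- meta$group[match(names(v), meta$sample_id)]
  keep <- !is.na(v) & !is.na(grp)
  v <- v[keep]; grp <- grp[keep]
  tum <- v[grp == "tumor"]; nor <- v[grp == "normal"]
  if (length(tum) < 2L || length(nor) < 2L)
    stop("each group needs at least 2 samples (tumor=", length(tum),
         ", normal=", length(nor), ")")
  lin <- function(z) if (x$scale == "log2") 2^z else z
  fold <- mean(lin(tum)) / mean(lin(nor))
  p <- stats::t.test(tum, nor, var.equal = pooled)$p.value
  data.frame(feature_id = feature_id, fold = fold, p = p,
             n_tumor = length(tum), n_normal = length(nor),
             stringsAsFactors = FALSE)
}
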