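# Synthetic matched-cohort generator with planted miRNA -> target
# repression, plus noisy prediction tables and Ct tables, so every stage
# of the screen runs and its operating characteristics can be measured
# without external data.
#
# Generative model (all on the log2 scale):
#   miRNA_i  ~ Normal(mirna_mean + tumor_shift_i * 1[tumor], mirna_sd)
#   gene g planted for miRNA i at probe-level population correlation r:
#     signal_g = baseline_mean - beta * (miRNA_i - E[miRNA_i]) + eps_g,
#     beta = -r * baseline_sd / mirna_sd,
#     sd(eps_g) chosen so the TOTAL probe variance is baseline_sd^2
#   probe of g = signal_g + Normal(0, noise_sd)
# With total probe variance pinned at baseline_sd^2, the population
# correlation between any probe of g and miRNA_i is exactly r, and the
# attainable |r| is bounded by sqrt(1 - noise_sd^2 / baseline_sd^2).

#' Simulation configuration for a matched miRNA/mRNA cohort
#'
#' Defaults encode the study-scale conditions used throughout: 57 matched
#' tumor samples, 200 genes carrying 1-3 probes each (uniform), 20 miRNAs,
#' unit total probe variance on the log2 scale with probe-level noise
#' sd 0.3.
#'
#' @param n_samples Number of tumor samples (>= 3; default 57).
#' @param n_normal Number of normal samples appended to the cohort
#'   (default 0; set > 0 to exercise tumor-vs-normal fold changes).
#' @param n_genes Number of genes (default 200).
#' @param probes_per_gene Integer vector of allowed probe counts per gene,
#'   sampled uniformly (default `1:3`).
#' @param n_mirnas Number of miRNAs (default 20).
#' @param planted_pairs Data.frame with columns `mirna`, `gene`, `r`
#'   (target probe-level population correlation, each in (-1, 0)); `NULL`
#'   for a null cohort.
#' @param tumor_shift Named numeric vector of per-miRNA mean log2 shifts
#'   applied to tumor samples (names = miRNA ids); unnamed miRNAs shift 0.
#' @param noise_sd Probe-level noise sd (default 0.3).
#' @param baseline_mean,baseline_sd Mean and TOTAL sd of probe signal
#'   (defaults 8 and 1).
#' @param mirna_mean,mirna_sd miRNA abundance mean and sd (defaults 6
#'   and 1).
#' @param seed Integer seed; a fixed seed yields identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 57, n_normal = 0, n_genes = 200,
                       probes_per_gene = 1:3, n_mirnas = 20,
                       planted_pairs = NULL, tumor_shift = NULL,
                       noise_sd = 0.3, baseline_mean = 8, baseline_sd = 1,
                       mirna_mean = 6, mirna_sd = 1, seed = 1) {
  stopifnot(n_samples >= 3, n_normal >= 0, n_genes >= 1, n_mirnas >= 1,
            noise_sd >= 0, baseline_sd > 0, mirna_sd > 0,
            all(probes_per_gene >= 1))
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("mirna", "gene", "r") %in% names(planted_pairs)))
    if (any(planted_pairs$r >= 0 | planted_pairs$r <= -1))
      stop("planted target correlations must lie in (-1, 0)")
    if (anyDuplicated(planted_pairs$gene))
      stop("each gene may be planted for at most one miRNA")
  }
  structure(list(
    n_samples = n_samples, n_normal = n_normal, n_genes = n_genes,
    probes_per_gene = as.integer(probes_per_gene), n_mirnas = n_mirnas,
    planted_pairs = planted_pairs, tumor_shift = tumor_shift,
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, mirna_mean = mirna_mean,
    mirna_sd = mirna_sd, seed = as.integer(seed)), class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("GENE%03d", seq_len(n))
sim_mirna_ids <- function(n) sprintf("hsa-miR-%03d", seq_len(n))

#' Largest attainable |probe-level correlation| under a configuration
#'
#' With total probe variance fixed at `baseline_sd^2` and probe noise
#' `noise_sd`, the planted correlation magnitude cannot exceed
#' `sqrt(1 - noise_sd^2 / baseline_sd^2)`.
#'
#' @param config A `sim_config`.
#' @return The attainable bound in [0, 1].
#' @export
attainable_r <- function(config) {
  v <- 1 - (config$noise_sd / config$baseline_sd)^2
  if (v <= 0) 0 else sqrt(v)
}

#' Pick random (miRNA, gene) pairs to plant
#'
#' Convenience helper: samples `n_pairs` distinct genes and assigns each a
#' random miRNA at a common target correlation.
#'
#' @param config A `sim_config`.
#' @param n_pairs Number of pairs.
#' @param r Target probe-level population correlation (negative).
#' @param seed Integer seed.
#' @return A `planted_pairs` data.frame.
#' @export
plant_random_pairs <- function(config, n_pairs = 30, r = -0.5, seed = 1) {
  stopifnot(n_pairs <= config$n_genes)
  set.seed(seed)
  data.frame(
    mirna = sample(sim_mirna_ids(config$n_mirnas), n_pairs, replace = TRUE),
    gene = sample(sim_gene_ids(config$n_genes), n_pairs),
    r = r, stringsAsFactors = FALSE)
}

#' Simulate a matched miRNA/mRNA cohort with planted repression
#'
#' @param config A [sim_config()].
#' @return A list: `cohort` (a `matched_cohort` on the log2 scale, probe
#'   annotation attached), `meta` (sample metadata), `truth` (the planted
#'   (mirna, gene, r) pairs), `annotation` (probe -> gene map).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bound <- attainable_r(config)
  if (!is.null(config$planted_pairs) &&
      any(abs(config$planted_pairs$r) > bound))
    stop(sprintf(
      "target correlation magnitude exceeds the attainable bound %.4f given noise_sd = %g",
      bound, config$noise_sd))
  set.seed(config$seed)
  n_tot <- config$n_samples + config$n_normal
  sids <- c(sprintf("TUM%03d", seq_len(config$n_samples)),
            if (config$n_normal > 0) sprintf("NRM%03d", seq_len(config$n_normal)))
  grp <- c(rep("tumor", config$n_samples), rep("normal", config$n_normal))
  meta <- sample_metadata(sids, grp)

  mids <- sim_mirna_ids(config$n_mirnas)
  shift <- setNames(rep(0, config$n_mirnas), mids)
  if (!is.null(config$tumor_shift)) {
    unknown <- setdiff(names(config$tumor_shift), mids)
    if (length(unknown)) stop("tumor_shift names not in the miRNA panel: ",
                              paste(unknown, collapse = ", "))
    shift[names(config$tumor_shift)] <- config$tumor_shift
  }
  is_tum <- grp == "tumor"
  mir_mu <- outer(shift, as.numeric(is_tum)) + config$mirna_mean
  mir_dev <- matrix(stats::rnorm(config$n_mirnas * n_tot, 0, config$mirna_sd),
                    config$n_mirnas, n_tot, dimnames = list(mids, sids))
  mir_vals <- mir_mu + mir_dev
  dimnames(mir_vals) <- list(mids, sids)

  gids <- sim_gene_ids(config$n_genes)
  planted_of <- setNames(rep(NA_character_, config$n_genes), gids)
  r_of <- setNames(rep(NA_real_, config$n_genes), gids)
  truth <- data.frame(mirna = character(), gene = character(), r = numeric(),
                      stringsAsFactors = FALSE)
  if (!is.null(config$planted_pairs)) {
    pp <- config$planted_pairs
    unknown <- setdiff(pp$gene, gids)
    if (length(unknown)) stop("planted gene(s) outside the simulated panel: ",
                              paste(unknown, collapse = ", "))
    unknown <- setdiff(pp$mirna, mids)
    if (length(unknown)) stop("planted miRNA(s) outside the panel: ",
                              paste(unknown, collapse = ", "))
    planted_of[pp$gene] <- pp$mirna
    r_of[pp$gene] <- pp$r
    truth <- data.frame(mirna = pp$mirna, gene = pp$gene, r = pp$r,
                        stringsAsFactors = FALSE)
  }

  n_probes <- sample(config$probes_per_gene, config$n_genes, replace = TRUE)
  sig2 <- config$baseline_sd^2
  noise2 <- config$noise_sd^2
  probe_rows <- vector("list", config$n_genes)
  pids <- vector("list", config$n_genes)
  for (g in seq_along(gids)) {
    if (!is.na(planted_of[g])) {
      r <- r_of[g]
      beta <- -r * config$baseline_sd / config$mirna_sd
      resid_sd <- sqrt(sig2 - beta^2 * config$mirna_sd^2 - noise2)
      signal <- config$baseline_mean -
        beta * mir_dev[planted_of[g], ] +
        stats::rnorm(n_tot, 0, resid_sd)
    } else {
      signal <- config$baseline_mean +
        stats::rnorm(n_tot, 0, sqrt(max(sig2 - noise2, 0)))
    }
    k <- n_probes[g]
    probe_rows[[g]] <- matrix(rep(signal, each = k), k, n_tot) +
      matrix(stats::rnorm(k * n_tot, 0, config$noise_sd), k, n_tot)
    pids[[g]] <- sprintf("%s_at%d", gids[g], seq_len(k))
  }
  mrna_vals <- do.call(rbind, probe_rows)
  dimnames(mrna_vals) <- list(unlist(pids), sids)
  annotation <- data.frame(probe_id = unlist(pids),
                           gene_symbol = rep(gids, n_probes),
                           stringsAsFactors = FALSE)

  mrna <- expr_matrix(mrna_vals, scale = "log2", platform = "synthetic mRNA")
  mrna <- attach_probe_annotation(mrna, annotation)
  mirna <- expr_matrix(mir_vals, scale = "log2",
                       platform = "synthetic miRNA")
  cohort <- match_samples(mrna, mirna, meta)
  list(cohort = cohort, meta = meta, truth = truth, annotation = annotation)
}

#' Simulate per-source target-prediction tables with controlled error
#'
#' Each source contains each true pair with probability `1 - fn_rate` and
#' each non-true pair of the miRNA x gene universe with probability
#' `fp_rate`, independently across sources.
#'
#' @param truth Planted-truth data.frame (`mirna`, `gene`).
#' @param mirnas,genes The full simulated universes.
#' @param fp_rate,fn_rate False-positive / false-negative probabilities in
#'   [0, 1]; scalars or named per-source vectors.
#' @param sources Source names (default the four supported tools).
#' @param seed Integer seed.
#' @return A single data.frame of normalized prediction records across
#'   sources (columns `source`, `mirna_id`, `gene_symbol`, `score`).
#' @export
simulate_prediction_tables <- function(truth, mirnas, genes,
                                       fp_rate = 0.01, fn_rate = 0.2,
                                       sources = PREDICTION_SOURCES,
                                       seed = 1) {
  get_rate <- function(rate, s) {
    r <- if (length(rate) > 1L) rate[[s]] else rate
    stopifnot(r >= 0, r <= 1)
    r
  }
  set.seed(seed)
  univ <- expand.grid(mirna = mirnas, gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tkey <- paste(truth$mirna, truth$gene)
  is_true <- paste(univ$mirna, univ$gene) %in% tkey
  out <- lapply(sources, function(s) {
    fp <- get_rate(fp_rate, s); fn <- get_rate(fn_rate, s)
    keep_p <- ifelse(is_true, 1 - fn, fp)
    keep <- stats::runif(nrow(univ)) < keep_p
    if (!any(keep)) return(NULL)
    data.frame(source = s, mirna_id = univ$mirna[keep],
               gene_symbol = toupper(univ$gene[keep]), score = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(source = character(), mirna_id = character(),
                      gene_symbol = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a replicated qPCR Ct table for a known true fold change
#'
#' Generates Ct values for a target and an endogenous control gene under a
#' treated and a negative-control condition such that the expected ddCt is
#' `-log2(true_fold)`; [delta_delta_ct()] then recovers `true_fold` in
#' expectation (exactly, when `replicate_sd = 0`).
#'
#' @param true_fold True expression ratio treated / control (> 0).
#' @param replicate_sd Per-well Ct noise sd in cycles.
#' @param n_replicates Replicates per condition.
#' @param seed Integer seed.
#' @param target_gene,control_gene,treated_condition,control_condition
#'   Labels used in the emitted table.
#' @param base_ct_target,base_ct_control Baseline Ct of target and
#'   endogenous control in the negative-control condition.
#' @return A Ct data.frame consumable by [delta_delta_ct()].
#' @export
simulate_ct_table <- function(true_fold, replicate_sd = 0.2,
                              n_replicates = 3, seed = 1,
                              target_gene = "TARGET", control_gene = "UBC",
                              treated_condition = "miR-200",
                              control_condition = "miR-scr",
                              base_ct_target = 25, base_ct_control = 20) {
  stopifnot(true_fold > 0, n_replicates >= 1, replicate_sd >= 0)
  set.seed(seed)
  conds <- c(treated_condition, control_condition)
  rows <- list()
  for (cond in conds) {
    tshift <- if (cond == treated_condition) -log2(true_fold) else 0
    for (rep_i in seq_len(n_replicates)) {
      rid <- sprintf("%s_rep%d", cond, rep_i)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = rid, condition = cond, gene = target_gene,
        ct = base_ct_target + tshift + stats::rnorm(1, 0, replicate_sd),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = rid, condition = cond, gene = control_gene,
        ct = base_ct_control + stats::rnorm(1, 0, replicate_sd),
        stringsAsFactors = FALSE)
    }
  }
  validate_ct_table(do.call(rbind, rows))
}

#' Sensitivity and precision of recovered consensus targets
#'
#' @param consensus Candidate-pair data.frame (`mirna_id`, `gene_symbol`).
#' @param truth Planted-truth data.frame (`mirna`, `gene`); must be
#'   nonempty.
#' @return A list with `sensitivity` (= recovered / planted), `precision`
#'   (= true recoveries / reported; `NA` when nothing is reported),
#'   `n_true_positive`.
#' @export
recovery_metrics <- function(consensus, truth) {
  if (is.null(truth) || nrow(truth) == 0L)
    stop("truth set is empty; recovery metrics undefined")
  tkey <- paste(normalize_mirna_id(truth$mirna), toupper(truth$gene))
  okey <- if (nrow(consensus) == 0L) character(0) else
    paste(normalize_mirna_id(consensus$mirna_id),
          toupper(consensus$gene_symbol))
  tp <- length(intersect(unique(okey), unique(tkey)))
  list(sensitivity = tp / length(unique(tkey)),
       precision = if (length(okey) == 0L) NA_real_ else
         tp / length(unique(okey)),
       n_true_positive = tp)
}

#' Run the full screen on one simulated cohort and score recovery
#'
#' Convenience wrapper used by the benchmark: simulates a cohort and
#' prediction tables, runs [correlate_pairs()], [filter_significant()] and
#' [build_candidate_pairs()], and scores the result against the planted
#' truth.
#'
#' @param seed Integer seed (drives cohort, planted pairs and prediction
#'   tables).
#' @param n_pairs,target_r Planted-pair count and correlation.
#' @param fp_rate,fn_rate Per-source prediction error rates.
#' @param config Base [sim_config()]; its seed and planted pairs are
#'   overridden.
#' @param thresholds Screening [analysis_thresholds()].
#' @return A list: `metrics` (from [recovery_metrics()]), `consensus`,
#'   `truth`.
#' @export
run_recovery_once <- function(seed, n_pairs = 30, target_r = -0.5,
                              fp_rate = 0.01, fn_rate = 0.2,
                              config = sim_config(),
                              thresholds = analysis_thresholds()) {
  config$planted_pairs <- plant_random_pairs(config, n_pairs, target_r,
                                             seed = seed)
  config$seed <- as.integer(seed)
  sim <- simulate_cohort(config)
  preds <- simulate_prediction_tables(
    sim$truth, mirnas = rownames(sim$cohort$mirna$values),
    genes = unique(sim$annotation$gene_symbol),
    fp_rate = fp_rate, fn_rate = fn_rate, seed = seed + 500000L)
  cors <- correlate_pairs(sim$cohort, thresholds = thresholds)
  sig <- filter_significant(cors, thresholds)
  cons <- build_candidate_pairs(preds, sig)
  list(metrics = recovery_metrics(cons, sim$truth), consensus = cons,
       truth = sim$truth)
}
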