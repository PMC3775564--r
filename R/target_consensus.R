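# Consensus target nomination.
#
# A (miRNA, gene) pair becomes a candidate when it is predicted by at
# least one sequence-based tool AND at least one probe of that gene shows
# a significant NEGATIVE expression correlation with the miRNA. Gene
# identity is by official symbol (matched case-insensitively), miRNA
# identity by the normalized "hsa-miR-..." name. Per-source support is
# retained so a stricter k-of-n consensus is a configuration choice.

PREDICTION_SOURCES <- c("targetscan", "pictar", "mirdb", "microrna_org")

# column-name adapters for the supported export dialects; every source
# also accepts the canonical columns (mirna_id, gene_symbol, score)
source_dialects <- list(
  targetscan   = c(mirna = "miRNA",        gene = "Gene.Symbol",  score = "context_score"),
  pictar       = c(mirna = "microRNA",     gene = "gene",         score = "pictar_score"),
  mirdb        = c(mirna = "mirna_name",   gene = "gene_symbol",  score = "target_score"),
  microrna_org = c(mirna = "mirna",        gene = "gene_symbol",  score = "mirsvr_score")
)

#' Normalize a miRNA identifier to canonical hsa-miR form
#'
#' Ensures the `hsa-` species prefix and canonical casing of the `miR` /
#' `let` stem while preserving the suffix verbatim (`"MIR-200A"` and
#' `"miR-200a"` both normalize to `"hsa-miR-200a"`; mature-arm and family
#' suffixes like `-3p` pass through unchanged).
#'
#' @param x Character vector of miRNA names.
#' @return Normalized names.
#' @export
normalize_mirna_id <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^hsa-", "", x, ignore.case = TRUE)
  x <- sub("^mir-?", "miR-", x, ignore.case = TRUE)
  x <- sub("^let-?", "let-", x, ignore.case = TRUE)
  # lowercase the variant letter directly after the numeric stem
  x <- sub("^(miR-[0-9]+)([A-Z])", "\\1\\L\\2", x, perl = TRUE)
  x <- sub("^(let-[0-9]+)([A-Z])", "\\1\\L\\2", x, perl = TRUE)
  paste0("hsa-", x)
}

#' Read and normalize a target-prediction table
#'
#' Accepts either the canonical TSV (columns `mirna_id`, `gene_symbol` and
#' optional `score`, with or without a `source` column) or the named
#' source's export dialect. Records are deduplicated on
#' (source, miRNA, gene) after normalization; rows with an empty miRNA or
#' gene field are skipped with a counted warning.
#'
#' @param path Path to the table, or a data.frame already in memory.
#' @param source One of `"targetscan"`, `"pictar"`, `"mirdb"`,
#'   `"microrna_org"`.
#' @return A data.frame with columns `source`, `mirna_id`, `gene_symbol`,
#'   `score` (NA when the source reports none).
#' @export
normalize_prediction_table <- function(path, source) {
  if (!source %in% PREDICTION_SOURCES)
    stop("unknown prediction source '", source, "'; expected one of: ",
         paste(PREDICTION_SOURCES, collapse = ", "))
  df <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  dial <- source_dialects[[source]]
  pick <- function(canon, alias) {
    if (canon %in% names(df)) df[[canon]]
    else if (alias %in% names(df)) df[[alias]]
    else NULL
  }
  mirna <- pick("mirna_id", dial[["mirna"]])
  gene <- pick("gene_symbol", dial[["gene"]])
  if (is.null(mirna) || is.null(gene))
    stop("cannot locate miRNA/gene columns for source '", source, "'")
  score <- pick("score", dial[["score"]])
  if (is.null(score)) score <- rep(NA_real_, length(mirna))
  bad <- is.na(mirna) | !nzchar(trimws(mirna)) |
    is.na(gene) | !nzchar(trimws(gene))
  if (any(bad))
    warning(sum(bad), " unmappable row(s) skipped for source ", source)
  out <- data.frame(
    source = source,
    mirna_id = normalize_mirna_id(mirna[!bad]),
    gene_symbol = toupper(trimws(gene[!bad])),
    score = as.numeric(score)[!bad],
    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("source", "mirna_id", "gene_symbol")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect predictions with significant negative correlations
#'
#' Emits a candidate (miRNA, gene) pair iff at least one source predicts
#' it and at least one probe of that gene has a significant negative
#' correlation with that miRNA in `correlations` (which must already have
#' passed [filter_significant()]). Pairs whose only significant
#' correlations are positive are excluded. Probes without a gene symbol
#' cannot join a prediction and are ignored.
#'
#' @param predictions Data.frame of normalized prediction records
#'   ([normalize_prediction_table()] output, possibly several sources
#'   row-bound together).
#' @param correlations Filtered correlation results.
#' @return A data.frame with columns `mirna_id`, `gene_symbol`, `sources`,
#'   `n_sources`, `supporting_probes`, `min_r` (the most negative
#'   supporting correlation), plus placeholder `validated` and
#'   `binding_site_count` columns filled by later steps.
#' @export
build_candidate_pairs <- function(predictions, correlations) {
  empty <- data.frame(mirna_id = character(), gene_symbol = character(),
                      sources = character(), n_sources = integer(),
                      supporting_probes = character(), min_r = numeric(),
                      validated = logical(), binding_site_count = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(predictions) == 0L || nrow(correlations) == 0L) return(empty)
  neg <- correlations[!is.na(correlations$r) & correlations$r < 0 &
                        !is.na(correlations$gene_symbol), , drop = FALSE]
  if (nrow(neg) == 0L) return(empty)
  key <- function(m, g) paste(normalize_mirna_id(m), toupper(trimws(g)),
                              sep = "\r")
  neg$key <- key(neg$mirna_id, neg$gene_symbol)
  pred <- predictions
  pred$key <- key(pred$mirna_id, pred$gene_symbol)
  shared <- intersect(unique(pred$key), unique(neg$key))
  if (length(shared) == 0L) return(empty)
  neg <- neg[neg$key %in% shared, , drop = FALSE]
  pred <- pred[pred$key %in% shared, , drop = FALSE]
  probes <- split(neg$probe_id, neg$key)
  min_r <- vapply(split(neg$r, neg$key), min, numeric(1))
  srcs <- lapply(split(pred$source, pred$key), function(s) sort(unique(s)))
  ord <- shared[order(match(shared, pred$key))]   # stable: prediction order
  parts <- strsplit(ord, "\r", fixed = TRUE)
  out <- data.frame(
    mirna_id = vapply(parts, `[`, character(1), 1L),
    gene_symbol = vapply(parts, `[`, character(1), 2L),
    sources = vapply(srcs[ord], paste, character(1), collapse = ";"),
    n_sources = vapply(srcs[ord], length, integer(1)),
    supporting_probes = vapply(probes[ord], function(p)
      paste(sort(unique(p)), collapse = ";"), character(1)),
    min_r = unname(min_r[ord]),
    validated = NA,
    binding_site_count = NA_integer_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag candidate pairs present in a validated-interaction catalogue
#'
#' Annotation only: a catalogued pair is marked `validated = TRUE`, but
#' validation status never gates inclusion. Symbols match
#' case-insensitively, miRNA names after normalization.
#'
#' @param pairs Candidate pairs from [build_candidate_pairs()].
#' @param validated Data.frame with columns `mirna_id`, `gene_symbol`
#'   (TarBase-style catalogue); may have zero rows.
#' @return `pairs` with the `validated` column filled.
#' @export
annotate_validation_status <- function(pairs, validated) {
  if (nrow(pairs) == 0L) { pairs$validated <- logical(0); return(pairs) }
  if (is.null(validated) || nrow(validated) == 0L) {
    pairs$validated <- FALSE
    return(pairs)
  }
  vkey <- paste(normalize_mirna_id(validated$mirna_id),
                toupper(trimws(validated$gene_symbol)))
  pkey <- paste(normalize_mirna_id(pairs$mirna_id),
                toupper(trimws(pairs$gene_symbol)))
  pairs$validated <- pkey %in% vkey
  pairs
}

#' Binding-site score thresholds
#'
#' Defaults mirror the published site query: mirSVR score <= 0 (more
#' negative = stronger predicted repression) and PhastCons conservation
#' >= 0; both bounds inclusive.
#'
#' @param mirsvr_max Maximum (i.e. least negative) mirSVR score retained.
#' @param phastcons_min Minimum PhastCons score retained.
#' @return An object of class `binding_site_thresholds`.
#' @export
binding_site_thresholds <- function(mirsvr_max = 0, phastcons_min = 0) {
  stopifnot(is.finite(mirsvr_max), is.finite(phastcons_min))
  structure(list(mirsvr_max = mirsvr_max, phastcons_min = phastcons_min),
            class = "binding_site_thresholds")
}

#' Read a 3'UTR binding-site table
#'
#' @param path TSV with columns `mirna_id`, `gene_symbol`, `utr_start`,
#'   `utr_end`, `mirsvr`, `phastcons` (1-based inclusive UTR-relative
#'   coordinates).
#' @return The validated data.frame.
#' @export
read_binding_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "gene_symbol", "utr_start", "utr_end",
            "mirsvr", "phastcons")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("binding-site table lacks column(s): ",
                         paste(miss, collapse = ", "))
  validate_binding_sites(df)
}

validate_binding_sites <- function(df) {
  if (nrow(df) == 0L) return(df)
  if (any(df$utr_start > df$utr_end))
    stop("binding site with utr_start > utr_end")
  if (any(df$phastcons < 0 | df$phastcons > 1, na.rm = TRUE))
    stop("PhastCons scores must lie in [0, 1]")
  df
}

#' Filter binding sites on mirSVR and PhastCons scores
#'
#' Keeps records with `mirsvr <= mirsvr_max` and
#' `phastcons >= phastcons_min`, both comparisons inclusive.
#'
#' @param sites Binding-site data.frame (see [read_binding_sites()]).
#' @param thresholds A [binding_site_thresholds()] object.
#' @return The retained subset, input order preserved.
#' @export
filter_binding_sites <- function(sites, thresholds = binding_site_thresholds()) {
  stopifnot(inherits(thresholds, "binding_site_thresholds"))
  if (nrow(sites) == 0L) return(sites)
  validate_binding_sites(sites)
  keep <- sites$mirsvr <= thresholds$mirsvr_max &
    sites$phastcons >= thresholds$phastcons_min
  out <- sites[!is.na(keep) & keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count retained binding sites for one (gene, miRNA) pair
#'
#' Records at identical (utr_start, utr_end) coordinates collapse to one
#' site; overlapping but non-identical sites count separately.
#'
#' @param gene Gene symbol (case-insensitive).
#' @param mirna miRNA id (normalized before matching).
#' @param sites Binding-site records, already passed through
#'   [filter_binding_sites()].
#' @return Integer site count.
#' @export
count_binding_sites <- function(gene, mirna, sites) {
  if (nrow(sites) == 0L) return(0L)
  sel <- toupper(trimws(sites$gene_symbol)) == toupper(trimws(gene)) &
    normalize_mirna_id(sites$mirna_id) == normalize_mirna_id(mirna)
  sub <- sites[sel, c("utr_start", "utr_end"), drop = FALSE]
  nrow(unique(sub))
}

#' Attach binding-site counts to candidate pairs
#'
#' @param pairs Candidate pairs.
#' @param sites Binding-site records (filtered).
#' @return `pairs` with `binding_site_count` filled.
#' @export
annotate_binding_sites <- function(pairs, sites) {
  if (nrow(pairs) == 0L) return(pairs)
  pairs$binding_site_count <- vapply(seq_len(nrow(pairs)), function(i)
    count_binding_sites(pairs$gene_symbol[i], pairs$mirna_id[i], sites),
    integer(1))
  pairs
}
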