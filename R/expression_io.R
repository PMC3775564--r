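# Expression matrix containers and I/O.
#
# The screen consumes two matched feature x sample matrices: probe-level
# mRNA signal (e.g. Affymetrix MAS5) and miRNA abundance. Both are held in
# a lightweight "expr_matrix" object: a numeric matrix with feature/sample
# dimnames plus scale ("linear" or "log2") and platform tags. Missing
# values are NA, never silently zeroed.

#' Construct an expression matrix
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   complete dimnames. `NA` marks a missing measurement; all other values
#'   must be finite.
#' @param scale Measurement scale of `values`: `"linear"` or `"log2"`.
#' @param platform Free-text platform tag (e.g. `"U133A MAS5"`).
#' @param gene_symbol Optional character vector of gene symbols aligned to
#'   rows (`NA` = unmapped probe). Usually attached later via
#'   [attach_probe_annotation()].
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale = c("linear", "log2"), platform = "",
                        gene_symbol = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("`values` must carry feature rownames and sample colnames")
  dup <- fid[duplicated(fid)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  dup <- sid[duplicated(sid)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  bad <- !is.finite(values) & !is.na(values)
  if (any(bad))
    stop("non-finite value at ", which(bad)[1])
  if (!is.null(gene_symbol)) {
    if (length(gene_symbol) != nrow(values))
      stop("`gene_symbol` must have one entry per feature")
    gene_symbol <- as.character(gene_symbol)
  }
  structure(
    list(values = values, scale = scale, platform = platform,
         gene_symbol = gene_symbol),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%s scale%s)\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (nzchar(x$platform)) paste0(", ", x$platform) else ""))
  n_mapped <- if (is.null(x$gene_symbol)) NA_integer_ else sum(!is.na(x$gene_symbol))
  if (!is.na(n_mapped))
    cat(sprintf("  %d/%d features mapped to gene symbols\n",
                n_mapped, nrow(x$values)))
  n_miss <- sum(is.na(x$values))
  if (n_miss > 0) cat(sprintf("  %d missing values\n", n_miss))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from a delimited text file
#'
#' Canonical dialect (`tsv_matrix`): UTF-8 TSV, first row is
#' `feature_id` followed by sample ids, one feature per subsequent row,
#' empty cells mark missing values. The `series_matrix` dialect additionally
#' tolerates leading metadata/comment lines prefixed by `!` and double
#' quotes around identifiers, as found in GEO series-matrix exports.
#'
#' @param path Path to the file.
#' @param dialect `"tsv_matrix"` (default) or `"series_matrix"`.
#' @param scale,platform Passed to [expr_matrix()].
#'
#' @return An `expr_matrix`. Missing cells are `NA`.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv_matrix", "series_matrix"),
                                   scale = "linear", platform = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "series_matrix") {
    lines <- lines[!startsWith(lines, "!")]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("expected a header row and at least one feature row in ", path)
  unquote <- function(x) gsub('^"|"$', "", x)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- unquote(cells[[1L]])
  sids <- header[-1L]
  if (anyDuplicated(sids))
    stop("duplicate sample id(s): ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "))
  n_feat <- length(cells) - 1L
  fids <- character(n_feat)
  vals <- matrix(NA_real_, nrow = n_feat, ncol = length(sids))
  for (i in seq_len(n_feat)) {
    row <- cells[[i + 1L]]
    # trailing empty cells are dropped by strsplit; pad them back
    if (length(row) < length(sids) + 1L)
      row <- c(row, rep("", length(sids) + 1L - length(row)))
    if (length(row) != length(sids) + 1L)
      stop("row ", i + 1L, " has ", length(row), " cells; expected ",
           length(sids) + 1L)
    fids[i] <- unquote(row[1L])
    body <- row[-1L]
    missing <- body == "" | body == "NA"
    num <- suppressWarnings(as.numeric(body))
    bad <- which(is.na(num) & !missing)
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d, column %d of %s",
                   body[bad[1L]], i + 1L, bad[1L] + 1L, path))
    num[missing] <- NA_real_
    vals[i, ] <- num
  }
  if (anyDuplicated(fids))
    stop("duplicate feature id(s): ",
         paste(unique(fids[duplicated(fids)]), collapse = ", "))
  dimnames(vals) <- list(fids, sids)
  expr_matrix(vals, scale = scale, platform = platform)
}

#' Write an expression matrix in the canonical TSV dialect
#'
#' Inverse of [read_expression_matrix()] for the `tsv_matrix` dialect:
#' re-reading the written file reproduces the ids and values exactly.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 17, trim = TRUE,
                                                 scientific = FALSE))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", sample_ids(x)), collapse = "\t"), con)
  for (i in seq_len(nrow(x$values))) {
    writeLines(paste(c(feature_ids(x)[i], fmt(x$values[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read sample metadata (sample id -> tumor/normal group)
#'
#' @param path TSV with columns `sample_id` and `group`; groups must be
#'   `tumor` or `normal`.
#' @return A data.frame with columns `sample_id`, `group`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_metadata(df$sample_id, df$group)
}

#' Construct sample metadata
#'
#' @param sample_id Character vector of sample ids.
#' @param group Matching vector of group labels, each `"tumor"` or `"normal"`.
#' @return A data.frame with columns `sample_id`, `group`.
#' @export
sample_metadata <- function(sample_id, group) {
  if (length(sample_id) != length(group))
    stop("sample_id and group must have equal length")
  group <- as.character(group)
  bad <- setdiff(unique(group), c("tumor", "normal"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (allowed: tumor, normal)")
  if (anyDuplicated(sample_id))
    stop("duplicate sample id(s) in metadata")
  data.frame(sample_id = as.character(sample_id), group = group,
             stringsAsFactors = FALSE)
}

#' Attach probe-to-gene annotation to an expression matrix
#'
#' One gene may be measured by several probe sets; the annotation maps each
#' probe id to at most one official symbol. Probes absent from the
#' annotation are retained with an `NA` symbol (unmapped is a state, not an
#' error). Probe ids match case-sensitively.
#'
#' @param x An `expr_matrix` whose features are probe ids.
#' @param annotation Data.frame with columns `probe_id`, `gene_symbol`.
#' @return `x` with its `gene_symbol` field populated.
#' @export
attach_probe_annotation <- function(x, annotation) {
  stopifnot(inherits(x, "expr_matrix"))
  if (nrow(annotation) == 0L) {
    x$gene_symbol <- rep(NA_character_, nrow(x$values))
    return(x)
  }
  if (!all(c("probe_id", "gene_symbol") %in% names(annotation)))
    stop("annotation needs columns probe_id and gene_symbol")
  ann <- annotation[!duplicated(annotation$probe_id), , drop = FALSE]
  if (nrow(ann) < nrow(annotation))
    warning("annotation contains duplicated probe ids; first mapping kept")
  sym <- ann$gene_symbol[match(feature_ids(x), ann$probe_id)]
  sym[!is.na(sym) & !nzchar(sym)] <- NA_character_
  x$gene_symbol <- as.character(sym)
  x
}

#' Restrict matched mRNA and miRNA matrices to their shared samples
#'
#' Both matrices are subset to the intersection of their sample ids and put
#' in identical sample order, mirroring a design where a subset of the
#' mRNA-profiled tumors was also miRNA-profiled.
#'
#' @param mrna,mirna `expr_matrix` objects.
#' @param meta Sample metadata data.frame (`sample_id`, `group`); subset to
#'   the shared samples. May be `NULL`.
#' @return A `matched_cohort`: list with elements `mrna`, `mirna`, `meta`,
#'   `sample_ids`, `n`.
#' @export
match_samples <- function(mrna, mirna, meta = NULL) {
  stopifnot(inherits(mrna, "expr_matrix"), inherits(mirna, "expr_matrix"))
  shared <- intersect(sample_ids(mrna), sample_ids(mirna))
  if (length(shared) < 3L)
    stop("only ", length(shared),
         " shared sample(s); at least 3 required for correlation")
  mrna$values <- mrna$values[, shared, drop = FALSE]
  mirna$values <- mirna$values[, shared, drop = FALSE]
  if (!is.null(meta)) {
    meta <- meta[match(shared, meta$sample_id), , drop = FALSE]
    if (anyNA(meta$sample_id))
      stop("metadata is missing entries for some matched samples")
    rownames(meta) <- NULL
  }
  structure(
    list(mrna = mrna, mirna = mirna, meta = meta,
         sample_ids = shared, n = length(shared)),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("matched_cohort: %d samples; %d mRNA features, %d miRNAs\n",
              x$n, nrow(x$mrna$values), nrow(x$mirna$values)))
  if (!is.null(x$meta))
    cat("  groups:", paste(sprintf("%s=%d", names(table(x$meta$group)),
                                   table(x$meta$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Log2-transform a linear-scale expression matrix
#'
#' Replaces every value by `log2(value + offset)`. Refuses to transform a
#' matrix already on the log2 scale, and refuses any cell where
#' `value + offset <= 0`.
#'
#' @param x An `expr_matrix` with `scale == "linear"`.
#' @param offset Small positive pseudo-count added before the log
#'   (default 1).
#' @return The transformed `expr_matrix` with `scale == "log2"`.
#' @export
log_transform <- function(x, offset = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale == "log2")
    stop("matrix is already on the log2 scale; refusing to transform twice")
  shifted <- x$values + offset
  bad <- which(!is.na(shifted) & shifted <= 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(x$values))
    stop(sprintf(
      "value + offset <= 0 for feature '%s', sample '%s' (value %g, offset %g)",
      feature_ids(x)[rc[1L]], sample_ids(x)[rc[2L]],
      x$values[bad[1L]], offset))
  }
  x$values <- log2(shifted)
  x$scale <- "log2"
  x
}
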