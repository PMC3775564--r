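test_that("miRNA identifiers normalize to canonical hsa-miR form", {
  expect_identical(normalize_mirna_id("miR-200a"), "hsa-miR-200a")
  expect_identical(normalize_mirna_id("MIR-200A"), "hsa-miR-200a")
  expect_identical(normalize_mirna_id("hsa-miR-200b"), "hsa-miR-200b")
  expect_identical(normalize_mirna_id("hsa-miR-141-3p"), "hsa-miR-141-3p")
  expect_identical(normalize_mirna_id("let-7a"), "hsa-let-7a")
})

test_that("prediction tables normalize, deduplicate and reject bad sources", {
  p <- write_tsv_fixture(c(
    "mirna_id\tgene_symbol\tscore",
    "miR-200a\tDlc1\t-0.3",
    "miR-200b\tHNRNPA3\t-0.1",
    "miR-200c\tATRX\t-0.5"))
  rec <- normalize_prediction_table(p, "targetscan")
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$mirna_id[1], "hsa-miR-200a")
  expect_identical(rec$gene_symbol[1], "DLC1")
  # round-trip stable: re-normalizing its own output changes nothing
  expect_identical(normalize_prediction_table(rec, "targetscan"), rec)

  # duplicated (mirna, gene) rows collapse; unique-key count is the oracle
  dup <- data.frame(mirna_id = c("miR-1", "MIR-1", "miR-2"),
                    gene_symbol = c("g1", "G1", "G1"))
  rec2 <- normalize_prediction_table(dup, "mirdb")
  n_unique <- length(unique(paste(normalize_mirna_id(dup$mirna_id),
                                  toupper(dup$gene_symbol))))
  expect_identical(nrow(rec2), n_unique)

  expect_error(normalize_prediction_table(dup, "foo"), "unknown prediction source")
})

test_that("source dialect columns are understood", {
  df <- data.frame(mirna = "miR-200c", gene_symbol = "DLC1",
                   mirsvr_score = -1.2)
  rec <- normalize_prediction_table(df, "microrna_org")
  expect_identical(rec$mirna_id, "hsa-miR-200c")
  expect_equal(rec$score, -1.2)
})

test_that("candidate pairs need >=1 prediction and >=1 significant negative probe", {
  preds <- data.frame(source = "targetscan",
                      mirna_id = c("hsa-miR-1", "hsa-miR-1"),
                      gene_symbol = c("G1", "G2"), score = NA_real_)
  # G1: one significant negative probe + one non-significant positive
  # (already filtered out); G2: only a significant POSITIVE correlation.
  cors <- data.frame(
    mirna_id = c("hsa-miR-1", "hsa-miR-1"),
    probe_id = c("probeA", "probeC"),
    gene_symbol = c("G1", "G2"),
    r = c(-0.40, 0.45), n = 57, t = NA_real_,
    p = correlation_pvalue(c(-0.40, 0.45), 57),
    adj_p = NA_real_, significant = TRUE)
  out <- build_candidate_pairs(preds, cors)
  expect_identical(out$gene_symbol, "G1")
  expect_identical(out$supporting_probes, "probeA")
  expect_equal(out$min_r, -0.40)
  # empty prediction set -> empty output
  expect_identical(nrow(build_candidate_pairs(preds[0, ], cors)), 0L)
})

test_that("consensus output obeys set algebra against brute force", {
  set.seed(41)
  for (trial in 1:5) {
    mirnas <- paste0("hsa-miR-", 1:3)
    genes <- paste0("G", 1:6)
    univ <- expand.grid(m = mirnas, g = genes, stringsAsFactors = FALSE)
    pred_idx <- runif(nrow(univ)) < 0.4
    preds <- data.frame(source = sample(c("targetscan", "pictar"),
                                        sum(pred_idx), replace = TRUE),
                        mirna_id = univ$m[pred_idx],
                        gene_symbol = univ$g[pred_idx], score = NA_real_)
    cor_idx <- runif(nrow(univ)) < 0.5
    cors <- data.frame(mirna_id = univ$m[cor_idx],
                       probe_id = paste0(univ$g[cor_idx], "_at1"),
                       gene_symbol = univ$g[cor_idx],
                       r = runif(sum(cor_idx), -0.6, 0.6), n = 57,
                       t = NA_real_, p = 0.01, adj_p = NA_real_,
                       significant = TRUE)
    out <- build_candidate_pairs(preds, cors)
    expect_ok <- paste(out$mirna_id, out$gene_symbol)
    want <- intersect(
      unique(paste(preds$mirna_id, preds$gene_symbol)),
      unique(paste(cors$mirna_id, cors$gene_symbol)[cors$r < 0]))
    expect_setequal(expect_ok, want)
    # re-deriving supporting probes from the correlation table matches
    for (i in seq_len(nrow(out))) {
      sel <- cors$mirna_id == out$mirna_id[i] &
        cors$gene_symbol == out$gene_symbol[i] & cors$r < 0
      expect_identical(out$supporting_probes[i],
                       paste(sort(unique(cors$probe_id[sel])), collapse = ";"))
      expect_equal(out$min_r[i], min(cors$r[sel]))
    }
    # adding a prediction source never removes a pair
    extra <- data.frame(source = "mirdb", mirna_id = univ$m,
                        gene_symbol = univ$g, score = NA_real_)
    out2 <- build_candidate_pairs(rbind(preds, extra), cors)
    expect_true(all(expect_ok %in% paste(out2$mirna_id, out2$gene_symbol)))
  }
})

test_that("validation status is case-insensitive annotation that never filters", {
  pairs <- build_candidate_pairs(
    data.frame(source = "pictar", mirna_id = c("hsa-miR-1", "hsa-miR-2"),
               gene_symbol = c("G1", "G1"), score = NA_real_),
    data.frame(mirna_id = c("hsa-miR-1", "hsa-miR-2"),
               probe_id = c("p1", "p1"), gene_symbol = "G1",
               r = -0.4, n = 57, t = NA_real_, p = 0.01,
               adj_p = NA_real_, significant = TRUE))
  # empty catalogue: all FALSE, nothing dropped
  out0 <- annotate_validation_status(pairs, data.frame(mirna_id = character(),
                                                       gene_symbol = character()))
  expect_identical(out0$validated, c(FALSE, FALSE))
  expect_identical(nrow(out0), nrow(pairs))
  # case-insensitive symbol match; a different miRNA of the same gene
  # stays FALSE
  cat1 <- data.frame(mirna_id = "miR-1", gene_symbol = "g1",
                     evidence = "reporter assay")
  out1 <- annotate_validation_status(pairs, cat1)
  expect_identical(out1$validated[out1$mirna_id == "hsa-miR-1"], TRUE)
  expect_identical(out1$validated[out1$mirna_id == "hsa-miR-2"], FALSE)
})

test_that("binding-site filtering is inclusive at both score boundaries", {
  sites <- data.frame(
    mirna_id = "hsa-miR-200a", gene_symbol = "DLC1",
    utr_start = c(10, 50, 90, 120), utr_end = c(16, 56, 96, 126),
    mirsvr = c(-0.5, 0.1, 0, -1.1), phastcons = c(0.6, 0.9, 0, 1))
  kept <- filter_binding_sites(sites)
  # (-0.5, 0.6) kept; (+0.1, 0.9) dropped; boundary (0, 0) kept
  expect_identical(kept$utr_start, c(10, 90, 120))
  expect_identical(nrow(filter_binding_sites(sites[0, ])), 0L)
  # tightening thresholds never increases the retained count
  for (th in list(binding_site_thresholds(-0.2, 0),
                  binding_site_thresholds(0, 0.5),
                  binding_site_thresholds(-0.6, 0.7))) {
    expect_lte(nrow(filter_binding_sites(sites, th)), nrow(kept))
  }
})

test_that("binding-site counts collapse identical coordinates only", {
  sites <- data.frame(
    mirna_id = c(rep("hsa-miR-1", 4), "hsa-miR-2"),
    gene_symbol = c(rep("G1", 4), "G1"),
    utr_start = c(10, 40, 40, 70, 10), utr_end = c(16, 46, 46, 76, 16),
    mirsvr = -0.5, phastcons = 0.5)
  kept <- filter_binding_sites(sites)
  expect_identical(count_binding_sites("g1", "miR-1", kept), 3L)
  expect_identical(count_binding_sites("G1", "hsa-miR-2", kept), 1L)
  expect_identical(count_binding_sites("G9", "hsa-miR-1", kept), 0L)
  # overlapping but non-identical intervals count separately
  ov <- data.frame(mirna_id = "hsa-miR-1", gene_symbol = "G1",
                   utr_start = c(10, 12), utr_end = c(16, 18),
                   mirsvr = -1, phastcons = 0.2)
  expect_identical(count_binding_sites("G1", "hsa-miR-1", ov), 2L)
})
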