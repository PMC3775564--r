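make_ct <- function(ct_target_tr, ct_ctrl_tr, ct_target_co, ct_ctrl_co) {
  n <- length(ct_target_tr)
  rbind(
    data.frame(replicate_id = paste0("t", seq_len(n)), condition = "miR-200a",
               gene = "DLC1", ct = ct_target_tr),
    data.frame(replicate_id = paste0("t", seq_len(n)), condition = "miR-200a",
               gene = "UBC", ct = ct_ctrl_tr),
    data.frame(replicate_id = paste0("c", seq_len(n)), condition = "miR-scr",
               gene = "DLC1", ct = ct_target_co),
    data.frame(replicate_id = paste0("c", seq_len(n)), condition = "miR-scr",
               gene = "UBC", ct = ct_ctrl_co))
}

test_that("ddCt arithmetic reproduces hand-derived folds and identities", {
  # Ct(target,treated)=25, Ct(ctrl,treated)=20, Ct(target,control)=24,
  # Ct(ctrl,control)=20 -> dCt 5 vs 4 -> ddCt 1 -> fold 0.5
  res <- delta_delta_ct(make_ct(25, 20, 24, 20), "DLC1", "UBC",
                        "miR-200a", "miR-scr")
  expect_equal(res$delta_delta_ct, 1)
  expect_equal(res$fold, 0.5)
  expect_true(is.na(res$p))  # single replicate: fold returned, p unavailable
  # ddCt = 0 -> fold exactly 1
  res0 <- delta_delta_ct(make_ct(24, 20, 24, 20), "DLC1", "UBC",
                         "miR-200a", "miR-scr")
  expect_equal(res0$fold, 1)
  # fold(x) * fold(-x) = 1 at x = 2.7
  up <- delta_delta_ct(make_ct(24 + 2.7, 20, 24, 20), "DLC1", "UBC",
                       "miR-200a", "miR-scr")
  dn <- delta_delta_ct(make_ct(24 - 2.7, 20, 24, 20), "DLC1", "UBC",
                       "miR-200a", "miR-scr")
  expect_equal(up$fold * dn$fold, 1, tolerance = 1e-12)
  # log2(fold) == -ddCt and fold strictly decreasing in ddCt
  set.seed(51)
  folds <- sapply(sort(runif(6, -3, 3)), function(x) {
    r <- delta_delta_ct(make_ct(24 + x, 20, 24, 20), "DLC1", "UBC",
                        "miR-200a", "miR-scr")
    expect_equal(log2(r$fold), -r$delta_delta_ct, tolerance = 1e-12)
    r$fold
  })
  expect_true(all(diff(folds) < 0))
})

test_that("ddCt replicate t-test matches the textbook oracle and errors are clear", {
  set.seed(52)
  tab <- make_ct(25 + rnorm(3, 0, .2), 20 + rnorm(3, 0, .2),
                 24 + rnorm(3, 0, .2), 20 + rnorm(3, 0, .2))
  res <- delta_delta_ct(tab, "DLC1", "UBC", "miR-200a", "miR-scr",
                        pooled = TRUE)
  dct_tr <- tab$ct[1:3] - tab$ct[4:6]
  dct_co <- tab$ct[7:9] - tab$ct[10:12]
  expect_equal(res$p, oracle_pooled_t(dct_tr, dct_co), tolerance = 1e-12)
  expect_equal(res$delta_delta_ct, mean(dct_tr) - mean(dct_co))
  # missing cell named in the error
  expect_error(delta_delta_ct(tab[tab$gene != "UBC", ], "DLC1", "UBC",
                              "miR-200a", "miR-scr"), "UBC")
  # out-of-range Ct rejected
  expect_error(validate_ct_table(data.frame(replicate_id = "r1",
                                            condition = "c", gene = "g",
                                            ct = 45)), "Ct values")
})

test_that("Ct values at the assay ceiling flag the fold as censored", {
  tab <- make_ct(40, 20, 24, 20)
  res <- delta_delta_ct(validate_ct_table(tab, max_cycles = 40),
                        "DLC1", "UBC", "miR-200a", "miR-scr")
  expect_true(res$censored)
  expect_false(delta_delta_ct(make_ct(25, 20, 24, 20), "DLC1", "UBC",
                              "miR-200a", "miR-scr")$censored)
})

test_that("relative protein levels normalize to loading control and reference", {
  bands <- data.frame(
    protein = "DLC1",
    condition = c("miR-scr", "miR-200a"),
    raw_intensity = c(80, 50),
    loading_control_intensity = c(80, 100))
  out <- relative_protein_level(bands, "miR-scr")
  # (50/100) / (80/80) = 0.5
  expect_equal(out$relative_level[out$condition == "miR-200a"], 0.5)
  expect_equal(out$relative_level[out$condition == "miR-scr"], 1)
  expect_equal(out$percent_change[out$condition == "miR-scr"], 0)
  # relative level 0.6 <-> 40% downregulation
  b2 <- data.frame(protein = "HFE", condition = c("miR-scr", "miR-200a"),
                   raw_intensity = c(100, 60),
                   loading_control_intensity = c(100, 100))
  rb2 <- relative_protein_level(b2)
  expect_equal(rb2$percent_change[rb2$condition == "miR-200a"], 40)
  expect_error(relative_protein_level(transform(bands, raw_intensity = c(0, 50))),
               "positive")
})

test_that("relative protein level is invariant to per-lane rescaling", {
  set.seed(53)
  bands <- data.frame(
    protein = rep(c("DLC1", "HFE"), each = 3),
    condition = rep(c("miR-scr", "miR-200a", "miR-200b"), 2),
    raw_intensity = runif(6, 20, 200),
    loading_control_intensity = runif(6, 20, 200))
  base <- relative_protein_level(bands)
  scaled <- bands
  k <- runif(6, 0.1, 10)  # exposure factor per lane
  scaled$raw_intensity <- scaled$raw_intensity * k
  scaled$loading_control_intensity <- scaled$loading_control_intensity * k
  expect_equal(relative_protein_level(scaled)$relative_level,
               base$relative_level, tolerance = 1e-12)
})

test_that("the confirmation rule is the documented disjunction with a strict boundary", {
  th <- confirmation_thresholds()
  prot <- function(pc) data.frame(protein = "DLC1", condition = "miR-200c",
                                  relative_level = 1 - pc / 100,
                                  percent_change = pc)
  mrna <- function(fold, p) data.frame(gene = "DLC1", condition = "miR-200c",
                                       delta_ct_treated = NA, delta_ct_control = NA,
                                       delta_delta_ct = -log2(fold), fold = fold,
                                       p = p, n_replicates = 3, censored = FALSE)
  # protein-only call: 20% down with non-significant mRNA confirms
  call <- confirm_target(mrna(0.9, 0.4), prot(20), th)
  expect_true(call$confirmed)
  expect_false(call$mrna_down_significant)
  # no change in either -> not confirmed
  expect_false(confirm_target(mrna(1, 1), prot(0), th)$confirmed)
  # strict 15% boundary: 14.9% + p = 0.2 fails, 15.0% passes
  expect_false(confirm_target(mrna(0.9, 0.2), prot(14.9), th)$confirmed)
  expect_true(confirm_target(protein = prot(15), th = th)$confirmed)
  # significant mRNA downregulation alone confirms; upregulation never does
  expect_true(confirm_target(mrna(0.5, 0.01), th = th)$confirmed)
  expect_false(confirm_target(mrna(2, 0.01), th = th)$confirmed)
  expect_error(confirm_target(th = th), "at least one")
})

test_that("confirmation is monotone in protein decrease and mRNA p", {
  th <- confirmation_thresholds()
  prot <- function(pc) data.frame(protein = "x", condition = "y",
                                  relative_level = 1 - pc / 100,
                                  percent_change = pc)
  mrna <- function(p) data.frame(gene = "x", condition = "y",
                                 delta_ct_treated = NA, delta_ct_control = NA,
                                 delta_delta_ct = 1, fold = 0.5, p = p,
                                 n_replicates = 3, censored = FALSE)
  grid_pc <- seq(0, 40, by = 5)
  grid_p <- c(0.3, 0.1, 0.04, 0.01)
  prev <- FALSE
  for (pc in grid_pc) {
    cur <- confirm_target(mrna(0.5), prot(pc), th)$confirmed
    expect_true(cur >= prev); prev <- cur
  }
  prev <- FALSE
  for (p in grid_p) {
    cur <- confirm_target(mrna(p), prot(0), th)$confirmed
    expect_true(cur >= prev); prev <- cur
  }
})

test_that("group fold change matches hand arithmetic and the t oracle", {
  vals <- matrix(c(4, 5, 6, 1, 2, 3), 1, 6,
                 dimnames = list("hsa-miR-200a", paste0("S", 1:6)))
  meta <- sample_metadata(paste0("S", 1:6),
                          rep(c("tumor", "normal"), each = 3))
  m <- expr_matrix(vals, scale = "linear")
  res <- group_fold_change(m, meta, "hsa-miR-200a", pooled = TRUE)
  expect_equal(res$fold, 2.5)
  expect_equal(res$p, oracle_pooled_t(c(4, 5, 6), c(1, 2, 3)),
               tolerance = 1e-12)
  # identical groups: fold 1, p = 1 for a mirror-symmetric layout
  v2 <- matrix(c(1, 2, 3, 1, 2, 3), 1, 6,
               dimnames = list("f", paste0("S", 1:6)))
  res2 <- group_fold_change(expr_matrix(v2, scale = "linear"), meta, "f")
  expect_equal(res2$fold, 1)
  expect_gt(res2$p, 0.99)
  # log2-scale input back-transforms for the ratio
  res3 <- group_fold_change(expr_matrix(log2(vals), scale = "log2"),
                            meta, "hsa-miR-200a")
  expect_equal(res3$fold, 2.5)
  # group with < 2 samples errors
  meta_bad <- sample_metadata(paste0("S", 1:6),
                              c(rep("tumor", 5), "normal"))
  expect_error(group_fold_change(m, meta_bad, "hsa-miR-200a"), "at least 2")
  expect_error(group_fold_change(m, meta, "nope"), "not present")
})

test_that("group fold change ignores within-group sample order", {
  set.seed(54)
  vals <- matrix(rnorm(20, 8), 1, 20,
                 dimnames = list("f", paste0("S", 1:20)))
  meta <- sample_metadata(paste0("S", 1:20), rep(c("tumor", "normal"), 10))
  m <- expr_matrix(vals, scale = "log2")
  base <- group_fold_change(m, meta, "f")
  perm <- sample(20)
  m2 <- expr_matrix(vals[, perm, drop = FALSE], scale = "log2")
  expect_equal(group_fold_change(m2, meta, "f")$fold, base$fold)
  expect_equal(group_fold_change(m2, meta, "f")$p, base$p)
})
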