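toy_expr <- function(vals_by_strain, gene = "g1") {
  # build a one-gene expression matrix with given replicate RPKM values;
  # lengths/totals chosen so counts == rpkm for simplicity (len 1 kb, 1e6)
  libs <- unlist(lapply(names(vals_by_strain), function(s)
    sprintf("%s_r%d", s, seq_along(vals_by_strain[[s]]))))
  counts <- matrix(unlist(vals_by_strain), nrow = 1,
                   dimnames = list(gene, libs))
  lib_strains <- setNames(rep(names(vals_by_strain),
                              lengths(vals_by_strain)), libs)
  rpkm_normalize(counts, gene_lengths = 1000,
                 totals = rep(1e6, length(libs)), lib_strains = lib_strains)
}

test_that("RPKM normalisation implements the standard formula", {
  m <- matrix(c(1000, 0), 2, 1, dimnames = list(c("g1", "g2"), "lib1"))
  ex <- rpkm_normalize(m, gene_lengths = c(g1 = 1000, g2 = 500),
                       totals = 1e6)
  expect_equal(ex$rpkm["g1", "lib1"], 1000)
  expect_equal(ex$rpkm["g2", "lib1"], 0)
  # random matrix matches element-wise recomputation
  set.seed(12)
  cnt <- matrix(rpois(50, 200), 10, 5,
                dimnames = list(sprintf("g%d", 1:10), sprintf("l%d", 1:5)))
  len <- sample(300:3000, 10)
  tot <- colSums(cnt)
  ex2 <- rpkm_normalize(cnt, len, tot)
  for (i in 1:10) for (j in 1:5)
    expect_equal(ex2$rpkm[i, j], cnt[i, j] * 1e9 / (len[i] * tot[[j]]))
  expect_error(rpkm_normalize(cnt, rep(0, 10), tot), "lengths")
  expect_error(rpkm_normalize(cnt, len, rep(0, 5)), "totals")
})

test_that("within-library RPKM ratios are invariant to count scaling", {
  set.seed(13)
  cnt <- matrix(rpois(20, 500), 10, 2,
                dimnames = list(sprintf("g%d", 1:10), c("a", "b")))
  len <- sample(500:2000, 10)
  ex1 <- rpkm_normalize(cnt, len)
  cnt2 <- cnt
  cnt2[, "a"] <- cnt[, "a"] * 5
  ex2 <- rpkm_normalize(cnt2, len)
  expect_equal(ex2$rpkm[, "a"] / ex2$rpkm[1, "a"],
               ex1$rpkm[, "a"] / ex1$rpkm[1, "a"])
})

test_that("upstream-effect test: identical replicates give FC 1, p ~ 1", {
  ex <- toy_expr(list(child = c(10, 10, 10), parent = c(10, 10, 10)))
  res <- test_upstream_effect(ex, "g1", "child", "parent")
  expect_equal(res$fold_change, 1)
  expect_gte(res$p_value, 0.999)
  # noiseless symmetric inputs: fc(a,b) * fc(b,a) = 1
  ex2 <- toy_expr(list(a = c(40, 44, 36), b = c(10, 11, 9)))
  fab <- test_upstream_effect(ex2, "g1", "a", "b")$fold_change
  fba <- test_upstream_effect(ex2, "g1", "b", "a")$fold_change
  expect_equal(fab * fba, 1)
  expect_error(test_upstream_effect(
    toy_expr(list(a = 5, b = c(1, 2))), "g1", "a", "b"), ">= 2 replicate")
})

test_that("a planted 4x effect is recovered and significant", {
  set.seed(14)
  parent <- 100 * exp(rnorm(4, 0, 0.1))
  child <- 400 * exp(rnorm(4, 0, 0.1))
  ex <- toy_expr(list(child = child, parent = parent))
  res <- test_upstream_effect(ex, "g1", "child", "parent")
  expect_gt(res$fold_change, 3)
  expect_lt(res$fold_change, 5.3)
  expect_lt(res$p_value, 0.01)
})

test_that("Bonferroni filter thresholds at alpha over family size", {
  p_table <- c(0.0017, 0.0003, 0.0020, 0.0010, 0.0001, 0.0005)
  out <- bonferroni_filter(data.frame(p_value = p_table), m = 22)
  expect_true(all(out$significant))
  # boundary: alpha/m = 0.0022727...; 0.0023 misses it
  out2 <- bonferroni_filter(data.frame(p_value = 0.0023), m = 22)
  expect_false(out2$significant)
  out3 <- bonferroni_filter(data.frame(p_value = 0.0023), m = 21)
  expect_true(out3$significant)
  # m = 1: raw alpha applies
  expect_true(bonferroni_filter(data.frame(p_value = 0.049),
                                m = 1)$significant)
  expect_error(bonferroni_filter(data.frame(p_value = 0.01), m = 0), ">= 1")
  expect_error(bonferroni_filter(data.frame(p_value = c(0.01, 0.02)),
                                 m = 1), "smaller")
})

test_that("planted upstream effects are recovered through the full linkage", {
  cfg <- test_config(seed = 2)
  ex <- generate_expression(cfg)
  expr <- rpkm_normalize(ex$counts, ex$gene_lengths, ex$totals,
                         ex$lib_strains)
  tests <- link_expression(cfg$upstream_effects[, c("strain", "gene")],
                           expr, cfg$pedigree, m = 22)
  expect_equal(nrow(tests), nrow(cfg$upstream_effects))
  # estimated fold changes sit within 25% of the planted truth
  key <- paste(tests$strain, tests$gene)
  truth <- cfg$upstream_effects$fold_change[
    match(key, paste(cfg$upstream_effects$strain,
                     cfg$upstream_effects$gene))]
  expect_true(all(abs(tests$fold_change - truth) / truth < 0.25))
  # the largest planted effect (4.33x) is Bonferroni-significant
  expect_true(tests$significant[truth == max(truth)])
  # a gene with no planted effect reports FC ~ 1
  null_gene <- setdiff(rownames(expr$rpkm), cfg$upstream_effects$gene)[1]
  res0 <- test_upstream_effect(expr, null_gene, "LL1042", "LL1036")
  expect_lt(abs(res0$fold_change - 1), 0.25)
})
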