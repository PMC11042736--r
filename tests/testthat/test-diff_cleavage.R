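test_that("CPM filter keeps positions supported in the enriched condition", {
  # library size 1e6 so counts are CPM directly; targeting = first 3
  cond <- rep(c("targeting", "nontargeting"), each = 3)
  counts <- rbind(
    c(12, 11, 10, 0, 0, 0),     # 3 targeting reps at/above 10 -> keep
    c(12, 11, 9, 50, 50, 50),   # only 2 pass -> drop
    c(0, 0, 0, 900, 900, 900),  # huge nontargeting only -> drop
    c(10, 10, 10, 10, 10, 10))  # keep
  tab <- make_table(counts, cond, lib_sizes = rep(1e6, 6))
  kept <- filter_positions(tab, model_config())
  expect_equal(kept$axis$pos, c(0L, 3L))
  # nontargeting columns are untouched by the criterion but stay in the
  # table for the test stage
  expect_equal(ncol(kept$counts), 6L)
  expect_error(
    filter_positions(make_table(counts[, c(1, 2, 4, 5)],
                                cond[c(1, 2, 4, 5)],
                                lib_sizes = rep(1e6, 4))),
    "min_replicates")
})

test_that("site calling takes top-N by FDR then applies the log2FC rule", {
  mkdiff <- function(n, fdr, lfc) {
    structure(data.frame(ref = "chr", strand = "+", pos = seq_len(n) - 1L,
                         log2fc = lfc, lrt_stat = 1, pvalue = fdr,
                         fdr = fdr, stringsAsFactors = FALSE),
              class = c("DiffResult", "data.frame"))
  }
  # 150 positions; the 100 smallest FDR all have log2fc 6
  d <- mkdiff(150, fdr = (1:150) / 1000, lfc = c(rep(6, 100), rep(0, 50)))
  s <- call_sites(d, model_config())
  expect_equal(nrow(s), 100L)
  expect_equal(s$pos, 0:99)
  # nothing above the threshold: empty set, no error
  d2 <- mkdiff(30, fdr = (1:30) / 100, lfc = rep(3.9, 30))
  expect_equal(nrow(call_sites(d2, model_config())), 0L)
  # log2fc exactly 4 fails the strict inequality
  d3 <- mkdiff(5, fdr = (1:5) / 100, lfc = rep(4, 5))
  expect_equal(nrow(call_sites(d3, model_config())), 0L)
  # 60 of the top 100 pass: exactly those, in FDR order
  lfc <- rep(2, 150); lfc[seq(1, 120, 2)] <- 8
  d4 <- mkdiff(150, fdr = (1:150) / 1000, lfc = lfc)
  s4 <- call_sites(d4, model_config())
  expect_equal(nrow(s4), 50L)   # odd positions among the first 100
  expect_equal(s4$pos, seq(0, 98, 2))
  expect_true(!is.unsorted(s4$fdr))
})

test_that("infinite fold changes rank via the +/-20 clamp", {
  d <- structure(data.frame(ref = "chr", strand = "+", pos = 0:2,
                            log2fc = c(Inf, 10, -Inf), lrt_stat = 1,
                            pvalue = c(0.01, 0.01, 0.01),
                            fdr = c(0.01, 0.01, 0.01),
                            stringsAsFactors = FALSE),
                 class = c("DiffResult", "data.frame"))
  # tie on FDR: |clamped log2fc| descending ranks +/-Inf (as 20) ahead
  # of 10, position breaking the +Inf/-Inf tie; with top_n = 2 the
  # -Inf entry occupies a slot but fails the threshold
  s <- call_sites(d, model_config(top_n = 2))
  expect_equal(s$pos, 0L)
  expect_equal(s$log2fc, Inf)
  s3 <- call_sites(d, model_config(top_n = 3))
  expect_equal(s3$pos, c(0L, 1L))
})

sim_tables <- function(seed, n_pos = 400, effect_pos = integer(0),
                       effect = 6, base = 50, depth_factor = 1) {
  set.seed(seed)
  mu <- rep(base, n_pos)
  counts <- sapply(1:6, function(j) {
    m <- mu
    if (j <= 3) m[effect_pos] <- m[effect_pos] * 2^effect
    rnbinom(n_pos, mu = m * depth_factor, size = 1 / 0.15)
  })
  make_table(counts, rep(c("targeting", "nontargeting"), each = 3),
             lib_sizes = colSums(counts))
}

test_that("the full contrast finds implanted positions and is deterministic", {
  tab <- sim_tables(31, effect_pos = c(5, 50, 300))
  d1 <- test_cleavage(tab, model_config(min_cpm = 0))
  s1 <- call_sites(d1, model_config(min_cpm = 0))
  expect_true(all(c(4L, 49L, 299L) %in% s1$pos[1:3]))
  # byte-identical rerun
  d2 <- test_cleavage(tab, model_config(min_cpm = 0))
  s2 <- call_sites(d2, model_config(min_cpm = 0))
  expect_identical(s1, s2)
})

test_that("raising an implanted effect never worsens its FDR rank", {
  base_tab <- sim_tables(32, effect_pos = 10, effect = 0)
  pos_rank <- function(mult) {
    tab <- base_tab
    # scale the targeting counts at the implant on the same noise draw
    tab$counts[10, 1:3] <- as.integer(round(tab$counts[10, 1:3] * mult))
    d <- test_cleavage(tab, model_config(min_cpm = 0))
    o <- cleavemap:::rank_order(d)
    which(d$pos[o] == 9L)
  }
  ranks <- vapply(c(1, 4, 16, 64), pos_rank, numeric(1))
  expect_true(all(diff(ranks) <= 0))
})

test_that("TSS calling contrasts RppH-treated against untreated", {
  set.seed(33)
  n <- 300
  mu <- rep(60, n)
  rpph <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  counts <- sapply(1:6, function(j) {
    m <- mu
    if (rpph[j]) m[7] <- m[7] * 32  # primary 5' end visible after RppH
    rnbinom(n, mu = m, size = 1 / 0.15)
  })
  tab <- make_table(counts, rep("nontargeting", 6), rpph = rpph,
                    lib_sizes = colSums(counts))
  s <- call_tss(tab, model_config(min_cpm = 0))
  expect_s3_class(s, "SiteSet")
  expect_equal(attr(s, "site_type"), "tss")
  expect_true(6L %in% s$pos)
  # a position equally represented in both treatments is not called
  expect_false(10L %in% s$pos)
  # without untreated libraries the contrast is impossible
  tab2 <- make_table(counts[, 1:3], rep("nontargeting", 3),
                     rpph = rep(TRUE, 3))
  expect_error(call_tss(tab2, model_config()), "untreated")
})

test_that("TSS/cleavage cross-check intersects top-k positions", {
  mks <- function(pos) {
    structure(data.frame(ref = "chr", strand = "+", pos = pos,
                         log2fc = 6, fdr = seq_along(pos) / 100,
                         stringsAsFactors = FALSE),
              class = c("SiteSet", "data.frame"))
  }
  expect_equal(crosscheck_tss_vs_cleavage(mks(1:10), mks(11:20),
                                          k = 10)$n_shared, 0L)
  res <- crosscheck_tss_vs_cleavage(mks(1:10), mks(10:1), k = 10)
  expect_equal(res$n_shared, 10L)
  expect_equal(res$shared$pos, 1:10)
  # both sets are smaller than k: one warning each
  expect_warning(expect_warning(
    res2 <- crosscheck_tss_vs_cleavage(mks(1:5), mks(3:12), k = 1000),
    "whole set"), "whole set")
  expect_equal(res2$n_shared, 3L)
})
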