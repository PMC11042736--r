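mksites <- function(pos, strand = "+", ref = "chrT", lfc = 6,
                    fdr = seq_along(pos) / 100) {
  structure(data.frame(ref = ref, strand = strand, pos = pos,
                       log2fc = lfc, fdr = fdr,
                       feature = NA_character_,
                       feature_class = NA_character_,
                       stringsAsFactors = FALSE),
            site_type = "cleavage", class = c("SiteSet", "data.frame"))
}

test_that("sites are assigned to same-strand features or intergenic", {
  g <- make_toy_genome()
  s <- assign_sites_to_features(
    mksites(c(120L, 250L, 310L, 50L), strand = c("+", "+", "+", "+")), g)
  expect_equal(s$feature, c("lysT", "intergenic", "cdsA", "intergenic"))
  expect_equal(s$feature_class, c("tRNA", "intergenic", "CDS",
                                  "intergenic"))
  # antisense hit: inside lysW's interval but on the opposite strand is
  # intergenic; on the annotated strand it is the tRNA
  s2 <- assign_sites_to_features(mksites(250L, strand = "-"), g)
  expect_equal(s2$feature, "lysW")
})

test_that("nested features resolve to the nearest start, logged", {
  g <- make_toy_genome()
  g$features <- rbind(g$features, data.frame(
    name = "inner", ref = "chrT", start = 115L, end = 130L,
    strand = "+", feature_class = "other", stringsAsFactors = FALSE))
  expect_message(
    s <- assign_sites_to_features(mksites(120L), g),
    "assigned to inner")
  expect_equal(s$feature, "inner")
})

test_that("logo windows flank the scissile bond in transcript sense", {
  # genome spelled so the window around a + site at pos 50 reads
  # AAAAA | TTTTT (cleaved base first downstream column)
  seqs <- c(chrL = paste0(strrep("G", 45), "AAAAA", "TTTTT",
                          strrep("G", 45)))
  g <- cleavemap:::new_genome_bundle(seqs)
  logo <- build_logo_matrix(mksites(50L, ref = "chrL"), g)
  expect_equal(colSums(logo), rep(1, 10), ignore_attr = TRUE)
  expect_equal(unname(logo["A", 1:5]), rep(1, 5))
  expect_equal(unname(logo["T", 6:10]), rep(1, 5))
  # the same cut seen from the reverse-complemented genome: the minus
  # strand 5' end sits at position L-1-50 = 49 of the revcomp sequence
  rc <- cleavemap:::revcomp(seqs)
  names(rc) <- "chrL"
  g2 <- cleavemap:::new_genome_bundle(rc)
  logo2 <- build_logo_matrix(mksites(49L, ref = "chrL", strand = "-"), g2)
  expect_equal(logo2, logo, ignore_attr = TRUE)
})

test_that("edge sites are dropped and counted; all-dropped errors", {
  seqs <- c(chrL = strrep("ACGT", 30))
  g <- cleavemap:::new_genome_bundle(seqs)
  logo <- build_logo_matrix(mksites(c(2L, 60L), ref = "chrL"), g)
  expect_equal(attr(logo, "n_sites"), 1L)
  expect_equal(attr(logo, "n_dropped"), 1L)
  expect_error(build_logo_matrix(mksites(1L, ref = "chrL"), g), "edge")
})

test_that("anticodon profile collects loop values strand-aware", {
  g <- make_toy_genome()
  # DiffResult covering both lysT (plus) and lysW (minus) loops, with a
  # strong value at N1 (loop offset 33) and mild elsewhere
  spec_p <- anticodon_spec(g, "lysT")
  spec_m <- anticodon_spec(g, "lysW")
  d <- data.frame(
    ref = "chrT",
    strand = c(rep("+", 7), rep("-", 7)),
    pos = c(spec_p$loop_genomic, spec_m$loop_genomic),
    log2fc = rep(c(0.1, 0.2, 6, 0.3, 0.2, 0.1, 0), 2),
    lrt_stat = 1, pvalue = 0.01,
    fdr = rep(c(0.5, 0.5, 1e-8, 0.5, 0.5, 0.5, 0.5), 2),
    stringsAsFactors = FALSE)
  prof <- anticodon_loop_profile(d, g)
  # the two genes are identical copies -> one collapsed group + aggregate
  expect_equal(rownames(prof$log2fc), c("lysTW", "aggregate"))
  expect_equal(unname(prof$log2fc["lysTW", "34"]), 6)
  expect_equal(which.max(prof$log2fc["aggregate", ]), c(`34` = 3L))
  expect_equal(unname(prof$neg_log10_fdr["lysTW", "34"]), 8)
  # positions never tested stay NA, not zero
  d2 <- d[d$strand == "+", ][1:3, ]
  prof2 <- anticodon_loop_profile(d2, g)
  expect_true(all(is.na(prof2$log2fc["lysTW", c("35", "38")])))
})

test_that("volcano table flags both calling thresholds", {
  d <- structure(data.frame(
    ref = "chr", strand = "+", pos = 0:149,
    log2fc = c(rep(8, 60), rep(4, 40), rep(0.5, 50)),
    lrt_stat = 1,
    pvalue = (1:150) / 1000, fdr = (1:150) / 1000,
    stringsAsFactors = FALSE), class = c("DiffResult", "data.frame"))
  v <- volcano_table(d, config = model_config())
  expect_equal(sum(v$in_top_n), 100L)
  expect_equal(sum(v$above_lfc), 60L)     # log2fc exactly 4 is below
  expect_equal(v$neg_log10_fdr, -log10(v$fdr))
  expect_equal(nrow(volcano_table(d[0, , drop = FALSE])), 0L)
})

test_that("experiment intersection works on collapsed transcripts", {
  g <- make_toy_genome()
  a <- assign_sites_to_features(mksites(c(120L, 310L)), g)       # lysT, cdsA
  b <- assign_sites_to_features(mksites(250L, strand = "-"), g)  # lysW
  res <- intersect_experiments(list(A = a, B = b), g)
  # lysT and lysW collapse to lysTW: counted as shared
  expect_true("lysTW" %in% rownames(res$membership))
  expect_true(all(res$membership["lysTW", ]))
  expect_equal(res$region_counts[["A&B"]], 1L)
  expect_equal(res$region_counts[["A"]], 1L)
  expect_equal(sum(res$region_counts), nrow(res$membership))

  # four identical sets: everything in the centre region
  four <- list(W = a, X = a, Y = a, Z = a)
  res4 <- intersect_experiments(four, g)
  expect_equal(res4$region_counts[["W&X&Y&Z"]], 2L)
  expect_equal(sum(res4$region_counts), 2L)

  # disjoint sets share nothing
  c_ <- assign_sites_to_features(mksites(310L), g)
  d_ <- assign_sites_to_features(mksites(120L), g)
  resd <- intersect_experiments(list(P = c_, Q = d_), g)
  expect_false(any(rowSums(resd$membership) > 1))

  expect_error(intersect_experiments(list(A = a), g), "two")
  expect_error(intersect_experiments(stats::setNames(list(a, b),
                                                     c("A", "A")), g),
               "unique")
})
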