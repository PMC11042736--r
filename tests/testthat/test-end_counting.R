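refs <- c(chr = 1000L)

test_that("single-end reads become fragments with the correct 5' end", {
  sam <- tempfile(fileext = ".sam")
  recs <- rbind(
    sam_rec("r1", 0L, "chr", 101L, "50M"),       # + strand [100,150)
    sam_rec("r2", 16L, "chr", 201L, "50M"))      # - strand [200,250)
  write_sam(recs, refs, sam)
  fr <- fragments_from_alignments(sam)
  fr <- fr[order(fr$start), ]
  expect_equal(fr$start, c(100L, 200L))
  expect_equal(fr$end, c(150L, 250L))
  expect_equal(fr$five_prime, c(100L, 249L))
  expect_equal(fr$strand, c("+", "-"))
})

test_that("a proper pair collapses to one fragment on read 1's strand", {
  sam <- tempfile(fileext = ".sam")
  recs <- rbind(
    sam_rec("p1", 99L, "chr", 101L, "36M", "=", 181L, 116L),
    sam_rec("p1", 147L, "chr", 181L, "36M", "=", 101L, -116L))
  write_sam(recs, refs, sam)
  fr <- fragments_from_alignments(sam)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$start, 100L)
  expect_equal(fr$end, 216L)
  expect_equal(fr$strand, "+")
  expect_equal(fr$five_prime, 100L)
  # pair_collapse = FALSE counts both reads separately
  fr2 <- fragments_from_alignments(sam, pair_collapse = FALSE)
  expect_equal(nrow(fr2), 2L)
  expect_setequal(fr2$five_prime, c(100L, 215L))
})

test_that("mapq, secondary and supplementary filters drop records", {
  sam <- tempfile(fileext = ".sam")
  recs <- rbind(
    sam_rec("a", 0L, "chr", 101L, "36M", mapq = 5),
    sam_rec("b", 0L, "chr", 111L, "36M", mapq = 30),
    sam_rec("c", 256L, "chr", 121L, "36M"),   # secondary
    sam_rec("d", 2048L, "chr", 131L, "36M"))  # supplementary
  write_sam(recs, refs, sam)
  expect_warning(fr <- fragments_from_alignments(sam, min_mapq = 10),
                 "skipped")
  expect_equal(fr$five_prime, 110L)
})

test_that("fixture SAM of 20 hand-placed reads matches a hand tally", {
  sam <- tempfile(fileext = ".sam")
  # 8 plus reads at 0-based 100 (SAM pos 101), 5 plus at 140,
  # 4 minus ending at 0-based 299 (pos 265, 35M), 3 minus ending at 449
  recs <- do.call(rbind, c(
    lapply(1:8, function(i) sam_rec(paste0("a", i), 0L, "chr", 101L, "35M")),
    lapply(1:5, function(i) sam_rec(paste0("b", i), 0L, "chr", 141L, "35M")),
    lapply(1:4, function(i) sam_rec(paste0("c", i), 16L, "chr", 266L, "34M")),
    lapply(1:3, function(i) sam_rec(paste0("d", i), 16L, "chr", 416L, "34M"))))
  write_sam(recs, refs, sam)
  tab <- count_five_prime_ends(list(lib1 = fragments_from_alignments(sam)))
  expect_equal(tab$lib_sizes, c(lib1 = 20L), ignore_attr = TRUE)
  expected <- data.frame(
    ref = "chr", strand = c("+", "+", "-", "-"),
    pos = c(100L, 140L, 298L, 448L), stringsAsFactors = FALSE)
  got <- cbind(tab$axis, n = tab$counts[, 1])
  got <- got[order(got$strand, got$pos), ]
  rownames(got) <- NULL
  expect_equal(got$pos, expected$pos)
  expect_equal(got$strand, expected$strand)
  expect_equal(got$n, c(8L, 5L, 4L, 3L))
})

toy_frags <- function(tab) {
  data.frame(ref = tab$ref, strand = tab$strand,
             start = ifelse(tab$strand == "+", tab$p, tab$p - 49L),
             end = ifelse(tab$strand == "+", tab$p + 50L, tab$p + 1L),
             five_prime = tab$p, stringsAsFactors = FALSE)
}

test_that("5'-end counting conserves fragments and ignores order", {
  set.seed(1)
  tab <- data.frame(ref = "chr", strand = sample(c("+", "-"), 200, TRUE),
                    p = sample(100:150, 200, TRUE))
  fr <- toy_frags(tab)
  t1 <- count_five_prime_ends(list(A = fr))
  expect_equal(sum(t1$counts), nrow(fr))
  t2 <- count_five_prime_ends(list(A = fr[sample(nrow(fr)), ]))
  expect_identical(t1$axis, t2$axis)
  expect_identical(t1$counts, t2$counts)
})

test_that("strand flip under reverse complement mirrors the axis", {
  set.seed(2)
  L <- 1000L
  tab <- data.frame(ref = "chr", strand = sample(c("+", "-"), 100, TRUE),
                    p = sample(60:940, 100, TRUE))
  fr <- toy_frags(tab)
  t1 <- count_five_prime_ends(list(A = fr))
  # reverse-complementing the genome maps (+, p) onto (-, L-1-p)
  flip <- data.frame(ref = fr$ref,
                     strand = ifelse(fr$strand == "+", "-", "+"),
                     start = L - fr$end, end = L - fr$start,
                     stringsAsFactors = FALSE)
  flip$five_prime <- ifelse(flip$strand == "+", flip$start, flip$end - 1L)
  t2 <- count_five_prime_ends(list(A = flip))
  key1 <- paste(t1$axis$strand, t1$axis$pos)
  key2 <- paste(ifelse(t2$axis$strand == "+", "-", "+"),
                L - 1L - t2$axis$pos)
  expect_setequal(key1, key2)
  expect_equal(t1$counts[match(key2, key1), 1], t2$counts[, 1],
               ignore_attr = TRUE)
})

test_that("CPM normalization scales by recorded library size", {
  m <- matrix(c(10, 20, 30, 40), 2)
  cpm <- cpm_normalize(m, lib_sizes = c(1e6, 2e6))
  expect_equal(cpm[1, 1], 10)
  expect_equal(cpm[, 2], c(15, 20))
  # doubling counts and library size leaves CPM unchanged
  expect_equal(cpm_normalize(2 * m, lib_sizes = 2 * c(1e6, 2e6)), cpm)
  # column sums reach 1e6 when no positions are dropped
  set.seed(3)
  r <- matrix(rpois(400, 30), 100)
  expect_equal(colSums(cpm_normalize(r, colSums(r))), rep(1e6, 4),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(cpm_normalize(m, lib_sizes = c(0, 1)), "positive")
})

test_that("coverage profile reports replicate mean and SEM", {
  # one fragment covering [10,60) per library, library sizes set so the
  # CPM at covered positions is 8, 10 and 12
  fr <- data.frame(ref = "chr", strand = "+", start = 10L, end = 60L,
                   five_prime = 10L, stringsAsFactors = FALSE)
  libs <- list(r1 = fr, r2 = fr, r3 = fr)
  sizes <- c(1e6 / 8, 1e6 / 10, 1e6 / 12)
  cov <- coverage_profile(libs, sizes, "chr", "+", 10L, 12L)
  expect_equal(cov$mean_cpm, rep(10, 2))
  expect_equal(cov$sem_cpm, rep(sd(c(8, 10, 12)) / sqrt(3), 2))
  expect_equal(cov$sem_cpm, rep(2 / sqrt(3), 2))
  # equal replicates give SEM 0; single replicate reports SEM 0
  cov2 <- coverage_profile(libs, rep(1e5, 3), "chr", "+", 10L, 11L)
  expect_equal(cov2$sem_cpm, 0)
  cov3 <- coverage_profile(libs[1], sizes[1], "chr", "+", 10L, 11L)
  expect_equal(cov3$sem_cpm, 0)
  expect_error(coverage_profile(libs, sizes, "chr", "+", 10L, 10L),
               "empty region")
})
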