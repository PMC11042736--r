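# Independent oracles used to pin expected values. These deliberately
# re-derive each quantity by the most literal route available (loops,
# grids, closed forms) and share no code with the package internals.

# Textbook Benjamini-Hochberg step-up, computed by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Naive step-by-step TMM: explicit loops, sort-based trimming.
oracle_tmm <- function(counts, lib_sizes, trim_m = 0.30, trim_a = 0.05) {
  q75 <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    q75[j] <- stats::quantile(counts[, j], 0.75) / lib_sizes[j]
  }
  ref <- which.min(abs(q75 - mean(q75)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    m_vals <- a_vals <- v_vals <- numeric(0)
    for (p in seq_len(nrow(counts))) {
      yo <- counts[p, j]; yr <- counts[p, ref]
      if (yo > 0 && yr > 0) {
        m_vals <- c(m_vals, log2((yo / lib_sizes[j]) / (yr / lib_sizes[ref])))
        a_vals <- c(a_vals, 0.5 * log2((yo / lib_sizes[j]) *
                                         (yr / lib_sizes[ref])))
        v_vals <- c(v_vals, (lib_sizes[j] - yo) / (lib_sizes[j] * yo) +
                      (lib_sizes[ref] - yr) / (lib_sizes[ref] * yr))
      }
    }
    if (length(m_vals) == 0 || max(abs(m_vals)) < 1e-6) {
      f[j] <- 1
      next
    }
    n <- length(m_vals)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    rm_ <- rank(m_vals); ra_ <- rank(a_vals)
    keep <- which(rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a)
    if (length(keep) == 0) {
      f[j] <- 1
    } else {
      num <- 0; den <- 0
      for (i in keep) {
        num <- num + m_vals[i] / v_vals[i]
        den <- den + 1 / v_vals[i]
      }
      f[j] <- 2^(num / den)
    }
  }
  f / exp(mean(log(f)))
}

# NB log-likelihood of one group at scalar mean m under offsets.
oracle_nb_group_ll <- function(y, e_off, m, phi) {
  mu <- m * e_off
  if (phi < 1e-10) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
}

# Maximize the group-mean likelihood by dense grid search over log-mean,
# refined by optimize() on the bracketing interval.
oracle_nb_group_max <- function(y, e_off, phi) {
  hi <- max(sum(y) / sum(e_off) * 4, 1)
  grid <- exp(seq(log(1e-4), log(hi + 1), length.out = 3000))
  ll <- vapply(grid, function(m) oracle_nb_group_ll(y, e_off, m, phi),
               numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1, 1)]; up <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(function(m) oracle_nb_group_ll(y, e_off, m, phi),
                         lower = lo, upper = up, maximum = TRUE,
                         tol = 1e-12)
  opt$objective
}

# LRT statistic by brute-force likelihood maximization.
oracle_nb_lrt_stat <- function(y, x, offsets, phi) {
  e_off <- exp(offsets)
  ll_full <- oracle_nb_group_max(y[x == 0], e_off[x == 0], phi) +
    oracle_nb_group_max(y[x == 1], e_off[x == 1], phi)
  ll_null <- oracle_nb_group_max(y, e_off, phi)
  max(2 * (ll_full - ll_null), 0)
}

# Closed-form Poisson deviance LRT for a two-group design with offsets.
oracle_poisson_lrt_stat <- function(y, x, offsets) {
  e_off <- exp(offsets)
  m0 <- sum(y[x == 0]) / sum(e_off[x == 0])
  m1 <- sum(y[x == 1]) / sum(e_off[x == 1])
  mn <- sum(y) / sum(e_off)
  mu_full <- ifelse(x == 1, m1, m0) * e_off
  mu_null <- mn * e_off
  ok <- y > 0
  2 * sum(y[ok] * log(mu_full[ok] / mu_null[ok]))
}

# Minimal EndCountTable builder for statistics tests.
make_table <- function(counts, conditions,
                       rpph = rep(TRUE, ncol(counts)),
                       lib_sizes = colSums(counts),
                       axis = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("L", seq_len(ncol(counts)))
  }
  if (is.null(axis)) {
    axis <- data.frame(ref = "chr", strand = "+",
                       pos = seq_len(nrow(counts)) - 1L,
                       stringsAsFactors = FALSE)
  }
  meta <- data.frame(library = colnames(counts), condition = conditions,
                     replicate = stats::ave(seq_len(ncol(counts)),
                                            conditions, FUN = seq_along),
                     rpph = rpph, stringsAsFactors = FALSE)
  cleavemap:::new_end_count_table(axis, counts, lib_sizes, meta)
}

# Two-reference toy genome with annotated CDS and tRNA genes, built in
# code so coordinate conventions are explicit in the tests.
make_toy_genome <- function() {
  set.seed(42)
  base <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  # plus-strand tRNA at [100,176): anticodon TTT at transcript 33..35
  trna_plus <- sample(c("A", "C", "G", "T"), 76, replace = TRUE)
  trna_plus[34:36] <- c("T", "T", "T")
  # minus-strand tRNA at [220,296): identical transcript sequence
  seq_chars <- strsplit(base, NULL)[[1]]
  seq_chars[101:176] <- trna_plus
  rc <- rev(chartr("ACGT", "TGCA", trna_plus))
  seq_chars[221:296] <- rc
  genome <- cleavemap:::new_genome_bundle(
    sequences = c(chrT = paste(seq_chars, collapse = "")),
    features = data.frame(
      name = c("lysT", "lysW", "cdsA"),
      ref = "chrT",
      start = c(100L, 220L, 300L), end = c(176L, 296L, 360L),
      strand = c("+", "-", "+"),
      feature_class = c("tRNA", "tRNA", "CDS"),
      stringsAsFactors = FALSE),
    trna_index = data.frame(
      name = c("lysT", "lysW"), anticodon = c("TTT", "TTT"),
      n1_offset = c(33L, 33L), stringsAsFactors = FALSE))
  genome
}

# Write a SAM file from a record data.frame (1-based pos fields).
write_sam <- function(records, refs, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar,
          r$rnext, r$pnext, r$tlen, r$seq, r$qual, sep = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  path
}

sam_rec <- function(qname, flag, rname, pos, cigar, rnext = "*",
                    pnext = 0, tlen = 0, mapq = 42, width = NULL) {
  if (is.null(width)) {
    width <- sum(as.integer(
      regmatches(cigar, gregexpr("[0-9]+(?=M)", cigar, perl = TRUE))[[1]]))
  }
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
             tlen = tlen, seq = strrep("A", width),
             qual = strrep("I", width), stringsAsFactors = FALSE)
}
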