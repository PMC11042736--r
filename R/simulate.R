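#' @title Synthetic fixtures with implanted cleavage sites and TSSs
#' @name synthetic_data
#' @description
#' The generator emulates the statistical structure the enrichment test
#' assumes: a small genome with embedded CDS, rRNA and tRNA genes
#' (anticodons drawn from a supplied list rich in uridines, and at least
#' one pair of byte-identical tRNA genes to exercise collapsing);
#' background fragmentation 5' ends spread over transcripts; TSS peaks
#' present in both conditions but enriched in RppH-treated libraries;
#' and condition-specific cleavage 5' ends implanted at anticodon-loop
#' positions of tRNAs, with negative-binomial replicate noise throughout.
#' Every stage is reproducible from a single seed.
NULL

SIM_STAGES <- c("reference", "abundance", "implants", "counts",
                "alignments")

stage_seed <- function(seed, stage) {
  i <- match(stage, SIM_STAGES)
  as.integer((as.numeric(seed) + i * 1299709) %% 2147483562)
}

#' Simulation configuration
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param ref_length Reference length in nt (default 20000).
#' @param n_cds Number of CDS genes (default 20).
#' @param n_trna Number of tRNA genes (default 12), one extra identical
#'   copy of the first tRNA is always added to exercise collapsing.
#' @param anticodons Anticodon pool (DNA alphabet); defaults to the
#'   uridine-rich set TTT/TTC/TTG/TGT plus common others.
#' @param n_replicates Replicates per condition (default 3).
#' @param rpph_minus_replicates Untreated (RppH-) nontargeting
#'   replicates for the TSS contrast (default 3; 0 disables).
#' @param depth Expected background fragments per library (default 1e6,
#'   so that the 10-CPM filter corresponds to about 10 counts as in
#'   deeply sequenced libraries; alignment-level fixtures are usually
#'   generated at a smaller, explicitly requested depth).
#' @param dispersion NB dispersion shared by all positions (default 0.15).
#' @param implanted_cleavage data.frame(trna, loop_position, log2_effect,
#'   base_mean) or NULL.
#' @param implanted_tss data.frame(ref, strand, pos, strength,
#'   rpph_enrichment, targeting_log2_effect) or NULL.
#' @param frac_n1 Fraction of default cleavage implants placed at the
#'   first anticodon nucleotide (default 0.7).
#' @param read_length Read length of simulated pairs (default 35).
#' @param fragment_length Simulated fragment length (default 50).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ref_length = 20000L, n_cds = 20L,
                       n_trna = 12L,
                       anticodons = c("TTT", "TTC", "TTG", "TGT",
                                      "GTT", "CAT", "GCC", "TAC"),
                       n_replicates = 3L, rpph_minus_replicates = 3L,
                       depth = 1e6, dispersion = 0.15,
                       implanted_cleavage = NULL, implanted_tss = NULL,
                       frac_n1 = 0.7, read_length = 35L,
                       fragment_length = 50L) {
  stopifnot(depth > 0, dispersion >= 0, n_replicates >= 1,
            fragment_length >= read_length)
  structure(as.list(environment()), class = "sim_config")
}

TRNA_LEN <- 76L
TRNA_N1_OFFSET <- 33L  # 0-based transcript offset of the first anticodon nt

AA3 <- c(A = "ala", R = "arg", N = "asn", D = "asp", C = "cys",
         Q = "gln", E = "glu", G = "gly", H = "his", I = "ile",
         L = "leu", K = "lys", M = "met", F = "phe", P = "pro",
         S = "ser", T = "thr", W = "trp", Y = "tyr", V = "val",
         `*` = "sup")

anticodon_gene_prefix <- function(anticodon) {
  codon <- revcomp(anticodon)
  aa <- Biostrings::GENETIC_CODE[[codon]]
  unname(AA3[aa])
}

#' Generate a synthetic genome with annotated CDS, rRNA and tRNA genes
#'
#' Genes are packed left to right with fixed margins; tRNAs alternate
#' between strands, carry their declared anticodon at the annotated
#' offset, and the first tRNA is duplicated verbatim under the next
#' suffix letter so that [collapse_identical_trnas()] has work to do.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, `genome.fasta` and
#'   `annotation.bed` are written there.
#' @return A `GenomeBundle`.
#' @export
generate_reference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "reference"))
  margin <- 100L; gap <- 60L
  cds_len <- 300L; rrna_len <- 400L

  n_genes <- config$n_cds + config$n_trna + 1L + 1L  # + duplicate + rRNA
  need <- margin * 2L + config$n_cds * (cds_len + gap) +
    (config$n_trna + 1L) * (TRNA_LEN + gap) + rrna_len + gap
  if (need > config$ref_length) {
    stop("reference too short to pack ", n_genes, " genes (need ",
         need, " nt, have ", config$ref_length, ")")
  }
  seq_chars <- sample(c("A", "C", "G", "T"), config$ref_length,
                      replace = TRUE)

  feats <- list(); trna <- list()
  cursor <- margin
  place <- function(len) {
    s <- cursor; cursor <<- cursor + len + gap; c(s, s + len)
  }

  # tRNA gene bodies: random, anticodon written at offsets 33..35
  ac_pool <- rep_len(config$anticodons, config$n_trna)
  suffixes <- c("T", "U", "V", "W", "X", "Y", "Z", LETTERS)
  prefix_count <- list()
  trna_seqs <- character(config$n_trna + 1L)
  trna_names <- character(config$n_trna + 1L)
  acs <- character(config$n_trna + 1L)
  for (i in seq_len(config$n_trna)) {
    body <- sample(c("A", "C", "G", "T"), TRNA_LEN, replace = TRUE)
    body[TRNA_N1_OFFSET + 1:3] <- strsplit(ac_pool[i], NULL)[[1L]]
    trna_seqs[i] <- paste(body, collapse = "")
    acs[i] <- ac_pool[i]
  }
  # identical copy of the first tRNA
  trna_seqs[config$n_trna + 1L] <- trna_seqs[1L]
  acs[config$n_trna + 1L] <- acs[1L]
  for (i in seq_len(config$n_trna + 1L)) {
    pre <- anticodon_gene_prefix(acs[i])
    k <- (prefix_count[[pre]] %||% 0L) + 1L
    prefix_count[[pre]] <- k
    trna_names[i] <- paste0(pre, suffixes[k])
  }

  for (i in seq_len(config$n_cds)) {
    iv <- place(cds_len)
    feats[[length(feats) + 1L]] <- data.frame(
      name = sprintf("cds%03d", i), ref = "chrS",
      start = iv[1L], end = iv[2L], strand = "+",
      feature_class = "CDS", stringsAsFactors = FALSE)
  }
  iv <- place(rrna_len)
  feats[[length(feats) + 1L]] <- data.frame(
    name = "rrsX", ref = "chrS", start = iv[1L], end = iv[2L],
    strand = "+", feature_class = "rRNA", stringsAsFactors = FALSE)
  for (i in seq_len(config$n_trna + 1L)) {
    iv <- place(TRNA_LEN)
    strand <- if (i %% 2L == 0L) "-" else "+"
    feats[[length(feats) + 1L]] <- data.frame(
      name = trna_names[i], ref = "chrS", start = iv[1L], end = iv[2L],
      strand = strand, feature_class = "tRNA", stringsAsFactors = FALSE)
    gene <- trna_seqs[i]
    if (strand == "-") gene <- revcomp(gene)
    seq_chars[(iv[1L] + 1L):iv[2L]] <- strsplit(gene, NULL)[[1L]]
    trna[[length(trna) + 1L]] <- data.frame(
      name = trna_names[i], anticodon = acs[i],
      n1_offset = TRNA_N1_OFFSET, stringsAsFactors = FALSE)
  }

  bundle <- new_genome_bundle(
    sequences = c(chrS = paste(seq_chars, collapse = "")),
    features = do.call(rbind, feats),
    trna_index = do.call(rbind, trna))
  validate_features(bundle$features, bundle$sequences)
  check_anticodons(bundle$trna_index,
                   bundle$features[bundle$features$feature_class == "tRNA", ],
                   bundle$sequences)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genome(bundle, file.path(dir, "genome.fasta"))
    write_annotation(bundle, file.path(dir, "annotation.bed"))
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default cleavage implants at tRNA anticodon-loop positions
#'
#' Picks `n` distinct (tRNA, loop position) pairs, preferring tRNAs
#' whose anticodon carries at least two uridines (the preferred
#' substrate class), with a `frac_n1` share placed at the first
#' anticodon nucleotide and the rest spread over the other loop
#' positions.
#'
#' @param genome A `GenomeBundle` from [generate_reference()].
#' @param config A [sim_config()] (supplies seed, frac_n1).
#' @param n Number of implants (default 20).
#' @param log2_effect Targeting enrichment in log2 units (default 6).
#' @param base_mean Expected nontargeting count (default 50).
#' @return data.frame(trna, loop_position, log2_effect, base_mean).
#' @export
default_cleavage_implants <- function(genome, config, n = 20L,
                                      log2_effect = 6, base_mean = 50) {
  set.seed(stage_seed(config$seed, "implants"))
  idx <- genome$trna_index
  u_rich <- idx$name[vapply(strsplit(idx$anticodon, NULL),
                            function(ch) sum(ch == "T") >= 2L,
                            logical(1))]
  pool <- if (length(u_rich) > 0L) u_rich else idx$name
  cand <- expand.grid(trna = pool, loop_position = 32:38,
                      stringsAsFactors = FALSE)
  # drop pairs that collide on genomic position (identical-copy genes
  # occupy distinct loci, so only exact duplicates within a gene matter)
  n <- min(n, nrow(cand))
  n_n1 <- round(config$frac_n1 * n)
  at_n1 <- cand[cand$loop_position == 34L, , drop = FALSE]
  off_n1 <- cand[cand$loop_position != 34L, , drop = FALSE]
  pick <- rbind(
    at_n1[sample(nrow(at_n1), min(n_n1, nrow(at_n1))), , drop = FALSE],
    off_n1[sample(nrow(off_n1), n - min(n_n1, nrow(at_n1))), ,
           drop = FALSE])
  pick$log2_effect <- log2_effect
  pick$base_mean <- base_mean
  rownames(pick) <- NULL
  pick
}

resolve_cleavage_implants <- function(implants, genome) {
  if (is.null(implants) || nrow(implants) == 0L) {
    return(data.frame(trna = character(), loop_position = integer(),
                      ref = character(), strand = character(),
                      pos = integer(), log2_effect = numeric(),
                      base_mean = numeric(), stringsAsFactors = FALSE))
  }
  out <- implants
  out$ref <- NA_character_; out$strand <- NA_character_
  out$pos <- NA_integer_
  for (i in seq_len(nrow(out))) {
    spec <- anticodon_spec(genome, out$trna[i])
    out$ref[i] <- spec$ref
    out$strand[i] <- spec$strand
    out$pos[i] <- spec$loop_genomic[out$loop_position[i] - 31L]
  }
  if (anyDuplicated(paste(out$ref, out$strand, out$pos))) {
    stop("cleavage implants collide on a genomic position")
  }
  out
}

#' Simulate per-position 5'-end count tables with ground truth
#'
#' Background 5' ends are distributed over transcript positions
#' proportional to lognormal per-feature abundances (uniform within a
#' feature, on the feature's strand). Implanted TSS positions receive
#' concentrated mass in both conditions, multiplied by
#' `rpph_enrichment` in RppH-treated libraries; implanted cleavage
#' positions receive `base_mean x 2^log2_effect` in targeting libraries
#' and `base_mean` elsewhere. Replicate counts are drawn
#' NB(mean, dispersion).
#'
#' @param config A [sim_config()].
#' @param genome A `GenomeBundle` from [generate_reference()].
#' @return List: `table` (an `EndCountTable`), `truth` (implant records
#'   with genomic coordinates and expected per-library means).
#' @export
simulate_counts <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "GenomeBundle"))
  set.seed(stage_seed(config$seed, "abundance"))
  feats <- genome$features
  abundance <- stats::rlnorm(nrow(feats), meanlog = 0, sdlog = 1)

  # background mean per feature position
  pos_list <- lapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    data.frame(ref = f$ref, strand = f$strand, pos = f$start:(f$end - 1L),
               w = abundance[i], stringsAsFactors = FALSE)
  })
  bg <- do.call(rbind, pos_list)
  bg_mean <- config$depth * bg$w / sum(bg$w)

  libs <- library_design(config)
  mean_mat <- matrix(rep(bg_mean, nrow(libs)), ncol = nrow(libs),
                     dimnames = list(NULL, libs$library))
  axis <- bg[, c("ref", "strand", "pos")]

  upsert_row <- function(ref, strand, pos) {
    i <- which(axis$ref == ref & axis$strand == strand & axis$pos == pos)
    if (length(i) == 1L) return(i)
    axis <<- rbind(axis, data.frame(ref = ref, strand = strand, pos = pos,
                                    stringsAsFactors = FALSE))
    mean_mat <<- rbind(mean_mat, 0)
    nrow(axis)
  }

  cleav <- resolve_cleavage_implants(config$implanted_cleavage, genome)
  for (i in seq_len(nrow(cleav))) {
    r <- upsert_row(cleav$ref[i], cleav$strand[i], cleav$pos[i])
    m <- cleav$base_mean[i]
    mean_mat[r, ] <- mean_mat[r, ] +
      ifelse(libs$condition == "targeting", m * 2^cleav$log2_effect[i], m)
  }
  tss <- config$implanted_tss
  if (!is.null(tss) && nrow(tss) > 0L) {
    if (is.null(tss$targeting_log2_effect)) tss$targeting_log2_effect <- 0
    for (i in seq_len(nrow(tss))) {
      r <- upsert_row(tss$ref[i], tss$strand[i], tss$pos[i])
      m <- tss$strength[i] *
        ifelse(libs$rpph, tss$rpph_enrichment[i], 1) *
        ifelse(libs$condition == "targeting",
               2^tss$targeting_log2_effect[i], 1)
      mean_mat[r, ] <- mean_mat[r, ] + m
    }
  } else {
    tss <- data.frame(ref = character(), strand = character(),
                      pos = integer(), strength = numeric(),
                      rpph_enrichment = numeric(),
                      targeting_log2_effect = numeric())
  }

  set.seed(stage_seed(config$seed, "counts"))
  counts <- matrix(0L, nrow(mean_mat), ncol(mean_mat),
                   dimnames = dimnames(mean_mat))
  for (j in seq_len(ncol(mean_mat))) {
    counts[, j] <- if (config$dispersion < 1e-10) {
      stats::rpois(nrow(mean_mat), mean_mat[, j])
    } else {
      stats::rnbinom(nrow(mean_mat), mu = mean_mat[, j],
                     size = 1 / config$dispersion)
    }
  }
  observed <- rowSums(counts) > 0L
  o <- order(axis$ref, axis$strand, axis$pos)
  keep <- o[observed[o]]
  table <- new_end_count_table(axis[keep, , drop = FALSE],
                               counts[keep, , drop = FALSE],
                               lib_sizes = colSums(counts),
                               meta = libs)
  truth <- list(cleavage = cleav, tss = tss,
                expected_means = mean_mat[c(
                  vapply(seq_len(nrow(cleav)), function(i)
                    which(axis$ref == cleav$ref[i] &
                          axis$strand == cleav$strand[i] &
                          axis$pos == cleav$pos[i]), integer(1))), ,
                  drop = FALSE])
  list(table = table, truth = truth)
}

library_design <- function(config) {
  n <- config$n_replicates
  m <- config$rpph_minus_replicates
  data.frame(
    library = c(paste0("T", seq_len(n)), paste0("NT", seq_len(n)),
                if (m > 0L) paste0("NTminus", seq_len(m))),
    condition = c(rep("targeting", n), rep("nontargeting", n),
                  rep("nontargeting", m)),
    replicate = c(seq_len(n), seq_len(n), seq_len(m)),
    rpph = c(rep(TRUE, 2L * n), rep(FALSE, m)),
    stringsAsFactors = FALSE)
}

#' Emit SAM files realizing a simulated count table
#'
#' Every counted 5' end becomes one properly paired 2 x `read_length`
#' fragment of length `fragment_length` whose 5'-most base sits at the
#' counted position, so that [fragments_from_alignments()] followed by
#' [count_five_prime_ends()] reproduces the table exactly.
#'
#' @param config A [sim_config()].
#' @param genome A `GenomeBundle`.
#' @param table The `EndCountTable` from [simulate_counts()].
#' @param dir Output directory; one `<library>.sam` per library.
#' @return Named character vector of SAM paths.
#' @export
simulate_alignments <- function(config, genome, table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rl <- config$read_length
  fl <- config$fragment_length
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$sequences),
                      nchar(genome$sequences)))
  paths <- character(ncol(table$counts))
  names(paths) <- colnames(table$counts)
  for (j in seq_len(ncol(table$counts))) {
    lib <- colnames(table$counts)[j]
    cnt <- table$counts[, j]
    rows <- rep(seq_len(nrow(table$axis)), cnt)
    lines <- character(0)
    if (length(rows) > 0L) {
      ax <- table$axis[rows, , drop = FALSE]
      reflen <- nchar(genome$sequences)[ax$ref]
      plus <- ax$strand == "+"
      flen <- ifelse(plus, pmin(fl, reflen - ax$pos),
                     pmin(fl, ax$pos + 1L))
      flen <- pmax(flen, rl)
      left <- ifelse(plus, ax$pos, ax$pos - flen + 1L)
      qn <- sprintf("%s_frag%07d", lib, seq_along(rows))
      r1_pos <- ifelse(plus, left, left + flen - rl) + 1L
      r2_pos <- ifelse(plus, left + flen - rl, left) + 1L
      r1_flag <- ifelse(plus, 99L, 83L)
      r2_flag <- ifelse(plus, 147L, 163L)
      r1_tlen <- ifelse(plus, flen, -flen)
      seq_at <- function(p1) substr_vec(genome$sequences, ax$ref, p1, rl)
      qual <- strrep("I", rl)
      cig <- paste0(rl, "M")
      lines <- c(
        sprintf("%s\t%d\t%s\t%d\t42\t%s\t=\t%d\t%d\t%s\t%s",
                qn, r1_flag, ax$ref, r1_pos, cig, r2_pos, r1_tlen,
                seq_at(r1_pos), qual),
        sprintf("%s\t%d\t%s\t%d\t42\t%s\t=\t%d\t%d\t%s\t%s",
                qn, r2_flag, ax$ref, r2_pos, cig, r1_pos, -r1_tlen,
                seq_at(r2_pos), qual))
    }
    paths[j] <- file.path(dir, paste0(lib, ".sam"))
    writeLines(c(header, lines), paths[j])
  }
  paths
}

substr_vec <- function(sequences, refs, start1, width) {
  substring(sequences[refs], start1, start1 + width - 1L)
}
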