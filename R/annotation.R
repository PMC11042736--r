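#' @title Interpretive products: feature assignment, anticodon profiles,
#'   logos, volcano tables and set intersections
#' @name downstream_annotation
NULL

#' Assign called sites to annotated features
#'
#' Each site is labeled with the overlapping feature on the same strand
#' and its class. Sites overlapping no same-strand feature are labeled
#' `intergenic` (this includes antisense hits to an opposite-strand
#' feature). When several features overlap, the one whose start is
#' nearest to the site wins; ambiguity is reported via `message()`.
#'
#' @param site_set A `SiteSet` (or any data.frame with ref/strand/pos).
#' @param genome A `GenomeBundle` with annotation.
#' @return The `SiteSet` with `feature` and `feature_class` filled in.
#' @export
assign_sites_to_features <- function(site_set, genome) {
  feats <- genome$features
  for (i in seq_len(nrow(site_set))) {
    s <- site_set[i, ]
    hit <- feats$ref == s$ref & feats$strand == s$strand &
      feats$start <= s$pos & feats$end > s$pos
    if (!any(hit)) {
      site_set$feature[i] <- "intergenic"
      site_set$feature_class[i] <- "intergenic"
      next
    }
    h <- feats[hit, , drop = FALSE]
    if (nrow(h) > 1L) {
      h <- h[order(abs(s$pos - h$start), h$name), , drop = FALSE]
      message("site ", s$ref, ":", s$strand, ":", s$pos + 1L,
              " overlaps ", nrow(h), " features; assigned to ",
              h$name[1L])
    }
    site_set$feature[i] <- h$name[1L]
    site_set$feature_class[i] <- h$feature_class[1L]
  }
  site_set
}

#' Anticodon-loop enrichment profile across tRNA groups
#'
#' For every collapsed tRNA group, the seven anticodon-loop offsets
#' (tRNA positions 32-38; anticodon N1-N3 at 34-36) are mapped to
#' genomic positions strand-aware, and the log2 fold change and
#' -log10(FDR) of the corresponding 5'-end positions are collected from
#' a `DiffResult`. Positions dropped by the CPM filter are absent (NA),
#' not zero-filled. The aggregate row averages groups with data at each
#' loop position.
#'
#' @param diff_result A `DiffResult`.
#' @param genome A `GenomeBundle` with tRNA annotation.
#' @return List with matrices `log2fc` and `neg_log10_fdr`
#'   (groups + "aggregate" x loop positions 32..38), and
#'   `anticodon_positions` (column indices of N1..N3).
#' @export
anticodon_loop_profile <- function(diff_result, genome) {
  groups <- collapse_identical_trnas(genome)
  key <- paste(diff_result$ref, diff_result$strand, diff_result$pos)
  loop_pos <- 32:38
  gnames <- sort(unique(groups))
  lfc <- fdr <- matrix(NA_real_, length(gnames), length(loop_pos),
                       dimnames = list(gnames, as.character(loop_pos)))
  for (g in gnames) {
    members <- names(groups)[groups == g]
    vals_l <- vals_f <- matrix(NA_real_, length(members), 7L)
    for (m in seq_along(members)) {
      spec <- tryCatch(anticodon_spec(genome, members[m]),
                       error = function(e) NULL)
      if (is.null(spec)) {
        warning("tRNA ", members[m], " lacks an anticodon record; skipped")
        next
      }
      i <- match(paste(spec$ref, spec$strand, spec$loop_genomic), key)
      vals_l[m, ] <- diff_result$log2fc[i]
      vals_f[m, ] <- -log10(diff_result$fdr[i])
    }
    lfc[g, ] <- colMeans(vals_l, na.rm = TRUE)
    fdr[g, ] <- colMeans(vals_f, na.rm = TRUE)
  }
  lfc[is.nan(lfc)] <- NA_real_
  fdr[is.nan(fdr)] <- NA_real_
  agg <- function(m) colMeans(m, na.rm = TRUE)
  lfc <- rbind(lfc, aggregate = agg(lfc))
  fdr <- rbind(fdr, aggregate = agg(fdr))
  lfc[is.nan(lfc)] <- NA_real_
  fdr[is.nan(fdr)] <- NA_real_
  list(log2fc = lfc, neg_log10_fdr = fdr,
       loop_positions = loop_pos, anticodon_positions = 3:5)
}

#' Position frequency matrix around called cleavage sites
#'
#' A called 5' end at position p marks a cut of the phosphodiester bond
#' 5' of p in transcript orientation; the window covers the `flank`
#' nucleotides upstream of the scissile bond and `flank` downstream
#' (the cleaved base first), reverse-complemented for minus-strand
#' sites. Sites too close to a sequence edge are dropped and counted in
#' attribute `n_dropped`.
#'
#' @param site_set A `SiteSet`.
#' @param genome A `GenomeBundle`.
#' @param flank Nucleotides on each side of the bond (default 5).
#' @return 4 x 2*flank matrix of A/C/G/T frequencies (columns sum to 1),
#'   with attributes `n_sites` and `n_dropped`.
#' @export
build_logo_matrix <- function(site_set, genome, flank = 5L) {
  nts <- c("A", "C", "G", "T")
  width <- 2L * flank
  counts <- matrix(0, 4L, width,
                   dimnames = list(nts, seq_len(width) - flank - 1L))
  n_used <- 0L; n_dropped <- 0L
  for (i in seq_len(nrow(site_set))) {
    s <- site_set[i, ]
    L <- nchar(genome$sequences[[s$ref]])
    if (s$strand == "+") {
      from <- s$pos - flank; to <- s$pos + flank - 1L
      if (from < 0L || to >= L) { n_dropped <- n_dropped + 1L; next }
      w <- substr(genome$sequences[[s$ref]], from + 1L, to + 1L)
    } else {
      from <- s$pos - flank + 1L; to <- s$pos + flank
      if (from < 0L || to >= L) { n_dropped <- n_dropped + 1L; next }
      w <- revcomp(substr(genome$sequences[[s$ref]], from + 1L, to + 1L))
    }
    ch <- strsplit(w, NULL)[[1L]]
    hit <- match(ch, nts)
    ok <- !is.na(hit)
    counts[cbind(hit[ok], which(ok))] <-
      counts[cbind(hit[ok], which(ok))] + 1
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("all sites fell too close to a sequence edge")
  freq <- sweep(counts, 2L, colSums(counts), "/")
  attr(freq, "n_sites") <- n_used
  attr(freq, "n_dropped") <- n_dropped
  freq
}

#' Volcano export table
#'
#' One row per tested position with the coordinates of the volcano
#' plot: log2 fold change, -log10(FDR), assigned feature class, and
#' flags for the two calling thresholds (within the top-N FDR cutoff;
#' log2fc strictly above the fold-change line).
#'
#' @param diff_result A `DiffResult`, ideally feature-annotated via
#'   [assign_sites_to_features()].
#' @param genome Optional `GenomeBundle` used to annotate when the
#'   result carries no feature columns.
#' @param config A [model_config()].
#' @return data.frame ordered by FDR.
#' @export
volcano_table <- function(diff_result, genome = NULL,
                          config = model_config()) {
  df <- as.data.frame(diff_result)
  if (nrow(df) == 0L) {
    return(cbind(df, neg_log10_fdr = numeric(0), in_top_n = logical(0),
                 above_lfc = logical(0)))
  }
  if (is.null(df$feature) && !is.null(genome)) {
    df$feature <- NA_character_; df$feature_class <- NA_character_
    df <- assign_sites_to_features(df, genome)
  }
  df <- df[rank_order(df), , drop = FALSE]
  rownames(df) <- NULL
  df$neg_log10_fdr <- -log10(df$fdr)
  df$in_top_n <- seq_len(nrow(df)) <= config$top_n
  # positions tied with the top_n-th FDR sit on the cutoff line
  if (nrow(df) > config$top_n) {
    cut_fdr <- df$fdr[config$top_n]
    df$on_cutoff <- df$fdr == cut_fdr
  } else {
    df$on_cutoff <- FALSE
  }
  df$above_lfc <- clamp_lfc(df$log2fc) > config$lfc_threshold
  df
}

#' Intersect cleavage-site sets from several experiments by transcript
#'
#' Sites are first mapped to transcripts: tRNA sites to their collapsed
#' tRNA group (identical multi-copy genes count once), other sites to
#' their feature name. Intersection is computed on transcript identity
#' rather than exact position, because the same RNA may be cleaved at
#' different positions in different experiments.
#'
#' @param site_sets Named list (>= 2) of feature-annotated `SiteSet`s.
#' @param genome A `GenomeBundle` with tRNA annotation.
#' @return List: `membership` (logical matrix transcripts x sets) and
#'   `region_counts` (named counts per Venn region, names like "A&B";
#'   they sum to the union size).
#' @export
intersect_experiments <- function(site_sets, genome) {
  if (length(site_sets) < 2L) stop("need at least two site sets")
  if (is.null(names(site_sets)) || anyDuplicated(names(site_sets))) {
    stop("site sets must have unique names")
  }
  groups <- collapse_identical_trnas(genome)
  to_transcripts <- function(s) {
    if (nrow(s) == 0L) return(character(0))
    if (any(is.na(s$feature))) {
      stop("site set must be feature-annotated first")
    }
    tx <- ifelse(s$feature_class == "tRNA",
                 unname(groups[s$feature]), s$feature)
    unique(tx)
  }
  txs <- lapply(site_sets, to_transcripts)
  all_tx <- sort(unique(unlist(txs)))
  membership <- vapply(txs, function(t) all_tx %in% t,
                       logical(length(all_tx)))
  membership <- matrix(membership, nrow = length(all_tx),
                       dimnames = list(all_tx, names(site_sets)))
  pattern <- apply(membership, 1L, function(r)
    paste(colnames(membership)[r], collapse = "&"))
  region_counts <- table(pattern)
  list(membership = membership,
       region_counts = stats::setNames(as.integer(region_counts),
                                       names(region_counts)))
}
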