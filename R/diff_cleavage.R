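#' @title Cleavage-site and TSS calling from 5'-end count tables
#' @name diff_cleavage
NULL

#' Analysis configuration
#'
#' @param min_cpm CPM filter threshold (default 10): a position is kept
#'   when its raw-library-size CPM reaches `min_cpm` in at least
#'   `min_replicates` libraries of the enriched (targeting) condition.
#' @param min_replicates Number of enriched-condition replicates that
#'   must pass the CPM filter (default 3).
#' @param top_n Number of smallest-FDR positions considered for site
#'   calling (default 100).
#' @param lfc_threshold log2 fold-change cutoff applied after the top-N
#'   selection, strict inequality (default 4).
#' @param dispersion_mode "common" or "per-position-moment".
#' @param prior_count Fold-change shrinkage prior (default 0).
#' @param trim_m,trim_a TMM trim fractions (defaults 0.30 / 0.05).
#' @param min_mapq Minimum mapping quality for fragment reconstruction.
#' @return A `model_config` list.
#' @export
model_config <- function(min_cpm = 10, min_replicates = 3, top_n = 100,
                         lfc_threshold = 4,
                         dispersion_mode = c("common",
                                             "per-position-moment"),
                         prior_count = 0, trim_m = 0.30, trim_a = 0.05,
                         min_mapq = 0) {
  stopifnot(min_cpm >= 0, top_n >= 1, is.finite(lfc_threshold),
            min_replicates >= 1, prior_count >= 0)
  structure(list(min_cpm = min_cpm, min_replicates = min_replicates,
                 top_n = top_n, lfc_threshold = lfc_threshold,
                 dispersion_mode = match.arg(dispersion_mode),
                 prior_count = prior_count,
                 trim_m = trim_m, trim_a = trim_a, min_mapq = min_mapq),
            class = "model_config")
}

#' Filter positions by CPM support in the enriched condition
#'
#' Positions with less than `min_cpm` counts per million mapped
#' fragments in fewer than `min_replicates` libraries of the enriched
#' condition are excluded. The criterion looks at the enriched
#' (targeting) libraries only; baseline libraries do not contribute.
#' CPM uses the raw library sizes (filtering precedes normalization).
#'
#' @param table An `EndCountTable` with condition metadata.
#' @param config A [model_config()].
#' @param enriched Logical vector marking the enriched-condition
#'   libraries; defaults to `condition == "targeting"` in the metadata.
#' @return The reduced `EndCountTable`.
#' @export
filter_positions <- function(table, config = model_config(),
                             enriched = NULL) {
  stopifnot(inherits(table, "EndCountTable"))
  if (is.null(enriched)) enriched <- table$meta$condition == "targeting"
  if (sum(enriched) < config$min_replicates) {
    stop("fewer enriched-condition libraries (", sum(enriched),
         ") than min_replicates (", config$min_replicates, ")")
  }
  cpm <- cpm_normalize(table$counts[, enriched, drop = FALSE],
                       table$lib_sizes[enriched])
  keep <- rowSums(cpm >= config$min_cpm) >= config$min_replicates
  subset_libraries(table, positions = keep)
}

#' Run the per-position enrichment test on a filtered table
#'
#' Chains the statistical recipe: TMM factors on the filtered counts,
#' offsets = log(library size x TMM factor), common NB dispersion by
#' Cox-Reid adjusted profile likelihood, per-position likelihood-ratio
#' test, and Benjamini-Hochberg correction over all retained positions.
#'
#' @param table A filtered `EndCountTable`.
#' @param config A [model_config()].
#' @param enriched Logical vector marking enriched-condition libraries;
#'   defaults to `condition == "targeting"`.
#' @return A `DiffResult` data.frame: ref, strand, pos, log2fc,
#'   lrt_stat, pvalue, fdr (plus `dispersion` attribute).
#' @export
run_enrichment_test <- function(table, config = model_config(),
                                enriched = NULL) {
  stopifnot(inherits(table, "EndCountTable"))
  if (is.null(enriched)) enriched <- table$meta$condition == "targeting"
  if (nrow(table$axis) == 0L) stop("no positions left to test")
  x <- as.integer(enriched)
  f <- tmm_factors(table$counts, table$lib_sizes,
                   trim_m = config$trim_m, trim_a = config$trim_a)
  offsets <- log(table$lib_sizes * f)
  phi <- estimate_dispersion(table$counts, x, offsets,
                             mode = config$dispersion_mode)
  res <- nb_lrt(table$counts, x, offsets, phi,
                prior_count = config$prior_count)
  out <- cbind(table$axis, res[, c("log2fc", "lrt_stat", "pvalue")])
  out$fdr <- bh_adjust(out$pvalue)
  attr(out, "dispersion") <- phi
  attr(out, "tmm_factors") <- f
  class(out) <- c("DiffResult", "data.frame")
  out
}

#' Full cleavage contrast: filter then test
#'
#' @param table An `EndCountTable` containing targeting and nontargeting
#'   libraries.
#' @param config A [model_config()].
#' @return A `DiffResult` (see [run_enrichment_test()]).
#' @export
test_cleavage <- function(table, config = model_config()) {
  filtered <- filter_positions(table, config)
  run_enrichment_test(filtered, config)
}

# Total ordering used everywhere a DiffResult or SiteSet is ranked:
# FDR ascending, then |log2fc| descending (non-finite fold changes
# clamped to +/-20), then reference / strand / position.
rank_order <- function(df) {
  order(df$fdr, -abs(clamp_lfc(df$log2fc)), df$ref, df$strand, df$pos,
        na.last = TRUE)
}

clamp_lfc <- function(lfc) {
  ifelse(is.infinite(lfc), sign(lfc) * 20, lfc)
}

#' Call sites from a DiffResult by the top-N / log2FC rule
#'
#' Positions are sorted by FDR ascending (ties: |log2fc| descending,
#' then genomic coordinate); the `top_n` best are selected and of those
#' only positions with log2fc strictly above `lfc_threshold` are kept,
#' so the result may be shorter than `top_n`, possibly empty.
#'
#' @param diff_result A `DiffResult`.
#' @param config A [model_config()].
#' @param site_type "cleavage" or "tss" (annotation only).
#' @return A `SiteSet` data.frame ordered by FDR, with attribute
#'   `site_type`.
#' @export
call_sites <- function(diff_result, config = model_config(),
                       site_type = c("cleavage", "tss")) {
  site_type <- match.arg(site_type)
  if (nrow(diff_result) == 0L) stop("empty DiffResult")
  df <- as.data.frame(diff_result)
  df <- df[!is.na(df$pvalue), , drop = FALSE]
  df <- df[rank_order(df), , drop = FALSE]
  top <- utils::head(df, config$top_n)
  sites <- top[clamp_lfc(top$log2fc) > config$lfc_threshold, , drop = FALSE]
  rownames(sites) <- NULL
  sites$feature <- rep(NA_character_, nrow(sites))
  sites$feature_class <- rep(NA_character_, nrow(sites))
  structure(sites, site_type = site_type,
            class = c("SiteSet", "data.frame"))
}

#' Call transcription start sites via the RppH treatment contrast
#'
#' Runs the identical machinery (CPM filter, TMM, dispersion, LRT, BH,
#' top-N calling) with the enriched role played by the RppH-treated
#' libraries, so that 5'-triphosphate (primary, TSS-derived) ends --
#' visible only after RppH conversion -- come out enriched over the
#' untreated libraries. Pass a table restricted to one biological
#' condition (typically nontargeting +/- RppH).
#'
#' @param table An `EndCountTable` whose metadata `rpph` flag separates
#'   treated from untreated libraries.
#' @param config A [model_config()].
#' @return A `SiteSet` with `site_type = "tss"` and the underlying
#'   `DiffResult` as attribute `diff_result`.
#' @export
call_tss <- function(table, config = model_config()) {
  stopifnot(inherits(table, "EndCountTable"))
  treated <- table$meta$rpph
  if (!any(treated) || !any(!treated)) {
    stop("call_tss needs both RppH-treated and untreated libraries")
  }
  filtered <- filter_positions(table, config, enriched = treated)
  diff <- run_enrichment_test(filtered, config,
                              enriched = filtered$meta$rpph)
  sites <- call_sites(diff, config, site_type = "tss")
  attr(sites, "diff_result") <- diff
  sites
}

#' Cross-check called TSSs against called cleavage sites
#'
#' Intersects the top-k (smallest FDR) strand-specific positions of the
#' two site sets. A small overlap indicates that condition-enriched 5'
#' ends are genuine cleavage products rather than newly activated
#' transcription starts.
#'
#' @param tss_sites,cleavage_sites `SiteSet`s (ordered by FDR).
#' @param k Number of top sites from each set to compare.
#' @return List: `n_shared`, and `shared` (data.frame ref/strand/pos).
#' @export
crosscheck_tss_vs_cleavage <- function(tss_sites, cleavage_sites,
                                       k = 1000) {
  topk <- function(s, label) {
    if (k > nrow(s)) {
      warning("k = ", k, " exceeds the ", label, " set (", nrow(s),
              "); using the whole set")
    }
    utils::head(as.data.frame(s), k)
  }
  a <- topk(tss_sites, "TSS")
  b <- topk(cleavage_sites, "cleavage")
  ka <- paste(a$ref, a$strand, a$pos)
  kb <- paste(b$ref, b$strand, b$pos)
  shared_keys <- intersect(ka, kb)
  shared <- a[match(shared_keys, ka), c("ref", "strand", "pos"),
              drop = FALSE]
  shared <- shared[order(shared$ref, shared$strand, shared$pos), ,
                   drop = FALSE]
  rownames(shared) <- NULL
  list(n_shared = length(shared_keys), shared = shared)
}
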