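#' @title Fragment reconstruction and strand-specific 5'-end counting
#' @name end_counting
#' @description
#' Sequencing fragments are reconstructed from alignments: a properly
#' paired read pair collapses to one fragment spanning its leftmost to
#' rightmost mapped base (strand taken from read 1), while an unpaired or
#' orphaned mapped read contributes one fragment equal to its alignment
#' span. The 5'-most base of each fragment (start on +, end - 1 on -)
#' marks a cleavage product or transcription start, and per-position
#' counts of these 5' ends, per strand and library, form the input of the
#' enrichment test.
NULL

#' Reconstruct fragments from a SAM/BAM file
#'
#' @param path Path to a SAM or BAM file (SAM text is converted on the fly).
#' @param min_mapq Minimum mapping quality; records below are skipped.
#' @param primary_only Drop secondary and supplementary alignments
#'   (default TRUE).
#' @param pair_collapse Collapse proper pairs to single fragments
#'   (default TRUE); when FALSE every mapped read is its own fragment.
#' @return data.frame with columns ref, strand, start, end (0-based
#'   half-open), five_prime (0-based position of the fragment 5' end).
#' @export
fragments_from_alignments <- function(path, min_mapq = 0,
                                      primary_only = TRUE,
                                      pair_collapse = TRUE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- as_bam_path(path)
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (primary_only) FALSE else NA,
    isSupplementaryAlignment = if (primary_only) FALSE else NA)
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = c("flag", "mapq", "mpos", "isize"))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  meta <- S4Vectors::mcols(aln)
  mapq <- meta$mapq
  mapq[is.na(mapq)] <- 0L
  keep <- mapq >= min_mapq
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(n_skipped, " alignment record(s) below min_mapq ", min_mapq,
            " skipped")
  }
  aln <- aln[keep]
  meta <- meta[keep, , drop = FALSE]
  if (length(aln) == 0L) return(empty_fragments())

  flag <- meta$flag
  paired <- bitwAnd(flag, 0x1L) > 0L
  proper <- paired & bitwAnd(flag, 0x2L) > 0L & !is.na(meta$isize) &
    meta$isize != 0L
  first <- bitwAnd(flag, 0x40L) > 0L
  st <- GenomicAlignments::start(aln) - 1L   # to 0-based
  en <- GenomicAlignments::end(aln)          # half-open end
  strand_chr <- as.character(GenomicAlignments::strand(aln))
  ref <- as.character(GenomicAlignments::seqnames(aln))

  frags <- list()
  if (pair_collapse) {
    # one fragment per proper pair, anchored on the first-of-pair record
    sel <- proper & first
    if (any(sel)) {
      left <- pmin(st[sel], meta$mpos[sel] - 1L)
      flen <- abs(meta$isize[sel])
      frags[[1L]] <- data.frame(
        ref = ref[sel], strand = strand_chr[sel],
        start = left, end = left + flen, stringsAsFactors = FALSE)
    }
    solo <- !proper
  } else {
    solo <- rep(TRUE, length(aln))
  }
  if (any(solo)) {
    frags[[length(frags) + 1L]] <- data.frame(
      ref = ref[solo], strand = strand_chr[solo],
      start = st[solo], end = en[solo], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, frags)
  if (is.null(out) || nrow(out) == 0L) return(empty_fragments())
  out$five_prime <- ifelse(out$strand == "+", out$start, out$end - 1L)
  rownames(out) <- NULL
  out
}

empty_fragments <- function() {
  data.frame(ref = character(), strand = character(), start = integer(),
             end = integer(), five_prime = integer(),
             stringsAsFactors = FALSE)
}

as_bam_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") return(path)
  dest <- tempfile(fileext = ".bam")
  Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                   overwrite = TRUE, indexDestination = FALSE)
}

#' Count fragment 5' ends per (reference, strand, position)
#'
#' @param fragment_list Named list of fragment data.frames (one per
#'   library), as returned by [fragments_from_alignments()].
#' @param meta data.frame with one row per library: columns `library`,
#'   `condition` ("targeting"/"nontargeting"), `replicate`, `rpph`
#'   (logical). Row order must match `fragment_list`.
#' @return An `EndCountTable`: sparse axis (positions observed in at
#'   least one library), integer count matrix, library sizes and metadata.
#' @export
count_five_prime_ends <- function(fragment_list, meta = NULL) {
  stopifnot(is.list(fragment_list), length(fragment_list) > 0L)
  if (is.null(names(fragment_list))) {
    names(fragment_list) <- paste0("lib", seq_along(fragment_list))
  }
  if (is.null(meta)) meta <- default_library_meta(names(fragment_list))
  stopifnot(nrow(meta) == length(fragment_list))

  keys <- lapply(fragment_list, function(fr)
    paste(fr$ref, fr$strand, fr$five_prime, sep = "\r"))
  all_keys <- sort(unique(unlist(keys, use.names = FALSE)))
  counts <- matrix(0L, nrow = length(all_keys), ncol = length(fragment_list),
                   dimnames = list(NULL, names(fragment_list)))
  for (j in seq_along(keys)) {
    tab <- table(keys[[j]])
    counts[match(names(tab), all_keys), j] <- as.integer(tab)
  }
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  axis <- data.frame(
    ref = vapply(parts, `[`, character(1), 1L),
    strand = vapply(parts, `[`, character(1), 2L),
    pos = as.integer(vapply(parts, `[`, character(1), 3L)),
    stringsAsFactors = FALSE)
  o <- order(axis$ref, axis$strand, axis$pos)
  new_end_count_table(axis[o, , drop = FALSE],
                      counts[o, , drop = FALSE],
                      lib_sizes = vapply(fragment_list, nrow, integer(1)),
                      meta = meta)
}

default_library_meta <- function(libs) {
  data.frame(library = libs, condition = NA_character_,
             replicate = seq_along(libs), rpph = TRUE,
             stringsAsFactors = FALSE)
}

new_end_count_table <- function(axis, counts, lib_sizes, meta) {
  stopifnot(nrow(axis) == nrow(counts), ncol(counts) == length(lib_sizes))
  rownames(axis) <- NULL
  structure(list(axis = axis, counts = counts,
                 lib_sizes = as.numeric(lib_sizes), meta = meta),
            class = "EndCountTable")
}

#' @export
print.EndCountTable <- function(x, ...) {
  cat("EndCountTable:", nrow(x$axis), "position(s) x",
      ncol(x$counts), "library(ies); library sizes",
      paste(x$lib_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Subset an EndCountTable to selected libraries or positions
#' @param table An `EndCountTable`.
#' @param libraries Library names or logical/integer index over columns.
#' @param positions Logical/integer index over axis rows.
#' @return A reduced `EndCountTable` (library sizes preserved).
#' @export
subset_libraries <- function(table, libraries = NULL, positions = NULL) {
  stopifnot(inherits(table, "EndCountTable"))
  if (!is.null(libraries)) {
    if (is.character(libraries)) {
      libraries <- match(libraries, colnames(table$counts))
      if (anyNA(libraries)) stop("unknown library name(s)")
    }
    table$counts <- table$counts[, libraries, drop = FALSE]
    table$lib_sizes <- table$lib_sizes[libraries]
    table$meta <- table$meta[libraries, , drop = FALSE]
  }
  if (!is.null(positions)) {
    table$axis <- table$axis[positions, , drop = FALSE]
    rownames(table$axis) <- NULL
    table$counts <- table$counts[positions, , drop = FALSE]
  }
  table
}

#' CPM-normalize a count matrix or EndCountTable
#'
#' Counts are scaled to counts per million mapped fragments using the
#' recorded library sizes (not column sums, so dropped positions do not
#' distort the scale).
#'
#' @param x An `EndCountTable` or a numeric matrix.
#' @param lib_sizes Library sizes (required when `x` is a matrix).
#' @return Numeric matrix of CPM values (same shape as the counts).
#' @export
cpm_normalize <- function(x, lib_sizes = NULL) {
  if (inherits(x, "EndCountTable")) {
    lib_sizes <- x$lib_sizes
    x <- x$counts
  }
  if (is.null(lib_sizes)) stop("lib_sizes required for a bare matrix")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(x, 2L, lib_sizes, "/") * 1e6
}

#' Per-position fragment coverage with cross-replicate mean and SEM
#'
#' Coverage counts, at every position of the requested region, the
#' fragments overlapping that position; values are CPM-normalized per
#' library and summarized as mean and standard error across replicates
#' (SEM = sd / sqrt(n); 0 when n = 1).
#'
#' @param fragment_list Named list of per-library fragment data.frames.
#' @param lib_sizes Total fragments per library (same order).
#' @param ref Reference id of the region.
#' @param strand Strand of the region ("+" or "-").
#' @param start,end Region interval, 0-based half-open.
#' @return data.frame: ref, strand, pos, per-library CPM columns,
#'   mean_cpm, sem_cpm.
#' @export
coverage_profile <- function(fragment_list, lib_sizes, ref, strand,
                             start, end) {
  if (end <= start) stop("empty region: end <= start")
  stopifnot(length(fragment_list) >= 1L,
            length(lib_sizes) == length(fragment_list))
  pos <- start:(end - 1L)
  cov <- vapply(seq_along(fragment_list), function(j) {
    fr <- fragment_list[[j]]
    fr <- fr[fr$ref == ref & fr$strand == strand, , drop = FALSE]
    vapply(pos, function(p) sum(fr$start <= p & fr$end > p), numeric(1))
  }, numeric(length(pos)))
  cov <- matrix(cov, nrow = length(pos))
  colnames(cov) <- names(fragment_list)
  cpm <- cpm_normalize(cov, lib_sizes)
  n <- ncol(cpm)
  sem <- if (n == 1L) rep(0, length(pos)) else apply(cpm, 1L, stats::sd) / sqrt(n)
  out <- data.frame(ref = ref, strand = strand, pos = pos,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cpm))
  out$mean_cpm <- rowMeans(cpm)
  out$sem_cpm <- sem
  out
}
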