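#' @title Reference sequences and feature annotation
#' @name reference_model
#' @description
#' A `GenomeBundle` holds reference nucleotide sequences together with a
#' feature table (CDS / tRNA / rRNA / other) and, for every tRNA gene, an
#' anticodon specification anchored in transcript coordinates. All
#' coordinates are 0-based half-open internally; user-facing reports are
#' 1-based fully closed.
NULL

FEATURE_CLASSES <- c("CDS", "tRNA", "rRNA", "other")

#' Load reference sequences from a FASTA file
#'
#' Sequences are uppercased and RNA alphabet (U) is converted to DNA (T).
#'
#' @param fasta_path Path to a FASTA file.
#' @return A `GenomeBundle` with sequences only (no features yet).
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) {
    stop("FASTA file contains no records: ", fasta_path)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- chartr("Uu", "Tt", as.character(seqs))
  x <- toupper(x)
  names(x) <- ids
  new_genome_bundle(sequences = x)
}

new_genome_bundle <- function(sequences, features = empty_feature_table(),
                              trna_index = empty_trna_index()) {
  structure(list(sequences = sequences, features = features,
                 trna_index = trna_index),
            class = "GenomeBundle")
}

empty_feature_table <- function() {
  data.frame(name = character(), ref = character(),
             start = integer(), end = integer(),
             strand = character(), feature_class = character(),
             stringsAsFactors = FALSE)
}

empty_trna_index <- function() {
  data.frame(name = character(), anticodon = character(),
             n1_offset = integer(), stringsAsFactors = FALSE)
}

#' @export
print.GenomeBundle <- function(x, ...) {
  cat("GenomeBundle:", length(x$sequences), "reference(s),",
      sum(nchar(x$sequences)), "nt total;",
      nrow(x$features), "feature(s) (",
      sum(x$features$feature_class == "tRNA"), "tRNA )\n")
  invisible(x)
}

#' Load feature annotation (BED6+3) into a GenomeBundle
#'
#' The annotation format is BED6 plus three columns:
#' feature class (`CDS`/`tRNA`/`rRNA`/`other`), the transcript-relative
#' 0-based offset of the first anticodon nucleotide (N1; `.` for
#' non-tRNA rows), and the anticodon sequence (`.` for non-tRNA rows).
#' Features are validated against sequence bounds and each tRNA anticodon
#' is cross-checked against the genome sequence at its annotated offsets.
#'
#' @param bed_path Path to the BED6+3 annotation file.
#' @param genome A `GenomeBundle` from [load_genome()].
#' @return The `GenomeBundle` with `features` and `trna_index` filled in.
#' @export
load_annotation <- function(bed_path, genome) {
  stopifnot(inherits(genome, "GenomeBundle"))
  if (!file.exists(bed_path)) stop("annotation file not found: ", bed_path)
  raw <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 9L) {
    stop("annotation must have 9 tab-separated columns (BED6+3), got ",
         ncol(raw))
  }
  feats <- data.frame(
    name = raw[[4L]], ref = raw[[1L]],
    start = as.integer(raw[[2L]]), end = as.integer(raw[[3L]]),
    strand = raw[[6L]], feature_class = raw[[7L]],
    stringsAsFactors = FALSE)
  validate_features(feats, genome$sequences)

  is_trna <- feats$feature_class == "tRNA"
  trna_index <- empty_trna_index()
  if (any(is_trna)) {
    off <- raw[[8L]][is_trna]
    ac <- toupper(chartr("Uu", "Tt", raw[[9L]][is_trna]))
    if (any(off == "." | ac == ".")) {
      stop("tRNA feature(s) missing anticodon offset/sequence: ",
           paste(feats$name[is_trna][off == "." | ac == "."], collapse = ", "))
    }
    trna_index <- data.frame(name = feats$name[is_trna], anticodon = ac,
                             n1_offset = as.integer(off),
                             stringsAsFactors = FALSE)
    check_anticodons(trna_index, feats[is_trna, , drop = FALSE],
                     genome$sequences)
  }
  genome$features <- feats
  genome$trna_index <- trna_index
  genome
}

validate_features <- function(feats, sequences) {
  if (anyDuplicated(feats$name)) {
    stop("duplicate feature names: ",
         paste(unique(feats$name[duplicated(feats$name)]), collapse = ", "))
  }
  bad <- !(feats$ref %in% names(sequences))
  if (any(bad)) {
    stop("feature(s) on unknown reference: ",
         paste(feats$name[bad], collapse = ", "))
  }
  if (any(feats$start >= feats$end)) {
    stop("feature(s) with start >= end: ",
         paste(feats$name[feats$start >= feats$end], collapse = ", "))
  }
  lens <- nchar(sequences)[feats$ref]
  oob <- feats$start < 0L | feats$end > lens
  if (any(oob)) {
    stop("feature(s) outside reference bounds: ",
         paste(feats$name[oob], collapse = ", "))
  }
  if (!all(feats$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-'")
  }
  if (!all(feats$feature_class %in% FEATURE_CLASSES)) {
    stop("feature_class must be one of: ",
         paste(FEATURE_CLASSES, collapse = ", "))
  }
  invisible(feats)
}

# Map transcript-relative offsets (0-based, from the transcript 5' end) of a
# feature to genomic 0-based positions, strand-aware.
transcript_to_genomic <- function(offsets, start, end, strand) {
  if (strand == "+") start + offsets else (end - 1L) - offsets
}

#' Anticodon specification of a tRNA gene
#'
#' The seven anticodon-loop offsets follow the canonical 32-38 numbering:
#' loop positions 1..7 correspond to tRNA positions 32..38 and the
#' anticodon (N1, N2, N3) sits at loop positions 3..5 (tRNA 34-36).
#'
#' @param genome A `GenomeBundle` with annotation loaded.
#' @param trna_name Name of an annotated tRNA gene.
#' @return List with `anticodon_seq`, `loop_offsets` (7 transcript-relative
#'   0-based offsets), `loop_genomic` (genomic 0-based positions, in
#'   transcript order), `anticodon_genomic` (N1..N3), and `strand`.
#' @export
anticodon_spec <- function(genome, trna_name) {
  i <- match(trna_name, genome$trna_index$name)
  if (is.na(i)) stop("no anticodon record for tRNA: ", trna_name)
  f <- genome$features[match(trna_name, genome$features$name), ]
  n1 <- genome$trna_index$n1_offset[i]
  loop_offsets <- (n1 - 2L):(n1 + 4L)
  loop_genomic <- transcript_to_genomic(loop_offsets, f$start, f$end, f$strand)
  list(name = trna_name,
       anticodon_seq = genome$trna_index$anticodon[i],
       loop_offsets = loop_offsets,
       loop_positions = 32:38,
       loop_genomic = loop_genomic,
       anticodon_genomic = loop_genomic[3:5],
       ref = f$ref, strand = f$strand)
}

check_anticodons <- function(trna_index, trna_feats, sequences) {
  for (i in seq_len(nrow(trna_index))) {
    f <- trna_feats[i, ]
    n1 <- trna_index$n1_offset[i]
    if (n1 - 2L < 0L || n1 + 4L >= f$end - f$start) {
      stop("anticodon loop of ", f$name, " extends outside the gene body")
    }
    gen <- transcript_to_genomic(n1 + 0:2, f$start, f$end, f$strand)
    obs <- feature_sense_nt(sequences[[f$ref]], gen, f$strand)
    if (obs != trna_index$anticodon[i]) {
      stop("anticodon mismatch for ", f$name, ": annotated ",
           trna_index$anticodon[i], " but genome has ", obs)
    }
  }
  invisible(TRUE)
}

# Transcript-sense nucleotides at genomic 0-based positions `pos`
# (in transcript order) of sequence `seq`.
feature_sense_nt <- function(seq, pos, strand) {
  nts <- substring(seq, pos + 1L, pos + 1L)
  if (strand == "-") nts <- chartr("ACGT", "TGCA", nts)
  paste(nts, collapse = "")
}

#' Extract the genomic (transcript-sense) sequence of a feature
#' @param genome A `GenomeBundle`.
#' @param name Feature name.
#' @return Character scalar, 5'->3' in transcript orientation.
#' @export
feature_sequence <- function(genome, name) {
  f <- genome$features[match(name, genome$features$name), ]
  if (is.na(f$name)) stop("unknown feature: ", name)
  s <- substr(genome$sequences[[f$ref]], f$start + 1L, f$end)
  if (f$strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(ch)
    paste(rev(ch), collapse = ""), character(1)))
}

#' Collapse tRNA genes with identical sequences
#'
#' Multi-copy tRNAs encoded by byte-identical genes are merged into one
#' group so they count once in set intersections. The group name is the
#' longest common prefix of the member names followed by the
#' distinguishing suffixes sorted lexicographically (glnU + glnW ->
#' glnUW). Singleton genes map to themselves.
#'
#' @param genome A `GenomeBundle` with tRNA annotation.
#' @return Named character vector: tRNA gene name -> collapsed group name.
#' @export
collapse_identical_trnas <- function(genome) {
  trna <- genome$features[genome$features$feature_class == "tRNA", ,
                          drop = FALSE]
  if (nrow(trna) == 0L) stop("no tRNA features in annotation")
  seqs <- vapply(trna$name, function(n) feature_sequence(genome, n),
                 character(1))
  out <- character(nrow(trna))
  names(out) <- trna$name
  for (s in unique(seqs)) {
    members <- sort(trna$name[seqs == s])
    out[members] <- collapsed_group_name(members)
  }
  out
}

collapsed_group_name <- function(members) {
  if (length(members) == 1L) return(members)
  chars <- strsplit(members, NULL)
  minlen <- min(lengths(chars))
  k <- 0L
  while (k < minlen &&
         length(unique(vapply(chars, `[`, character(1), k + 1L))) == 1L) {
    k <- k + 1L
  }
  prefix <- substr(members[1L], 1L, k)
  suffixes <- sort(substring(members, k + 1L))
  paste0(prefix, paste(suffixes, collapse = ""))
}

#' Write a GenomeBundle's annotation back to BED6+3
#' @param genome A `GenomeBundle` with annotation.
#' @param path Output file path.
#' @export
write_annotation <- function(genome, path) {
  f <- genome$features
  idx <- match(f$name, genome$trna_index$name)
  off <- ifelse(is.na(idx), ".",
                as.character(genome$trna_index$n1_offset[idx]))
  ac <- ifelse(is.na(idx), ".", genome$trna_index$anticodon[idx])
  out <- data.frame(f$ref, f$start, f$end, f$name, 0L, f$strand,
                    f$feature_class, off, ac)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write genome sequences to FASTA
#' @param genome A `GenomeBundle`.
#' @param path Output file path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$sequences), path)
  invisible(path)
}
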