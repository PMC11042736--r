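#' @title Pipeline orchestration, file formats and run manifest
#' @name cli_pipeline
#' @description
#' Thin orchestrators chain the stages (simulate, count, call, call-tss,
#' crosscheck, annotate) with validation, per-stage record counts and a
#' JSON run manifest. A command-line front end over these functions
#' ships in `inst/cli/cleavemap.R`.
NULL

#' Write / read an EndCountTable as TSV plus JSON sidecar
#'
#' The TSV holds reference, strand, 1-based position and one count
#' column per library; the sidecar (`<path>.json`) holds library sizes
#' and metadata.
#'
#' @param table An `EndCountTable`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_end_counts <- function(table, path) {
  out <- data.frame(reference = table$axis$ref, strand = table$axis$strand,
                    position = table$axis$pos + 1L,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(table$counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(lib_sizes = as.list(stats::setNames(table$lib_sizes,
                                             colnames(table$counts))),
         meta = table$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_end_counts
#' @export
read_end_counts <- function(path) {
  tsv <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  libs <- names(side$lib_sizes)
  axis <- data.frame(ref = tsv$reference, strand = tsv$strand,
                     pos = tsv$position - 1L, stringsAsFactors = FALSE)
  counts <- as.matrix(tsv[, libs, drop = FALSE])
  storage.mode(counts) <- "integer"
  meta <- as.data.frame(side$meta, stringsAsFactors = FALSE)
  new_end_count_table(axis, counts, unlist(side$lib_sizes), meta)
}

#' Write a DiffResult or SiteSet as TSV (1-based positions)
#' @param x A `DiffResult` or `SiteSet`.
#' @param path Output TSV path.
#' @export
write_result_table <- function(x, path) {
  df <- as.data.frame(x)
  df$pos <- df$pos + 1L
  names(df)[names(df) == "pos"] <- "position"
  names(df)[names(df) == "ref"] <- "reference"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_site_set <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[names(df) == "position"] <- "pos"
  names(df)[names(df) == "reference"] <- "ref"
  df$pos <- df$pos - 1L
  structure(df, class = c("SiteSet", "data.frame"))
}

new_manifest <- function(stage, config = NULL) {
  list(tool = "cleavemap",
       version = as.character(utils::packageVersion("cleavemap")),
       stage = stage, started = format(Sys.time(), usetz = TRUE),
       config = config, counts = list(), inputs = list(),
       status = "running")
}

finish_manifest <- function(manifest, out_dir, status = "ok",
                            failed_stage = NULL) {
  manifest$status <- status
  manifest$failed_stage <- failed_stage
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  manifest
}

checksum <- function(paths) {
  as.list(stats::setNames(vapply(paths, function(p)
    unname(tools::md5sum(p)), character(1)), basename(paths)))
}

#' Produce a complete synthetic fixture directory
#'
#' Writes `genome.fasta`, `annotation.bed`, one SAM per library, the
#' simulated count table, the ground truth (`truth.json`) and a config
#' echo, then a run manifest.
#'
#' @param config A [sim_config()]; when `implant_defaults` is TRUE and
#'   no implants are configured, [default_cleavage_implants()] supplies
#'   20 anticodon-loop implants.
#' @param out Output directory.
#' @param implant_defaults Add default cleavage implants when none are
#'   configured (default TRUE).
#' @return List: genome, table, truth, sam paths, out.
#' @export
cmd_simulate <- function(config, out, implant_defaults = TRUE) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- new_manifest("simulate", unclass(config))
  result <- tryCatch({
    genome <- generate_reference(config, dir = out)
    if (implant_defaults && is.null(config$implanted_cleavage)) {
      config$implanted_cleavage <- default_cleavage_implants(genome, config)
    }
    sim <- simulate_counts(config, genome)
    sams <- simulate_alignments(config, genome, sim$table,
                                file.path(out, "alignments"))
    write_end_counts(sim$table, file.path(out, "end_counts.tsv"))
    jsonlite::write_json(
      lapply(sim$truth[c("cleavage", "tss")], as.data.frame),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    manifest$counts <- list(
      references = length(genome$sequences),
      features = nrow(genome$features),
      positions = nrow(sim$table$axis),
      libraries = ncol(sim$table$counts),
      implanted_cleavage = nrow(sim$truth$cleavage),
      implanted_tss = nrow(sim$truth$tss))
    list(genome = genome, table = sim$table, truth = sim$truth,
         sam_paths = sams, out = out)
  }, error = function(e) {
    finish_manifest(manifest, out, "failed", "simulate")
    stop(e)
  })
  finish_manifest(manifest, out, "ok")
  result
}

#' Count fragment 5' ends from alignment files
#'
#' @param alignment_paths Named character vector of SAM/BAM paths (names
#'   become library ids).
#' @param meta Library metadata data.frame (see
#'   [count_five_prime_ends()]); defaults inferred from names.
#' @param out Output directory for `end_counts.tsv` + manifest.
#' @param config A [model_config()] (supplies `min_mapq`).
#' @return The `EndCountTable`.
#' @export
cmd_count <- function(alignment_paths, meta = NULL, out = NULL,
                      config = model_config()) {
  missing_files <- alignment_paths[!file.exists(alignment_paths)]
  if (length(missing_files) > 0L) {
    stop("alignment file(s) not found: ",
         paste(missing_files, collapse = ", "))
  }
  if (is.null(names(alignment_paths))) {
    names(alignment_paths) <-
      tools::file_path_sans_ext(basename(alignment_paths))
  }
  manifest <- new_manifest("count")
  manifest$inputs <- checksum(alignment_paths)
  frags <- lapply(alignment_paths, fragments_from_alignments,
                  min_mapq = config$min_mapq)
  n_frag <- vapply(frags, nrow, integer(1))
  if (any(n_frag == 0L)) {
    warning("empty alignment file(s): ",
            paste(names(frags)[n_frag == 0L], collapse = ", "))
  }
  table <- count_five_prime_ends(frags, meta)
  manifest$counts <- list(fragments = as.list(n_frag),
                          positions = nrow(table$axis))
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_end_counts(table, file.path(out, "end_counts.tsv"))
    finish_manifest(manifest, out)
  }
  table
}

#' Run the cleavage contrast and call sites
#'
#' @param table An `EndCountTable` (targeting vs nontargeting; only
#'   RppH-treated libraries are used when untreated ones are present).
#' @param config A [model_config()].
#' @param genome Optional `GenomeBundle` for feature assignment.
#' @param out Optional output directory (`diff_result.tsv`,
#'   `cleavage_sites.tsv`, manifest).
#' @return List: `diff` (`DiffResult`), `sites` (`SiteSet`).
#' @export
cmd_call <- function(table, config = model_config(), genome = NULL,
                     out = NULL) {
  manifest <- new_manifest("call", unclass(config))
  if (any(!table$meta$rpph)) {
    table <- subset_libraries(table, libraries = which(table$meta$rpph))
  }
  res <- tryCatch({
    filtered <- filter_positions(table, config)
    diff <- run_enrichment_test(filtered, config)
    sites <- call_sites(diff, config, site_type = "cleavage")
    if (!is.null(genome)) sites <- assign_sites_to_features(sites, genome)
    manifest$counts <- list(positions_input = nrow(table$axis),
                            positions_filtered = nrow(filtered$axis),
                            positions_tested = sum(!is.na(diff$pvalue)),
                            sites_called = nrow(sites))
    manifest$dispersion <- attr(diff, "dispersion")
    list(diff = diff, sites = sites)
  }, error = function(e) {
    if (!is.null(out)) {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      finish_manifest(manifest, out, "failed", "call")
    }
    stop(e)
  })
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_result_table(res$diff, file.path(out, "diff_result.tsv"))
    write_result_table(res$sites, file.path(out, "cleavage_sites.tsv"))
    finish_manifest(manifest, out)
  }
  res
}

#' Run the RppH contrast and call TSSs
#'
#' Restricts the table to nontargeting libraries (both RppH states)
#' when targeting libraries are present, then applies [call_tss()].
#'
#' @inheritParams cmd_call
#' @return List: `diff`, `sites` (site_type "tss").
#' @export
cmd_call_tss <- function(table, config = model_config(), genome = NULL,
                         out = NULL) {
  manifest <- new_manifest("call-tss", unclass(config))
  res <- tryCatch({
    nt <- table$meta$condition == "nontargeting"
    if (any(nt) && any(table$meta$rpph[nt]) && any(!table$meta$rpph[nt])) {
      table <- subset_libraries(table, libraries = which(nt))
    }
    sites <- call_tss(table, config)
    diff <- attr(sites, "diff_result")
    if (!is.null(genome)) sites <- assign_sites_to_features(sites, genome)
    manifest$counts <- list(positions_tested = sum(!is.na(diff$pvalue)),
                            tss_called = nrow(sites))
    list(diff = diff, sites = sites)
  }, error = function(e) {
    if (!is.null(out)) {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      finish_manifest(manifest, out, "failed", "call-tss")
    }
    stop(e)
  })
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_result_table(res$diff, file.path(out, "tss_diff_result.tsv"))
    write_result_table(res$sites, file.path(out, "tss_sites.tsv"))
    finish_manifest(manifest, out)
  }
  res
}

#' Cross-check TSS against cleavage calls and record the overlap
#'
#' @param tss_sites,cleavage_sites `SiteSet`s (see
#'   [crosscheck_tss_vs_cleavage()]).
#' @param k Top-k sites of each set to intersect.
#' @param out Optional output directory (`tss_cleavage_shared.tsv`,
#'   manifest).
#' @return The crosscheck list (`n_shared`, `shared`).
#' @export
cmd_crosscheck <- function(tss_sites, cleavage_sites, k = 1000,
                           out = NULL) {
  manifest <- new_manifest("crosscheck")
  res <- crosscheck_tss_vs_cleavage(tss_sites, cleavage_sites, k)
  manifest$counts <- list(tss = nrow(tss_sites),
                          cleavage = nrow(cleavage_sites),
                          shared = res$n_shared)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_result_table(
      structure(res$shared, class = c("SiteSet", "data.frame")),
      file.path(out, "tss_cleavage_shared.tsv"))
    finish_manifest(manifest, out)
  }
  res
}

#' Annotate called sites and export interpretive tables
#'
#' Writes the volcano table, the logo frequency matrix and the
#' anticodon-loop profile for a called cleavage-site set.
#'
#' @param sites A `SiteSet` (cleavage).
#' @param diff The matching `DiffResult`.
#' @param genome A `GenomeBundle` with annotation.
#' @param out Output directory.
#' @param config A [model_config()].
#' @return List: `sites` (annotated), `volcano`, `logo`, `profile`.
#' @export
cmd_annotate <- function(sites, diff, genome, out = NULL,
                         config = model_config()) {
  manifest <- new_manifest("annotate")
  res <- tryCatch({
    if (any(is.na(sites$feature))) {
      sites <- assign_sites_to_features(sites, genome)
    }
    volcano <- volcano_table(diff, genome, config)
    logo <- if (nrow(sites) > 0L) {
      build_logo_matrix(sites, genome)
    } else NULL
    profile <- anticodon_loop_profile(diff, genome)
    manifest$counts <- list(
      sites = nrow(sites),
      logo_sites = if (is.null(logo)) 0L else attr(logo, "n_sites"),
      trna_groups = nrow(profile$log2fc) - 1L)
    list(sites = sites, volcano = volcano, logo = logo,
         profile = profile)
  }, error = function(e) {
    if (!is.null(out)) {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      finish_manifest(manifest, out, "failed", "annotate")
    }
    stop(e)
  })
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_result_table(res$sites, file.path(out, "annotated_sites.tsv"))
    utils::write.table(res$volcano, file.path(out, "volcano.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$logo)) {
      utils::write.table(res$logo, file.path(out, "logo_matrix.tsv"),
                         sep = "\t", quote = FALSE)
    }
    utils::write.table(res$profile$log2fc,
                       file.path(out, "anticodon_profile_log2fc.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(res$profile$neg_log10_fdr,
                       file.path(out, "anticodon_profile_fdr.tsv"),
                       sep = "\t", quote = FALSE)
    finish_manifest(manifest, out)
  }
  res
}

#' End-to-end run: simulate, count from SAM, call, annotate
#'
#' @param sim A [sim_config()].
#' @param config A [model_config()].
#' @param out Output directory.
#' @return List with all stage results plus `recovered` (fraction of
#'   implanted cleavage positions present in the called site set).
#' @export
run_pipeline <- function(sim = sim_config(), config = model_config(),
                         out = tempfile("cleavemap_run_")) {
  fixture <- cmd_simulate(sim, file.path(out, "fixture"))
  table <- cmd_count(fixture$sam_paths,
                     meta = fixture$table$meta,
                     out = file.path(out, "counts"), config = config)
  call <- cmd_call(table, config, genome = fixture$genome,
                   out = file.path(out, "call"))
  ann <- cmd_annotate(call$sites, call$diff, fixture$genome,
                      out = file.path(out, "annotate"), config = config)
  truth <- fixture$truth$cleavage
  recovered <- if (nrow(truth) > 0L) {
    called <- paste(call$sites$ref, call$sites$strand, call$sites$pos)
    mean(paste(truth$ref, truth$strand, truth$pos) %in% called)
  } else NA_real_
  list(fixture = fixture, table = table, call = call, annotate = ann,
       recovered = recovered, out = out)
}
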