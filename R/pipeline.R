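#' Pipeline configuration
#'
#' Collects every threshold of the pipeline with its default: junction
#' clustering (`min_cluster_reads` 30, `min_fraction` 0.01), novelty
#' (`novel_min_reads` 10), exonization geometry (`max_exon_len` 500,
#' `min_site_reads` 5, strictly greater), intron retention (`ir_min_ratio`
#' 0.1, `ir_min_body_reads` 10), the NMD rule (`nmd_window` 50 nt),
#' reference selection (`tpm_min` 1 TPM, `min_orf_aa` 25), peptide lengths
#' (`kmin` 8, `kmax` 11; use 15/15 for MHC-II), the binder threshold
#' (`threshold_nm` 500; 300 for the stricter secondary analysis), and the
#' empirical test (`alpha` 0.05, `n_random` 100, `seed`).
#'
#' @param ... named overrides of any default.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_cluster_reads = 30L, min_fraction = 0.01,
              novel_min_reads = 10L, max_exon_len = 500L,
              min_site_reads = 5L, ir_min_ratio = 0.1,
              ir_min_body_reads = 10L, nmd_window = 50L, tpm_min = 1,
              min_orf_aa = 25L, kmin = 8L, kmax = 11L, threshold_nm = 500,
              alpha = 0.05, n_random = 100L, seed = 1L,
              self_scope = "event")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  num <- setdiff(names(cfg), "self_scope")
  if (any(vapply(cfg[num], function(x) !is.numeric(x) || x <= 0, TRUE)))
    stop("all numeric config fields must be positive")
  if (cfg$kmin > cfg$kmax) stop("kmin must not exceed kmax")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (n in names(x)) cat(sprintf("  %-18s %s\n", n, format(x[[n]])))
  invisible(x)
}

#' Read / write a pipeline configuration file
#'
#' A flat key:value YAML document; round-trips losslessly.
#'
#' @param path config file.
#' @name config_io
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @param config a [pipeline_config()].
#' @rdname config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Stage order: `events` (junction evidence → classified, significance-
#' filtered splicing events), `orf` (reference/altered protein pairs),
#' `epitopes` (neo- and self-epitope calls), `stats` (self-epitope
#' proportions, MS validation, biomarker enrichment).  Stage outputs are
#' TSV/FASTA files under `outdir` plus a `manifest.json` recording the
#' configuration, input checksums and package version; a rerun on unchanged
#' inputs is byte-identical (no timestamps are written).
#'
#' @param inputs named list of input paths: `genome`, `gtf`, `sj` (named
#'   list, sample id → STAR SJ.out.tab), `expression`, `compendium`,
#'   `hla`, and optionally `coverage`, `genic_background`, `ms`,
#'   `biomarkers`, `netmhc` (external affinity table instead of the
#'   surrogate predictor).  The `$paths` element of [generate_fixtures()]
#'   is directly usable.
#' @param outdir output directory (created).
#' @param tumor_samples sample ids treated as tumor; defaults to the first
#'   SJ sample.
#' @param config a [pipeline_config()].
#' @param stages subset of `c("events", "orf", "epitopes", "stats")`
#'   (prefix-closed: each stage needs its predecessors' outputs in memory).
#' @return Invisibly, a list with the stage results (`events`, `orf_pairs`,
#'   `epitopes`, `stats`) and `outdir`.
#' @export
run_pipeline <- function(inputs, outdir,
                         tumor_samples = names(inputs$sj)[1L],
                         config = pipeline_config(),
                         stages = c("events", "orf", "epitopes", "stats")) {
  stages <- match.arg(stages, several.ok = TRUE)
  need <- c("genome", "gtf", "sj", "expression")
  miss <- setdiff(need, names(inputs))
  if (length(miss))
    stop("missing input(s) for the events stage: ",
         paste(miss, collapse = ", "),
         " (supply them in `inputs`)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  genome <- read_genome(inputs$genome)
  transcripts <- read_gtf(inputs$gtf)
  junctions <- do.call(rbind, lapply(names(inputs$sj), function(s)
    read_star_junctions(inputs$sj[[s]], s)))
  normals <- if (!is.null(inputs$compendium))
    read_normal_compendium(inputs$compendium) else character()
  coverage <- NULL
  if (!is.null(inputs$coverage)) {
    coverage <- read.table(inputs$coverage, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    coverage$start <- coverage$start - 1L
  }
  genic_bg <- if (!is.null(inputs$genic_background))
    read.table(inputs$genic_background, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE) else NULL

  results <- list(outdir = outdir)
  events <- detect_events(junctions, transcripts, genome, normals,
                          tumor_samples, coverage, genic_bg, config)
  write_events_tsv(events, file.path(outdir, "events.tsv"))
  write_events_bed(events, file.path(outdir, "events.bed"))
  results$events <- events

  orf_pairs <- list()
  epitopes <- empty_calls()
  reference <- NULL
  if (any(c("orf", "epitopes", "stats") %in% stages)) {
    expr <- read_expression(inputs$expression)
    normal_cols <- setdiff(colnames(expr), tumor_samples)
    reference <- select_reference_transcriptome(
      transcripts, expr, genome,
      control_samples = if (length(normal_cols)) normal_cols else NULL,
      tpm_min = config$tpm_min, min_orf_aa = config$min_orf_aa)
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      tid <- reference$gene_to_transcript[ev$gene_id]
      if (is.na(tid)) {
        message("event ", ev$event_id, ": gene ", ev$gene_id,
                " has no qualifying reference transcript; skipped")
        next
      }
      pr <- tryCatch(
        derive_orf_pair(transcripts[[tid]], ev, genome,
                        reference$proteome, config$min_orf_aa,
                        config$nmd_window),
        error = function(e) {
          message("event ", ev$event_id, " skipped: ", conditionMessage(e))
          NULL
        })
      if (!is.null(pr)) orf_pairs[[ev$event_id]] <- pr
    }
    write_orf_pairs(orf_pairs, file.path(outdir, "orf_pairs.fa"),
                    file.path(outdir, "orf_flags.tsv"))
    results$orf_pairs <- orf_pairs
  }

  if (any(c("epitopes", "stats") %in% stages) && length(orf_pairs)) {
    index <- build_reference_index(reference$proteome, config$kmin,
                                   config$kmax)
    hla <- if (!is.null(inputs$hla))
      read.table(inputs$hla, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE) else
      data.frame(sample = tumor_samples,
                 allele = .surrogate_alleles[1L])
    ext_aff <- if (!is.null(inputs$netmhc))
      read_netmhc_output(inputs$netmhc) else NULL
    calls <- list()
    for (eid in names(orf_pairs)) {
      pr <- orf_pairs[[eid]]
      ev <- events[events$event_id == eid, ]
      alleles <- hla$allele[hla$sample == ev$sample_id]
      if (!length(alleles)) alleles <- unique(hla$allele)
      cand <- unique(c(
        if (!is.null(pr$alt_protein))
          enumerate_kmers(pr$alt_protein, config$kmin, config$kmax),
        enumerate_kmers(pr$ref_protein, config$kmin, config$kmax)))
      cand <- cand[!grepl("X", cand, fixed = TRUE)]
      aff <- if (!is.null(ext_aff))
        ext_aff[ext_aff$peptide %in% cand &
                  ext_aff$hla_allele %in% alleles, , drop = FALSE] else
        predict_affinity_surrogate(cand, alleles)
      cl <- suppressWarnings(
        call_epitopes(pr, index, aff, config$threshold_nm,
                      self_scope = config$self_scope,
                      sample_id = ev$sample_id,
                      kmin = config$kmin, kmax = config$kmax))
      if (nrow(cl)) {
        cl$gene_id <- ev$gene_id
        cl$event_type <- ev$event_type
        calls[[eid]] <- cl
      }
    }
    epitopes <- if (length(calls)) do.call(rbind, calls) else empty_calls()
    rownames(epitopes) <- NULL
    write.table(epitopes, file.path(outdir, "epitopes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$epitopes <- epitopes
  }

  if ("stats" %in% stages) {
    st <- list()
    st$proportions <- self_epitope_proportion(
      epitopes, group_by = intersect("event_type", names(epitopes)))
    write.table(st$proportions, file.path(outdir, "self_proportions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(inputs$ms) && nrow(epitopes)) {
      ms <- read_ms_peptides(inputs$ms)
      st$ms_match <- match_ms_peptides(unique(epitopes$peptide), ms)
    }
    if (!is.null(inputs$biomarkers) && nrow(epitopes)) {
      sets <- read_biomarker_sets(inputs$biomarkers)
      universe <- unique(vapply(transcripts, `[[`, "", "gene_id"))
      st$enrichment <- biomarker_enrichment(
        intersect(unique(epitopes$gene_id), universe), universe, sets)
      write.table(st$enrichment, file.path(outdir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    results$stats <- st
  }

  manifest <- list(
    package = "splicetope",
    version = as.character(utils::packageVersion("splicetope")),
    config = unclass(config),
    stages = stages,
    inputs = lapply(inputs, function(x)
      if (is.list(x)) lapply(x, unname_md5) else unname_md5(x)),
    n_events = nrow(events),
    n_orf_pairs = length(orf_pairs),
    n_epitope_calls = if (is.null(results$epitopes)) 0L
      else nrow(results$epitopes))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

unname_md5 <- function(path) {
  if (is.character(path) && length(path) == 1L && file.exists(path))
    unname(tools::md5sum(path)) else NA_character_
}

empty_calls <- function() {
  data.frame(peptide = character(), hla_allele = character(),
             affinity_nm = numeric(), epitope_class = character(),
             event_id = character(), sample_id = character(),
             gene_id = character(), event_type = character(),
             stringsAsFactors = FALSE)
}
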