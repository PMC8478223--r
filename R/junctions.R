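#' Read a STAR SJ.out.tab junction file
#'
#' STAR's splice-junction table: chrom, intron start, intron end (1-based
#' inclusive), strand code (0 undefined / 1 `+` / 2 `-`), motif, annotated
#' flag, unique-mapping reads, multi-mapping reads, max overhang.  Only
#' uniquely-mapping reads (column 7) are kept as junction support.
#'
#' @param path SJ.out.tab file (9 tab-separated columns, no header).
#' @param sample_id sample label attached to every junction.
#' @param min_intron_len gaps shorter than this are treated as alignment
#'   artifacts (deletions) and dropped with a message; default 20 nt.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open intron), `strand`, `sample`, `count`.
#' @export
read_star_junctions <- function(path, sample_id, min_intron_len = 20L) {
  nf <- count.fields(path, sep = "\t", quote = "")
  bad <- which(!is.na(nf) & nf != 9L)
  if (length(bad))
    stop("malformed SJ line ", bad[1L], " in ", path,
         ": expected 9 columns, found ", nf[bad[1L]])
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", rep("integer", 8L)))
  jx <- data.frame(chrom = df[[1L]],
                   start = df[[2L]] - 1L,      # to 0-based half-open
                   end = df[[3L]],
                   strand = c(".", "+", "-")[df[[4L]] + 1L],
                   sample = sample_id,
                   count = df[[7L]],
                   stringsAsFactors = FALSE)
  short <- jx$end - jx$start < min_intron_len
  if (any(short))
    message(sum(short), " gap(s) shorter than ", min_intron_len,
            " nt dropped from ", path)
  jx[!short, , drop = FALSE]
}

#' Read / write a generic junction TSV
#'
#' Columns `chrom`, `start`, `end`, `strand`, `sample`, `count` with a header
#' row; coordinates 1-based inclusive externally, converted to the internal
#' 0-based half-open convention.
#'
#' @param path file path.
#' @name junction_tsv
#' @export
read_junction_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "integer",
                                  "character", "character", "integer"))
  df$start <- df$start - 1L
  df
}

#' @param junctions junction data.frame (internal coordinates).
#' @rdname junction_tsv
#' @export
write_junction_tsv <- function(junctions, path) {
  out <- junctions
  out$start <- out$start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a normal-junction compendium
#'
#' A compendium is the union of junctions seen in a panel of normal samples,
#' used to subtract non-tumor-specific junctions.  Membership is
#' strand-agnostic `(chrom, start, end)`: compendia built from unstranded
#' libraries carry no reliable strand.
#'
#' @param path TSV with columns `chrom`, `start`, `end` (1-based inclusive)
#'   and a header row.
#' @return Character vector of membership keys (`chrom:start-end`, internal
#'   coordinates), usable with [filter_novel()].
#' @export
read_normal_compendium <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  unique(junction_key(df$chrom, df$start - 1L, df$end))
}

junction_key <- function(chrom, start, end) {
  if (!length(chrom)) return(character())
  paste0(chrom, ":", start, "-", end)
}

#' Cluster junctions by shared splice sites
#'
#' LeafCutter-style clustering: junctions sharing a donor or acceptor
#' coordinate (transitively, within a chromosome/strand stratum) form a
#' cluster.  Clusters whose summed read count (over all samples and members)
#' is below `min_cluster_reads` are dropped; member junctions carrying less
#' than `min_fraction` of the cluster's reads are removed and cluster totals
#' recomputed once (a single pruning pass, not LeafCutter's iterative
#' refinement).
#'
#' @param junctions long-format junction data.frame (one row per junction x
#'   sample) as returned by [read_star_junctions()].
#' @param min_cluster_reads minimum summed reads per cluster (default 30).
#' @param min_fraction minimum fraction of cluster reads supporting a member
#'   junction (default 0.01).
#' @return The surviving junction rows with an added `cluster_id` column.
#' @export
cluster_junctions <- function(junctions, min_cluster_reads = 30L,
                              min_fraction = 0.01) {
  if (nrow(junctions) == 0L) {
    junctions$cluster_id <- character(0)
    return(junctions)
  }
  key <- junction_key(junctions$chrom, junctions$start, junctions$end)
  tot <- tapply(junctions$count, key, sum)
  uk <- names(tot)
  parts <- strsplit(uk, "[:-]")
  uchrom <- vapply(parts, `[`, "", 1L)
  ustart <- as.integer(vapply(parts, `[`, "", 2L))
  uend <- as.integer(vapply(parts, `[`, "", 3L))
  ustrand <- junctions$strand[match(uk, key)]
  stratum <- paste0(uchrom, "/", ustrand)

  # union-find over unique junctions; union all members sharing a splice site
  parent <- seq_along(uk)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  for (site in list(paste0(stratum, "@d", ustart), paste0(stratum, "@a", uend))) {
    for (grp in split(seq_along(uk), site)) {
      if (length(grp) > 1L)
        for (i in grp[-1L]) unite(grp[1L], i)
    }
  }
  roots <- vapply(seq_along(uk), find, 1L)
  comp <- match(roots, unique(roots))

  ctot <- tapply(tot, comp, sum)
  keep_cluster <- as.integer(names(ctot)[ctot >= min_cluster_reads])
  frac <- tot / as.numeric(ctot[as.character(comp)])
  keep_j <- comp %in% keep_cluster & frac >= min_fraction
  kept_keys <- uk[keep_j]
  kept_comp <- comp[keep_j]

  out <- junctions[key %in% kept_keys, , drop = FALSE]
  out$cluster_id <- if (nrow(out)) paste0("clu", kept_comp[match(
    junction_key(out$chrom, out$start, out$end), kept_keys)]) else
    character()
  rownames(out) <- NULL
  out
}

#' Normalize junction counts within clusters
#'
#' Read counts per junction are expressed as the fraction of total cluster
#' reads, per sample.  Samples with zero cluster coverage get a missing value
#' (`NA`), not 0 — absence of coverage is not evidence of absence of the
#' junction.
#'
#' @param clustered output of [cluster_junctions()] (needs `cluster_id`).
#' @return Numeric matrix junction-key x sample of fractions in `[0, 1]`
#'   (each cluster column-slice sums to 1 where covered), with `NA` for
#'   uncovered (cluster, sample) pairs.
#' @export
normalize_cluster <- function(clustered) {
  samples <- sort(unique(clustered$sample))
  key <- junction_key(clustered$chrom, clustered$start, clustered$end)
  ukeys <- unique(key)
  m <- matrix(0, nrow = length(ukeys), ncol = length(samples),
              dimnames = list(ukeys, samples))
  m[cbind(match(key, ukeys), match(clustered$sample, samples))] <-
    clustered$count
  clu <- clustered$cluster_id[match(ukeys, key)]
  for (cl in unique(clu)) {
    rows <- which(clu == cl)
    tots <- colSums(m[rows, , drop = FALSE])
    zero <- tots == 0
    m[rows, ] <- sweep(m[rows, , drop = FALSE], 2L, tots, "/")
    if (any(zero)) m[rows, zero] <- NA_real_
  }
  m
}

#' Filter samples by missing-junction fraction
#'
#' Removes samples for which more than 30% of the junctions observed in at
#' least one other sample carry a missing value, a symptom of shallow or
#' degraded libraries.
#'
#' @param norm_matrix junction x sample fraction matrix from
#'   [normalize_cluster()] (`NA` = missing).
#' @param max_missing maximum tolerated missing fraction (default 0.30,
#'   strictly greater removes).
#' @return Character vector of retained sample ids.
#' @export
sample_qc_filter <- function(norm_matrix, max_missing = 0.30) {
  samples <- colnames(norm_matrix)
  if (length(samples) < 2L) return(samples)
  keep <- vapply(seq_along(samples), function(j) {
    seen_elsewhere <- rowSums(!is.na(norm_matrix[, -j, drop = FALSE])) > 0L
    if (!any(seen_elsewhere)) return(TRUE)
    mean(is.na(norm_matrix[seen_elsewhere, j])) <= max_missing
  }, TRUE)
  dropped <- samples[!keep]
  if (length(dropped))
    message("sample QC removed: ", paste(dropped, collapse = ", "))
  samples[keep]
}

# splice-site and intron indices of an annotation: donor/acceptor coordinate
# sets (strand-agnostic chrom:pos) and annotated-intron keys, plus gene maps
annotation_index <- function(transcripts) {
  rows <- lapply(transcripts, function(tx) {
    intr <- tx_introns(tx)
    if (nrow(intr) == 0L) return(NULL)
    data.frame(chrom = tx$chrom, start = intr[, 1L], end = intr[, 2L],
               gene = tx$gene_id, strand = tx$strand,
               stringsAsFactors = FALSE)
  })
  intr <- do.call(rbind, rows)
  if (is.null(intr))
    intr <- data.frame(chrom = character(), start = integer(),
                       end = integer(), gene = character(),
                       strand = character())
  ex <- do.call(rbind, lapply(transcripts, function(tx)
    data.frame(chrom = tx$chrom, start = tx$exons[, 1L],
               end = tx$exons[, 2L], gene = tx$gene_id, strand = tx$strand,
               tid = tx$transcript_id, stringsAsFactors = FALSE)))
  gene_span <- do.call(rbind, lapply(split(ex, ex$gene), function(d)
    data.frame(chrom = d$chrom[1L], start = min(d$start), end = max(d$end),
               gene = d$gene[1L], strand = d$strand[1L],
               stringsAsFactors = FALSE)))
  list(
    donor_sites = unique(paste0(intr$chrom, ":", intr$start)),
    acceptor_sites = unique(paste0(intr$chrom, ":", intr$end)),
    introns = unique(junction_key(intr$chrom, intr$start, intr$end)),
    intron_tbl = unique(intr),
    exon_tbl = ex,
    gene_span = gene_span,
    donor_gene = setNames(intr$gene, paste0(intr$chrom, ":", intr$start)),
    acceptor_gene = setNames(intr$gene, paste0(intr$chrom, ":", intr$end)))
}

#' Select novel tumor-specific junctions
#'
#' A junction is retained when (i) it is not an annotated intron, (ii) it has
#' at least `min_reads` uniquely-mapping reads in at least one tumor sample,
#' (iii) it is absent from the normal-junction compendium and carries no
#' reads in any matched normal sample.  The returned table records which
#' splice sites are unannotated: junctions with both sites on annotated exon
#' boundaries but forming an unannotated connection are kept as neoskipping
#' candidates (`novelty == "novel_connection"`).
#'
#' @param junctions long-format junction table (typically the output of
#'   [cluster_junctions()]).
#' @param transcripts annotation as a named list of transcript models (or a
#'   prebuilt index from the internal indexer).
#' @param normals character vector of compendium keys from
#'   [read_normal_compendium()].
#' @param tumor_samples sample ids counted as tumor; all others are treated
#'   as matched normals (any read there disqualifies a junction).
#' @param min_reads novelty support threshold (default 10), applied after
#'   cluster pruning.
#' @return One row per unique retained junction: `chrom`, `start`, `end`,
#'   `strand`, `max_tumor_reads`, `novelty` in
#'   `c("novel_donor", "novel_acceptor", "both_novel", "novel_connection")`.
#' @export
filter_novel <- function(junctions, transcripts, normals = character(),
                         tumor_samples = unique(junctions$sample),
                         min_reads = 10L) {
  idx <- if (is.list(transcripts) && !is.null(transcripts$donor_sites))
    transcripts else annotation_index(transcripts)
  if (nrow(junctions) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      max_tumor_reads = integer(), novelty = character()))
  }
  key <- junction_key(junctions$chrom, junctions$start, junctions$end)
  uk <- unique(key)
  first <- match(uk, key)
  is_tumor <- junctions$sample %in% tumor_samples
  max_tumor <- setNames(rep(0L, length(uk)), uk)
  tt <- tapply(junctions$count[is_tumor], key[is_tumor], max)
  max_tumor[names(tt)] <- as.integer(tt)
  normal_reads <- setNames(rep(0L, length(uk)), uk)
  nn <- tapply(junctions$count[!is_tumor], key[!is_tumor], sum)
  normal_reads[names(nn)] <- as.integer(nn)

  chrom <- junctions$chrom[first]
  start <- junctions$start[first]
  end <- junctions$end[first]
  donor_ann <- paste0(chrom, ":", start) %in% idx$donor_sites
  accept_ann <- paste0(chrom, ":", end) %in% idx$acceptor_sites
  annotated_intron <- uk %in% idx$introns

  novelty <- rep(NA_character_, length(uk))
  novelty[!donor_ann & accept_ann] <- "novel_donor"
  novelty[donor_ann & !accept_ann] <- "novel_acceptor"
  novelty[!donor_ann & !accept_ann] <- "both_novel"
  novelty[donor_ann & accept_ann & !annotated_intron] <- "novel_connection"

  keep <- !annotated_intron &
    max_tumor >= min_reads &
    !(uk %in% normals) &
    normal_reads == 0L
  out <- data.frame(chrom = chrom, start = start, end = end,
                    strand = junctions$strand[first],
                    max_tumor_reads = as.integer(max_tumor),
                    novelty = novelty, stringsAsFactors = FALSE)[keep, ,
                                                                drop = FALSE]
  rownames(out) <- NULL
  out
}
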