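#' Match candidate peptides against a mass-spectrometry peptide list
#'
#' Exact string intersection, optionally after folding isoleucine to leucine
#' (MS cannot distinguish the isobaric pair).
#'
#' @param candidates character vector (or set) of predicted peptides.
#' @param ms_list character vector of MS-identified peptides.
#' @param il_equivalent fold `I` and `L` together before matching.
#' @return List (`ms_match`) with `matched` (the matched candidates, original
#'   spelling), `n_candidates`, `n_matched`.
#' @export
match_ms_peptides <- function(candidates, ms_list, il_equivalent = FALSE) {
  candidates <- unique(toupper(candidates))
  ms_list <- unique(toupper(ms_list))
  fold <- function(x) if (il_equivalent) chartr("I", "L", x) else x
  matched <- candidates[fold(candidates) %in% fold(ms_list)]
  structure(list(matched = matched, n_candidates = length(candidates),
                 n_matched = length(matched)), class = "ms_match")
}

#' @export
print.ms_match <- function(x, ...) {
  cat(sprintf("<ms_match %d / %d candidates found in MS list>\n",
              x$n_matched, x$n_candidates))
  invisible(x)
}

#' Randomized mass-spectrometry validation test
#'
#' Draws `n_draw` peptides from the high-affinity pool and `n_draw` from the
#' full candidate pool, counts how many of each are identified in the MS
#' list, repeats `reps` times, and compares the two count distributions with
#' a two-sample Kolmogorov-Smirnov test.  A significant difference means MS
#' support is concentrated in the high-affinity predictions.
#'
#' @param high_affinity peptides with good predicted affinity (e.g. <= 500
#'   nM).
#' @param all_candidates the full prediction set.
#' @param ms_list MS-identified peptides.
#' @param n_draw peptides per draw, default 1000 (pools smaller than this
#'   are sampled with replacement, with a message).
#' @param reps repetitions, default 100 (at least 2).
#' @param seed integer seed.
#' @param il_equivalent fold I/L before matching.
#' @param n_perm permutations for the p-value (default 999).  The two count
#'   samples are small and heavily tied, where the asymptotic two-sample KS
#'   p-value is badly conservative; the KS statistic is therefore calibrated
#'   by label permutation, which handles ties exactly.
#' @return List with `high_counts`, `all_counts` (length `reps`),
#'   `statistic` (KS D) and `p` (permutation p-value of D).
#' @export
randomized_validation_test <- function(high_affinity, all_candidates,
                                       ms_list, n_draw = 1000L,
                                       reps = 100L, seed = 1L,
                                       il_equivalent = FALSE,
                                       n_perm = 999L) {
  if (reps < 2L) stop("reps must be at least 2 for a KS comparison")
  fold <- function(x) if (il_equivalent) chartr("I", "L", toupper(x))
    else toupper(x)
  ms <- unique(fold(ms_list))
  hi <- fold(unique(high_affinity)) %in% ms
  al <- fold(unique(all_candidates)) %in% ms
  draw_counts <- function(hits) {
    n <- length(hits)
    repl <- n < n_draw
    if (repl) message("pool of ", n, " < n_draw = ", n_draw,
                      ": sampling with replacement")
    vapply(seq_len(reps), function(i)
      sum(hits[sample.int(n, n_draw, replace = repl)]), 1L)
  }
  set.seed(seed)
  high_counts <- draw_counts(hi)
  all_counts <- draw_counts(al)
  if (!length(ms)) {
    warning("empty MS list: both count distributions degenerate at zero")
    return(list(high_counts = high_counts, all_counts = all_counts,
                statistic = 0, p = 1))
  }
  d_obs <- ks_statistic(high_counts, all_counts)
  pooled <- c(high_counts, all_counts)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(2L * reps, reps)
    if (ks_statistic(pooled[idx], pooled[-idx]) >= d_obs)
      exceed <- exceed + 1L
  }
  list(high_counts = high_counts, all_counts = all_counts,
       statistic = d_obs, p = (1L + exceed) / (1L + n_perm))
}

# two-sample KS statistic with ties handled by evaluating the ECDFs on the
# pooled support
ks_statistic <- function(a, b) {
  u <- sort(unique(c(a, b)))
  fa <- cumsum(tabulate(match(a, u), length(u))) / length(a)
  fb <- cumsum(tabulate(match(b, u), length(u))) / length(b)
  max(abs(fa - fb))
}

#' Compare two affinity distributions (cumulative KS)
#'
#' Two-sample Kolmogorov-Smirnov comparison of binding affinities between
#' groups (e.g. therapy responders vs non-responders); lower nM means
#' stronger MHC interaction.  Cumulative curves are returned for plotting.
#'
#' @param group_a,group_b numeric affinity vectors (nM), non-empty.
#' @return List with `statistic` (D), `p`, `low_power` (set when either
#'   group has fewer than 2 values) and `curves`, a data.frame
#'   (`group`, `affinity_nm`, `cumulative`).
#' @export
ks_affinity_compare <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both affinity groups must be non-empty")
  ks <- suppressWarnings(stats::ks.test(group_a, group_b))
  curve <- function(x, g) {
    x <- sort(x)
    data.frame(group = g, affinity_nm = x,
               cumulative = seq_along(x) / length(x))
  }
  list(statistic = unname(ks$statistic), p = ks$p.value,
       low_power = length(group_a) < 2L || length(group_b) < 2L,
       curves = rbind(curve(group_a, "a"), curve(group_b, "b")))
}

#' Self-epitope proportion per stratum
#'
#' Proportion of splicing-affected self-epitopes over all epitope calls,
#' optionally stratified (e.g. by event type and therapy response).
#'
#' @param calls epitope-call data.frame from [call_epitopes()], with an
#'   `epitope_class` column and any grouping columns.
#' @param group_by character vector of column names to stratify by (empty
#'   for one overall proportion).
#' @return data.frame with the grouping columns, `n_self`, `n_neo` and
#'   `proportion_self` (`NA` when a stratum has no calls).
#' @export
self_epitope_proportion <- function(calls, group_by = character()) {
  stopifnot(all(group_by %in% names(calls)))
  strat <- if (length(group_by))
    interaction(calls[group_by], drop = TRUE, sep = "\r") else
      factor(rep("all", nrow(calls)))
  levs <- levels(strat)
  if (!length(levs)) {
    out <- data.frame(n_self = integer(), n_neo = integer(),
                      proportion_self = numeric())
    return(out)
  }
  rows <- lapply(levs, function(lv) {
    sub <- calls$epitope_class[strat == lv]
    ns <- sum(sub == "SELF_EPITOPE")
    nn <- sum(sub == "SPLICING_NEOEPITOPE")
    keyvals <- strsplit(lv, "\r", fixed = TRUE)[[1L]]
    row <- if (length(group_by))
      as.data.frame(as.list(setNames(keyvals, group_by)),
                    stringsAsFactors = FALSE) else data.frame(row.names = 1L)
    row$n_self <- ns
    row$n_neo <- nn
    row$proportion_self <- if (ns + nn == 0L) NA_real_ else ns / (ns + nn)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Biomarker enrichment of epitope-bearing genes
#'
#' For each biomarker gene set, a 2x2 Fisher exact test of the overlap
#' between genes carrying predicted epitopes and the set, within the tested
#' gene universe, with Benjamini-Hochberg correction across sets.
#'
#' @param hit_genes genes with predicted neo- or self-epitopes (subset of
#'   `universe`).
#' @param universe all genes tested.
#' @param biomarker_sets named list of gene-id vectors (intersected with
#'   the universe).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return data.frame `gene_set_id`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p`, `fdr`; the contingency cells are (hit&set, hit&!set, !hit&set,
#'   !hit&!set) and `odds_ratio` is the sample odds ratio `ad/bc` (with the
#'   `Inf` convention for empty off-diagonals).
#' @export
biomarker_enrichment <- function(hit_genes, universe, biomarker_sets,
                                 alternative = "two.sided") {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  hit_genes <- unique(hit_genes)
  extra <- setdiff(hit_genes, universe)
  if (length(extra))
    stop("hit genes outside the universe: ", paste(head(extra, 5L),
                                                   collapse = ", "))
  rows <- lapply(names(biomarker_sets), function(id) {
    set <- intersect(unique(biomarker_sets[[id]]), universe)
    a <- length(intersect(hit_genes, set))
    b <- length(hit_genes) - a
    cc <- length(set) - a
    d <- length(universe) - a - b - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE),
                            alternative = alternative)$p.value
    or <- if (b == 0L || cc == 0L) {
      if (a == 0L || d == 0L) NaN else Inf
    } else a * d / (b * cc)
    data.frame(gene_set_id = id, a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Read an MS peptide list / biomarker gene sets
#'
#' MS lists are plain text, one peptide per line; biomarker sets are a
#' two-column TSV (`set_id`, `gene`) with a header row.
#'
#' @param path input file.
#' @name stats_io
#' @export
read_ms_peptides <- function(path) {
  x <- trimws(readLines(path))
  unique(toupper(x[nzchar(x)]))
}

#' @rdname stats_io
#' @export
read_biomarker_sets <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  split(df[[2L]], df[[1L]])
}
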