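#' Construct a transcript model
#'
#' A transcript model is the exon-chain scaffold used throughout the package:
#' an ordered set of exons in genomic coordinates plus an optional annotated
#' CDS span.  Coordinates are 0-based half-open.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column integer matrix (`start`, `end`), 0-based half-open;
#'   rows are sorted by start and must not overlap.
#' @param cds optional length-2 integer vector: genomic CDS span
#'   `[cds_start, cds_end)`, which must lie within the exon union.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript ", transcript_id, ": exon with end <= start")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("transcript ", transcript_id, ": overlapping exons")
  if (!strand %in% c("+", "-"))
    stop("transcript ", transcript_id, ": strand must be '+' or '-'")
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    inside <- any(cds[1L] >= exons[, 1L] & cds[1L] < exons[, 2L]) &&
      any(cds[2L] > exons[, 1L] & cds[2L] <= exons[, 2L])
    if (!inside)
      stop("transcript ", transcript_id, ": CDS span outside exon union")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s:%s %d exon(s)%s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              if (is.null(x$cds)) "" else " +CDS"))
  invisible(x)
}

# introns of a transcript model as a k x 2 matrix (possibly 0 rows)
tx_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(matrix(integer(), ncol = 2L,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = tx$exons[-n, 2L], end = tx$exons[-1L, 1L])
}

#' Read a Gencode-dialect GTF into transcript models
#'
#' Uses `rtracklayer` for the parsing proper; a light pre-scan reports
#' malformed lines by number.  Exon features are mandatory, CDS features
#' optional (their genomic span becomes the model's CDS).  GTF 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention.
#'
#' @param path GTF file. Features other than exon/CDS are ignored.
#' @return Named list of [transcript_model()] objects (names = transcript ids).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  nf <- count.fields(path, sep = "\t", comment.char = "#", quote = "")
  bad <- which(!is.na(nf) & nf != 9L)
  if (length(bad))
    stop("malformed GTF line ", bad[1L], " in ", path,
         ": expected 9 tab-separated fields, found ", nf[bad[1L]])
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) stop("no exon/CDS features in ", path)
  tid <- as.character(S4Vectors::mcols(gr)$transcript_id)
  gid <- as.character(S4Vectors::mcols(gr)$gene_id)
  if (anyNA(tid))
    stop("GTF exon/CDS feature without transcript_id in ", path)
  df <- data.frame(
    tid = tid, gid = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    stringsAsFactors = FALSE)
  out <- lapply(split(df, df$tid), function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L)
      stop("transcript ", d$tid[1L], " has CDS but no exon features")
    cds <- NULL
    cd <- d[d$type == "CDS", , drop = FALSE]
    if (nrow(cd)) cds <- c(min(cd$start), max(cd$end))
    transcript_model(d$tid[1L], ex$gid[1L], ex$chrom[1L], ex$strand[1L],
                     cbind(ex$start, ex$end), cds = cds)
  })
  out[order(names(out))]
}

#' Write transcript models to GTF
#'
#' Inverse of [read_gtf()]: emits exon features (and CDS features where the
#' model has a CDS span), converting back to 1-based inclusive coordinates.
#'
#' @param models named list of transcript models.
#' @param path output file.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(tx) {
    ex <- sprintf(
      "%s\tsplicetope\texon\t%d\t%d\t.\t%s\t.\ttranscript_id \"%s\"; gene_id \"%s\";",
      tx$chrom, tx$exons[, 1L] + 1L, tx$exons[, 2L], tx$strand,
      tx$transcript_id, tx$gene_id)
    if (is.null(tx$cds)) return(ex)
    # clip CDS span to exons so each CDS feature is genuinely exonic
    keep <- tx$exons[, 2L] > tx$cds[1L] & tx$exons[, 1L] < tx$cds[2L]
    cs <- pmax(tx$exons[keep, 1L], tx$cds[1L])
    ce <- pmin(tx$exons[keep, 2L], tx$cds[2L])
    cd <- sprintf(
      "%s\tsplicetope\tCDS\t%d\t%d\t.\t%s\t.\ttranscript_id \"%s\"; gene_id \"%s\";",
      tx$chrom, cs + 1L, ce, tx$strand, tx$transcript_id, tx$gene_id)
    c(ex, cd)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path multi-record FASTA; the header up to the first whitespace is
#'   the chromosome name.
#' @return Named character vector of chromosome sequences (uppercase).
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write a genome FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70L)
  invisible(path)
}

# fetch genome[chrom][start, end) with bounds checking; 0-based half-open
genome_slice <- function(genome, chrom, start, end) {
  seq <- genome[[chrom]]
  if (is.null(seq)) stop("chromosome not in genome: ", chrom)
  if (start < 0L || end > nchar(seq))
    stop(sprintf("interval %s:%d-%d outside chromosome bounds (length %d)",
                 chrom, start, end, nchar(seq)))
  substr(seq, start + 1L, end)
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences in transcript (5'→3') order; for minus
#' strand models the concatenated forward-strand sequence is
#' reverse-complemented.
#'
#' @param tx a [transcript_model()] or an `altered_transcript`.
#' @param genome named character vector from [read_genome()].
#' @return Nucleotide string.
#' @export
spliced_sequence <- function(tx, genome) {
  parts <- vapply(seq_len(nrow(tx$exons)), function(i)
    genome_slice(genome, tx$chrom, tx$exons[i, 1L], tx$exons[i, 2L]), "")
  fwd <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp(fwd) else fwd
}

#' Read a transcript expression table
#'
#' @param path TSV with header; first column transcript ids, remaining
#'   columns one TPM value per sample.
#' @return Numeric matrix, rows = transcripts, columns = samples.
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0))
    stop("expression table contains negative or non-finite values")
  m
}

# longest ATG->stop ORF of a nucleotide string; returns protein (no stop) or NULL
longest_orf_protein <- function(seq) {
  orf <- longest_orf(seq)
  if (is.null(orf)) NULL else orf$protein
}

#' Select the per-gene reference transcriptome and proteome
#'
#' Per gene, picks the transcript with the largest mean TPM, keeping only
#' transcripts whose mean exceeds `tpm_min` (default 1 TPM); the mean is taken
#' over `control_samples` when given, otherwise over all samples.  Ties are
#' broken by lexicographically smallest transcript id so the choice is
#' deterministic.  The reference protein is the translated annotated CDS, or
#' the longest ORF of the spliced sequence when no CDS is annotated; selected
#' transcripts yielding no protein of at least `min_orf_aa` residues drop
#' their gene from the proteome (with a message).
#'
#' @param transcripts named list of transcript models.
#' @param expr TPM matrix from [read_expression()]; transcripts missing from
#'   it are treated as expression 0.
#' @param genome named character vector from [read_genome()].
#' @param control_samples optional character vector of column names to
#'   average over (normal/control set).
#' @param tpm_min minimum mean TPM for a transcript to qualify.
#' @param min_orf_aa minimum protein length admitted to the proteome.
#' @return List with `gene_to_transcript` (named character vector) and
#'   `proteome` (named character vector of amino-acid strings, names =
#'   transcript ids).
#' @export
select_reference_transcriptome <- function(transcripts, expr, genome,
                                           control_samples = NULL,
                                           tpm_min = 1, min_orf_aa = 25L) {
  if (is.null(expr) || ncol(expr) == 0L || nrow(expr) == 0L)
    stop("empty expression table")
  cols <- if (!is.null(control_samples)) {
    missing_cols <- setdiff(control_samples, colnames(expr))
    if (length(missing_cols))
      stop("control samples absent from expression table: ",
           paste(missing_cols, collapse = ", "))
    control_samples
  } else colnames(expr)
  tids <- names(transcripts)
  means <- setNames(numeric(length(tids)), tids)
  hit <- intersect(tids, rownames(expr))
  means[hit] <- rowMeans(expr[hit, cols, drop = FALSE])
  if (length(setdiff(tids, rownames(expr))))
    message(length(setdiff(tids, rownames(expr))),
            " transcript(s) missing from expression table, treated as 0 TPM")

  ok <- names(means)[means > tpm_min]
  if (!length(ok))
    return(list(gene_to_transcript = setNames(character(), character()),
                proteome = setNames(character(), character())))
  gid <- vapply(transcripts[ok], `[[`, "", "gene_id")
  # max mean per gene, ties to lexicographically smallest transcript id
  ord <- order(gid, -means[ok], ok)
  sel <- ok[ord][!duplicated(gid[ord])]
  g2t <- setNames(sel, gid[match(sel, ok)])

  proteome <- character(0)
  keep <- character(0)
  for (g in names(g2t)) {
    tx <- transcripts[[g2t[[g]]]]
    prot <- reference_protein(tx, genome)
    if (is.null(prot) || nchar(prot) < min_orf_aa) {
      message("gene ", g, ": reference transcript ", tx$transcript_id,
              " yields no ORF >= ", min_orf_aa, " aa; excluded from proteome")
      next
    }
    proteome[[tx$transcript_id]] <- prot
    keep <- c(keep, g)
  }
  list(gene_to_transcript = g2t[keep], proteome = proteome)
}

# protein of a transcript: translated annotated CDS, else longest ORF
reference_protein <- function(tx, genome) {
  seq <- spliced_sequence(tx, genome)
  if (!is.null(tx$cds)) {
    off <- cds_transcript_offsets(tx)
    cds_seq <- substr(seq, off[1L] + 1L, off[2L])
    prot <- translate_nt(cds_seq)
    prot <- sub("\\*.*$", "", prot)   # trim at stop
    if (nchar(prot)) return(prot)
  }
  longest_orf_protein(seq)
}

# transcript-coordinate [start, end) of the CDS span of a model
cds_transcript_offsets <- function(tx) {
  stopifnot(!is.null(tx$cds))
  g2t <- function(gpos) genomic_to_transcript(tx, gpos)
  if (tx$strand == "+") {
    c(g2t(tx$cds[1L]), g2t(tx$cds[2L] - 1L) + 1L)
  } else {
    c(g2t(tx$cds[2L] - 1L), g2t(tx$cds[1L]) + 1L)
  }
}

# map a genomic position (0-based, must be exonic) to transcript coordinate
genomic_to_transcript <- function(tx, gpos) {
  ex <- tx$exons
  lens <- ex[, 2L] - ex[, 1L]
  i <- which(gpos >= ex[, 1L] & gpos < ex[, 2L])
  if (!length(i)) return(NA_integer_)
  i <- i[1L]
  if (tx$strand == "+") {
    sum(lens[seq_len(i - 1L)]) + (gpos - ex[i, 1L])
  } else {
    n <- nrow(ex)
    before <- if (i < n) sum(lens[(i + 1L):n]) else 0L
    before + (ex[i, 2L] - 1L - gpos)
  }
}
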