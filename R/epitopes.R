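#' Enumerate candidate peptides
#'
#' All distinct substrings of each length in `[kmin, kmax]` (MHC-I default
#' 8–11).
#'
#' @param protein amino-acid string.
#' @param kmin,kmax peptide length range.
#' @return Character vector (set semantics; empty when the protein is
#'   shorter than `kmin`).
#' @export
enumerate_kmers <- function(protein, kmin = 8L, kmax = 11L) {
  L <- nchar(protein)
  if (is.null(protein) || L < kmin) return(character())
  unique(unlist(lapply(kmin:min(kmax, L), function(k)
    substring(protein, 1:(L - k + 1L), k:L)), use.names = FALSE))
}

# k-mers with the 1-based residue position of each occurrence start
kmers_with_pos <- function(protein, kmin = 8L, kmax = 11L) {
  L <- nchar(protein)
  if (L < kmin) return(data.frame(peptide = character(), start = integer(),
                                  end = integer()))
  do.call(rbind, lapply(kmin:min(kmax, L), function(k)
    data.frame(peptide = substring(protein, 1:(L - k + 1L), k:L),
               start = 1:(L - k + 1L), end = k:L,
               stringsAsFactors = FALSE)))
}

#' Reference-proteome peptide index
#'
#' Hash-style membership oracle over every `kmin`–`kmax`-mer occurring in
#' any reference protein; used to enforce that neoepitope candidates are
#' absent from the reference proteome.
#'
#' @param proteome named character vector of protein sequences.
#' @param kmin,kmax peptide length range (must match the enumeration).
#' @return Object of class `peptide_index`.
#' @export
build_reference_index <- function(proteome, kmin = 8L, kmax = 11L) {
  if (!length(proteome)) stop("empty proteome")
  kmers <- unique(unlist(lapply(unname(proteome), enumerate_kmers,
                                kmin = kmin, kmax = kmax),
                         use.names = FALSE))
  structure(list(kmers = kmers, kmin = kmin, kmax = kmax),
            class = "peptide_index")
}

#' @param index a `peptide_index`.
#' @param peptides character vector of query peptides.
#' @rdname build_reference_index
#' @export
peptide_in_index <- function(index, peptides) {
  peptides %in% index$kmers
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("<peptide_index %d distinct %d-%d-mers>\n",
              length(x$kmers), x$kmin, x$kmax))
  invisible(x)
}

#' Call splicing-derived neoepitopes and splicing-affected self-epitopes
#'
#' Peptides common to the reference and altered protein are discarded.
#' Neoepitopes are altered-protein peptides absent from the whole reference
#' proteome with binding affinity at or below the threshold for at least one
#' of the sample's alleles; self-epitopes are reference-protein binders
#' whose encoding is lost in the altered protein.  When the altered protein
#' is absent because of NMD or loss of the ORF, self-epitopes are restricted
#' to reference peptides overlapping the event's footprint on the reference
#' protein (`self_scope = "event"`, the default) or taken from the whole
#' protein (`"protein"`); events that only touch the UTR yield no calls.
#' Peptides containing `X` (fuzzy codons) are never called.
#'
#' @param pair an `orf_pair` from [derive_orf_pair()].
#' @param index reference [build_reference_index()].
#' @param affinities data.frame `peptide`, `hla_allele`, `affinity_nm`
#'   covering the candidates for the sample's alleles.
#' @param threshold_nm binder threshold, default 500 nM (300 nM reproduces
#'   the stricter secondary analysis).
#' @param self_scope `"event"` or `"protein"`, see above.
#' @param sample_id recorded in the calls.
#' @param kmin,kmax peptide length range.
#' @param strict error (rather than warn and skip) on candidates missing
#'   from `affinities`.
#' @return data.frame of epitope calls: `peptide`, `hla_allele`,
#'   `affinity_nm`, `epitope_class` (`SPLICING_NEOEPITOPE` / `SELF_EPITOPE`),
#'   `event_id`, `sample_id`.
#' @export
call_epitopes <- function(pair, index, affinities, threshold_nm = 500,
                          self_scope = c("event", "protein"),
                          sample_id = NA_character_, kmin = 8L, kmax = 11L,
                          strict = FALSE) {
  self_scope <- match.arg(self_scope)
  empty <- data.frame(peptide = character(), hla_allele = character(),
                      affinity_nm = numeric(), epitope_class = character(),
                      event_id = character(), sample_id = character(),
                      stringsAsFactors = FALSE)
  if (isTRUE(pair$flags$utr_only)) return(empty)
  ref_k <- enumerate_kmers(pair$ref_protein, kmin, kmax)
  neo <- self <- character()
  if (!is.null(pair$alt_protein)) {
    alt_k <- enumerate_kmers(pair$alt_protein, kmin, kmax)
    neo <- setdiff(alt_k, ref_k)
    neo <- neo[!peptide_in_index(index, neo)]
    self <- setdiff(ref_k, alt_k)
  } else if (pair$flags$nmd_discarded || pair$flags$no_orf) {
    self <- if (self_scope == "protein" || is.null(pair$ref_affected_aa)) {
      ref_k
    } else {
      kp <- kmers_with_pos(pair$ref_protein, kmin, kmax)
      w <- pair$ref_affected_aa
      unique(kp$peptide[kp$start <= w[2L] & kp$end >= w[1L]])
    }
  }
  neo <- neo[!grepl("X", neo, fixed = TRUE)]
  self <- self[!grepl("X", self, fixed = TRUE)]

  score <- function(peps, class) {
    if (!length(peps)) return(empty)
    hit <- affinities[affinities$peptide %in% peps, , drop = FALSE]
    missing <- setdiff(peps, hit$peptide)
    if (length(missing)) {
      msg <- paste0(length(missing), " candidate peptide(s) without ",
                    "affinity predictions")
      if (strict) stop(msg) else warning(msg, ", skipped")
    }
    hit <- hit[hit$affinity_nm <= threshold_nm, , drop = FALSE]
    if (!nrow(hit)) return(empty)
    data.frame(peptide = hit$peptide, hla_allele = hit$hla_allele,
               affinity_nm = hit$affinity_nm, epitope_class = class,
               event_id = pair$event_id, sample_id = sample_id,
               stringsAsFactors = FALSE)
  }
  out <- rbind(score(neo, "SPLICING_NEOEPITOPE"),
               score(self, "SELF_EPITOPE"))
  out <- out[order(out$epitope_class, out$peptide, out$hla_allele), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

surrogate_env <- new.env(parent = emptyenv())

load_surrogate_weights <- function() {
  if (is.null(surrogate_env$w)) {
    path <- system.file("extdata", "surrogate_weights.tsv",
                        package = "splicetope")
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE)
    surrogate_env$w <- df
  }
  surrogate_env$w
}

#' Deterministic surrogate MHC affinity predictor
#'
#' A pure-function stand-in for an external binding predictor, with no
#' predictive value: each allele ships a fixed position-weight matrix
#' (`inst/extdata/surrogate_weights.tsv`; residues x positions 1–15, values
#' in `[0, 1]`).  A peptide's score `s` is the weighted mean of its residue
#' weights with the classic anchor positions (2 and the C-terminus) counted
#' four-fold, and its affinity is `50000^(1 - s)` nM — `s = 1` gives 1 nM,
#' `s = 0` gives 50000 nM.  Identical inputs always give identical output.
#'
#' @param peptides character vector (lengths 8–15, 20-letter alphabet).
#' @param alleles HLA allele names; must be among the shipped set.
#' @return data.frame `peptide`, `hla_allele`, `affinity_nm`,
#'   `predictor_id`, one row per peptide x allele.
#' @export
predict_affinity_surrogate <- function(peptides, alleles) {
  w <- load_surrogate_weights()
  known <- unique(w$allele)
  bad <- setdiff(alleles, known)
  if (length(bad))
    stop("unknown allele(s) ", paste(bad, collapse = ", "),
         "; shipped alleles: ", paste(known, collapse = ", "))
  peptides <- unique(peptides)
  rows <- lapply(alleles, function(al) {
    wa <- w[w$allele == al, , drop = FALSE]
    wa <- wa[order(wa$pos), , drop = FALSE]
    wm <- as.matrix(wa[, -(1:2)])        # positions x residues
    rownames(wm) <- NULL
    s <- vapply(peptides, function(p) {
      k <- nchar(p)
      aa <- strsplit(p, "")[[1L]]
      col <- match(aa, colnames(wm))
      if (anyNA(col)) stop("peptide with non-standard residue: ", p)
      if (k > nrow(wm)) stop("peptide longer than ", nrow(wm), ": ", p)
      vals <- wm[cbind(seq_len(k), col)]
      wt <- rep(1, k); wt[c(2L, k)] <- 4
      sum(vals * wt) / sum(wt)
    }, 1, USE.NAMES = FALSE)
    data.frame(peptide = peptides, hla_allele = al,
               affinity_nm = 50000^(1 - s), predictor_id = "surrogate-pwm",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read NetMHC-style affinity output
#'
#' Auto-detects a header carrying peptide, allele and affinity (nM) columns
#' in the tabular (whitespace- or tab-separated) output dialects of
#' NetMHC-4 / NetMHCpan-4 / NetMHCII; column names such as `Peptide`,
#' `Allele`/`HLA`/`MHC`, `Affinity(nM)`/`Aff(nM)`/`nM` are recognized.
#'
#' @param path predictor output file.
#' @return data.frame `peptide`, `hla_allele`, `affinity_nm`,
#'   `predictor_id` (empty for an empty file).
#' @export
read_netmhc_output <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^[#-]", lines)]
  if (!length(lines))
    return(data.frame(peptide = character(), hla_allele = character(),
                      affinity_nm = numeric(), predictor_id = character(),
                      stringsAsFactors = FALSE))
  header <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  pep_col <- which(tolower(header) == "peptide")
  al_col <- which(tolower(header) %in% c("allele", "hla", "mhc"))
  aff_col <- which(tolower(header) %in%
                     c("affinity(nm)", "aff(nm)", "nm", "affinity"))
  if (!length(pep_col) || !length(al_col) || !length(aff_col))
    stop("unrecognized predictor output dialect in ", path,
         ": need peptide, allele and affinity (nM) columns, found: ",
         paste(header, collapse = " "))
  body <- strsplit(trimws(lines[-1L]), "[ \t]+")
  ok <- lengths(body) >= max(pep_col, al_col, aff_col)
  body <- body[ok]
  data.frame(
    peptide = vapply(body, `[`, "", pep_col[1L]),
    hla_allele = vapply(body, `[`, "", al_col[1L]),
    affinity_nm = as.numeric(vapply(body, `[`, "", aff_col[1L])),
    predictor_id = "netmhc", stringsAsFactors = FALSE)
}

#' Write candidate peptides as FASTA for an external predictor
#'
#' @param peptides character vector; headers are `pep1..pepN` or the
#'   vector's names when present.
#' @param path output file.
#' @export
write_peptides_fasta <- function(peptides, path) {
  nm <- names(peptides)
  if (is.null(nm)) nm <- paste0("pep", seq_along(peptides))
  writeLines(as.vector(rbind(paste0(">", nm), unname(peptides))), path)
  invisible(path)
}
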