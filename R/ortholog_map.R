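## Cross-species orthologous-exon calling. An exon pair is orthologous
## when (1) the host genes' proteins are at least 75% conserved, (2) the
## exons occupy the same transcription-order position in at least one
## annotated transcript pair, and (3) the translated local alignment of
## the exon sequences has an e-value below 0.05.
##
## The translated search is an internal Smith-Waterman over the three
## forward reading frames of each (coding-strand-oriented) exon with a
## closed-form Karlin-Altschul e-value, so e-values are comparable within
## this package; that suffices for thresholding.

# gapped BLOSUM62 Karlin-Altschul constants (gap open 11 / extend 1)
.ka_K <- 0.041
.ka_lambda <- 0.267

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

#' Global protein percent identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps open 11 /
#' extend 1); identity is the number of identically aligned residue pairs
#' over all alignment columns (gap columns included in the denominator),
#' times 100. `X` residues are allowed but never count as identical.
#'
#' @param protein_a,protein_b amino-acid sequences (character or
#'   `AAString`), non-empty.
#' @return Percent identity in \[0, 100\].
#' @export
gene_conservation <- function(protein_a, protein_b) {
  a <- toupper(as.character(protein_a)); b <- toupper(as.character(protein_b))
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty protein sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  ident <- sum(pa == sa & pa != "-" & pa != "X")
  100 * ident / length(pa)
}

#' Same-position test for an exon pair across transcript annotations
#'
#' TRUE iff some annotated transcript of gene A and some transcript of
#' gene B place the two exons at the same 1-based transcription-order
#' index (existential over transcript pairs).
#'
#' @param exon_a,exon_b exon identifiers.
#' @param transcripts_a,transcripts_b lists of transcripts, each a
#'   character vector of exon ids in transcription order.
#' @return Logical.
#' @export
exon_index_match <- function(exon_a, transcripts_a, exon_b, transcripts_b) {
  idx <- function(exon, transcripts) {
    found <- unlist(lapply(transcripts, function(tr) match(exon, tr)))
    found <- found[!is.na(found)]
    if (length(found) == 0L)
      stop("exon '", exon, "' not found in any transcript")
    found
  }
  length(intersect(idx(exon_a, transcripts_a),
                   idx(exon_b, transcripts_b))) > 0L
}

# three forward-frame translations (stop codons kept as '*')
.translations <- function(nt) {
  nt <- toupper(as.character(nt))
  lapply(1:3, function(f) {
    width <- ((nchar(nt) - f + 1L) %/% 3L) * 3L
    if (width < 3L) return(NULL)
    Biostrings::translate(
      Biostrings::DNAString(substr(nt, f, f + width - 1L)),
      if.fuzzy.codon = "X")
  })
}

#' Translated local-alignment e-value for an exon pair
#'
#' Best Smith-Waterman score over the 3 x 3 pairings of forward-frame
#' translations (sequences are supplied coding-strand oriented, so reverse
#' frames are omitted unless `all_frames = TRUE` adds the reverse
#' complement's frames), scored with BLOSUM62 and affine gaps 11/1. The
#' e-value is the Karlin-Altschul closed form
#' \deqn{E = K \, m \, n \, e^{-\lambda S}}
#' with K = 0.041 and lambda = 0.267 (gapped BLOSUM62 constants), m the
#' total translated length of sequence A over its searched frames, and n
#' likewise for B — or `db_size_nt / 3` when a database-style search space
#' is requested.
#'
#' @param exon_seq_a,exon_seq_b nucleotide sequences, each >= 12 nt.
#' @param db_size_nt optional database size in nt replacing sequence B's
#'   side of the search space; default is the pairwise product.
#' @param all_frames also search the three reverse-complement frames of
#'   each sequence (for unoriented input).
#' @return list with `evalue`, `score`, and `frames` (the best frame
#'   pair).
#' @export
translated_exon_evalue <- function(exon_seq_a, exon_seq_b, db_size_nt = NULL,
                                   all_frames = FALSE) {
  a <- toupper(as.character(exon_seq_a)); b <- toupper(as.character(exon_seq_b))
  if (nchar(a) < 12L || nchar(b) < 12L)
    stop("exon sequences must be at least 12 nt")
  expand <- function(nt) {
    tr <- .translations(nt)
    if (all_frames)
      tr <- c(tr, .translations(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(nt)))))
    Filter(Negate(is.null), tr)
  }
  ta <- expand(a); tb <- expand(b)
  bl <- .blosum62()
  best <- -Inf; best_pair <- c(NA_integer_, NA_integer_)
  for (i in seq_along(ta)) for (j in seq_along(tb)) {
    s <- Biostrings::pairwiseAlignment(
      ta[[i]], tb[[j]], substitutionMatrix = bl,
      gapOpening = 11, gapExtension = 1, type = "local",
      scoreOnly = TRUE)
    if (s > best) { best <- s; best_pair <- c(i, j) }
  }
  m <- sum(lengths(ta))
  n <- if (is.null(db_size_nt)) sum(lengths(tb)) else db_size_nt / 3
  list(evalue = .ka_K * m * n * exp(-.ka_lambda * best),
       score = best, frames = best_pair)
}

#' Call an orthologous exon pair by the three-criterion rule
#'
#' The pair is orthologous iff gene conservation >= `min_identity`
#' (inclusive), the exons match position in some transcript pair, and the
#' translated e-value is strictly below `max_evalue`. All three criterion
#' values are reported even when the conjunction fails early, and each
#' criterion can be disabled.
#'
#' @param pair list with `protein_a`, `protein_b` (amino-acid sequences),
#'   `transcripts_a`, `transcripts_b` (lists of exon-id vectors in
#'   transcription order).
#' @param exon_a,exon_b exon ids within the pair's transcripts.
#' @param exon_seq_a,exon_seq_b the exon nucleotide sequences
#'   (coding-strand oriented).
#' @param min_identity percent-identity threshold (default 75, inclusive).
#' @param max_evalue e-value threshold (default 0.05, strict).
#' @param db_size_nt passed to [translated_exon_evalue()].
#' @param use logical vector of length 3 (identity, index, evalue)
#'   enabling each criterion; disabled criteria always pass.
#' @return list (`ortholog_call`) with `exon_a`, `exon_b`,
#'   `gene_identity_pct`, `exon_index_matched`, `evalue`, `is_ortholog`.
#' @export
call_orthologous_exons <- function(pair, exon_a, exon_b, exon_seq_a,
                                   exon_seq_b, min_identity = 75,
                                   max_evalue = 0.05, db_size_nt = NULL,
                                   use = c(TRUE, TRUE, TRUE)) {
  ident <- gene_conservation(pair$protein_a, pair$protein_b)
  idx <- exon_index_match(exon_a, pair$transcripts_a, exon_b,
                          pair$transcripts_b)
  ev <- translated_exon_evalue(exon_seq_a, exon_seq_b,
                               db_size_nt = db_size_nt)$evalue
  ok <- (!use[1L] || ident >= min_identity) &&
    (!use[2L] || idx) &&
    (!use[3L] || ev < max_evalue)
  structure(list(exon_a = exon_a, exon_b = exon_b,
                 gene_identity_pct = ident, exon_index_matched = idx,
                 evalue = ev, is_ortholog = ok),
            class = "ortholog_call")
}

#' Cross-species splicing-change concordance
#'
#' Spearman's rank correlation of delta-PSI across orthologous exon
#' pairs, plus the per-pair table ordered by |delta-PSI| in species A.
#'
#' @param calls data.frame with columns `exon_a`, `exon_b`,
#'   `dpsi_a`, `dpsi_b` (at least 3 rows).
#' @return list with `rho` and `table`.
#' @export
cross_species_concordance <- function(calls) {
  stopifnot(all(c("exon_a", "exon_b", "dpsi_a", "dpsi_b") %in% names(calls)))
  if (nrow(calls) < 3L)
    stop("at least 3 orthologous pairs required")
  rho <- spearman_rho(calls$dpsi_a, calls$dpsi_b)
  list(rho = rho,
       table = calls[order(-abs(calls$dpsi_a)), , drop = FALSE])
}
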