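## YGCY motif enrichment in five sequence windows around regulated
## cassette exons, relative to composition-matched control 4-mers and to
## non-regulated exons.
##
## The five windows are: the cassette exon itself; the intronic 1-250 nt
## immediately 5' and 3' of the cassette; and the intronic 1-250 nt 3' of
## the upstream constitutive exon and 5' of the downstream constitutive
## exon. "5'/3'" always means transcriptional direction; minus-strand
## sequences are reverse-complemented. When the two windows claimed from
## the two ends of a short intron would overlap, each is truncated at the
## intron midpoint.

#' Motif set constructors
#'
#' `ygcy_motifs()` is the canonical YGCY preset \{TGCT, TGCC, CGCT, CGCC\}
#' (Y a pyrimidine). `ygcy_printed_motifs()` is an alternative published
#' list \{GCTT, CGCT, TGCT, GCGC\} that deviates from the strict YGCY
#' pattern; both are provided so either can be run. `motif_set()` builds a
#' custom set.
#'
#' @param name label for the set.
#' @param motifs character vector of distinct 4-mers over A/C/G/T.
#' @return An object of class `motif_set`.
#' @export
motif_set <- function(name, motifs) {
  motifs <- unique(toupper(motifs))
  if (length(motifs) == 0L) stop("motif set must be non-empty")
  if (any(nchar(motifs) != 4L) || any(grepl("[^ACGT]", motifs)))
    stop("motifs must be 4-mers over A/C/G/T")
  structure(list(name = name, motifs = motifs), class = "motif_set")
}

#' @rdname motif_set
#' @export
ygcy_motifs <- function() motif_set("YGCY", c("TGCT", "TGCC", "CGCT", "CGCC"))

#' @rdname motif_set
#' @export
ygcy_printed_motifs <- function()
  motif_set("YGCY-printed", c("GCTT", "CGCT", "TGCT", "GCGC"))

# midpoint rule: how much of an intron of length L each end may claim
# when both ends request a window of w nt
.claims <- function(L, w) {
  L <- max(L, 0L)
  if (2L * w <= L) c(w, w) else c(ceiling(L / 2), floor(L / 2))
}

# genomic 0-based half-open coordinates of the five windows; exons are in
# transcription order (rows of model$exons)
.window_coords <- function(model, cassette_index, window_nt = 250L) {
  n <- nrow(model$exons)
  if (cassette_index <= 1L || cassette_index >= n)
    stop("cassette exon must have constitutive neighbours on both sides")
  cas <- model$exons[cassette_index, ]
  up <- model$exons[cassette_index - 1L, ]   # 5' neighbour (transcription)
  down <- model$exons[cassette_index + 1L, ] # 3' neighbour
  if (model$strand == "+") {
    L5 <- cas$start - up$end
    L3 <- down$start - cas$end
    c5 <- .claims(L5, window_nt)  # c5[1] cassette side, c5[2] exon side
    c3 <- .claims(L3, window_nt)
    list(
      cassette_exon = list(start = cas$start, end = cas$end),
      intron_5prime_of_cassette =
        list(start = cas$start - c5[1L], end = cas$start),
      intron_3prime_of_cassette =
        list(start = cas$end, end = cas$end + c3[1L]),
      intron_3prime_of_upstream_constitutive =
        list(start = up$end, end = up$end + c5[2L]),
      intron_5prime_of_downstream_constitutive =
        list(start = down$start - c3[2L], end = down$start))
  } else {
    L5 <- up$start - cas$end
    L3 <- cas$start - down$end
    c5 <- .claims(L5, window_nt)
    c3 <- .claims(L3, window_nt)
    list(
      cassette_exon = list(start = cas$start, end = cas$end),
      intron_5prime_of_cassette =
        list(start = cas$end, end = cas$end + c5[1L]),
      intron_3prime_of_cassette =
        list(start = cas$start - c3[1L], end = cas$start),
      intron_3prime_of_upstream_constitutive =
        list(start = up$start - c5[2L], end = up$start),
      intron_5prime_of_downstream_constitutive =
        list(start = down$end, end = down$end + c3[2L]))
  }
}

.get_chrom_seq <- function(genome, chrom) {
  if (is(genome, "DNAStringSet")) {
    if (!(chrom %in% names(genome))) stop("sequence '", chrom, "' not in genome")
    return(genome[[chrom]])
  }
  if (is(genome, "DNAString")) return(genome)
  stop("genome must be a DNAString or named DNAStringSet")
}

#' Extract the five sequence windows around a cassette exon
#'
#' Windows are taken strand-aware and returned coding-strand oriented
#' (minus-strand extractions are reverse-complemented). Intronic windows
#' are truncated where the intron is shorter than `window_nt`, with
#' overlapping claims from the two ends of a short intron cut at the
#' intron midpoint.
#'
#' @param gene_model a [gene_model()].
#' @param cassette_exon_index 1-based transcription-order index of the
#'   cassette exon; must not be the first or last exon. Defaults to the
#'   model's `cassette_index`.
#' @param genome a named [Biostrings::DNAStringSet] (keyed by chromosome)
#'   or a single [Biostrings::DNAString].
#' @param window_nt intronic window length (default 250).
#' @return Named list of five `region_window` objects, each with `name`,
#'   `seq` (uppercase character), `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
extract_windows <- function(gene_model, cassette_exon_index = NULL, genome,
                            window_nt = 250L) {
  if (is.null(cassette_exon_index)) cassette_exon_index <- gene_model$cassette_index
  if (is.null(cassette_exon_index)) stop("no cassette exon index given")
  coords <- .window_coords(gene_model, cassette_exon_index, window_nt)
  chrom_seq <- .get_chrom_seq(genome, gene_model$chrom)
  out <- lapply(names(coords), function(w) {
    co <- coords[[w]]
    s <- if (co$end > co$start)
      Biostrings::subseq(chrom_seq, start = co$start + 1L, end = co$end)
    else Biostrings::DNAString("")
    if (gene_model$strand == "-") s <- Biostrings::reverseComplement(s)
    structure(list(name = w, seq = toupper(as.character(s)),
                   chrom = gene_model$chrom, start = co$start, end = co$end,
                   strand = gene_model$strand), class = "region_window")
  })
  names(out) <- names(coords)
  out
}

.window_seq <- function(window) {
  if (inherits(window, "region_window")) window$seq else toupper(window)
}

#' Count motif occurrences in a window
#'
#' Overlapping occurrences are counted at every offset; positions
#' containing N never match. Sequences shorter than 4 nt count 0.
#'
#' @param window a `region_window` or a character sequence.
#' @param motifs a [motif_set()].
#' @return Integer occurrence count summed over the set's motifs.
#' @export
count_motifs <- function(window, motifs) {
  s <- .window_seq(window)
  if (nchar(s) < 4L) return(0L)
  subj <- Biostrings::DNAString(s)
  sum(vapply(motifs$motifs, function(m)
    Biostrings::countPattern(m, subj, fixed = TRUE), integer(1L)))
}

.at_count <- function(kmer) sum(strsplit(kmer, "")[[1L]] %in% c("A", "T"))
.cg_count <- function(kmer) {
  b <- strsplit(kmer, "")[[1L]]
  sum(b[-length(b)] == "C" & b[-1L] == "G")
}

#' Composition-matched control 4-mers
#'
#' All 4-mers over A/C/G/T with the same A+T base count and the same CpG
#' (CG dinucleotide) count as the query motif, excluding the query itself
#' and every motif in `exclude`.
#'
#' @param motif a 4-mer.
#' @param exclude a [motif_set()] whose members are removed from the
#'   control set (typically the whole analysis set, to avoid
#'   self-contamination of the control mean).
#' @return Character vector of control 4-mers.
#' @export
control_kmers <- function(motif, exclude = NULL) {
  motif <- toupper(motif)
  if (nchar(motif) != 4L || grepl("[^ACGT]", motif))
    stop("motif must be a 4-mer over A/C/G/T")
  bases <- c("A", "C", "G", "T")
  all4 <- apply(expand.grid(bases, bases, bases, bases,
                            stringsAsFactors = FALSE), 1L, paste, collapse = "")
  want_at <- .at_count(motif); want_cg <- .cg_count(motif)
  keep <- vapply(all4, function(k)
    .at_count(k) == want_at && .cg_count(k) == want_cg, logical(1L))
  out <- setdiff(all4[keep], c(motif, if (!is.null(exclude)) exclude$motifs))
  if (length(out) == 0L)
    stop("empty control set for '", motif,
         "'; relax the exclude policy")
  unname(out)
}

#' Length-normalised motif enrichment over control 4-mers
#'
#' Counts are pooled over all supplied windows before division. The
#' statistic is the mean per-analysed-nt frequency of the set's motifs
#' divided by the mean per-nt frequency of the pooled control 4-mers, with
#' a pseudocount added to each occurrence count to keep downstream log
#' ratios finite.
#'
#' @param windows list of `region_window` objects (or character
#'   sequences), all for one region name.
#' @param motifs a [motif_set()].
#' @param pseudocount added to the motif-mean numerator count and to each
#'   control count (default 1).
#' @return Enrichment ratio (dimensionless; 1 = no enrichment).
#' @export
enrichment_ratio <- function(windows, motifs, pseudocount = 1) {
  if (inherits(windows, "region_window") || is.character(windows))
    windows <- list(windows)
  seqs <- vapply(windows, .window_seq, character(1L))
  total_len <- sum(nchar(seqs))
  if (total_len == 0) stop("zero analysed sequence length")
  controls <- sort(unique(unlist(lapply(motifs$motifs, control_kmers,
                                        exclude = motifs))))
  subj <- Biostrings::DNAStringSet(seqs)
  pooled <- function(kmer) sum(Biostrings::vcountPattern(kmer, subj, fixed = TRUE))
  motif_mean <- mean(vapply(motifs$motifs, pooled, numeric(1L))) + pseudocount
  ctrl_mean <- mean(vapply(controls, pooled, numeric(1L)) + pseudocount)
  motif_mean / ctrl_mean
}

.windows_for_ids <- function(ids, gene_models, genome, window_nt) {
  lapply(ids, function(id) {
    m <- gene_models[[id]]
    if (is.null(m)) stop("no gene model for '", id, "'")
    extract_windows(m, genome = genome, window_nt = window_nt)
  })
}

#' Motif-enrichment heatmap cells
#'
#' For each (region, regulation class, exon-set label) the cell is
#' \deqn{\log_2\frac{E_{regulated}}{E_{non-regulated}}}
#' where E is the length-normalised enrichment of the set's motifs over
#' composition-matched control 4-mers ([enrichment_ratio()]), pooled over
#' the exon set.
#'
#' @param regulated_sets named list (one entry per exon-set label); each
#'   entry a list with components `activated` and/or `repressed`, the
#'   character vectors of regulated gene ids (keys into `gene_models`).
#' @param nonregulated character vector of non-regulated gene ids.
#' @param gene_models named list of [gene_model()] objects with
#'   `cassette_index` set.
#' @param genome named [Biostrings::DNAStringSet].
#' @param motifs a [motif_set()] (default canonical YGCY).
#' @param window_nt intronic window size (default 250).
#' @param pseudocount passed to [enrichment_ratio()].
#' @return data.frame with columns `region`, `class`, `set_label`,
#'   `log2_ratio`.
#' @export
enrichment_heatmap <- function(regulated_sets, nonregulated, gene_models,
                               genome, motifs = ygcy_motifs(),
                               window_nt = 250L, pseudocount = 1) {
  if (length(nonregulated) == 0L) stop("non-regulated set is empty")
  non_w <- .windows_for_ids(nonregulated, gene_models, genome, window_nt)
  non_ratio <- vapply(.region_names, function(r)
    enrichment_ratio(lapply(non_w, `[[`, r), motifs, pseudocount),
    numeric(1L))
  rows <- list()
  for (lab in names(regulated_sets)) {
    for (cls in intersect(c("activated", "repressed"),
                          names(regulated_sets[[lab]]))) {
      ids <- regulated_sets[[lab]][[cls]]
      if (length(ids) == 0L) stop("empty regulated set: ", lab, "/", cls)
      ws <- .windows_for_ids(ids, gene_models, genome, window_nt)
      for (r in .region_names) {
        reg_ratio <- enrichment_ratio(lapply(ws, `[[`, r), motifs, pseudocount)
        rows[[length(rows) + 1L]] <- data.frame(
          region = r, class = cls, set_label = lab,
          log2_ratio = log2(reg_ratio / non_ratio[[r]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Non-regulated cassette exons
#'
#' Tested cassette events that show no evidence of regulation in a
#' genotype: FDR above `fdr_min` and |delta-PSI| below `dpsi_max`.
#'
#' @param table an [event_table()].
#' @param genotype genotype label.
#' @param fdr_min minimum FDR (default 0.5).
#' @param dpsi_max maximum |delta-PSI| (default 0.05).
#' @return Character vector of gene ids of non-regulated cassette events.
#' @export
nonregulated_exons <- function(table, genotype, fdr_min = 0.5,
                               dpsi_max = 0.05) {
  .check_genotype(table, genotype)
  keep <- table$events$event_type == "SE" &
    !is.na(table$fdr[, genotype]) & table$fdr[, genotype] > fdr_min &
    !is.na(table$delta_psi[, genotype]) &
    abs(table$delta_psi[, genotype]) < dpsi_max
  table$events$gene_id[keep]
}
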