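## Readers and writers for the external files the pipeline touches.
##
## Conventions used throughout the package:
##  * inclusion levels (PSI) live on the 0-1 scale internally; the x100
##    percent scale is a display concern only
##  * genomic coordinates are 0-based half-open internally, whatever the
##    input dialect (BED is already 0-based half-open; GFF3 is converted)
##  * exons are indexed in transcription order: exon 1 is the 5'-most exon
##    on the coding strand

#' Construct an event table
#'
#' Container for a set of alternative-splicing events with per-replicate
#' inclusion levels and, optionally, per-genotype test results against the
#' wild-type reference.
#'
#' @param events data.frame with columns `event_id`, `event_type` (one of
#'   SE, A3SS, A5SS, RI, MXE), `gene_id`, `chrom`, `strand`, and the
#'   0-based half-open coordinates `exon_start`, `exon_end`,
#'   `upstream_start`, `upstream_end`, `downstream_start`, `downstream_end`
#'   (NA allowed for non-cassette event types).
#' @param psi numeric matrix (events x replicates) of inclusion levels in
#'   \[0,1\]; `NA` marks missing coverage. Row names must be the event ids.
#' @param sample_labels named list mapping genotype label to the character
#'   vector of its replicate column names; must cover every column of `psi`.
#' @param fdr optional numeric matrix (events x genotypes) of FDR values
#'   for the mutant-vs-wild-type comparison.
#' @param delta_psi optional numeric matrix (events x genotypes) of mean
#'   inclusion differences, mutant minus wild-type, in \[-1,1\].
#' @return An object of class `event_table`.
#' @export
event_table <- function(events, psi, sample_labels, fdr = NULL, delta_psi = NULL) {
  stopifnot(is.data.frame(events))
  req <- c("event_id", "event_type", "gene_id", "chrom", "strand",
           "exon_start", "exon_end", "upstream_start", "upstream_end",
           "downstream_start", "downstream_end")
  miss <- setdiff(req, names(events))
  if (length(miss) > 0L)
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(events$event_id))
    stop("event identifiers must be unique")
  if (!all(events$event_type %in% .event_types))
    stop("unknown event type(s): ",
         paste(setdiff(events$event_type, .event_types), collapse = ", "))
  psi <- as.matrix(psi)
  if (nrow(psi) != nrow(events))
    stop("psi matrix must have one row per event")
  rownames(psi) <- events$event_id
  bad <- which(!is.na(psi) & (psi < 0 | psi > 1))
  if (length(bad) > 0L)
    stop("inclusion level outside [0,1] at matrix position ", bad[1L])
  covered <- unlist(sample_labels, use.names = FALSE)
  if (!all(colnames(psi) %in% covered))
    stop("sample_labels do not cover replicate column(s): ",
         paste(setdiff(colnames(psi), covered), collapse = ", "))
  fix <- function(m, what, lo, hi) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (nrow(m) != nrow(events)) stop(what, " matrix must have one row per event")
    rownames(m) <- events$event_id
    if (any(!is.na(m) & (m < lo | m > hi)))
      stop(what, " values outside [", lo, ",", hi, "]")
    m
  }
  structure(
    list(events = events, psi = psi, sample_labels = sample_labels,
         fdr = fix(fdr, "fdr", 0, 1), delta_psi = fix(delta_psi, "delta_psi", -1, 1)),
    class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("event_table:", nrow(x$events), "events (",
      paste(names(table(x$events$event_type)), table(x$events$event_type),
            sep = "=", collapse = ", "),
      ");", ncol(x$psi), "replicates;",
      length(x$sample_labels), "genotypes\n")
  invisible(x)
}

#' Number of events in an event table
#' @param table an `event_table`
#' @return integer count
#' @export
n_events <- function(table) nrow(table$events)

# coordinate column names per rMATS event type; first pair is the
# "cassette" (target) region stored in exon_start/exon_end
.rmats_coord_cols <- list(
  SE   = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  MXE  = c("1stExonStart_0base", "1stExonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  A3SS = c("longExonStart_0base", "longExonEnd", "flankingES", "flankingEE",
           NA, NA),
  A5SS = c("longExonStart_0base", "longExonEnd", "flankingES", "flankingEE",
           NA, NA),
  RI   = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE")
)

.parse_inclevel <- function(s) {
  lapply(strsplit(as.character(s), ","), function(v) {
    v <- trimws(v)
    out <- suppressWarnings(as.numeric(v))
    out[v %in% c("NA", "nan", "")] <- NA_real_
    out
  })
}

#' Read an rMATS-style splicing event table
#'
#' Parses the tab-separated per-event output of an rMATS-like caller for a
#' single mutant-vs-wild-type comparison. Inclusion levels (`IncLevel1`,
#' `IncLevel2`; comma-separated per replicate) are parsed onto the 0-1
#' scale and coordinates are stored 0-based half-open. Sample 1 is taken
#' as the mutant group, sample 2 as the wild-type reference, following the
#' rMATS convention that `IncLevelDifference` is sample1 minus sample2.
#'
#' @param path path to the TSV file.
#' @param event_type one of `"SE"`, `"A3SS"`, `"A5SS"`, `"RI"`, `"MXE"`.
#' @param genotype label for the sample-1 (mutant) group.
#' @param wt_label label for the sample-2 (wild-type) group.
#' @return An [event_table()] whose `fdr` and `delta_psi` matrices have a
#'   single column named after `genotype`.
#' @export
read_rmats_table <- function(path, event_type = "SE", genotype = "mutant",
                             wt_label = "WT") {
  event_type <- match.arg(event_type, .event_types)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("ID", "GeneID", "chr", "strand", "IncLevel1", "IncLevel2", "FDR")
  cc <- .rmats_coord_cols[[event_type]]
  req <- c(req, cc[!is.na(cc)])
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("rMATS table is missing required column(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(df)
  getc <- function(i) if (is.na(cc[i])) rep(NA_real_, n) else as.numeric(df[[cc[i]]])
  inc1 <- .parse_inclevel(if (n) df$IncLevel1 else character())
  inc2 <- .parse_inclevel(if (n) df$IncLevel2 else character())
  n1 <- if (n) max(lengths(inc1)) else 0L
  n2 <- if (n) max(lengths(inc2)) else 0L
  for (i in seq_len(n)) {
    bad <- c(inc1[[i]], inc2[[i]])
    bad <- bad[!is.na(bad)]
    if (any(bad < 0 | bad > 1))
      stop("inclusion level outside [0,1] in row ", i)
  }
  pad <- function(v, len) c(v, rep(NA_real_, len - length(v)))
  psi <- if (n) {
    t(vapply(seq_len(n),
             function(i) c(pad(inc1[[i]], n1), pad(inc2[[i]], n2)),
             numeric(n1 + n2)))
  } else matrix(numeric(), 0L, n1 + n2)
  reps1 <- if (n1) paste0(genotype, "_", seq_len(n1)) else character()
  reps2 <- if (n2) paste0(wt_label, "_", seq_len(n2)) else character()
  colnames(psi) <- c(reps1, reps2)
  events <- data.frame(
    event_id = sprintf("%s_%s", event_type, df$ID),
    event_type = rep(event_type, n),
    gene_id = as.character(df$GeneID),
    chrom = as.character(df$chr),
    strand = as.character(df$strand),
    exon_start = getc(1L), exon_end = getc(2L),
    upstream_start = getc(3L), upstream_end = getc(4L),
    downstream_start = getc(5L), downstream_end = getc(6L),
    stringsAsFactors = FALSE)
  dpsi <- if ("IncLevelDifference" %in% names(df)) as.numeric(df$IncLevelDifference)
          else rowMeans(psi[, reps1, drop = FALSE], na.rm = TRUE) -
               rowMeans(psi[, reps2, drop = FALSE], na.rm = TRUE)
  labels <- list(reps1, reps2)
  names(labels) <- c(genotype, wt_label)
  event_table(
    events, psi, labels,
    fdr = matrix(as.numeric(df$FDR), ncol = 1L, dimnames = list(NULL, genotype)),
    delta_psi = matrix(dpsi, ncol = 1L, dimnames = list(NULL, genotype)))
}

#' Write an event table in the rMATS-style dialect
#'
#' Inverse of [read_rmats_table()] for single-comparison tables; numeric
#' fields are written at full precision so read/write round-trips exactly.
#'
#' @param table an `event_table` with exactly two genotype groups (mutant
#'   first, wild type second) and one `fdr`/`delta_psi` column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rmats_table <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  if (length(table$sample_labels) != 2L)
    stop("write_rmats_table expects a single mutant-vs-WT comparison")
  type <- unique(table$events$event_type)
  if (length(type) > 1L) stop("mixed event types; write one table per type")
  type <- if (length(type) == 0L) "SE" else type
  cc <- .rmats_coord_cols[[type]]
  ev <- table$events
  g <- names(table$sample_labels)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  joinrow <- function(reps) apply(table$psi[, reps, drop = FALSE], 1L,
                                  function(v) paste(fmt(v), collapse = ","))
  n <- nrow(ev)
  out <- data.frame(
    ID = sub(paste0("^", type, "_"), "", ev$event_id),
    GeneID = ev$gene_id, chr = ev$chrom, strand = ev$strand,
    stringsAsFactors = FALSE, check.names = FALSE)
  coords <- list(ev$exon_start, ev$exon_end, ev$upstream_start, ev$upstream_end,
                 ev$downstream_start, ev$downstream_end)
  for (i in seq_along(cc)) if (!is.na(cc[i])) out[[cc[i]]] <- coords[[i]]
  out$IncLevel1 <- if (n) joinrow(table$sample_labels[[1L]]) else character()
  out$IncLevel2 <- if (n) joinrow(table$sample_labels[[2L]]) else character()
  out$FDR <- if (is.null(table$fdr)) rep(NA_real_, n) else fmt(table$fdr[, g[1L]])
  out$IncLevelDifference <- if (is.null(table$delta_psi)) rep(NA_real_, n)
                            else fmt(table$delta_psi[, g[1L]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene model
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with 0-based half-open `start`, `end`, given in
#'   any order; they are sorted into transcription order (exon 1 is the
#'   5'-most exon on the coding strand, i.e. the rightmost block on the
#'   minus strand).
#' @param cassette_index optional 1-based transcription-order index of a
#'   cassette exon of interest.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons,
                       cassette_index = NULL) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)))
  if (any(exons$end <= exons$start)) stop("exon end must exceed exon start")
  ord <- order(exons$start)
  if (strand == "-") ord <- rev(ord)
  exons <- exons[ord, c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cassette_index = cassette_index),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, "/", x$transcript_id, "on", x$chrom,
      x$strand, "with", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read gene models from GFF3 or BED12
#'
#' Exon order is transcription order and coordinates are converted to
#' 0-based half-open. For BED12 the block name is used as both gene and
#' transcript id. A transcript whose exons fall on mixed strands is a
#' format error.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED12 (`.bed`) file.
#' @return Named list of [gene_model()] objects (by transcript id).
#' @export
read_gene_models <- function(path) {
  is_bed <- grepl("\\.bed$", path, ignore.case = TRUE)
  if (is_bed) {
    gr <- rtracklayer::import(path, format = "BED")
    out <- lapply(seq_along(gr), function(i) {
      g <- gr[i]
      blocks <- S4Vectors::mcols(g)$blocks[[1L]]
      abs_start <- GenomicRanges::start(g) - 1L + IRanges::start(blocks) - 1L
      abs_end <- GenomicRanges::start(g) - 1L + IRanges::end(blocks)
      gene_model(gene_id = S4Vectors::mcols(g)$name,
                 transcript_id = S4Vectors::mcols(g)$name,
                 chrom = as.character(GenomicRanges::seqnames(g)),
                 strand = as.character(GenomicRanges::strand(g)),
                 exons = data.frame(start = abs_start, end = abs_end))
    })
    names(out) <- vapply(out, function(m) m$transcript_id, character(1L))
    return(out)
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  ex <- gr[tolower(as.character(S4Vectors::mcols(gr)$type)) == "exon"]
  if (length(ex) == 0L) stop("no exon features found in ", path)
  parents <- vapply(as.list(S4Vectors::mcols(ex)$Parent),
                    function(p) if (length(p)) p[[1L]] else NA_character_,
                    character(1L))
  if (anyNA(parents)) stop("exon feature without Parent attribute")
  tx <- gr[tolower(as.character(S4Vectors::mcols(gr)$type)) %in%
             c("mrna", "transcript")]
  tx_gene <- setNames(
    vapply(as.list(S4Vectors::mcols(tx)$Parent),
           function(p) if (length(p)) p[[1L]] else NA_character_, character(1L)),
    as.character(S4Vectors::mcols(tx)$ID))
  out <- lapply(split(seq_along(ex), parents), function(idx) {
    e <- ex[idx]
    strands <- unique(as.character(GenomicRanges::strand(e)))
    if (length(strands) != 1L)
      stop("exons of one transcript on mixed strands: ", parents[idx[1L]])
    tid <- parents[idx[1L]]
    gid <- tx_gene[tid]
    gene_model(gene_id = if (is.na(gid)) tid else unname(gid),
               transcript_id = tid,
               chrom = as.character(GenomicRanges::seqnames(e))[1L],
               strand = strands,
               exons = data.frame(start = GenomicRanges::start(e) - 1L,
                                  end = GenomicRanges::end(e)))
  })
  out
}

#' Coordinate-convention converters
#'
#' Internal coordinates are 0-based half-open; these convert a range to
#' the 1-based closed convention (GFF3-style) and back. The two are
#' mutually inverse.
#'
#' @param start,end range endpoints in the source convention.
#' @return list with converted `start` and `end`.
#' @export
to_1based_closed <- function(start, end) list(start = start + 1L, end = end)

#' @rdname to_1based_closed
#' @export
to_0based_halfopen <- function(start, end) list(start = start - 1L, end = end)

#' Tank geometry
#'
#' @param depth_cm,length_cm,width_cm dimensions in centimetres; defaults
#'   are the 18 x 25.4 x 7.6 cm novel-tank assay aquarium.
#' @return An object of class `tank_geometry`.
#' @export
tank_geometry <- function(depth_cm = 18, length_cm = 25.4, width_cm = 7.6) {
  if (any(c(depth_cm, length_cm, width_cm) <= 0))
    stop("all tank dimensions must be positive")
  structure(list(depth_cm = depth_cm, length_cm = length_cm,
                 width_cm = width_cm), class = "tank_geometry")
}

#' Construct a trajectory object
#'
#' @param frames strictly increasing integer frame numbers (0-based).
#' @param x_cm,y_cm positions in centimetres; `y_cm` is the height above
#'   the tank bottom.
#' @param fps frames per second.
#' @param tank a [tank_geometry()].
#' @return An object of class `trajectory` with a logical `gap_after`
#'   vector flagging intervals spanning missing frames.
#' @export
trajectory <- function(frames, x_cm, y_cm, fps, tank = tank_geometry()) {
  stopifnot(length(frames) == length(x_cm), length(frames) == length(y_cm))
  if (fps <= 0) stop("fps must be positive")
  if (length(frames) > 1L && any(diff(frames) <= 0))
    stop("frame numbers must be strictly increasing")
  if (any(!is.finite(x_cm)) || any(!is.finite(y_cm)))
    stop("positions must be finite")
  gap_after <- if (length(frames) > 1L) diff(frames) > 1L else logical()
  structure(list(frames = as.integer(frames), x_cm = x_cm, y_cm = y_cm,
                 fps = fps, tank = tank, gap_after = gap_after),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frames at", x$fps, "fps (",
      round(length(x$frames) / x$fps, 1), "s );",
      sum(x$gap_after), "gap(s)\n")
  invisible(x)
}

#' Read a tracked trajectory from CSV
#'
#' Expects columns `frame`, `x`, `y` in pixels; converts to centimetres.
#' Gaps in frame numbering are preserved and flagged, never interpolated.
#'
#' @param path CSV file.
#' @param fps frames per second of the recording.
#' @param tank a [tank_geometry()].
#' @param px_per_cm pixel-to-centimetre scale (> 0).
#' @param y_origin `"bottom"` if y grows upward from the tank bottom,
#'   `"top"` for image coordinates (y grows downward), which are flipped
#'   to height-above-bottom using the tank depth.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, fps, tank = tank_geometry(), px_per_cm,
                            y_origin = c("bottom", "top")) {
  y_origin <- match.arg(y_origin)
  if (px_per_cm <= 0) stop("px_per_cm must be positive")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("frame", "x", "y"), names(df))
  if (length(miss) > 0L)
    stop("trajectory file is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) > 1L && any(diff(df$frame) <= 0))
    stop("non-monotone frame numbers in ", path)
  y <- df$y / px_per_cm
  if (y_origin == "top") y <- tank$depth_cm - y
  trajectory(df$frame, df$x / px_per_cm, y, fps = fps, tank = tank)
}
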