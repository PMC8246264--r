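# Brute-force oracles and tiny fixture builders, independent of the
# package implementation paths they check.

# sliding-window motif count: compare every offset by substring equality
bf_count_motifs <- function(seq, motifs) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 4L) return(0L)
  count <- 0L
  for (i in seq_len(n - 3L))
    if (substr(seq, i, i + 3L) %in% motifs) count <- count + 1L
  count
}

# exhaustive enumeration of composition-matched control 4-mers
bf_control_kmers <- function(motif, exclude = character()) {
  bases <- c("A", "C", "G", "T")
  at <- function(k) {
    b <- strsplit(k, "")[[1L]]
    sum(b == "A" | b == "T")
  }
  cg <- function(k) {
    b <- strsplit(k, "")[[1L]]
    sum(b[1:3] == "C" & b[2:4] == "G")
  }
  out <- character()
  for (b1 in bases) for (b2 in bases) for (b3 in bases) for (b4 in bases) {
    k <- paste0(b1, b2, b3, b4)
    if (at(k) == at(motif) && cg(k) == cg(motif) &&
        !(k %in% c(motif, exclude)))
      out <- c(out, k)
  }
  out
}

# fastest window by scanning every start position
bf_fastest_window <- function(speeds, window) {
  best <- -Inf
  for (i in seq_len(length(speeds) - window + 1L))
    best <- max(best, mean(speeds[i:(i + window - 1L)]))
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# small rMATS-style SE file
write_rmats_fixture <- function(path, fdr = c(0.01, 0.2, 0.5),
                                inc1 = c("0.9,0.85,0.95", "0.5,0.55,0.45",
                                         "0.2,0.25,0.15"),
                                inc2 = c("0.1,0.15,0.05", "0.5,0.45,0.55",
                                         "0.2,0.15,0.25")) {
  n <- length(fdr)
  df <- data.frame(
    ID = seq_len(n), GeneID = sprintf("g%d", seq_len(n)),
    chr = rep("chr1", n), strand = rep("+", n),
    exonStart_0base = 1000 * seq_len(n), exonEnd = 1000 * seq_len(n) + 150,
    upstreamES = 1000 * seq_len(n) - 500, upstreamEE = 1000 * seq_len(n) - 400,
    downstreamES = 1000 * seq_len(n) + 600,
    downstreamEE = 1000 * seq_len(n) + 700,
    IncLevel1 = inc1, IncLevel2 = inc2, FDR = fdr,
    check.names = FALSE)
  df$IncLevelDifference <- vapply(seq_len(n), function(i) {
    m <- function(s) mean(suppressWarnings(as.numeric(strsplit(s, ",")[[1L]])),
                          na.rm = TRUE)
    m(inc1[i]) - m(inc2[i])
  }, numeric(1L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# hand-built multi-genotype event table: fdr_mat/dpsi_mat are events x
# genotypes; psi filled with a constant unless given
make_event_table <- function(fdr_mat, dpsi_mat = NULL,
                             event_type = "SE", psi_value = 0.5) {
  n <- nrow(fdr_mat)
  genos <- colnames(fdr_mat)
  labels <- c(setNames(lapply(genos, function(g) paste0(g, "_", 1:2)), genos),
              list(WT = c("WT_1", "WT_2")))
  reps <- unlist(labels, use.names = FALSE)
  event_type <- rep(event_type, length.out = n)
  events <- data.frame(
    event_id = sprintf("%s_%03d", event_type, seq_len(n)),
    event_type = event_type,
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = rep("chr1", n), strand = rep("+", n),
    exon_start = seq_len(n) * 1000, exon_end = seq_len(n) * 1000 + 150,
    upstream_start = seq_len(n) * 1000 - 500,
    upstream_end = seq_len(n) * 1000 - 400,
    downstream_start = seq_len(n) * 1000 + 600,
    downstream_end = seq_len(n) * 1000 + 700)
  psi <- matrix(psi_value, n, length(reps), dimnames = list(NULL, reps))
  event_table(events, psi, labels, fdr = fdr_mat, delta_psi = dpsi_mat)
}
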