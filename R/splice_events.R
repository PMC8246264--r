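## PSI arithmetic, significance filtering, tallies, consensus sets and
## magnitude summaries over event tables.
##
## Threshold conventions follow the source wording: FDR gates are strict
## ("< 0.10", "< 0.05"); the differential-expression fold-change gate is
## inclusive (|log2FC| >= 1).

#' Percent spliced in from gel band intensities
#'
#' The RT-PCR estimate of exon inclusion:
#' \deqn{PSI = 100 \cdot \frac{included}{included + excluded}}
#' from background-corrected band intensity sums.
#'
#' @param included_sum,excluded_sum non-negative background-corrected
#'   intensity sums of the exon-included and exon-excluded bands.
#' @return Percent inclusion in \[0, 100\].
#' @export
psi_from_band_intensities <- function(included_sum, excluded_sum) {
  if (included_sum < 0 || excluded_sum < 0)
    stop("band intensities must be non-negative")
  if (included_sum + excluded_sum == 0)
    stop("PSI undefined: both band intensities are zero")
  100 * included_sum / (included_sum + excluded_sum)
}

#' Mean inclusion difference, mutant minus wild type
#'
#' @param mutant_psis,wt_psis non-empty numeric vectors of replicate
#'   inclusion levels on the 0-1 scale.
#' @return Signed difference of group means, in \[-1, 1\].
#' @export
delta_psi <- function(mutant_psis, wt_psis) {
  mutant_psis <- mutant_psis[!is.na(mutant_psis)]
  wt_psis <- wt_psis[!is.na(wt_psis)]
  if (length(mutant_psis) == 0L || length(wt_psis) == 0L)
    stop("delta_psi requires at least one replicate per group")
  mean(mutant_psis) - mean(wt_psis)
}

.check_genotype <- function(table, genotype) {
  if (is.null(table$fdr) || !(genotype %in% colnames(table$fdr)))
    stop("no FDR values for genotype '", genotype, "'")
}

#' Significantly mis-spliced events for one genotype
#'
#' Retains events with FDR strictly below the threshold (default 0.10),
#' preserving input order.
#'
#' @param table an [event_table()].
#' @param genotype genotype label (column of the table's FDR matrix).
#' @param fdr_threshold significance cut-off; strict inequality.
#' @return An `event_table` restricted to the significant events.
#' @export
significant_events <- function(table, genotype, fdr_threshold = 0.10) {
  .check_genotype(table, genotype)
  keep <- which(!is.na(table$fdr[, genotype]) &
                  table$fdr[, genotype] < fdr_threshold)
  subset_events(table, keep)
}

#' Subset an event table by row index or event id
#' @param table an `event_table`
#' @param which integer indices or character event ids
#' @return the subsetted `event_table`
#' @export
subset_events <- function(table, which) {
  if (is.character(which)) which <- match(which, table$events$event_id)
  if (anyNA(which)) stop("unknown event id(s)")
  sub <- function(m) if (is.null(m)) NULL else m[which, , drop = FALSE]
  event_table(table$events[which, , drop = FALSE],
              table$psi[which, , drop = FALSE],
              table$sample_labels, sub(table$fdr), sub(table$delta_psi))
}

#' Classify an event's regulation by Mbnl proteins
#'
#' Loss of Mbnl raising inclusion (delta-PSI > `dpsi_threshold` at
#' FDR < `fdr_threshold`) means the proteins normally repress the exon
#' (`mbnl_repressed`); inclusion falling symmetrically means they normally
#' activate it (`mbnl_activated`); anything else is `not_regulated`.
#'
#' @param table an [event_table()] with `fdr` and `delta_psi` populated.
#' @param genotype genotype label.
#' @param fdr_threshold strict FDR gate (default 0.05).
#' @param dpsi_threshold strict magnitude gate on delta-PSI (default 0.2).
#' @return data.frame with columns `event_id`, `genotype`, `class`.
#' @export
classify_regulation <- function(table, genotype, fdr_threshold = 0.05,
                                dpsi_threshold = 0.2) {
  .check_genotype(table, genotype)
  if (is.null(table$delta_psi)) stop("delta_psi not populated")
  fdr <- table$fdr[, genotype]
  dp <- table$delta_psi[, genotype]
  cls <- rep("not_regulated", nrow(table$events))
  sig <- !is.na(fdr) & !is.na(dp) & fdr < fdr_threshold
  cls[sig & dp > dpsi_threshold] <- "mbnl_repressed"
  cls[sig & dp < -dpsi_threshold] <- "mbnl_activated"
  data.frame(event_id = table$events$event_id, genotype = genotype,
             class = cls, stringsAsFactors = FALSE)
}

#' Count significant events per type
#'
#' @inheritParams significant_events
#' @return Named integer vector over all five event types (zero counts
#'   included).
#' @export
count_events_by_type <- function(table, genotype, fdr_threshold = 0.10) {
  sig <- significant_events(table, genotype, fdr_threshold)
  counts <- table(factor(sig$events$event_type, levels = .event_types))
  setNames(as.integer(counts), .event_types)
}

#' Consensus set of cassette exons across genotypes
#'
#' Cassette (SE) events significantly mis-spliced (FDR < `fdr_threshold`)
#' in at least `min_support` of the given genotypes.
#'
#' @param table an [event_table()] with FDR columns for all `genotypes`.
#' @param genotypes genotype labels to poll.
#' @param min_support minimum number of supporting genotypes (default 4).
#' @param fdr_threshold strict FDR gate (default 0.10).
#' @return An `event_table` of the consensus cassette events, with a
#'   `support` attribute giving each retained event's genotype count.
#' @export
consensus_set <- function(table, genotypes, min_support = 4,
                          fdr_threshold = 0.10) {
  if (length(genotypes) < min_support)
    stop("min_support (", min_support, ") exceeds number of genotypes (",
         length(genotypes), ")")
  for (g in genotypes) .check_genotype(table, g)
  se <- which(table$events$event_type == "SE")
  fdr <- table$fdr[se, genotypes, drop = FALSE]
  support <- rowSums(!is.na(fdr) & fdr < fdr_threshold)
  keep <- se[support >= min_support]
  out <- subset_events(table, keep)
  attr(out, "support") <- support[support >= min_support]
  out
}

#' Mean absolute splicing-change magnitude
#'
#' Average of |delta-PSI| over a set of events for one genotype. When the
#' table carries replicate-level PSI, a per-fish breakdown is also
#' returned: for each mutant replicate, the mean over events of the
#' absolute difference between that replicate's PSI and the wild-type
#' mean. Events with missing values are dropped, not imputed.
#'
#' @param subset an [event_table()] (e.g. from [consensus_set()]).
#' @param genotype genotype label.
#' @param wt_label wild-type group label for the per-fish breakdown.
#' @return list with `mean_abs_dpsi` and, when computable, `per_fish`
#'   (named by replicate).
#' @export
magnitude_summary <- function(subset, genotype, wt_label = "WT") {
  if (nrow(subset$events) == 0L) stop("empty event subset")
  if (is.null(subset$delta_psi) || !(genotype %in% colnames(subset$delta_psi)))
    stop("no delta_psi for genotype '", genotype, "'")
  dp <- subset$delta_psi[, genotype]
  out <- list(mean_abs_dpsi = mean(abs(dp), na.rm = TRUE))
  reps <- subset$sample_labels[[genotype]]
  wt <- subset$sample_labels[[wt_label]]
  if (!is.null(reps) && !is.null(wt)) {
    wt_mean <- rowMeans(subset$psi[, wt, drop = FALSE], na.rm = TRUE)
    out$per_fish <- vapply(reps, function(r)
      mean(abs(subset$psi[, r] - wt_mean), na.rm = TRUE), numeric(1L))
  }
  out
}

#' Filter differentially expressed genes
#'
#' Retains genes with |log2 fold change| >= `lfc_threshold` (inclusive)
#' and FDR < `fdr_threshold` (strict).
#'
#' @param expression_table data.frame with columns `gene_id`, `log2fc`,
#'   `fdr`.
#' @param lfc_threshold inclusive absolute log2 fold-change gate
#'   (default 1.0).
#' @param fdr_threshold strict FDR gate (default 0.05).
#' @return Character vector of retained gene ids.
#' @export
de_gene_filter <- function(expression_table, lfc_threshold = 1.0,
                           fdr_threshold = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(expression_table)))
  keep <- !is.na(expression_table$log2fc) & !is.na(expression_table$fdr) &
    abs(expression_table$log2fc) >= lfc_threshold &
    expression_table$fdr < fdr_threshold
  expression_table$gene_id[keep]
}
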