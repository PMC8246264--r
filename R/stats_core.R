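## The statistics layer: one-way ANOVA + Tukey with compact letters,
## unpaired t-test, Spearman rho, BH FDR, chi-square goodness of fit and
## comparative C_T expression. Standard tests are delegated to base R
## (aov/TukeyHSD, t.test, cor, p.adjust, chisq.test); this file adds the
## grouped-data plumbing, edge-case handling and the letter display.

.as_grouped <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)))
  if (any(lengths(groups) < 2L))
    stop("each group needs at least 2 values")
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups), lengths(groups)),
                            levels = names(groups)))
}

#' Ordinary one-way ANOVA
#'
#' Fixed-effects equal-variance decomposition. The degenerate case of zero
#' within-group variance with equal means returns F = 0, p = 1 rather than
#' failing on a 0/0 division (Welch correction available via `welch`).
#'
#' @param groups named list of numeric vectors, one per group, each with
#'   at least 2 values.
#' @param welch use Welch's unequal-variance correction (default FALSE).
#' @return list with `f`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups, welch = FALSE) {
  d <- .as_grouped(groups)
  k <- nlevels(d$group); n <- nrow(d)
  gm <- tapply(d$value, d$group, mean)
  ssw <- sum((d$value - gm[d$group])^2)
  ssb <- sum(tapply(d$value, d$group, length) * (gm - mean(d$value))^2)
  if (ssw == 0 && ssb == 0)
    return(list(f = 0, p = 1, df_between = k - 1L, df_within = n - k))
  if (welch) {
    fit <- oneway.test(value ~ group, data = d, var.equal = FALSE)
    return(list(f = unname(fit$statistic), p = fit$p.value,
                df_between = unname(fit$parameter[1L]),
                df_within = unname(fit$parameter[2L])))
  }
  if (ssw == 0)
    return(list(f = Inf, p = 0, df_between = k - 1L, df_within = n - k))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = pf(f, k - 1, n - k, lower.tail = FALSE),
       df_between = k - 1L, df_within = n - k)
}

#' Tukey's honestly-significant-difference comparisons
#'
#' All-pairs adjusted p-values from the studentized-range distribution;
#' unbalanced designs use the Tukey-Kramer correction (as in
#' [stats::TukeyHSD()], which performs the computation).
#'
#' @inheritParams one_way_anova
#' @return Symmetric matrix of adjusted p-values with group names on both
#'   dimensions (diagonal NA).
#' @export
tukey_hsd <- function(groups) {
  d <- .as_grouped(groups)
  fit <- TukeyHSD(aov(value ~ group, data = d))$group
  g <- levels(d$group)
  p <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  pairs <- strsplit(rownames(fit), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1L]; b <- pairs[[i]][2L]
    p[a, b] <- p[b, a] <- fit[i, "p adj"]
  }
  p
}

#' Compact letter display
#'
#' Assigns letter codes so that two groups share a letter if and only if
#' their adjusted p-value is at least `alpha` (insert-and-absorb
#' algorithm). Data bars not sharing a letter differ significantly.
#'
#' @param pairwise_p symmetric matrix of adjusted p-values (as from
#'   [tukey_hsd()]).
#' @param alpha significance level (default 0.05).
#' @return Named character vector of letter strings, in group order.
#' @export
compact_letter_display <- function(pairwise_p, alpha = 0.05) {
  g <- rownames(pairwise_p)
  stopifnot(!is.null(g), identical(g, colnames(pairwise_p)))
  offd <- !diag(TRUE, length(g))
  if (any(abs(pairwise_p - t(pairwise_p))[offd] > 1e-12, na.rm = TRUE) ||
      any(is.na(pairwise_p[offd])))
    stop("pairwise p matrix must be symmetric and complete off-diagonal")
  absorb <- function(sets) {
    sets <- sets[lengths(sets) > 0L]
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a == b || !keep[a] || !keep[b]) next
      proper <- length(sets[[a]]) < length(sets[[b]])
      dup <- !proper && length(sets[[a]]) == length(sets[[b]]) && b < a
      if ((proper || dup) && all(sets[[a]] %in% sets[[b]]))
        keep[a] <- FALSE
    }
    sets[keep]
  }
  sets <- list(g)  # letter groups; start with everyone sharing one letter
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (j <= i) next
    if (pairwise_p[i, j] < alpha) {
      hit <- vapply(sets, function(s) all(c(g[i], g[j]) %in% s), logical(1L))
      if (any(hit)) {
        split_sets <- unlist(lapply(sets[hit], function(s)
          list(setdiff(s, g[i]), setdiff(s, g[j]))), recursive = FALSE)
        sets <- absorb(c(sets[!hit], split_sets))
      }
    }
  }
  # stable order: by first member's group position
  ord <- order(vapply(sets, function(s) min(match(s, g)), numeric(1L)))
  sets <- sets[ord]
  letters_used <- letters[seq_along(sets)]
  out <- vapply(g, function(gr)
    paste(letters_used[vapply(sets, function(s) gr %in% s, logical(1L))],
          collapse = ""), character(1L))
  out
}

#' Unpaired two-sided Student's t-test
#'
#' Pooled-variance test; zero pooled variance with equal means gives
#' t = 0, p = 1.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @return list with `t`, `p`, `df`.
#' @export
unpaired_t_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, p = 1, df = length(group_a) + length(group_b) - 2L))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, p = 0,
                df = length(group_a) + length(group_b) - 2L))
  }
  fit <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#'
#' @param x,y equal-length numeric vectors with at least 3 pairs.
#' @return rho.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("spearman_rho requires at least 3 pairs")
  if (var(x) == 0 || var(y) == 0)
    stop("spearman_rho undefined for a constant vector")
  cor(x, y, method = "spearman")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()] after validating the input range).
#'
#' @param p_values numeric vector of p-values in \[0,1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stop("p-values must lie in [0,1]")
  p.adjust(p_values, method = "BH")
}

#' Chi-square goodness of fit against an expected ratio
#'
#' Pearson chi-square with df = categories - 1, e.g. for checking
#' Mendelian segregation of genotypes.
#'
#' @param observed_counts non-negative integer counts per category.
#' @param expected_ratio expected proportions (normalised to sum to 1);
#'   all must be positive.
#' @return list with `chisq`, `p`, `df`.
#' @export
mendelian_fit <- function(observed_counts, expected_ratio) {
  stopifnot(length(observed_counts) == length(expected_ratio))
  if (any(observed_counts < 0)) stop("counts must be non-negative")
  if (any(expected_ratio <= 0)) stop("expected ratio entries must be positive")
  expected_ratio <- expected_ratio / sum(expected_ratio)
  fit <- suppressWarnings(chisq.test(observed_counts, p = expected_ratio))
  list(chisq = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Relative expression by the comparative C_T method
#'
#' Per sample: delta-C_T = C_T(target) - C_T(reference housekeeping gene);
#' delta-delta-C_T subtracts the calibrator group's mean delta-C_T; the
#' fold change is `2^(-ddCt)`.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct`.
#' @param target_gene gene whose expression is quantified.
#' @param reference_gene housekeeping normaliser (e.g. `eef1a1l1`).
#' @param calibrator_samples sample ids of the calibrator group.
#' @return data.frame with `sample`, `dct`, `ddct`, `fold`.
#' @export
ddct_relative_expression <- function(ct, target_gene, reference_gene,
                                     calibrator_samples) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  samples <- unique(ct$sample)
  getct <- function(s, gene) {
    v <- ct$ct[ct$sample == s & ct$gene == gene]
    if (length(v) == 0L)
      stop("missing C_T for gene '", gene, "' in sample '", s, "'")
    mean(v)  # technical replicates averaged
  }
  dct <- vapply(samples, function(s)
    getct(s, target_gene) - getct(s, reference_gene), numeric(1L))
  if (!all(calibrator_samples %in% samples))
    stop("calibrator sample(s) not present")
  ddct <- dct - mean(dct[match(calibrator_samples, samples)])
  data.frame(sample = samples, dct = unname(dct), ddct = unname(ddct),
             fold = 2^(-unname(ddct)), stringsAsFactors = FALSE)
}
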