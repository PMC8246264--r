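test_that("RT-PCR PSI formula and its edge cases", {
  expect_equal(psi_from_band_intensities(300, 100), 75.0)
  expect_equal(psi_from_band_intensities(0, 512), 0.0)
  expect_equal(psi_from_band_intensities(7, 7), 50.0)
  expect_error(psi_from_band_intensities(0, 0), "undefined")
  expect_error(psi_from_band_intensities(-1, 5), "non-negative")
})

test_that("delta-PSI is the mutant-minus-WT difference of group means", {
  expect_equal(delta_psi(c(0.9, 0.9, 0.9), c(0.1, 0.1, 0.1)), 0.8)
  expect_equal(delta_psi(c(0.4, 0.6), c(0.4, 0.6)), 0.0)
  expect_equal(delta_psi(0.2, 0.7), -0.5)
  expect_error(delta_psi(numeric(), 0.5), "replicate")
})

test_that("significance filtering is strict and monotone in the threshold", {
  tab <- make_event_table(matrix(c(0.05, 0.10, 0.2), ncol = 1,
                                 dimnames = list(NULL, "mut")))
  sig <- significant_events(tab, "mut")  # default 0.10, strict
  expect_equal(n_events(sig), 1L)
  expect_equal(sig$events$event_id, tab$events$event_id[1L])
  expect_equal(n_events(significant_events(tab, "mut", 1.1)), 3L)
  expect_error(significant_events(tab, "nope"), "genotype")

  empty <- make_event_table(matrix(numeric(), ncol = 1,
                                   dimnames = list(NULL, "mut")))
  expect_equal(n_events(significant_events(empty, "mut")), 0L)

  # monotonicity over random FDRs
  set.seed(42)
  tab2 <- make_event_table(matrix(runif(50), ncol = 1,
                                  dimnames = list(NULL, "mut")))
  for (pair in list(c(0.01, 0.05), c(0.05, 0.10), c(0.10, 0.5))) {
    lo <- significant_events(tab2, "mut", pair[1L])$events$event_id
    hi <- significant_events(tab2, "mut", pair[2L])$events$event_id
    expect_true(all(lo %in% hi))
  }
})

test_that("regulation classes follow the FDR<0.05, |dPSI|>0.2 rule", {
  fdr <- matrix(c(0.01, 0.01, 0.2, 0.01), ncol = 1,
                dimnames = list(NULL, "mut"))
  dp <- matrix(c(0.3, -0.3, 0.3, 0.1), ncol = 1,
               dimnames = list(NULL, "mut"))
  cls <- classify_regulation(make_event_table(fdr, dp), "mut")$class
  expect_equal(cls, c("mbnl_repressed", "mbnl_activated",
                      "not_regulated", "not_regulated"))
})

test_that("per-type tallies report zero for absent types", {
  fdr <- matrix(c(0.01, 0.01, 0.01, 0.5), ncol = 1,
                dimnames = list(NULL, "mut"))
  tab <- make_event_table(fdr, event_type = c("SE", "SE", "RI", "A3SS"))
  counts <- count_events_by_type(tab, "mut")
  expect_equal(counts, c(SE = 2L, A3SS = 0L, A5SS = 0L, RI = 1L, MXE = 0L))
  none <- make_event_table(matrix(rep(0.9, 3), ncol = 1,
                                  dimnames = list(NULL, "mut")))
  expect_true(all(count_events_by_type(none, "mut") == 0L))
})

test_that("consensus sets honour the at-least-min_support rule", {
  genos <- paste0("m", 1:7)
  fdr <- matrix(0.9, 3, 7, dimnames = list(NULL, genos))
  fdr[1L, 1:4] <- 0.01  # significant in exactly 4 of 7
  fdr[2L, 1:3] <- 0.01  # 3 of 7
  fdr[3L, ] <- 0.01     # all 7
  tab <- make_event_table(fdr)
  cs <- consensus_set(tab, genos)
  expect_equal(cs$events$event_id, tab$events$event_id[c(1L, 3L)])
  expect_error(consensus_set(tab, genos[1:3], min_support = 4),
               "min_support")
})

test_that("consensus with support 1/7 is the union/intersection of per-genotype sets", {
  set.seed(7)
  genos <- paste0("m", 1:7)
  fdr <- matrix(runif(200 * 7), 200, 7, dimnames = list(NULL, genos))
  tab <- make_event_table(fdr)
  per_geno <- lapply(genos, function(g)
    significant_events(tab, g)$events$event_id)
  expect_setequal(consensus_set(tab, genos, 1)$events$event_id,
                  Reduce(union, per_geno))
  expect_setequal(consensus_set(tab, genos, 7)$events$event_id,
                  Reduce(intersect, per_geno))
})

test_that("magnitude summaries average |dPSI| and rank planted effects", {
  fdr <- matrix(0.01, 2, 1, dimnames = list(NULL, "mut"))
  dp <- matrix(c(0.4, -0.2), ncol = 1, dimnames = list(NULL, "mut"))
  tab <- make_event_table(fdr, dp)
  expect_equal(magnitude_summary(tab, "mut")$mean_abs_dpsi, 0.3)
  zero <- make_event_table(fdr, dp * 0)
  expect_equal(magnitude_summary(zero, "mut")$mean_abs_dpsi, 0.0)
  expect_error(magnitude_summary(subset_events(tab, integer()), "mut"),
               "empty")

  # genotype with the larger planted delta ranks first on synthetic data
  spec_small <- splice_sim_spec(
    n_events = 150, genotypes = c(WT = 3L, weak = 3L, strong = 3L),
    frac_regulated = 0.5, delta_mean = c(weak = 0.25, strong = 0.6),
    delta_sd = 0.05, read_depth = 300, seed = 11)
  sim <- simulate_splice_table(spec_small)
  cs <- consensus_set(sim$table, c("weak", "strong"), min_support = 1)
  expect_gt(magnitude_summary(cs, "strong")$mean_abs_dpsi,
            magnitude_summary(cs, "weak")$mean_abs_dpsi)
})

test_that("differential-expression filter: inclusive fold gate, strict FDR gate", {
  df <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(1.0, 0.5, -2.0, 3.0),
                   fdr = c(0.01, 0.001, 0.04, 0.05))
  expect_equal(de_gene_filter(df), c("a", "c"))
})
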