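test_that("overlapping motif occurrences are counted at every offset", {
  expect_equal(count_motifs("TGCTGCT", motif_set("m", "TGCT")), 2L)
  expect_equal(count_motifs("TGC", ygcy_motifs()), 0L)
  # N in the subject never matches
  expect_equal(count_motifs("TGNTGCT", motif_set("m", "TGCT")), 1L)
  expect_equal(count_motifs("TGNT", motif_set("m", "TGCT")), 0L)

  set.seed(14)
  for (i in 1:200) {
    s <- random_dna(sample(4:300, 1L))
    expect_identical(count_motifs(s, ygcy_motifs()),
                     bf_count_motifs(s, ygcy_motifs()$motifs))
  }
})

test_that("concatenation changes counts only by bounded junction effects", {
  set.seed(15)
  for (i in 1:50) {
    s1 <- random_dna(sample(10:100, 1L))
    s2 <- random_dna(sample(10:100, 1L))
    both <- count_motifs(paste0(s1, s2), ygcy_motifs())
    parts <- count_motifs(s1, ygcy_motifs()) + count_motifs(s2, ygcy_motifs())
    expect_lte(abs(both - parts), 3L)
  }
})

test_that("control 4-mers match A+T and CpG composition exactly", {
  for (preset in list(ygcy_motifs(), ygcy_printed_motifs())) {
    for (m in preset$motifs) {
      got <- sort(control_kmers(m, exclude = preset))
      expect_identical(got, sort(bf_control_kmers(m, preset$motifs)))
      expect_false(m %in% got)
      expect_false(any(preset$motifs %in% got))
    }
  }
  expect_error(control_kmers("TG"), "4-mer")
})

test_that("windows are 250 nt with long introns and split short introns at the midpoint", {
  # plus strand, exons at transcription order 1..3, 1000-nt introns
  m <- gene_model("g", "t", "chr", "+",
                  data.frame(start = c(0, 1100, 2200),
                             end = c(100, 1200, 2300)),
                  cassette_index = 2L)
  genome <- Biostrings::DNAStringSet(setNames(
    paste(rep("A", 2300), collapse = ""), "chr"))
  w <- extract_windows(m, genome = genome)
  expect_equal(vapply(w, function(x) nchar(x$seq), numeric(1)),
               c(cassette_exon = 100,
                 intron_5prime_of_cassette = 250,
                 intron_3prime_of_cassette = 250,
                 intron_3prime_of_upstream_constitutive = 250,
                 intron_5prime_of_downstream_constitutive = 250))

  # 300-nt introns: both claimed windows truncate to 150
  m2 <- gene_model("g", "t", "chr", "+",
                   data.frame(start = c(0, 400, 800),
                              end = c(100, 500, 900)),
                   cassette_index = 2L)
  w2 <- extract_windows(m2, genome = genome)
  expect_equal(nchar(w2$intron_5prime_of_cassette$seq), 150)
  expect_equal(nchar(w2$intron_3prime_of_upstream_constitutive$seq), 150)

  # cassette at an end is a structural error
  expect_error(extract_windows(m, 1L, genome), "constitutive neighbours")
})

test_that("minus-strand windows are the reverse complement of the mirrored extraction", {
  set.seed(16)
  seqchar <- random_dna(3000)
  genome <- Biostrings::DNAStringSet(setNames(seqchar, "chr"))
  exons <- data.frame(start = c(100, 1200, 2400), end = c(250, 1350, 2550))
  mp <- gene_model("g", "t", "chr", "+", exons, cassette_index = 2L)
  mm <- gene_model("g", "t", "chr", "-", exons, cassette_index = 2L)
  wp <- extract_windows(mp, genome = genome)
  wm <- extract_windows(mm, genome = genome)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # the minus-strand 5'-of-cassette window mirrors the plus-strand
  # 3'-of-cassette window, etc.
  expect_identical(wm$cassette_exon$seq, rc(wp$cassette_exon$seq))
  expect_identical(wm$intron_5prime_of_cassette$seq,
                   rc(wp$intron_3prime_of_cassette$seq))
  expect_identical(wm$intron_3prime_of_cassette$seq,
                   rc(wp$intron_5prime_of_cassette$seq))
  expect_identical(wm$intron_3prime_of_upstream_constitutive$seq,
                   rc(wp$intron_5prime_of_downstream_constitutive$seq))
})

test_that("enrichment ratio is 1 under symmetry and scale-invariant without pseudocount", {
  # no occurrences of anything: pseudocounts alone -> exactly 1
  expect_equal(enrichment_ratio("AAAAAAAAAA", ygcy_motifs()), 1.0)
  # with pseudocount 0, doubling every window leaves the ratio unchanged
  set.seed(17)
  w <- replicate(5, random_dna(400))
  r1 <- enrichment_ratio(as.list(w), ygcy_motifs(), pseudocount = 0)
  r2 <- enrichment_ratio(as.list(c(w, w)), ygcy_motifs(), pseudocount = 0)
  expect_equal(r1, r2)
  expect_error(enrichment_ratio("", ygcy_motifs()), "zero analysed")
})

test_that("planted motif excess raises the enrichment ratio above 1", {
  sp <- sequence_sim_spec(n_genes = 10,
                          motif_density = c(intron_3prime_of_cassette = 5),
                          seed = 18)
  out <- simulate_gene_sequences(sp)
  wins <- lapply(out$models, extract_windows, genome = out$genome)
  planted_w <- lapply(wins, `[[`, "intron_3prime_of_cassette")
  empty_w <- lapply(wins, `[[`, "intron_5prime_of_cassette")
  expect_gt(enrichment_ratio(planted_w, ygcy_motifs()), 1)
  expect_lt(enrichment_ratio(empty_w, ygcy_motifs()), 1.2)
})

test_that("heatmap is antisymmetric under swapping regulated and non-regulated", {
  sp <- sequence_sim_spec(n_genes = 20,
                          motif_density = c(cassette_exon = 3),
                          seed = 19)
  out <- simulate_gene_sequences(sp)
  ids <- names(out$models)
  a <- ids[1:10]; b <- ids[11:20]
  hm_ab <- enrichment_heatmap(list(set = list(activated = a)), b,
                              out$models, out$genome)
  hm_ba <- enrichment_heatmap(list(set = list(activated = b)), a,
                              out$models, out$genome)
  expect_equal(hm_ab$log2_ratio, -hm_ba$log2_ratio)
})

test_that("non-regulated exon selection uses the FDR and |dPSI| gates", {
  fdr <- matrix(c(0.9, 0.6, 0.3, 0.9), ncol = 1,
                dimnames = list(NULL, "mut"))
  dp <- matrix(c(0.01, 0.2, 0.01, 0.04), ncol = 1,
               dimnames = list(NULL, "mut"))
  tab <- make_event_table(fdr, dp)
  expect_equal(nonregulated_exons(tab, "mut"),
               tab$events$gene_id[c(1L, 4L)])
})
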