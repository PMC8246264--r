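## Generators for inputs with the statistical structure the analyses
## assume: multi-genotype splicing tables with planted mis-splicing,
## piecewise active/pause trajectories, and gene sequences with motifs
## planted at controlled per-window densities. Every generator is a pure
## function of its spec (including its seed) and returns the ground truth
## needed to score the downstream module.

#' Specification for a synthetic splicing table
#'
#' @param n_events number of cassette events.
#' @param genotypes named integer vector of replicate counts per genotype;
#'   must include `"WT"`; every count >= 2. Default mirrors a three-
#'   replicate wild-type-plus-mutant RNA-Seq design.
#' @param frac_regulated fraction of events planted as mis-spliced in each
#'   mutant genotype.
#' @param delta_mean,delta_sd distribution of the planted |delta-PSI|;
#'   sign is drawn uniformly per event. `delta_mean` may be a named
#'   vector (one entry per mutant genotype) to plant genotype-specific
#'   effect sizes.
#' @param read_depth mean total junction reads per event per replicate.
#' @param logit_sd replicate-level biological noise on the logit-PSI scale.
#' @param seed RNG seed.
#' @return An object of class `splice_sim_spec`.
#' @export
splice_sim_spec <- function(n_events = 500,
                            genotypes = c(WT = 3L, mut = 3L),
                            frac_regulated = 0.2,
                            delta_mean = 0.4, delta_sd = 0.1,
                            read_depth = 100, logit_sd = 0.2,
                            seed = 1L) {
  stopifnot(frac_regulated >= 0, frac_regulated <= 1, read_depth >= 1,
            all(genotypes >= 2L), "WT" %in% names(genotypes))
  structure(as.list(environment()), class = "splice_sim_spec")
}

#' Simulate a multi-genotype splicing event table
#'
#' Each event gets a latent baseline PSI (uniform on \[0.05, 0.95\]).
#' Planted events shift the mutant-genotype latent PSI by a signed delta;
#' baselines for which the drawn delta cannot fit in \[0,1\] are resampled
#' rather than clipping the effect. Replicate PSI adds logit-normal noise,
#' and observed PSI is the binomial inclusion fraction at a Poisson read
#' total. Per-event significance versus WT is a two-sample t-test on
#' logit-PSI with Benjamini-Hochberg correction across events (standing in
#' schema-compatibly for an rMATS-style likelihood test).
#'
#' @param spec a [splice_sim_spec()].
#' @return list with `table` (an [event_table()]) and `truth`, a
#'   data.frame of `event_id`, `genotype`, `planted`, `delta` (signed
#'   planted latent shift, 0 for unplanted).
#' @export
simulate_splice_table <- function(spec) {
  stopifnot(inherits(spec, "splice_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_events
    genos <- names(spec$genotypes)
    muts <- setdiff(genos, "WT")
    logit <- function(p) log(p / (1 - p))
    inv_logit <- function(x) 1 / (1 + exp(-x))
    baseline <- runif(n, 0.05, 0.95)
    # direction-consistent mis-splicing: the sign of the planted shift is
    # a per-event property shared by every genotype in which the event is
    # planted (magnitudes stay genotype-specific); this also guarantees a
    # baseline accommodating all shifts exists
    planted <- matrix(FALSE, n, length(muts), dimnames = list(NULL, muts))
    delta <- matrix(0, n, length(muts), dimnames = list(NULL, muts))
    event_sign <- sample(c(-1, 1), n, replace = TRUE)
    for (g in muts) {
      planted[, g] <- runif(n) < spec$frac_regulated
      k <- sum(planted[, g])
      dm <- if (length(spec$delta_mean) > 1L) spec$delta_mean[[g]]
            else spec$delta_mean
      if (k > 0L)
        delta[planted[, g], g] <-
          event_sign[planted[, g]] *
          pmin(pmax(abs(rnorm(k, dm, spec$delta_sd)), 0.01), 0.9)
    }
    eps <- 0.02
    for (i in seq_len(n)) {
      for (tries in seq_len(1000L)) {
        shifted <- baseline[i] + delta[i, ]
        if (all(shifted >= eps & shifted <= 1 - eps)) break
        baseline[i] <- runif(1, 0.05, 0.95)
        if (tries == 1000L) stop("cannot place planted delta in [0,1]")
      }
    }
    rep_ids <- unlist(lapply(genos, function(g)
      paste0(g, "_", seq_len(spec$genotypes[[g]]))))
    labels <- lapply(genos, function(g)
      paste0(g, "_", seq_len(spec$genotypes[[g]])))
    names(labels) <- genos
    psi <- matrix(NA_real_, n, length(rep_ids),
                  dimnames = list(NULL, rep_ids))
    for (g in genos) {
      mu <- if (g == "WT") baseline else baseline + delta[, g]
      for (r in labels[[g]]) {
        latent <- inv_logit(logit(mu) + rnorm(n, 0, spec$logit_sd))
        total <- pmax(rpois(n, spec$read_depth), 1L)
        psi[, r] <- rbinom(n, total, latent) / total
      }
    }
    # two-sample t-test on logit-PSI (counts clamped away from 0/1)
    clamp <- function(p) pmin(pmax(p, 0.5 / spec$read_depth),
                              1 - 0.5 / spec$read_depth)
    fdr <- dpsi <- matrix(NA_real_, n, length(muts),
                          dimnames = list(NULL, muts))
    wt_cols <- labels[["WT"]]
    for (g in muts) {
      gc <- labels[[g]]
      pv <- vapply(seq_len(n), function(i) {
        a <- logit(clamp(psi[i, gc])); b <- logit(clamp(psi[i, wt_cols]))
        if (var(a) == 0 && var(b) == 0) return(if (mean(a) == mean(b)) 1 else 0)
        unpaired_t_test(a, b)$p
      }, numeric(1L))
      fdr[, g] <- bh_fdr(pv)
      dpsi[, g] <- rowMeans(psi[, gc, drop = FALSE]) -
        rowMeans(psi[, wt_cols, drop = FALSE])
    }
    width <- 150L
    starts <- seq_len(n) * 10000L
    events <- data.frame(
      event_id = sprintf("SE_%05d", seq_len(n)),
      event_type = "SE",
      gene_id = sprintf("gene%05d", seq_len(n)),
      chrom = "chrSim", strand = "+",
      exon_start = starts, exon_end = starts + width,
      upstream_start = starts - 1000L, upstream_end = starts - 1000L + width,
      downstream_start = starts + 1000L,
      downstream_end = starts + 1000L + width,
      stringsAsFactors = FALSE)
    truth <- do.call(rbind, lapply(muts, function(g)
      data.frame(event_id = events$event_id, genotype = g,
                 planted = planted[, g], delta = delta[, g],
                 stringsAsFactors = FALSE)))
    list(table = event_table(events, psi, labels, fdr = fdr,
                             delta_psi = dpsi),
         truth = truth)
  })
}

#' Specification for a synthetic swim trajectory
#'
#' @param segments data.frame with columns `duration_s`, `mode` (`"active"`
#'   or `"pause"`), `speed_cm_s`; active speeds must be >= 1.5 cm/s and
#'   pause speeds < 1.5 cm/s so planted modes are recoverable under the
#'   pause rule.
#' @param fps frames per second (default 10, so 20 frames span 2 s).
#' @param tank a [tank_geometry()].
#' @param jitter_sd positional noise sd in cm, added after integration.
#' @param seed RNG seed.
#' @return An object of class `trajectory_sim_spec`.
#' @export
trajectory_sim_spec <- function(segments, fps = 10,
                                tank = tank_geometry(),
                                jitter_sd = 0, seed = 1L) {
  stopifnot(is.data.frame(segments),
            all(c("duration_s", "mode", "speed_cm_s") %in% names(segments)),
            all(segments$duration_s > 0),
            all(segments$mode %in% c("active", "pause")))
  if (any(segments$speed_cm_s[segments$mode == "pause"] >= 1.5))
    stop("pause-mode speed must be < 1.5 cm/s")
  if (any(segments$speed_cm_s[segments$mode == "active"] < 1.5))
    stop("active-mode speed must be >= 1.5 cm/s")
  structure(as.list(environment()), class = "trajectory_sim_spec")
}

#' Simulate a swim trajectory from piecewise-constant segment speeds
#'
#' Positions integrate each segment's speed along a per-frame random
#' heading in the length x depth plane; headings that would carry the
#' fish through a tank wall are redrawn, so every between-frame
#' displacement equals exactly speed/fps and planted speeds are exact.
#' Jitter is added after integration.
#'
#' @param spec a [trajectory_sim_spec()].
#' @return list with `traj` (a [trajectory()]) and `truth`: data.frame of
#'   per-segment `mode`, `start_interval`, `end_interval` (1-based,
#'   inclusive, over between-frame intervals), `speed_cm_s`, and
#'   `detectable_pause` (pause segments spanning >= 20 intervals).
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_sim_spec"))
  with_seed(spec$seed, {
    seg <- spec$segments
    n_int <- round(seg$duration_s * spec$fps)
    step <- seg$speed_cm_s / spec$fps
    if (any(step > min(spec$tank$length_cm, spec$tank$depth_cm) / 2))
      stop("segment speed unrealisable inside the tank at this fps")
    total <- sum(n_int)
    mode_by_int <- rep(seg$mode, n_int)
    step_by_int <- rep(step, n_int)
    x <- numeric(total + 1L); y <- numeric(total + 1L)
    x[1L] <- spec$tank$length_cm / 2; y[1L] <- spec$tank$depth_cm / 2
    # headings that would cross a wall are redrawn, so every between-frame
    # displacement is exactly speed/fps and planted speeds are recovered
    # without bias (a direction into the tank always exists because the
    # realisability check bounds the step by the smaller tank dimension)
    for (i in seq_len(total)) {
      repeat {
        theta <- runif(1, 0, 2 * pi)
        nx <- x[i] + step_by_int[i] * cos(theta)
        ny <- y[i] + step_by_int[i] * sin(theta)
        if (nx >= 0 && nx <= spec$tank$length_cm &&
            ny >= 0 && ny <= spec$tank$depth_cm) break
      }
      x[i + 1L] <- nx; y[i + 1L] <- ny
    }
    if (spec$jitter_sd > 0) {
      x <- pmin(pmax(x + rnorm(total + 1L, 0, spec$jitter_sd), 0),
                spec$tank$length_cm)
      y <- pmin(pmax(y + rnorm(total + 1L, 0, spec$jitter_sd), 0),
                spec$tank$depth_cm)
    }
    ends <- cumsum(n_int)
    truth <- data.frame(
      mode = seg$mode,
      start_interval = c(1L, head(ends, -1L) + 1L),
      end_interval = ends,
      speed_cm_s = seg$speed_cm_s,
      detectable_pause = seg$mode == "pause" & n_int >= 20L,
      stringsAsFactors = FALSE)
    list(traj = trajectory(seq.int(0L, total), x, y, fps = spec$fps,
                           tank = spec$tank),
         truth = truth)
  })
}

#' Specification for synthetic gene sequences
#'
#' @param n_genes number of genes (one synthetic chromosome each).
#' @param exon_count_range inclusive range of exon counts; at least 3 so a
#'   cassette exon has constitutive neighbours.
#' @param exon_length_range inclusive range of exon lengths (nt).
#' @param intron_length_range inclusive range of intron lengths (nt);
#'   minimum 60 so 250-bp windows truncate predictably at the midpoint.
#' @param motif_density named numeric vector, YGCY occurrences per 100 nt
#'   to plant in each of the five windows around the cassette exon (names
#'   from the region vocabulary; omitted windows get density 0).
#' @param base_comp background base composition over A, C, G, T.
#' @param motifs motif set planted (default the canonical YGCY preset).
#' @param prefix gene-id prefix, so independently generated sets can be
#'   combined without id collisions.
#' @param seed RNG seed.
#' @return An object of class `sequence_sim_spec`.
#' @export
sequence_sim_spec <- function(n_genes = 50,
                              exon_count_range = c(5L, 7L),
                              exon_length_range = c(90L, 150L),
                              intron_length_range = c(600L, 1000L),
                              motif_density = c(),
                              base_comp = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                              motifs = ygcy_motifs(),
                              prefix = "sgene",
                              seed = 1L) {
  stopifnot(intron_length_range[1L] >= 60L, exon_count_range[1L] >= 3L,
            all(motif_density >= 0),
            all(names(motif_density) %in% .region_names))
  base_comp <- base_comp / sum(base_comp)
  structure(as.list(environment()), class = "sequence_sim_spec")
}

# draw background sequence free of YGCY occurrences: generate iid bases,
# then break every [CT]GC[CT] by mutating its G to A until none remain
.background_seq <- function(len, comp) {
  s <- sample(names(comp), len, replace = TRUE, prob = comp)
  repeat {
    str <- paste(s, collapse = "")
    m <- gregexpr("(?=[CT]GC[CT])", str, perl = TRUE)[[1L]]
    if (m[1L] == -1L) break
    s[as.integer(m) + 1L] <- "A"
  }
  s
}

#' Simulate gene sequences with motifs planted per window
#'
#' Background sequence is i.i.d. over A/C/G/T at the spec's composition
#' with YGCY occurrences rejected, so planted motifs are the only ones
#' present. Motifs are then planted at non-overlapping random offsets
#' within each named window around the cassette exon (the middle exon) at
#' the requested per-100-nt density. Windows follow the same strand-aware
#' definition as [extract_windows()].
#'
#' @param spec a [sequence_sim_spec()].
#' @return list with `genome` (a [Biostrings::DNAStringSet], one sequence
#'   per gene), `models` (list of [gene_model()] with `cassette_index`
#'   set), and `planted`: data.frame of `gene_id`, `region`, `start`
#'   (0-based genomic), `motif`.
#' @export
simulate_gene_sequences <- function(spec) {
  stopifnot(inherits(spec, "sequence_sim_spec"))
  with_seed(spec$seed, {
    motifs <- spec$motifs$motifs
    seqs <- character(spec$n_genes)
    models <- vector("list", spec$n_genes)
    planted <- list()
    for (gi in seq_len(spec$n_genes)) {
      gid <- sprintf("%s%04d", spec$prefix, gi)
      n_ex <- sample(seq(spec$exon_count_range[1L], spec$exon_count_range[2L]), 1L)
      ex_len <- sample(seq(spec$exon_length_range[1L], spec$exon_length_range[2L]),
                       n_ex, replace = TRUE)
      in_len <- sample(seq(spec$intron_length_range[1L], spec$intron_length_range[2L]),
                       n_ex - 1L, replace = TRUE)
      flank <- 100L
      total <- 2L * flank + sum(ex_len) + sum(in_len)
      s <- .background_seq(total, spec$base_comp)
      starts <- integer(n_ex); pos <- flank
      for (e in seq_len(n_ex)) {
        starts[e] <- pos
        pos <- pos + ex_len[e] + if (e < n_ex) in_len[e] else 0L
      }
      model <- gene_model(gid, paste0(gid, ".t1"), gid, "+",
                          data.frame(start = starts, end = starts + ex_len),
                          cassette_index = (n_ex + 1L) %/% 2L)
      # plant motifs in each requested window
      wins <- .window_coords(model, model$cassette_index, window_nt = 250L)
      for (w in names(spec$motif_density)) {
        dens <- spec$motif_density[[w]]
        wlen <- wins[[w]]$end - wins[[w]]$start
        k <- round(dens * wlen / 100)
        if (k == 0L) next
        if (k * 8L > wlen)
          stop("motif density too high to place without overlap in ", w)
        # non-overlapping offsets at spacing >= 4
        for (try in seq_len(10000L)) {
          off <- sort(sample.int(wlen - 3L, k))
          if (k == 1L || all(diff(off) >= 4L)) break
          if (try == 10000L)
            stop("motif density too high to place without overlap in ", w)
        }
        for (o in off) {
          motif <- sample(motifs, 1L)
          gpos <- wins[[w]]$start + o  # 1-based within gene sequence
          s[gpos:(gpos + 3L)] <- strsplit(motif, "")[[1L]]
          planted[[length(planted) + 1L]] <-
            data.frame(gene_id = gid, region = w, start = gpos - 1L,
                       motif = motif, stringsAsFactors = FALSE)
        }
      }
      seqs[gi] <- paste(s, collapse = "")
      models[[gi]] <- model
    }
    names(seqs) <- vapply(models, function(m) m$gene_id, character(1L))
    names(models) <- names(seqs)
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(gene_id = character(), region = character(),
                 start = integer(), motif = character())
    list(genome = Biostrings::DNAStringSet(seqs), models = models,
         planted = planted)
  })
}
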