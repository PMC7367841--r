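# Synthetic-cohort generators: every input the pipeline consumes can be
# produced here with planted ground truth, so all downstream stages are
# testable end to end without any external data. All generators use one
# RNG stream per call, seeded from the spec seed; per-sample sub-streams
# are derived by fixed offsets, so enlarging a cohort never reshuffles the
# samples already generated.

SAMPLE_SEED_OFFSET <- 7919L    # per-sample mutation stream
PURITY_SEED_OFFSET <- 104729L  # per-sample purity draw (shared by generators)
DEPTH_SEED_OFFSET <- 15485863L # per-sample depth stream

#' Specification of a synthetic tumor cohort
#'
#' Defaults emulate the study conditions of a cohort of spontaneous canine
#' mammary tumors: roughly a fifth benign samples, a mean of ~43 exonic
#' mutations per case, histology-dependent driver-gene frequencies
#' (PIK3CA common in both groups, TP53/KRAS restricted to malignant), an
#' age-related CpG C>T deamination signature dominating the trinucleotide
#' spectrum, and purities above 0.7.
#'
#' @param n_samples Cohort size.
#' @param benign_fraction Fraction of benign samples in \[0, 1\]
#'   (default 0.225).
#' @param driver_freqs Tibble `gene`, `benign_freq`, `malignant_freq` in
#'   \[0, 1\].
#' @param catalog Signature catalog (K x 96 row-stochastic) the spectra are
#'   drawn from; default [synthetic_signature_catalog()].
#' @param signature_weights Mixture weights over catalog signatures, sums
#'   to 1 (default 0.85 deamination / 0.15 flat background).
#' @param tmb_rate Mean exonic mutations per sample (Poisson; default 43.5).
#' @param indel_fraction Fraction of mutations that are indels
#'   (default 0.21).
#' @param purity_range Uniform purity bounds in (0, 1] (default 0.7-1).
#' @param target_mb Callable-region size in Mb (default 38).
#' @param error_site_rate Fraction of variant sites planted as alignment
#'   errors (suboptimal score close to optimal; default 0.02).
#' @param seed Integer RNG seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 60,
                        benign_fraction = 0.225,
                        driver_freqs = default_driver_freqs(),
                        catalog = synthetic_signature_catalog(),
                        signature_weights = c(0.85, 0.15),
                        tmb_rate = 43.5,
                        indel_fraction = 0.21,
                        purity_range = c(0.7, 1),
                        target_mb = 38,
                        error_site_rate = 0.02,
                        seed = 1) {
  assert_prob(benign_fraction, "benign_fraction")
  assert_prob(c(driver_freqs$benign_freq, driver_freqs$malignant_freq),
              "driver_freqs")
  if (abs(sum(signature_weights) - 1) > 1e-9) {
    abort("`signature_weights` must sum to 1")
  }
  if (length(signature_weights) != nrow(catalog)) {
    abort("one signature weight per catalog signature is required")
  }
  if (purity_range[1] > purity_range[2] || purity_range[1] <= 0 ||
      purity_range[2] > 1) {
    abort("`purity_range` must be ordered bounds in (0, 1]")
  }
  if (tmb_rate <= 0) abort("`tmb_rate` must be positive")
  structure(
    list(n_samples = n_samples, benign_fraction = benign_fraction,
         driver_freqs = driver_freqs, catalog = as_catalog_matrix(catalog),
         signature_weights = signature_weights, tmb_rate = tmb_rate,
         indel_fraction = indel_fraction, purity_range = purity_range,
         target_mb = target_mb, error_site_rate = error_site_rate,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

default_driver_freqs <- function() {
  tibble(
    gene = c("PIK3CA", "TP53", "KRAS", "PTEN", "AKT1"),
    benign_freq = c(0.55, 0.00, 0.02, 0.04, 0.00),
    malignant_freq = c(0.38, 0.11, 0.13, 0.07, 0.05)
  )
}

#' Specification of a toy genome
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param bin_size Depth-bin width in bp.
#' @param planted_segments Tibble `chrom`, `start`, `end`, `true_log2` of
#'   copy-number segments planted into malignant samples (0-based
#'   half-open; must lie within chromosome bounds).
#' @param gc_profile Optional per-bin GC fraction; by default a smooth
#'   deterministic wave in \[0.35, 0.65\].
#' @return List of class `genome_spec` with a `bins` tibble tiling each
#'   chromosome half-open without overlap.
#' @export
genome_spec <- function(chrom_lengths, bin_size = 1e4,
                        planted_segments = NULL, gc_profile = NULL) {
  if (bin_size <= 0) abort("`bin_size` must be positive")
  if (is.null(names(chrom_lengths))) abort("`chrom_lengths` must be named")
  bins <- imap(chrom_lengths, function(len, chrom) {
    starts <- seq(0, len - 1, by = bin_size)
    tibble(chrom = chrom, start = starts, end = pmin(starts + bin_size, len))
  }) |> list_rbind()
  if (is.null(gc_profile)) {
    # short-period wobble: GC content varies at a much finer scale than
    # copy-number segments, so GC bands sample bins across the genome
    gc_profile <- 0.5 + 0.15 * sin(2 * pi * seq_len(nrow(bins)) / 7.13)
  }
  if (length(gc_profile) != nrow(bins)) {
    abort("`gc_profile` must have one value per bin")
  }
  assert_prob(gc_profile, "gc_profile")
  bins$gc <- gc_profile
  if (!is.null(planted_segments)) {
    assert_cols(planted_segments, c("chrom", "start", "end", "true_log2"),
                "planted_segments")
    lims <- chrom_lengths[planted_segments$chrom]
    if (anyNA(lims) || any(planted_segments$start < 0) ||
        any(planted_segments$end > lims)) {
      abort("planted segments must lie within chromosome bounds")
    }
  }
  structure(
    list(chrom_lengths = chrom_lengths, bin_size = bin_size,
         planted_segments = planted_segments, bins = bins),
    class = "genome_spec"
  )
}

#' Simulate a toy reference genome
#'
#' I.i.d. uniform A/C/G/T sequence per chromosome; mutation contexts are
#' later located by scanning this sequence, never by resampling it.
#'
#' @param genome A [genome_spec()].
#' @param seed Integer RNG seed.
#' @return Named character vector of chromosome sequences.
#' @export
simulate_reference <- function(genome, seed = 1) {
  withr::with_seed(as.integer(seed), {
    vapply(names(genome$chrom_lengths), function(chrom) {
      paste(sample(BASES, genome$chrom_lengths[[chrom]], replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

sample_purity <- function(spec, i) {
  withr::with_seed(spec$seed + PURITY_SEED_OFFSET + i, {
    runif(1, spec$purity_range[1], spec$purity_range[2])
  })
}

# positions of every trinucleotide context, pyrimidine-strand convention;
# positions inside `exclude` intervals (the driver gene models) are left
# out so passenger placement never contaminates planted driver frequencies
context_index <- function(reference, exclude = NULL) {
  res <- list()
  for (chrom in names(reference)) {
    seq <- reference[[chrom]]
    len <- nchar(seq)
    if (len < 3) next
    tri <- substring(seq, seq_len(len - 2), 3:len)
    mid <- substr(tri, 2, 2)
    flip <- mid %in% c("A", "G")
    key <- tri
    key[flip] <- revcomp(tri[flip])
    keep <- !str_detect(tri, "N")
    df <- tibble(chrom = chrom,
                 pos = which(keep) + 1L, # 1-based SNV position
                 context = key[keep], flipped = flip[keep])
    if (!is.null(exclude)) {
      ex <- exclude[exclude$chrom == chrom, ]
      for (k in seq_len(nrow(ex))) {
        df <- df[!(df$pos > ex$start[k] & df$pos <= ex$end[k]), ]
      }
    }
    res[[chrom]] <- df
  }
  df <- list_rbind(res)
  split(df, df$context)
}

driver_gene_model <- function(spec, genome, gene_size = 3000) {
  chrom <- names(genome$chrom_lengths)[
    which.max(unlist(genome$chrom_lengths))]
  n <- nrow(spec$driver_freqs)
  starts <- 1000 + (seq_len(n) - 1) * (gene_size + 1000)
  if (max(starts) + gene_size > genome$chrom_lengths[[chrom]]) {
    abort("genome too small to place driver genes")
  }
  tibble(gene = spec$driver_freqs$gene, chrom = chrom,
         start = starts, end = starts + gene_size)
}

locate_gene <- function(chrom, pos, gene_model, gene_size = 10000) {
  hit <- rep(NA_character_, length(pos))
  for (k in seq_len(nrow(gene_model))) {
    sel <- chrom == gene_model$chrom[k] & pos > gene_model$start[k] &
      pos <= gene_model$end[k]
    hit[sel] <- gene_model$gene[k]
  }
  psg <- paste0("PSG_", chrom, "_", pos %/% gene_size)
  ifelse(is.na(hit), psg, hit)
}

#' Simulate a somatic-mutation cohort with planted ground truth
#'
#' Per sample, the exonic mutation count is Poisson(`tmb_rate`); SNV
#' trinucleotide channels are drawn from the planted signature mixture and
#' placed at reference positions whose context matches; driver genes are
#' mutated by histology-specific Bernoulli draws; VAF is the clonal
#' fraction times purity/2 plus binomial read-sampling noise (clonal
#' fractions Uniform(0.2, 1) for benign, Uniform(0.5, 1) for malignant, so
#' malignant allele frequencies are stochastically larger). Deterministic
#' given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @param genome A [genome_spec()]; the reference must cover all its
#'   chromosomes.
#' @param reference Named character vector of chromosome sequences
#'   (default [simulate_reference()] from the spec seed).
#' @param read_depth Simulated read depth at variant sites (default 100).
#' @return List: `variants` (one row per mutation: `sample_id`, `chrom`,
#'   `pos` 1-based, `ref`, `alt`, `consequence`, `vaf`, `gene`, plus
#'   mutation classes), `metadata` (`sample_id`, `histology`, `purity`,
#'   `age`), and `scores`, a per-read AS/XS sidecar with
#'   `error_site_rate` of sites planted as alignment errors.
#' @export
simulate_mutation_cohort <- function(spec, genome,
                                     reference = simulate_reference(genome, spec$seed),
                                     read_depth = 100) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(genome, "genome_spec"))
  missing_chrom <- setdiff(names(genome$chrom_lengths), names(reference))
  if (length(missing_chrom) > 0) {
    abort(paste0("reference lacks chromosome(s): ",
                 paste(missing_chrom, collapse = ", ")))
  }
  n <- spec$n_samples
  n_benign <- round(spec$benign_fraction * n)
  histology <- c(rep("benign", n_benign), rep("malignant", n - n_benign))
  sample_ids <- sprintf("CMT-%03d", seq_len(n))
  mixture <- as.numeric(spec$signature_weights %*% spec$catalog)
  names(mixture) <- colnames(spec$catalog)
  gene_model <- driver_gene_model(spec, genome)
  ctx_idx <- context_index(reference, exclude = gene_model)
  channels <- sbs_channels()
  passenger_csq <- c(missense_variant = 0.55, synonymous_variant = 0.30,
                     stop_gained = 0.08, splice_region_variant = 0.07)

  metadata <- tibble(
    sample_id = sample_ids, histology = histology,
    purity = vapply(seq_len(n), function(i) sample_purity(spec, i),
                    numeric(1)),
    age = vapply(seq_len(n), function(i) {
      withr::with_seed(spec$seed + PURITY_SEED_OFFSET + 500000L + i,
                       round(rnorm(1, 11.8, 2.2), 1))
    }, numeric(1))
  )

  draw_vaf <- function(hist, purity, k) {
    u <- if (hist == "benign") runif(k, 0.2, 1) else runif(k, 0.5, 1)
    p <- u * purity / 2
    rbinom(k, read_depth, p) / read_depth
  }

  per_sample <- map(seq_len(n), function(i) {
    withr::with_seed(spec$seed + SAMPLE_SEED_OFFSET * i, {
      purity <- metadata$purity[i]
      m <- rpois(1, spec$tmb_rate)
      n_indel <- rbinom(1, m, spec$indel_fraction)
      n_snv <- m - n_indel
      rows <- list()
      if (n_snv > 0) {
        ch <- sample(channels, n_snv, replace = TRUE, prob = mixture)
        ctx <- paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7))
        alt_pyr <- substr(ch, 5, 5)
        pick_chrom <- character(n_snv)
        pick_pos <- integer(n_snv)
        pick_flip <- logical(n_snv)
        for (cc in unique(ctx)) {
          sel <- which(ctx == cc)
          pool <- ctx_idx[[cc]]
          if (is.null(pool) || nrow(pool) == 0) {
            abort(paste0("reference contains no context for channel ",
                         ch[sel[1]]))
          }
          draw <- sample.int(nrow(pool), length(sel), replace = TRUE)
          pick_chrom[sel] <- pool$chrom[draw]
          pick_pos[sel] <- pool$pos[draw]
          pick_flip[sel] <- pool$flipped[draw]
        }
        ref <- ifelse(pick_flip,
                      chartr("CT", "GA", substr(ch, 3, 3)),
                      substr(ch, 3, 3))
        alt <- ifelse(pick_flip, chartr("ACGT", "TGCA", alt_pyr), alt_pyr)
        rows$snv <- tibble(
          sample_id = sample_ids[i], chrom = pick_chrom, pos = pick_pos,
          ref = ref, alt = alt,
          consequence = sample(names(passenger_csq), n_snv, replace = TRUE,
                               prob = passenger_csq),
          vaf = draw_vaf(histology[i], purity, n_snv)
        )
      }
      if (n_indel > 0) {
        chroms <- sample(names(genome$chrom_lengths), n_indel, replace = TRUE,
                         prob = unlist(genome$chrom_lengths))
        in_driver <- function(cc, p) {
          any(gene_model$chrom == cc & p > gene_model$start &
                p <= gene_model$end)
        }
        pos <- vapply(chroms, function(cc) {
          repeat {
            p <- as.numeric(sample.int(genome$chrom_lengths[[cc]] - 5, 1) + 1)
            if (!in_driver(cc, p)) return(p)
          }
        }, numeric(1))
        base <- unname(substr(reference[chroms], pos, pos))
        ins_len <- sample(c(1, 2, 3), n_indel, replace = TRUE,
                          prob = c(0.5, 0.25, 0.25))
        is_ins <- runif(n_indel) < 0.5
        ref <- unname(ifelse(is_ins, base,
                             substr(reference[chroms], pos, pos + ins_len)))
        alt <- ifelse(is_ins,
                      paste0(base, strrep("A", ins_len)),
                      base)
        rows$indel <- tibble(
          sample_id = sample_ids[i], chrom = chroms, pos = pos,
          ref = ref, alt = alt,
          consequence = ifelse(ins_len %% 3 == 0, "inframe_insertion",
                               "frameshift_variant"),
          vaf = draw_vaf(histology[i], purity, n_indel)
        )
      }
      freqs <- if (histology[i] == "benign") {
        spec$driver_freqs$benign_freq
      } else {
        spec$driver_freqs$malignant_freq
      }
      mutated <- runif(nrow(spec$driver_freqs)) < freqs
      if (any(mutated)) {
        gm <- gene_model[mutated, ]
        pos <- gm$start + vapply(gm$end - gm$start, function(w) {
          sample.int(w, 1L)
        }, integer(1L))
        ref <- unname(substr(reference[gm$chrom], pos, pos))
        alt <- unname(vapply(ref, function(b) sample(setdiff(BASES, b), 1),
                             character(1)))
        rows$driver <- tibble(
          sample_id = sample_ids[i], chrom = gm$chrom, pos = pos,
          ref = ref, alt = alt, consequence = "missense_variant",
          vaf = draw_vaf(histology[i], purity, nrow(gm))
        )
      }
      list_rbind(rows)
    })
  })
  variants <- list_rbind(per_sample)
  variants$gene <- locate_gene(variants$chrom, variants$pos, gene_model)
  variants <- annotate_mutation_class(variants)

  scores <- withr::with_seed(spec$seed + 31L, {
    sites <- distinct(variants, .data$chrom, .data$pos, .data$ref, .data$alt)
    ns <- nrow(sites)
    err <- runif(ns) < spec$error_site_rate
    as_mean <- rnorm(ns, 60, 4)
    xs_frac <- ifelse(err, runif(ns, 0.85, 1), runif(ns, 0, 0.4))
    idx <- rep(seq_len(ns), each = 2)
    tibble(sites[idx, ], read = rep(1:2, ns),
           as = round(rnorm(2 * ns, as_mean[idx], 2), 1),
           xs = round(xs_frac[idx] * rnorm(2 * ns, as_mean[idx], 2), 1),
           planted_error = err[idx])
  })

  list(variants = variants, metadata = metadata, scores = scores,
       gene_model = gene_model)
}

#' Simulate binned tumor/normal read depth
#'
#' Normal depth is Poisson around a GC-dependent mean (monotone bias
#' curve); tumor depth is additionally scaled by the planted copy-number
#' ratio diluted by tumor purity,
#' `purity * 2^true_log2 + (1 - purity)`, within planted segments.
#' Planted segments are applied to malignant samples only, so malignant
#' genomes carry more copy-number alteration than benign ones.
#' Deterministic given the spec seed; purities agree with
#' [simulate_mutation_cohort()].
#'
#' @param spec A [cohort_spec()].
#' @param genome A [genome_spec()] (its `planted_segments` are the ground
#'   truth).
#' @param mean_depth Mean sequencing depth per bin (default 100).
#' @return Tibble: `sample_id`, `chrom`, `start`, `end`, `gc`, `t_depth`,
#'   `n_depth` (0-based half-open bins).
#' @export
simulate_depth_bins <- function(spec, genome, mean_depth = 100) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(genome, "genome_spec"))
  bins <- genome$bins
  bias <- 0.6 + 0.8 * bins$gc # monotone GC bias
  n <- spec$n_samples
  n_benign <- round(spec$benign_fraction * n)
  map(seq_len(n), function(i) {
    purity <- sample_purity(spec, i)
    r <- rep(1, nrow(bins))
    if (i > n_benign && !is.null(genome$planted_segments)) {
      ps <- genome$planted_segments
      for (k in seq_len(nrow(ps))) {
        sel <- bins$chrom == ps$chrom[k] & bins$start >= ps$start[k] &
          bins$end <= ps$end[k]
        r[sel] <- purity * 2^ps$true_log2[k] + (1 - purity)
      }
    }
    withr::with_seed(spec$seed + DEPTH_SEED_OFFSET + i, {
      tibble(
        sample_id = sprintf("CMT-%03d", i),
        bins[c("chrom", "start", "end", "gc")],
        t_depth = rpois(nrow(bins), mean_depth * bias * r),
        n_depth = rpois(nrow(bins), mean_depth * bias)
      )
    })
  }) |> list_rbind()
}

#' Specification of a synthetic expression cohort
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes (default 600).
#' @param k_true Number of planted metagene clusters (>= 2).
#' @param cluster_props Sample proportions per cluster, sums to 1.
#' @param loading_scale Signal level of a cluster's gene block (default 5).
#' @param noise_sd Standard deviation of the half-normal noise
#'   (default 0.5).
#' @param hazards Per-cluster exponential event rate (1/time).
#' @param censor_rate Independent exponential censoring rate
#'   (default 0.02).
#' @param normal_clusters Indices of clusters representing normal tissue
#'   (their samples are labeled `"normal"`); default none.
#' @param seed Integer RNG seed.
#' @return List of class `expression_spec`.
#' @export
expression_spec <- function(n_samples = 60, n_genes = 600, k_true = 3,
                            cluster_props = rep(1 / k_true, k_true),
                            loading_scale = 5, noise_sd = 0.5,
                            hazards = rep(0.1, k_true),
                            censor_rate = 0.02,
                            normal_clusters = integer(0), seed = 1) {
  if (k_true < 2) abort("`k_true` must be >= 2")
  if (k_true > n_samples) abort("`k_true` cannot exceed `n_samples`")
  if (abs(sum(cluster_props) - 1) > 1e-9) {
    abort("`cluster_props` must sum to 1")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (length(hazards) != k_true) abort("one hazard per cluster is required")
  structure(
    list(n_samples = n_samples, n_genes = n_genes, k_true = k_true,
         cluster_props = cluster_props, loading_scale = loading_scale,
         noise_sd = noise_sd, hazards = hazards, censor_rate = censor_rate,
         normal_clusters = normal_clusters, seed = as.integer(seed)),
    class = "expression_spec"
  )
}

#' Simulate an expression cohort with planted metagene clusters
#'
#' The matrix is a non-negative block model: each cluster owns a block of
#' genes expressed at `loading_scale` in its samples, plus half-normal
#' noise. Survival times are exponential with the cluster's hazard and
#' independent exponential censoring. Deterministic given the spec seed.
#'
#' @param spec An [expression_spec()].
#' @return List: `expression` (genes x samples matrix), `survival` tibble
#'   (`sample_id`, `time`, `event`), `labels` tibble (`sample_id`,
#'   `cluster`, `type`).
#' @export
simulate_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  n <- spec$n_samples; k <- spec$k_true
  counts <- diff(round(cumsum(c(0, spec$cluster_props)) * n))
  cluster <- rep(seq_len(k), counts)
  gene_block <- rep(seq_len(k), length.out = spec$n_genes)
  withr::with_seed(spec$seed, {
    signal <- matrix(0, spec$n_genes, n)
    for (c_id in seq_len(k)) {
      signal[gene_block == c_id, cluster == c_id] <- spec$loading_scale
    }
    noise <- abs(matrix(rnorm(spec$n_genes * n, 0, max(spec$noise_sd, 0)),
                        spec$n_genes, n))
    if (spec$noise_sd == 0) noise[] <- 0
    expr <- signal + noise
    rownames(expr) <- sprintf("G%04d", seq_len(spec$n_genes))
    colnames(expr) <- sprintf("S%03d", seq_len(n))
    t_event <- rexp(n, spec$hazards[cluster])
    t_cens <- rexp(n, spec$censor_rate)
    survival <- tibble(
      sample_id = colnames(expr),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
  })
  labels <- tibble(
    sample_id = colnames(expr), cluster = cluster,
    type = ifelse(cluster %in% spec$normal_clusters, "normal", "tumor")
  )
  list(expression = expr, survival = survival, labels = labels)
}

#' Build a toy chain alignment with an exact per-base map
#'
#' Emits syntactically valid UCSC chain text for a supplied block map
#' between a source ("t") and target ("q") chromosome, together with a
#' per-base source-to-target map computed directly from the block list —
#' independent of the chain arithmetic, so it can serve as an oracle for
#' parsing and projection. Consecutive blocks with the same strand and
#' consistent ordering are folded into one chain; others start a new
#' chain. Blocks must not overlap on either side.
#'
#' @param t_name,t_size Source chromosome name and length.
#' @param q_name,q_size Target chromosome name and length.
#' @param blocks Tibble `t_start`, `t_end`, `q_start` (target interval
#'   start on the + strand), `strand` (`"+"` or `"-"`); all 0-based
#'   half-open, equal lengths on both sides.
#' @param base_score Score of the first chain; later chains get lower
#'   scores (default 1000).
#' @return List of class `toy_chain`: `chains` (a `chain_set`), `text`
#'   (chain file text), and `map`, a per-base tibble (`src_pos`,
#'   `tgt_chrom`, `tgt_pos`; unmapped source bases absent).
#' @export
simulate_toy_chain <- function(t_name, t_size, q_name, q_size, blocks,
                               base_score = 1000) {
  assert_cols(blocks, c("t_start", "t_end", "q_start", "strand"), "blocks")
  blocks <- arrange(blocks, .data$t_start)
  len <- blocks$t_end - blocks$t_start
  if (any(len <= 0)) abort("blocks must have positive length")
  blocks$q_end <- blocks$q_start + len
  if (any(blocks$t_start < 0) || any(blocks$t_end > t_size) ||
      any(blocks$q_start < 0) || any(blocks$q_end > q_size)) {
    abort("blocks must lie within chromosome bounds")
  }
  if (nrow(blocks) > 1) {
    if (any(blocks$t_start[-1] < blocks$t_end[-nrow(blocks)])) {
      abort("overlapping blocks on the source side")
    }
    qb <- arrange(blocks, .data$q_start)
    if (any(qb$q_start[-1] < qb$q_end[-nrow(qb)])) {
      abort("overlapping blocks on the target side")
    }
  }
  # fold consecutive compatible blocks into chains
  grp <- 1
  group <- numeric(nrow(blocks))
  group[1] <- grp
  for (k in seq_len(nrow(blocks))[-1]) {
    same <- blocks$strand[k] == blocks$strand[k - 1]
    ord_ok <- if (blocks$strand[k] == "+") {
      blocks$q_start[k] >= blocks$q_end[k - 1]
    } else {
      blocks$q_end[k] <= blocks$q_start[k - 1]
    }
    if (!(same && ord_ok)) grp <- grp + 1
    group[k] <- grp
  }
  headers <- list(); chain_blocks <- list()
  for (g in unique(group)) {
    bl <- blocks[group == g, ]
    strand <- bl$strand[1]
    cid <- as.character(g)
    if (strand == "+") {
      q_start_chain <- bl$q_start[1]
      q_end_chain <- bl$q_end[nrow(bl)]
      dq <- c(bl$q_start[-1] - bl$q_end[-nrow(bl)], NA)
    } else {
      # chain q coordinates on the reversed strand
      rev_start <- q_size - bl$q_end
      rev_end <- q_size - bl$q_start
      q_start_chain <- rev_start[1]
      q_end_chain <- rev_end[nrow(bl)]
      dq <- c(rev_start[-1] - rev_end[-nrow(bl)], NA)
    }
    headers[[cid]] <- tibble(
      score = base_score - (g - 1) * 10,
      t_name = t_name, t_size = t_size, t_strand = "+",
      t_start = bl$t_start[1], t_end = bl$t_end[nrow(bl)],
      q_name = q_name, q_size = q_size, q_strand = strand,
      q_start = q_start_chain, q_end = q_end_chain, chain_id = cid
    )
    chain_blocks[[cid]] <- tibble(
      chain_id = cid, size = bl$t_end - bl$t_start,
      dt = c(bl$t_start[-1] - bl$t_end[-nrow(bl)], NA), dq = dq
    )
  }
  chains <- structure(list(header = list_rbind(headers),
                           blocks = list_rbind(chain_blocks)),
                      class = "chain_set")
  # per-base oracle map, straight from the block list
  map <- map(seq_len(nrow(blocks)), function(k) {
    off <- seq_len(len[k]) - 1
    tgt <- if (blocks$strand[k] == "+") {
      blocks$q_start[k] + off
    } else {
      blocks$q_end[k] - 1 - off
    }
    tibble(src_pos = blocks$t_start[k] + off, tgt_chrom = q_name,
           tgt_pos = tgt)
  }) |> list_rbind()
  structure(list(chains = chains, text = write_chain(chains), map = map),
            class = "toy_chain")
}

#' Write / read the minimal somatic-variant VCF subset
#'
#' Writes VCF v4.2 with 1-based positions and INFO keys `SAMPLE`, `VAF`,
#' `CSQ`, `GENE`; reading goes through the vcfR parser.
#'
#' @param variants Variant tibble (`sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `consequence`, `vaf`, `gene`).
#' @param path File path.
#' @export
write_variant_vcf <- function(variants, path) {
  assert_cols(variants, c("sample_id", "chrom", "pos", "ref", "alt",
                          "consequence", "vaf"), "variants")
  gene <- variants$gene %||% rep(".", nrow(variants))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSAMPLE=%s;VAF=%s;CSQ=%s;GENE=%s",
            variants$chrom, as.integer(variants$pos), variants$ref,
            variants$alt, variants$sample_id,
            formatC(variants$vaf, digits = 6, format = "g"),
            variants$consequence, gene)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_variant_vcf
#' @return For reading: a variant tibble with 1-based `pos`.
#' @export
read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_field <- function(key) {
    vcfR::extract.info(vcf, element = key)
  }
  tibble(
    sample_id = info_field("SAMPLE"),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    consequence = info_field("CSQ"),
    vaf = as.numeric(info_field("VAF")),
    gene = info_field("GENE")
  )
}

#' Synthetic signature catalog
#'
#' Builds a small row-stochastic 96-channel catalog whose first signature
#' is an aging-like CpG deamination profile (mass concentrated on
#' `N[C>T]G` channels) and whose remaining signatures are random sparse
#' profiles (the last one flat when `k = 2`).
#'
#' @param k Number of signatures (default 2).
#' @param seed RNG seed for the random signatures.
#' @return K x 96 row-stochastic matrix with channel column names.
#' @export
synthetic_signature_catalog <- function(k = 2, seed = 99) {
  channels <- sbs_channels()
  clock <- rep(0.001, 96)
  cpg <- str_detect(channels, "\\[C>T\\]G$")
  clock[cpg] <- 1
  clock <- clock / sum(clock)
  sigs <- list(clock)
  if (k >= 2) sigs[[2]] <- rep(1 / 96, 96)
  if (k > 2) {
    withr::with_seed(seed, {
      for (j in 3:k) {
        w <- rexp(96)^2
        sigs[[j]] <- w / sum(w)
      }
    })
  }
  m <- do.call(rbind, sigs[seq_len(k)])
  rownames(m) <- c("Deamination", "Flat", paste0("Rand", seq_len(max(0, k - 2))))[seq_len(k)]
  colnames(m) <- channels
  m
}
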