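# Synthetic-cohort generators: determinism, planted parameters, format
# round trips.

test_that("cohort generation is deterministic and splits histology by rounding", {
  g <- toy_genome(chr1 = 3e4, chr2 = 2e4)
  sp <- cohort_spec(n_samples = 20, benign_fraction = 0.25, tmb_rate = 10,
                    seed = 7)
  cm1 <- simulate_mutation_cohort(sp, g)
  expect_equal(sum(cm1$metadata$histology == "benign"), 5)
  expect_equal(sum(cm1$metadata$histology == "malignant"), 15)
  cm2 <- simulate_mutation_cohort(sp, g)
  expect_identical(cm1$variants, cm2$variants)
  expect_identical(cm1$metadata, cm2$metadata)
  expect_identical(cm1$scores, cm2$scores)
  # per-sample counts sum to the table length
  expect_equal(sum(table(cm1$variants$sample_id)), nrow(cm1$variants))
  # enlarging the cohort does not reshuffle earlier samples
  # (n chosen so the benign count, hence every histology, is unchanged)
  sp_big <- cohort_spec(n_samples = 21, benign_fraction = 0.25,
                        tmb_rate = 10, seed = 7)
  cm3 <- simulate_mutation_cohort(sp_big, g)
  first20 <- dplyr::filter(cm3$variants,
                           sample_id %in% unique(cm1$variants$sample_id))
  expect_equal(dplyr::arrange(first20, sample_id, chrom, pos, alt),
               dplyr::arrange(cm1$variants, sample_id, chrom, pos, alt))
  expect_error(cohort_spec(tmb_rate = -1), "positive")
})

test_that("driver frequencies match the planted Bernoulli rates", {
  g <- toy_genome(chr1 = 3e4, chr2 = 1e4)
  freqs <- tibble::tibble(gene = "PIK3CA", benign_freq = 0.55,
                          malignant_freq = 0.38)
  sp <- cohort_spec(n_samples = 400, benign_fraction = 0.5, tmb_rate = 0.5,
                    driver_freqs = freqs, seed = 3)
  cm <- simulate_mutation_cohort(sp, g)
  hit <- cm$variants |>
    dplyr::filter(gene == "PIK3CA") |>
    dplyr::distinct(sample_id) |>
    dplyr::left_join(cm$metadata, by = "sample_id")
  n_benign_hit <- sum(hit$histology == "benign")
  # observed benign frequency within the exact binomial 99% CI of 0.55
  ci <- qbinom(c(0.005, 0.995), 200, 0.55)
  expect_gte(n_benign_hit, ci[1])
  expect_lte(n_benign_hit, ci[2])
})

test_that("generated spectra match the planted signature mixture", {
  g <- toy_genome(chr1 = 4e4, chr2 = 2e4)
  sp <- cohort_spec(n_samples = 25, tmb_rate = 220, indel_fraction = 0,
                    seed = 11)
  cm <- simulate_mutation_cohort(sp, g)
  expect_gte(nrow(cm$variants), 5000)
  ref <- simulate_reference(g, sp$seed)
  spec96 <- build_spectrum(cm$variants, ref)
  pooled <- rowSums(spec96)
  mixture <- as.numeric(sp$signature_weights %*% sp$catalog)
  cosine <- sum(pooled * mixture) / sqrt(sum(pooled^2) * sum(mixture^2))
  expect_gte(cosine, 0.95)
})

test_that("malignant VAFs are stochastically larger than benign", {
  g <- toy_genome(chr1 = 3e4, chr2 = 1e4)
  sp <- cohort_spec(n_samples = 40, tmb_rate = 40, seed = 19)
  cm <- simulate_mutation_cohort(sp, g)
  res <- compare_burden_and_maf(cm$variants, cm$metadata,
                                target_mb = sp$target_mb)
  vaf <- res[res$measure == "vaf", ]
  expect_lt(vaf$median_benign, vaf$median_malignant)
  expect_lt(vaf$p, 0.01)
})

test_that("planted alignment-error sites are the ones the filter rejects", {
  g <- toy_genome(chr1 = 3e4, chr2 = 1e4)
  sp <- cohort_spec(n_samples = 15, tmb_rate = 30, error_site_rate = 0.1,
                    seed = 23)
  cm <- simulate_mutation_cohort(sp, g)
  res <- alignment_error_filter(cm$variants, cm$scores)
  planted <- dplyr::distinct(cm$scores, chrom, pos, ref, alt, planted_error)
  audit <- dplyr::left_join(res$audit, planted,
                            by = c("chrom", "pos", "ref", "alt"))
  # planted error sites have XS drawn at 85-100% of AS; clean sites 0-40%
  expect_gt(mean(audit$rejected[audit$planted_error]), 0.8)
  expect_lt(mean(audit$rejected[!audit$planted_error]), 0.05)
})

test_that("depth bins realize the planted copy-ratio expectations", {
  # null: no planted segments -> mean ratio 1 per bin
  g0 <- toy_genome(chr1 = 5e4, chr2 = 2e4, bin_size = 500)
  sp <- cohort_spec(n_samples = 2, benign_fraction = 0, purity_range = c(1, 1),
                    seed = 5)
  db0 <- simulate_depth_bins(sp, g0, mean_depth = 300)
  one <- db0[db0$sample_id == "CMT-001", ]
  expect_lt(abs(mean(one$t_depth / one$n_depth) - 1), 0.02)
  # planted +1 at purity 1 -> mean ratio 2 within 3 SE over 100 bins
  planted <- tibble::tibble(chrom = "chr1", start = 1e4, end = 2e4,
                            true_log2 = 1)
  g1 <- genome_spec(c(chr1 = 5e4, chr2 = 2e4), bin_size = 100,
                    planted_segments = planted)
  db1 <- simulate_depth_bins(sp, g1, mean_depth = 300)
  s1 <- db1[db1$sample_id == "CMT-001" & db1$chrom == "chr1" &
              db1$start >= 1e4 & db1$end <= 2e4, ]
  ratio <- s1$t_depth / s1$n_depth
  se <- sd(ratio) / sqrt(nrow(s1))
  expect_lt(abs(mean(ratio) - 2), 3 * se)
  # purity 0.5 dilutes the ratio to 1.5
  sp_half <- cohort_spec(n_samples = 2, benign_fraction = 0,
                         purity_range = c(0.5, 0.5), seed = 5)
  db2 <- simulate_depth_bins(sp_half, g1, mean_depth = 300)
  s2 <- db2[db2$sample_id == "CMT-002" & db2$chrom == "chr1" &
              db2$start >= 1e4 & db2$end <= 2e4, ]
  ratio2 <- s2$t_depth / s2$n_depth
  expect_lt(abs(mean(ratio2) - 1.5), 3 * sd(ratio2) / sqrt(nrow(s2)))
  expect_error(genome_spec(c(chr1 = 1e4), bin_size = 0), "positive")
})

test_that("malignant genomes carry more copy-number alteration than benign", {
  planted <- tibble::tibble(chrom = "chr1", start = c(5e3, 3e4),
                            end = c(1.5e4, 4e4), true_log2 = c(1, -1))
  g <- genome_spec(c(chr1 = 5e4, chr2 = 2e4), bin_size = 1000,
                   planted_segments = planted)
  sp <- cohort_spec(n_samples = 6, benign_fraction = 0.5, seed = 13)
  db <- simulate_depth_bins(sp, g)
  gfa <- db |>
    dplyr::group_by(sample_id) |>
    dplyr::group_map(function(bins, key) {
      segs <- cbs_segment(gc_correct_ratio(bins), nperm = 200, seed = 1)
      tibble::tibble(sample_id = key$sample_id,
                     gfa = genome_fraction_altered(segs))
    }) |>
    purrr::list_rbind() |>
    dplyr::left_join(sp |> (\(s) tibble::tibble(
      sample_id = sprintf("CMT-%03d", 1:s$n_samples),
      histology = rep(c("benign", "malignant"), each = 3)))(),
      by = "sample_id")
  expect_gt(mean(gfa$gfa[gfa$histology == "malignant"]),
            mean(gfa$gfa[gfa$histology == "benign"]))
})

test_that("expression generator: noiseless patterns, hazards, determinism", {
  es <- expression_spec(n_samples = 12, n_genes = 30, k_true = 3,
                        noise_sd = 0, seed = 2)
  ec <- simulate_expression_cohort(es)
  # exactly 3 distinct column patterns up to scaling
  pats <- apply(ec$expression, 2, function(col) {
    paste(round(col / max(col), 6), collapse = ",")
  })
  expect_equal(length(unique(pats)), 3)
  ec2 <- simulate_expression_cohort(es)
  expect_identical(ec$expression, ec2$expression)
  expect_identical(ec$survival, ec2$survival)
  expect_error(expression_spec(n_samples = 2, k_true = 5), "exceed")
  # planted hazard difference yields frequent log-rank detection
  detected <- 0
  for (s in 1:25) {
    ecs <- simulate_expression_cohort(expression_spec(
      n_samples = 150, n_genes = 30, k_true = 3,
      hazards = c(0.1, 0.1, 0.5), seed = s))
    p <- logrank_test(tibble::tibble(
      time = ecs$survival$time, event = ecs$survival$event,
      group = ecs$labels$cluster))$p
    if (p < 0.05) detected <- detected + 1
  }
  expect_gte(detected, 20)
})

test_that("null hazards give calibrated log-rank p-values over seeds", {
  ps <- vapply(1:60, function(s) {
    ec <- simulate_expression_cohort(expression_spec(
      n_samples = 60, n_genes = 12, k_true = 3, hazards = rep(0.2, 3),
      seed = 4000 + s))
    logrank_test(tibble::tibble(
      time = ec$survival$time, event = ec$survival$event,
      group = ec$labels$cluster))$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("variant VCF round-trips through the minimal v4.2 subset", {
  g <- toy_genome(chr1 = 2e4, chr2 = 1e4)
  sp <- cohort_spec(n_samples = 3, tmb_rate = 15, seed = 29)
  cm <- simulate_mutation_cohort(sp, g)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(cm$variants, path)
  back <- read_variant_vcf(path)
  expect_equal(back$chrom, cm$variants$chrom)
  expect_equal(back$pos, as.integer(cm$variants$pos))
  expect_equal(back$ref, cm$variants$ref)
  expect_equal(back$alt, cm$variants$alt)
  expect_equal(back$sample_id, cm$variants$sample_id)
  expect_equal(back$gene, cm$variants$gene)
  expect_equal(back$vaf, cm$variants$vaf, tolerance = 1e-5)
})

test_that("toy chains round-trip and keep gap/strand semantics", {
  tc <- simulate_toy_chain("chr1", 300, "h1", 400, tibble::tibble(
    t_start = c(0, 110), t_end = c(100, 210), q_start = c(0, 100),
    strand = "+"))
  # source bases 100-109 have no image in the per-base map
  expect_length(intersect(tc$map$src_pos, 100:109), 0)
  expect_setequal(tc$map$src_pos, c(0:99, 110:209))
  # round trip through text reproduces the block model
  pc <- parse_chain(tc$text)
  expect_equal(pc$header, tc$chains$header)
  expect_equal(pc$blocks, tc$chains$blocks)
  # identity chain: identity map
  id <- simulate_toy_chain("c", 50, "h", 50, tibble::tibble(
    t_start = 0, t_end = 50, q_start = 0, strand = "+"))
  expect_equal(id$map$tgt_pos, id$map$src_pos)
})
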