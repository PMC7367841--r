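# Chain parsing, interval projection and cross-species profile transfer.

two_block_chain <- function() {
  simulate_toy_chain("chr1", 300, "hchr1", 400, tibble::tibble(
    t_start = c(0, 110), t_end = c(100, 210), q_start = c(0, 100),
    strand = "+"))
}

test_that("chain text parses, validates invariants, and round-trips", {
  tc <- two_block_chain()
  pc <- parse_chain(tc$text)
  expect_equal(nrow(pc$header), 1)
  expect_equal(pc$blocks$size, c(100, 100))
  expect_equal(pc$blocks$dt[1], 10)
  expect_equal(pc$blocks$dq[1], 0)
  # round trip: emitted model == parsed model
  expect_equal(parse_chain(write_chain(pc))$header, pc$header)
  expect_equal(parse_chain(write_chain(pc))$blocks, pc$blocks)
  # identity chain has one whole-chromosome block
  id <- simulate_toy_chain("chr1", 500, "h1", 500, tibble::tibble(
    t_start = 0, t_end = 500, q_start = 0, strand = "+"))
  pid <- parse_chain(id$text)
  expect_equal(pid$blocks$size, 500)
  # arithmetic mismatch rejected with the chain id
  bad <- sub("chain 1000 chr1 300 \\+ 0 210",
             "chain 1000 chr1 300 + 0 211", tc$text)
  expect_error(parse_chain(bad), "do not match")
  expect_error(
    parse_chain("chain 1 t 100 - 0 50 q 100 + 0 50 1\n50\n"), "tStrand")
})

test_that("interval projection maps through blocks with gap accounting", {
  pc <- parse_chain(two_block_chain()$text)
  # wholly inside the first block
  r1 <- project_interval(pc, "chr1", 10, 50)
  expect_equal(r1$mapped, tibble::tibble(chrom = "hchr1", start = 10, end = 50))
  expect_equal(r1$unmapped_bp, 0)
  # inside the second block: offset by the source gap
  r2 <- project_interval(pc, "chr1", 120, 180)
  expect_equal(r2$mapped, tibble::tibble(chrom = "hchr1", start = 110,
                                         end = 170))
  expect_equal(r2$unmapped_bp, 0)
  # straddling the gap: split with 10 bp unmapped (source 100-110)
  r3 <- project_interval(pc, "chr1", 95, 115)
  expect_equal(r3$unmapped_bp, 10)
  expect_equal(r3$mapped, tibble::tibble(chrom = "hchr1", start = 95,
                                         end = 105))
  # source bases 100-109 have no image at all
  r4 <- project_interval(pc, "chr1", 100, 110)
  expect_equal(nrow(r4$mapped), 0)
  expect_equal(r4$unmapped_bp, 10)
  # absent chromosome: wholly unmapped, not an error
  r5 <- project_interval(pc, "chrX", 0, 50)
  expect_equal(r5$unmapped_bp, 50)
})

test_that("strand-flip chains reflect coordinates per the chain spec", {
  tc <- simulate_toy_chain("chr1", 200, "h1", 300, tibble::tibble(
    t_start = 50, t_end = 150, q_start = 120, strand = "-"))
  pc <- parse_chain(tc$text)
  expect_equal(pc$header$q_strand, "-")
  # oracle map satisfies tgt = q_end - 1 - offset
  expect_equal(tc$map$tgt_pos, 120 + 100 - 1 - (tc$map$src_pos - 50))
  # projection agrees base-for-base with the oracle map
  r <- project_interval(pc, "chr1", 60, 70)
  orc <- project_via_map(tc$map, 60, 70)
  expect_equal(r$unmapped_bp, orc$unmapped_bp)
  got <- unlist(purrr::map2(r$mapped$start, r$mapped$end, seq_range))
  expect_setequal(got, orc$mapped_positions)
})

test_that("projection agrees with the per-base oracle map on varied chains", {
  # mixed strands, gaps on both sides, several chains
  tc <- simulate_toy_chain("chr1", 1000, "h1", 1200, tibble::tibble(
    t_start = c(0, 150, 400, 700),
    t_end = c(100, 300, 600, 800),
    q_start = c(50, 200, 900, 500),
    strand = c("+", "+", "-", "+")))
  pc <- parse_chain(tc$text)
  set.seed(77)
  for (i in 1:25) {
    s <- sample(0:950, 1); e <- s + sample(1:50, 1)
    r <- project_interval(pc, "chr1", s, e)
    orc <- project_via_map(tc$map, s, e)
    expect_equal(r$unmapped_bp, orc$unmapped_bp)
    got <- sort(as.numeric(unlist(
      purrr::map2(r$mapped$start, r$mapped$end, seq_range))))
    expect_equal(got, sort(as.numeric(orc$mapped_positions)))
    # mapped mass conservation
    expect_equal(sum(r$mapped$end - r$mapped$start),
                 (e - s) - r$unmapped_bp)
  }
})

test_that("projection matches rtracklayer liftOver on a plus-strand chain", {
  tc <- two_block_chain()
  path <- withr::local_tempfile(fileext = ".chain")
  writeLines(tc$text, path)
  ch <- rtracklayer::import.chain(path)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(121, 180)) # 1-based
  lifted <- unlist(rtracklayer::liftOver(gr, ch))
  r <- project_interval(parse_chain(tc$text), "chr1", 120, 180)
  expect_equal(r$mapped$start, GenomicRanges::start(lifted) - 1)
  expect_equal(r$mapped$end, GenomicRanges::end(lifted))
})

test_that("overlapping toy-chain blocks are rejected", {
  expect_error(simulate_toy_chain("c", 100, "h", 100, tibble::tibble(
    t_start = c(0, 40), t_end = c(50, 90), q_start = c(0, 50),
    strand = "+")), "overlap")
  expect_error(simulate_toy_chain("c", 100, "h", 100, tibble::tibble(
    t_start = c(0, 60), t_end = c(50, 90), q_start = c(10, 0),
    strand = "+")), "overlap")
})

test_that("profile projection: identity, weighted bins, rearrangement", {
  id <- simulate_toy_chain("chr1", 1e4, "h1", 1e4, tibble::tibble(
    t_start = 0, t_end = 1e4, q_start = 0, strand = "+"))
  pc <- parse_chain(id$text)
  segs <- tibble::tibble(sample_id = "s1", chrom = "chr1",
                         start = c(0, 5e3), end = c(5e3, 1e4),
                         seg_mean = c(1, 0))
  res <- project_scna_profile(segs, pc, bin_size = 1e3, smooth_window = 1,
                              nperm = 200, seed = 2)
  # identity projection: binned values equal the source profile rebinned
  expect_equal(res$binned$value, rep(c(1, 0), each = 5))
  expect_equal(res$binned$coverage, rep(1e3, 10))
  # two segments each covering half a target bin -> 0.5
  segs2 <- tibble::tibble(sample_id = "s1", chrom = "chr1",
                          start = c(0, 500), end = c(500, 1e3),
                          seg_mean = c(1, 0))
  res2 <- project_scna_profile(segs2, pc, bin_size = 1e3, smooth_window = 1,
                               nperm = 50, seed = 2)
  expect_equal(res2$binned$value[1], 0.5)
  # rearrangement: one source segment split across two target regions
  re <- simulate_toy_chain("chr1", 1000, "h1", 3000, tibble::tibble(
    t_start = c(0, 500), t_end = c(500, 1000), q_start = c(0, 2500),
    strand = "+"))
  segs3 <- tibble::tibble(sample_id = "s1", chrom = "chr1", start = 0,
                          end = 1000, seg_mean = 0.7)
  res3 <- project_scna_profile(segs3, parse_chain(re$text), bin_size = 500,
                               smooth_window = 1, nperm = 50, seed = 1)
  covered <- res3$binned[res3$binned$coverage > 0, ]
  expect_equal(sort(covered$start), c(0, 2500))
  expect_true(all(covered$value == 0.7))
})

test_that("cross-cohort correlation: self-correlation 1, planted concordance", {
  grid_vals <- function(seed, planted = 0) {
    withr::with_seed(seed, tibble::tibble(
      sample_id = "s", chrom = "h1", start = 0:199 * 1e3,
      end = 1:200 * 1e3,
      value = rnorm(200, 0, 0.1) + c(rep(0, 90), rep(planted, 20),
                                     rep(0, 90))))
  }
  a <- grid_vals(1, planted = 1)
  res_self <- cross_cohort_correlation(a, a)
  expect_equal(res_self$r, c(1, 1), tolerance = 1e-12)
  # shared planted amplification, independent noise: amp r >> del r
  b <- grid_vals(2, planted = 1)
  res <- cross_cohort_correlation(a, b)
  expect_gt(res$r[res$part == "amplification"], 0.5)
  expect_gt(res$r[res$part == "amplification"],
            res$r[res$part == "deletion"] + 0.3)
  expect_error(cross_cohort_correlation(a[1:2, ], a[1:2, ]), "3 shared")
})

test_that("independent random profiles are uncorrelated", {
  fails <- 0
  for (s in 1:20) {
    a <- withr::with_seed(s, tibble::tibble(
      sample_id = "s", chrom = "h1", start = 0:1999 * 1e3, end = 1:2000 * 1e3,
      value = rnorm(2000, 0, 0.3)))
    b <- withr::with_seed(1000 + s, dplyr::mutate(a, value = rnorm(2000, 0, 0.3)))
    r <- cross_cohort_correlation(a, b)$r
    if (any(abs(r) >= 0.1)) fails <- fails + 1
  }
  expect_lte(fails, 2)
})
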