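# Copy-number analysis from binned read depth: GC-corrected log2 ratio
# profiles, circular binary segmentation (permutation-tested recursive
# splits), altered-genome fraction, and simplified recurrence (G-score)
# peaks with a cyclic-shift null.

#' GC-corrected log2 depth-ratio profile
#'
#' Computes per-bin tumor/normal depth ratios, normalizes by the profile
#' median, removes residual GC bias by dividing each bin's ratio by the
#' median ratio of its GC decile, and takes log2. Bins with zero tumor or
#' normal depth are masked (dropped).
#'
#' @param depth_bins Tibble with `chrom`, `start`, `end` (0-based
#'   half-open), `gc`, `t_depth`, `n_depth` for one sample (a `sample_id`
#'   column is carried through if present).
#' @param n_bands Number of GC bands for the correction (default 10
#'   deciles).
#' @return Tibble (`Log2Profile`): input bins with `log2_ratio` added,
#'   masked bins removed, sorted by chromosome and start.
#' @export
gc_correct_ratio <- function(depth_bins, n_bands = 10) {
  assert_cols(depth_bins, c("chrom", "start", "end", "gc", "t_depth",
                            "n_depth"), "depth_bins")
  if (all(depth_bins$n_depth == 0)) abort("all normal depths are zero")
  prof <- depth_bins |>
    filter(.data$n_depth > 0, .data$t_depth > 0) |>
    mutate(ratio = .data$t_depth / .data$n_depth)
  prof <- mutate(prof, ratio = .data$ratio / median(.data$ratio))
  bands <- dplyr::ntile(prof$gc, n_bands)
  band_med <- tapply(prof$ratio, bands, median)
  prof |>
    mutate(log2_ratio = log2(.data$ratio / unname(band_med[bands]))) |>
    select(-"ratio") |>
    arrange(.data$chrom, .data$start)
}

cbs_segment_chrom <- function(x, alpha, nperm, min_width) {
  n <- length(x)
  segment_rec <- function(lo, hi) { # half-open bin index range [lo, hi)
    len <- hi - lo
    if (len < 2 * min_width) return(c(lo, hi))
    scan <- .cbs_scan(x[(lo + 1):hi], min_width, nperm,
                      sample.int(.Machine$integer.max, 1))
    if (scan$i < 0 || scan$p > alpha) return(c(lo, hi))
    cuts <- sort(unique(c(lo, lo + scan$i, lo + scan$j, hi)))
    bounds <- lo
    for (k in seq_len(length(cuts) - 1)) {
      sub <- segment_rec(cuts[k], cuts[k + 1])
      bounds <- c(bounds, sub[-1])
    }
    sort(unique(bounds))
  }
  segment_rec(0, n)
}

#' Circular binary segmentation of a log2 profile
#'
#' Recursively splits each chromosome at the circular arc maximizing the
#' two-sample t statistic; a split is accepted only if its within-segment
#' permutation p-value is at most `alpha`. Segments never cross chromosome
#' boundaries and tile the binned genome. The "undo splits" refinement of
#' the reference implementation is deliberately omitted. Deterministic
#' given `seed`.
#'
#' @param profile Log2 profile tibble (`chrom`, `start`, `end`,
#'   `log2_ratio`), e.g. from [gc_correct_ratio()].
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param nperm Permutations per tested split (default 1000).
#' @param min_width Minimum segment width in bins (default 3).
#' @param seed Integer RNG seed.
#' @return Segment tibble: `chrom`, `start`, `end` (bp, 0-based half-open),
#'   `n_bins`, `seg_mean` (mean log2 ratio of member bins).
#' @export
cbs_segment <- function(profile, alpha = 0.01, nperm = 1000, min_width = 3,
                        seed = 1) {
  assert_cols(profile, c("chrom", "start", "end", "log2_ratio"), "profile")
  if (nrow(profile) == 0) abort("empty profile")
  profile <- arrange(profile, .data$chrom, .data$start)
  withr::with_seed(seed, {
    segs <- profile |>
      group_by(.data$chrom) |>
      group_map(function(bins, key) {
        bounds <- cbs_segment_chrom(bins$log2_ratio, alpha, nperm, min_width)
        map2(bounds[-length(bounds)], bounds[-1], function(a, b) {
          tibble(chrom = key$chrom,
                 start = bins$start[a + 1],
                 end = bins$end[b],
                 n_bins = b - a,
                 seg_mean = mean(bins$log2_ratio[(a + 1):b]))
        }) |> list_rbind()
      }) |>
      list_rbind()
  })
  arrange(segs, .data$chrom, .data$start)
}

#' Fraction of the genome with copy-number imbalance
#'
#' Length-weighted fraction of the segmented genome whose absolute segment
#' mean strictly exceeds `threshold`.
#'
#' @param segments Segment tibble from [cbs_segment()].
#' @param threshold Absolute log2-ratio cutoff (default 0.2, strict `>`).
#' @return Proportion in \[0, 1\].
#' @export
genome_fraction_altered <- function(segments, threshold = 0.2) {
  assert_cols(segments, c("chrom", "start", "end", "seg_mean"), "segments")
  len <- segments$end - segments$start
  sum(len[abs(segments$seg_mean) > threshold]) / sum(len)
}

segments_to_bins <- function(segments, bins) {
  # mean seg value per bin (bins fully inside one segment by construction)
  idx <- rep(NA_integer_, nrow(bins))
  for (k in seq_len(nrow(segments))) {
    sel <- bins$chrom == segments$chrom[k] &
      bins$start >= segments$start[k] & bins$end <= segments$end[k]
    idx[sel] <- k
  }
  segments$seg_mean[idx]
}

#' Recurrent amplification / deletion peaks (simplified G-score)
#'
#' For each bin, the amplification G-score sums `max(seg_mean - amp_thr, 0)`
#' over samples (mirrored below `del_thr` for deletions): frequency times
#' amplitude of alteration across the cohort. The null distribution pools
#' per-bin G-scores from random cyclic shifts of each sample's bin-level
#' profile (which preserves within-sample segment structure); per-bin
#' empirical p-values are BH-corrected and peaks are maximal runs of bins
#' with `q <= q_cutoff`.
#'
#' @param segment_sets Tibble of per-sample segments (`sample_id`, `chrom`,
#'   `start`, `end`, `seg_mean`) on a shared bin grid.
#' @param bins Tibble of the shared bin grid (`chrom`, `start`, `end`).
#' @param amp_thr,del_thr Amplitude thresholds (default +0.2 / -0.2).
#' @param nperm Cyclic-shift permutations (default 1000).
#' @param q_cutoff FDR cutoff defining peaks (default 0.25).
#' @param seed Integer RNG seed.
#' @return Tibble of peaks: `kind` ("amplification"/"deletion"), `chrom`,
#'   `start`, `end`, `g_score` (max over member bins), `q` (min over member
#'   bins).
#' @export
recurrence_peaks <- function(segment_sets, bins, amp_thr = 0.2,
                             del_thr = -0.2, nperm = 1000, q_cutoff = 0.25,
                             seed = 1) {
  assert_cols(segment_sets, c("sample_id", "chrom", "start", "end",
                              "seg_mean"), "segment_sets")
  assert_cols(bins, c("chrom", "start", "end"), "bins")
  samples <- unique(segment_sets$sample_id)
  if (length(samples) < 2) abort("recurrence analysis needs >= 2 samples")
  bins <- arrange(bins, .data$chrom, .data$start)
  n_bins <- nrow(bins)
  vals <- vapply(samples, function(s) {
    v <- segments_to_bins(filter(segment_sets, .data$sample_id == s), bins)
    if (anyNA(v)) abort("sample segments do not cover the shared bin grid")
    v
  }, numeric(n_bins))
  excess <- function(m) {
    list(amp = pmax(m - amp_thr, 0), del = pmax(del_thr - m, 0))
  }
  obs <- excess(vals)
  g_amp <- rowSums(obs$amp); g_del <- rowSums(obs$del)
  withr::with_seed(seed, {
    null_amp <- numeric(0); null_del <- numeric(0)
    for (p in seq_len(nperm)) {
      shifts <- sample.int(n_bins, length(samples), replace = TRUE)
      shifted <- vapply(seq_along(samples), function(k) {
        v <- vals[, k]
        s <- shifts[k] %% n_bins
        if (s == 0) v else c(v[(s + 1):n_bins], v[seq_len(s)])
      }, numeric(n_bins))
      e <- excess(shifted)
      null_amp <- c(null_amp, rowSums(e$amp))
      null_del <- c(null_del, rowSums(e$del))
    }
  })
  emp_p <- function(g, null) {
    vapply(g, function(v) (1 + sum(null >= v)) / (1 + length(null)),
           numeric(1))
  }
  peak_runs <- function(g, q, kind) {
    sig <- q <= q_cutoff & g > 0
    if (!any(sig)) return(NULL)
    runs <- rle(paste(bins$chrom, sig))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- which(sig[starts])
    map(keep, function(k) {
      i <- starts[k]:ends[k]
      tibble(kind = kind, chrom = bins$chrom[i[1]],
             start = bins$start[i[1]], end = bins$end[i[length(i)]],
             g_score = max(g[i]), q = min(q[i]))
    }) |> list_rbind()
  }
  q_amp <- bh_fdr(emp_p(g_amp, null_amp))
  q_del <- bh_fdr(emp_p(g_del, null_del))
  out <- bind_rows(peak_runs(g_amp, q_amp, "amplification"),
                   peak_runs(g_del, q_del, "deletion"))
  if (is.null(out)) {
    out <- tibble(kind = character(), chrom = character(), start = numeric(),
                  end = numeric(), g_score = numeric(), q = numeric())
  }
  out
}

#' Write / read segments in SEG format
#'
#' SEG files are 1-based inclusive on disk; coordinates are converted at
#' the boundary (internal representation is 0-based half-open).
#'
#' @param segments Tibble with `sample_id`, `chrom`, `start`, `end`,
#'   `n_bins`, `seg_mean`.
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  assert_cols(segments, c("sample_id", "chrom", "start", "end", "n_bins",
                          "seg_mean"), "segments")
  out <- tibble(
    ID = segments$sample_id, chrom = segments$chrom,
    loc.start = segments$start + 1, loc.end = segments$end,
    num.mark = segments$n_bins, seg.mean = segments$seg_mean
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  tibble(sample_id = df$ID, chrom = as.character(df$chrom),
         start = df$loc.start - 1, end = df$loc.end,
         n_bins = df$num.mark, seg_mean = df$seg.mean)
}

#' Plot a log2 profile with its segmentation
#'
#' @param profile Log2 profile tibble.
#' @param segments Optional segment tibble overlaid as horizontal bars.
#' @return A ggplot faceted by chromosome.
#' @export
plot_profile <- function(profile, segments = NULL) {
  p <- ggplot(profile, aes(x = (.data$start + .data$end) / 2,
                           y = .data$log2_ratio)) +
    geom_point(size = 0.3, alpha = 0.5) +
    geom_hline(yintercept = 0, linetype = 2) +
    facet_grid(cols = vars(.data$chrom), scales = "free_x",
               space = "free_x") +
    labs(x = "position (bp)", y = "log2 ratio") +
    theme_minimal()
  if (!is.null(segments)) {
    p <- p + geom_segment(
      data = segments,
      aes(x = .data$start, xend = .data$end,
          y = .data$seg_mean, yend = .data$seg_mean),
      color = "red", linewidth = 1, inherit.aes = FALSE
    )
  }
  p
}
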