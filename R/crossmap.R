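# UCSC chain parsing and validation, interval projection between genome
# assemblies, coverage-weighted projection of copy-number profiles onto a
# target genome with re-segmentation, and cross-cohort correlation of
# projected profiles.
#
# Conventions follow the UCSC chain format: the "t" (target) side of the
# chain is the assembly intervals are projected FROM and the "q" (query)
# side the assembly they are projected TO (as in *To*.over.chain files);
# tStrand is always '+'; negative-strand q coordinates are expressed on the
# reversed sequence. All coordinates are 0-based half-open.

#' Parse UCSC chain text
#'
#' Reads chain alignments and verifies the format invariants: block sizes
#' and gaps must sum to the stated target and query spans, gaps are
#' non-negative, and tStrand is '+'. Violations raise an error naming the
#' chain id and line number.
#'
#' @param x Path to a chain file (plain or gzip) or a character vector of
#'   chain lines.
#' @return Object of class `chain_set`: list with `header` (one row per
#'   chain: score, t/q name, size, strand, start, end, chain_id) and
#'   `blocks` (chain_id, size, dt, dq; dt/dq are NA on each chain's last
#'   block).
#' @export
parse_chain <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readr::read_lines(x)
  } else {
    unlist(str_split(x, "\n"))
  }
  lines_trim <- trimws(lines)
  header_idx <- which(str_detect(lines_trim, "^chain\\b"))
  if (length(header_idx) == 0) abort("no chain records found")
  headers <- list(); blocks <- list()
  for (h in seq_along(header_idx)) {
    i <- header_idx[h]
    fields <- strsplit(lines_trim[i], "\\s+")[[1]]
    if (length(fields) != 13) {
      abort(sprintf("malformed chain header at line %d", i))
    }
    hd <- tibble(
      score = as.numeric(fields[2]),
      t_name = fields[3], t_size = as.numeric(fields[4]),
      t_strand = fields[5], t_start = as.numeric(fields[6]),
      t_end = as.numeric(fields[7]),
      q_name = fields[8], q_size = as.numeric(fields[9]),
      q_strand = fields[10], q_start = as.numeric(fields[11]),
      q_end = as.numeric(fields[12]),
      chain_id = fields[13]
    )
    if (hd$t_strand != "+") {
      abort(sprintf("chain %s (line %d): tStrand must be '+'", hd$chain_id, i))
    }
    lim <- if (h < length(header_idx)) header_idx[h + 1] - 1 else length(lines_trim)
    body <- lines_trim[(i + 1):lim]
    body <- body[body != ""]
    parts <- str_split(body, "\\s+")
    sizes <- as.numeric(map_chr(parts, 1))
    dt <- as.numeric(map_chr(parts, function(p) if (length(p) >= 2) p[2] else NA))
    dq <- as.numeric(map_chr(parts, function(p) if (length(p) >= 3) p[3] else NA))
    nb <- length(sizes)
    if (nb == 0 || any(is.na(sizes)) ||
        any(is.na(dt[-nb])) || any(is.na(dq[-nb]))) {
      abort(sprintf("chain %s (line %d): malformed block list", hd$chain_id, i))
    }
    if (any(sizes <= 0) || any(dt[-nb] < 0) || any(dq[-nb] < 0)) {
      abort(sprintf("chain %s: block sizes must be > 0 and gaps >= 0",
                    hd$chain_id))
    }
    t_span <- sum(sizes) + sum(dt[-nb])
    q_span <- sum(sizes) + sum(dq[-nb])
    if (t_span != hd$t_end - hd$t_start || q_span != hd$q_end - hd$q_start) {
      abort(sprintf(
        "chain %s (line %d): blocks+gaps (%g t / %g q) do not match spans (%g / %g)",
        hd$chain_id, i, t_span, q_span,
        hd$t_end - hd$t_start, hd$q_end - hd$q_start))
    }
    headers[[h]] <- hd
    blocks[[h]] <- tibble(chain_id = hd$chain_id, size = sizes,
                          dt = dt, dq = dq)
  }
  structure(list(header = list_rbind(headers), blocks = list_rbind(blocks)),
            class = "chain_set")
}

#' @rdname parse_chain
#' @param chains A `chain_set`.
#' @param path Optional output path; when NULL the chain text is returned.
#' @export
write_chain <- function(chains, path = NULL) {
  stopifnot(inherits(chains, "chain_set"))
  out <- character(0)
  for (k in seq_len(nrow(chains$header))) {
    hd <- chains$header[k, ]
    bl <- filter(chains$blocks, .data$chain_id == hd$chain_id)
    out <- c(out, sprintf("chain %g %s %g %s %g %g %s %g %s %g %g %s",
                          hd$score, hd$t_name, hd$t_size, hd$t_strand,
                          hd$t_start, hd$t_end, hd$q_name, hd$q_size,
                          hd$q_strand, hd$q_start, hd$q_end, hd$chain_id))
    nb <- nrow(bl)
    body <- vapply(seq_len(nb), function(j) {
      if (j < nb) sprintf("%g %g %g", bl$size[j], bl$dt[j], bl$dq[j])
      else sprintf("%g", bl$size[j])
    }, character(1))
    out <- c(out, body, "")
  }
  if (is.null(path)) return(paste(out, collapse = "\n"))
  readr::write_lines(out, path)
  invisible(path)
}

# absolute block coordinates; q interval always on the + strand of q
chain_blocks_abs <- function(chains) {
  map(seq_len(nrow(chains$header)), function(k) {
    hd <- chains$header[k, ]
    bl <- filter(chains$blocks, .data$chain_id == hd$chain_id)
    t_starts <- hd$t_start + cumsum(c(0, head(bl$size + coalesce(bl$dt, 0), -1)))
    q_starts <- hd$q_start + cumsum(c(0, head(bl$size + coalesce(bl$dq, 0), -1)))
    q_plus_start <- if (hd$q_strand == "+") {
      q_starts
    } else {
      hd$q_size - (q_starts + bl$size)
    }
    tibble(chain_id = hd$chain_id, score = hd$score,
           t_name = hd$t_name,
           t_start = t_starts, t_end = t_starts + bl$size,
           q_name = hd$q_name, q_strand = hd$q_strand, q_size = hd$q_size,
           q_plus_start = q_plus_start, q_plus_end = q_plus_start + bl$size)
  }) |> list_rbind()
}

# map the sub-interval [s, e) of an aligned block to + strand q coordinates
map_block_piece <- function(block, s, e) {
  off_s <- s - block$t_start
  off_e <- e - block$t_start
  if (block$q_strand == "+") {
    tibble(tgt_start = block$q_plus_start + off_s,
           tgt_end = block$q_plus_start + off_e)
  } else {
    tibble(tgt_start = block$q_plus_end - off_e,
           tgt_end = block$q_plus_end - off_s)
  }
}

project_pieces <- function(chains, chrom, start, end) {
  abs_blocks <- chain_blocks_abs(chains) |>
    filter(.data$t_name == chrom) |>
    arrange(desc(.data$score))
  uncovered <- tibble(start = start, end = end)
  pieces <- list()
  for (cid in unique(abs_blocks$chain_id)) {
    if (nrow(uncovered) == 0) break
    cb <- filter(abs_blocks, .data$chain_id == cid)
    for (b in seq_len(nrow(cb))) {
      block <- cb[b, ]
      new_unc <- list()
      for (u in seq_len(nrow(uncovered))) {
        s <- max(uncovered$start[u], block$t_start)
        e <- min(uncovered$end[u], block$t_end)
        if (s < e) {
          m <- map_block_piece(block, s, e)
          pieces[[length(pieces) + 1]] <- tibble(
            src_start = s, src_end = e,
            tgt_chrom = block$q_name, tgt_start = m$tgt_start,
            tgt_end = m$tgt_end, strand = block$q_strand
          )
          if (uncovered$start[u] < s) {
            new_unc[[length(new_unc) + 1]] <-
              tibble(start = uncovered$start[u], end = s)
          }
          if (e < uncovered$end[u]) {
            new_unc[[length(new_unc) + 1]] <-
              tibble(start = e, end = uncovered$end[u])
          }
        } else {
          new_unc[[length(new_unc) + 1]] <- uncovered[u, ]
        }
      }
      uncovered <- if (length(new_unc)) list_rbind(new_unc) else
        tibble(start = numeric(), end = numeric())
    }
  }
  list(
    pieces = if (length(pieces)) {
      arrange(list_rbind(pieces), .data$src_start)
    } else {
      tibble(src_start = numeric(), src_end = numeric(),
             tgt_chrom = character(), tgt_start = numeric(),
             tgt_end = numeric(), strand = character())
    },
    unmapped_bp = sum(uncovered$end - uncovered$start)
  )
}

#' Project an interval onto the other assembly through chain alignments
#'
#' Maps the bases of a source (chain "t" side) interval through aligned
#' blocks only; bases falling in gaps are reported as unmapped. When
#' several chains cover a base, the highest-scoring chain wins.
#' Negative-strand query chains are handled by coordinate reflection onto
#' the forward strand. Adjacent output intervals are merged.
#'
#' @param chains A `chain_set` from [parse_chain()].
#' @param chrom,start,end Source interval (0-based half-open). A chromosome
#'   absent from the chains yields a wholly unmapped result, not an error.
#' @return List: `mapped` tibble (`chrom`, `start`, `end` on the target
#'   assembly, merged and sorted) and `unmapped_bp`.
#' @export
project_interval <- function(chains, chrom, start, end) {
  if (start < 0 || end <= start) abort("need 0 <= start < end")
  pr <- project_pieces(chains, chrom, start, end)
  mapped <- pr$pieces |>
    select(chrom = "tgt_chrom", start = "tgt_start", end = "tgt_end") |>
    arrange(.data$chrom, .data$start)
  # merge adjacent/overlapping target intervals
  if (nrow(mapped) > 1) {
    merged <- mapped[1, ]
    for (k in 2:nrow(mapped)) {
      last <- nrow(merged)
      if (mapped$chrom[k] == merged$chrom[last] &&
          mapped$start[k] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], mapped$end[k])
      } else {
        merged <- bind_rows(merged, mapped[k, ])
      }
    }
    mapped <- merged
  }
  list(mapped = mapped, unmapped_bp = pr$unmapped_bp)
}

#' Project per-sample copy-number segments onto a target assembly
#'
#' Each source segment is pushed through the chains; every target bin
#' receives the coverage-weighted mean log2 ratio of the projected pieces
#' overlapping it (`sum(log2 * bp) / sum(bp)`). Bins with no mapped
#' coverage carry NA. Profiles are then smoothed with a centered moving
#' median and re-segmented with [cbs_segment()].
#'
#' @param segments Per-sample segment tibble (`sample_id`, `chrom`,
#'   `start`, `end`, `seg_mean`) on the source assembly.
#' @param chains A `chain_set`.
#' @param bin_size Target bin width in bp (default 1e6).
#' @param smooth_window Centered moving-median window in bins (odd,
#'   default 5).
#' @param ... Passed to [cbs_segment()] for re-segmentation.
#' @return List: `binned` tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `value`, `coverage`) and `segments`, the re-segmented projected
#'   profiles.
#' @export
project_scna_profile <- function(segments, chains, bin_size = 1e6,
                                 smooth_window = 5, ...) {
  assert_cols(segments, c("sample_id", "chrom", "start", "end", "seg_mean"),
              "segments")
  if (bin_size <= 0) abort("`bin_size` must be positive")
  q_sizes <- distinct(chains$header, .data$q_name, .data$q_size)
  grid <- q_sizes |>
    group_by(.data$q_name) |>
    reframe(start = seq(0, max(.data$q_size) - 1, by = bin_size)) |>
    mutate(end = pmin(.data$start + bin_size,
                      q_sizes$q_size[match(.data$q_name, q_sizes$q_name)])) |>
    rename(chrom = "q_name") |>
    arrange(.data$chrom, .data$start)
  binned <- segments |>
    group_by(.data$sample_id) |>
    group_map(function(seg, key) {
      w <- numeric(nrow(grid)); wv <- numeric(nrow(grid))
      for (k in seq_len(nrow(seg))) {
        pr <- project_pieces(chains, seg$chrom[k], seg$start[k], seg$end[k])
        pieces <- pr$pieces
        for (j in seq_len(nrow(pieces))) {
          sel <- which(grid$chrom == pieces$tgt_chrom[j] &
                         grid$end > pieces$tgt_start[j] &
                         grid$start < pieces$tgt_end[j])
          if (length(sel) == 0) next
          ov <- pmin(grid$end[sel], pieces$tgt_end[j]) -
            pmax(grid$start[sel], pieces$tgt_start[j])
          w[sel] <- w[sel] + ov
          wv[sel] <- wv[sel] + ov * seg$seg_mean[k]
        }
      }
      value <- ifelse(w > 0, wv / pmax(w, 1e-300), NA_real_)
      tibble(sample_id = key$sample_id, grid, value = value, coverage = w)
    }) |>
    list_rbind()
  if (all(is.na(binned$value))) {
    warn("no chain overlap: all-missing projected profile")
    return(list(binned = binned, segments = NULL))
  }
  reseg <- binned |>
    filter(!is.na(.data$value)) |>
    group_by(.data$sample_id) |>
    group_map(function(prof, key) {
      prof <- prof |>
        group_by(.data$chrom) |>
        mutate(value = smooth_median(.data$value, smooth_window)) |>
        ungroup() |>
        rename(log2_ratio = "value")
      cbs_segment(prof, ...) |>
        mutate(sample_id = key$sample_id, .before = 1)
    }) |>
    list_rbind()
  list(binned = binned, segments = reseg)
}

smooth_median <- function(x, window) {
  if (window <= 1 || length(x) < window) return(x)
  if (window %% 2 == 0) window <- window + 1
  as.numeric(runmed(x, window, endrule = "median"))
}

#' Cross-cohort correlation of projected copy-number profiles
#'
#' Per target bin, each cohort's amplification score is the sum over
#' samples of the positive part of the binned log2 values (deletion:
#' negative part); Pearson r is computed for each part over bins covered
#' in both cohorts.
#'
#' @param binned_a,binned_b Binned profile tibbles (`sample_id`, `chrom`,
#'   `start`, `end`, `value`) on an identical target bin grid.
#' @return Tibble with `part` ("amplification" / "deletion"), `r`,
#'   `n_bins`.
#' @export
cross_cohort_correlation <- function(binned_a, binned_b) {
  score <- function(binned) {
    binned |>
      group_by(.data$chrom, .data$start, .data$end) |>
      summarise(
        amp = sum(pmax(.data$value, 0), na.rm = TRUE),
        del = sum(pmin(.data$value, 0), na.rm = TRUE),
        covered = any(!is.na(.data$value)), .groups = "drop"
      )
  }
  a <- score(binned_a); b <- score(binned_b)
  shared <- inner_join(a, b, by = c("chrom", "start", "end"),
                       suffix = c("_a", "_b")) |>
    filter(.data$covered_a, .data$covered_b)
  if (nrow(shared) < 3) abort("fewer than 3 shared covered bins")
  tibble(
    part = c("amplification", "deletion"),
    r = c(cor(shared$amp_a, shared$amp_b),
          cor(shared$del_a, shared$del_b)),
    n_bins = nrow(shared)
  )
}
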