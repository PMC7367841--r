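# Independent brute-force oracles used to check the package's statistics.
# These deliberately re-derive results from first principles (enumeration,
# closed forms) and never call the code paths they verify.

# Two-sided Fisher p by explicit hypergeometric enumeration over all 2x2
# tables with the observed margins (minimum-likelihood rule).
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n2, k)
  obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n+m, n)
# group labelings (no ties assumed).
mwu_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  us <- apply(utils::combn(nx + ny, nx), 2, function(ix) {
    sum(r[ix]) - nx * (nx + 1) / 2
  })
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mid <- nx * ny / 2
  p <- if (u_obs > mid) {
    2 * mean(us >= u_obs)
  } else if (u_obs < mid) {
    2 * mean(us <= u_obs)
  } else {
    1
  }
  list(u = u_obs, p = min(1, p))
}

# Per-base projection of [start, end) through a toy chain's oracle map.
project_via_map <- function(map, start, end) {
  sel <- map[map$src_pos >= start & map$src_pos < end, ]
  list(mapped_positions = sel$tgt_pos, unmapped_bp = (end - start) - nrow(sel))
}

seq_range <- function(s, e) if (e > s) s:(e - 1) else integer(0)

# small default toy genome shared across tests
toy_genome <- function(chr1 = 6e4, chr2 = 4e4, bin_size = 1000,
                       planted = NULL) {
  genome_spec(c(chr1 = chr1, chr2 = chr2), bin_size = bin_size,
              planted_segments = planted)
}
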