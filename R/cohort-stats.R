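# Cohort-level statistics: exact Fisher, Mann-Whitney U, log-rank, one-way
# ANOVA, BH-FDR and gene-set (pathway) enrichment. Every function takes plain
# vectors or a data frame and returns a one-row (or per-item) tibble so
# results bind and pipe cleanly.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test of association in a 2x2 contingency table
#' (rows = groups, columns = outcome). The two-sided p-value follows the
#' minimum-likelihood rule: it sums the probabilities of all tables (with the
#' observed margins) whose probability does not exceed that of the observed
#' table, with a small relative slack to absorb floating-point ties.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `a` group-1/outcome-1, `b` group-1/outcome-2, `c` group-2/outcome-1,
#'   `d` group-2/outcome-2. Alternatively pass a 2x2 matrix as `a`.
#' @return A one-row tibble with `odds_ratio` (conditional MLE), `p`, `n`
#'   and `method`.
#' @examples
#' fisher_exact_2x2(0, 78, 8, 36) # AKT1 restricted to complex carcinomas
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    tab <- a
  } else {
    tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  }
  if (any(tab < 0) || any(!is.finite(tab))) {
    abort("contingency table cells must be non-negative finite counts")
  }
  if (all(rowSums(tab) == 0) || all(colSums(tab) == 0)) {
    abort("at least one margin of the 2x2 table must be positive")
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  tibble(
    odds_ratio = unname(ft$estimate),
    p = ft$p.value,
    n = sum(tab),
    method = "fisher_exact_2x2"
  )
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The p-value is exact (full enumeration
#' of the U distribution) when both groups have at most `exact_threshold`
#' observations and the pooled data contain no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors (each with at least one observation).
#' @param exact_threshold Largest per-group size for which the exact null
#'   distribution is enumerated (default 20).
#' @return One-row tibble with `u` (U statistic for `x` over `y`), `p`,
#'   group medians, sizes, whether the exact rule applied, and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) abort("both samples must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= exact_threshold && length(y) <= exact_threshold &&
    !has_ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  # degenerate case: zero-variance rank distribution (all values equal)
  p <- if (is.nan(wt$p.value)) 1 else min(1, wt$p.value)
  tibble(
    u = unname(wt$statistic),
    p = p,
    median_x = median(x), median_y = median(y),
    n_x = length(x), n_y = length(y),
    exact = use_exact,
    method = "mann_whitney_u"
  )
}

#' Multi-group log-rank test
#'
#' Standard log-rank chi-square comparison of survival across two or more
#' groups with `df = n_groups - 1`; risk sets are evaluated simultaneously at
#' tied event times.
#'
#' @param data Data frame with columns `time` (> 0), `event` (0 = censored,
#'   1 = event) and `group`, or pass the three vectors directly.
#' @param time,event,group Used when `data` is not supplied.
#' @return One-row tibble with `statistic`, `df`, `p`, `n_groups`, `n_events`.
#' @export
logrank_test <- function(data = NULL, time = NULL, event = NULL, group = NULL) {
  if (!is.null(data)) {
    assert_cols(data, c("time", "event", "group"), "data")
    time <- data$time; event <- data$event; group <- data$group
  }
  if (any(time <= 0)) abort("survival times must be positive")
  if (!all(event %in% c(0, 1))) abort("`event` must be 0 (censored) or 1")
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) abort("log-rank test needs >= 2 groups")
  if (sum(event) == 0) abort("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  tibble(
    statistic = sd$chisq,
    df = df,
    p = pchisq(sd$chisq, df = df, lower.tail = FALSE),
    n_groups = length(sd$n),
    n_events = sum(event),
    method = "logrank"
  )
}

#' One-way analysis of variance
#'
#' Classical F test for equality of group means, `df = (k - 1, N - k)`.
#' If every group has zero within-group variance and all group means are
#' equal, the test is degenerate: F = 0 and p = 1 are returned with a
#' warning.
#'
#' @param values Numeric vector of observations.
#' @param group Group labels (coerced to factor); each group needs >= 2
#'   values.
#' @return One-row tibble with `statistic` (F), `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(values, group) {
  group <- as.factor(group)
  k <- nlevels(droplevels(group))
  if (k < 2) abort("ANOVA needs >= 2 groups")
  if (any(table(group) < 2)) abort("each group needs >= 2 observations")
  n <- length(values)
  gm <- tapply(values, group, mean)
  ss_between <- sum(tapply(values, group, length) * (gm - mean(values))^2)
  ss_within <- sum((values - gm[group])^2)
  df1 <- k - 1; df2 <- n - k
  if (ss_within == 0 && ss_between == 0) {
    warn("all groups constant and equal; returning F = 0, p = 1")
    return(tibble(statistic = 0, df1 = df1, df2 = df2, p = 1,
                  method = "one_way_anova"))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  tibble(
    statistic = f, df1 = df1, df2 = df2,
    p = pf(f, df1, df2, lower.tail = FALSE),
    method = "one_way_anova"
  )
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment; q-values are monotone non-decreasing in the sorted
#' p-values and idempotent under re-application.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  assert_prob(p[!is.na(p)], "p")
  p.adjust(p, method = "BH")
}

#' Pathway enrichment by Fisher's exact test
#'
#' For each gene set, builds the 2x2 table (in/out pathway x hit/not hit)
#' over an explicit gene universe and applies [fisher_exact_2x2()];
#' q-values by BH across pathways. Results are sorted by p.
#'
#' @param hit_genes Character vector of genes of interest (must be a subset
#'   of `universe`).
#' @param pathways Named list of character vectors (gene sets), each a
#'   subset of `universe`; see [read_gmt()].
#' @param universe Character vector: all assayable genes.
#' @return Tibble with one row per pathway: overlap counts, `p`, `q`.
#' @export
pathway_enrichment <- function(hit_genes, pathways, universe) {
  hit_genes <- unique(hit_genes)
  universe <- unique(universe)
  stray <- setdiff(hit_genes, universe)
  if (length(stray) > 0) {
    abort(paste0("hit genes outside the universe: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  if (length(pathways) == 0) abort("`pathways` is empty")
  res <- imap(pathways, function(genes, name) {
    genes <- intersect(unique(genes), universe)
    in_hit <- length(intersect(genes, hit_genes))
    in_not <- length(genes) - in_hit
    out_hit <- length(hit_genes) - in_hit
    out_not <- length(universe) - length(genes) - out_hit
    ft <- fisher_exact_2x2(in_hit, in_not, out_hit, out_not)
    tibble(pathway = name, n_pathway = length(genes), n_hit = length(hit_genes),
           overlap = in_hit, p = ft$p)
  })
  res <- list_rbind(res)
  res$q <- bh_fdr(res$p)
  arrange(res, .data$p, .data$pathway)
}

#' Read gene sets in GMT format
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
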