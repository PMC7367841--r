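# Transcriptome subtyping: consensus NMF metagene discovery with cophenetic
# rank selection, tumor-specific cluster assignment, preranked gene-set
# enrichment, generic up/down signature scoring, and survival
# stratification.

nmf_euclid <- function(v, r, n_iter = 300, tol = 1e-6) {
  eps <- 1e-12
  m <- nrow(v); n <- ncol(v)
  w <- matrix(runif(m * r, 0.1, 1), m, r)
  h <- matrix(runif(r * n, 0.1, 1), r, n)
  obj <- numeric(0)
  for (it in seq_len(n_iter)) {
    h <- h * (t(w) %*% v) / (t(w) %*% w %*% h + eps)
    w <- w * (v %*% t(h)) / (w %*% h %*% t(h) + eps)
    obj <- c(obj, sum((v - w %*% h)^2))
    if (it > 10 && abs(obj[it - 1] - obj[it]) < tol * (obj[it - 1] + eps)) {
      break
    }
  }
  list(w = w, h = h, objective = obj)
}

#' Consensus NMF metagene discovery with cophenetic rank selection
#'
#' For each candidate rank k, runs `restarts` non-negative factorizations
#' (Euclidean multiplicative updates) of the non-negative expression matrix
#' from random initializations; each run assigns every sample to its
#' dominant metagene, and the consensus matrix records co-assignment
#' frequencies. Rank stability is the cophenetic correlation between the
#' consensus distances and the cophenetic distances of average-linkage
#' clustering of the consensus. The selected rank is the largest k whose
#' consensus is both hierarchical (cophenetic score >= `threshold`) and
#' crisp (dispersion coefficient >= `threshold`; duplicated factors above
#' the true rank leave the consensus fuzzy but perfectly hierarchical, so
#' cophenetic correlation alone cannot reject them). If no k qualifies,
#' the smallest candidate is returned with a warning. Deterministic given
#' `seed`.
#'
#' @param mat Non-negative genes x samples matrix (e.g. log2(FPKM+1)).
#' @param k_range Candidate ranks (default 2:10); all must be < n_samples.
#' @param restarts NMF restarts per rank (default 30).
#' @param threshold Cophenetic score needed to accept a rank (default 0.95).
#' @param crisp_threshold Dispersion coefficient needed to accept a rank
#'   (default 0.99): the consensus must be near 0/1, not merely
#'   hierarchical.
#' @param top_n Number of most-variable genes kept before factorization
#'   (default 2000; `Inf` keeps all).
#' @param seed Integer RNG seed.
#' @param n_iter Maximum update iterations per run.
#' @return Object of class `metagene_model`: per-rank list with `W`, `H`
#'   (best run by objective), `consensus`, `cophenetic`; plus `k` (selected
#'   rank), `W`/`H` of the selected rank, and `cophenetic` per candidate.
#' @export
nmf_metagenes <- function(mat, k_range = 2:10, restarts = 30,
                          threshold = 0.95, crisp_threshold = 0.99,
                          top_n = 2000, seed = 1, n_iter = 300) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) abort("expression matrix must be non-negative")
  if (max(k_range) >= ncol(mat)) abort("max(k_range) must be < n_samples")
  if (is.finite(top_n) && top_n < nrow(mat)) {
    vars <- apply(mat, 1, var)
    mat <- mat[order(vars, decreasing = TRUE)[seq_len(top_n)], , drop = FALSE]
  }
  n <- ncol(mat)
  fits <- withr::with_seed(seed, {
    map(k_range, function(k) {
      best <- NULL
      consensus <- matrix(0, n, n)
      for (r in seq_len(restarts)) {
        fit <- nmf_euclid(mat, k, n_iter = n_iter)
        assign <- apply(fit$h, 2, which.max)
        consensus <- consensus + outer(assign, assign, "==")
        if (is.null(best) ||
            tail(fit$objective, 1) < tail(best$objective, 1)) {
          best <- fit
        }
      }
      consensus <- consensus / restarts
      coph <- consensus_cophenetic(consensus)
      rownames(best$w) <- rownames(mat)
      colnames(best$w) <- rownames(best$h) <- paste0("NMF", seq_len(k))
      colnames(best$h) <- colnames(mat)
      list(k = k, W = best$w, H = best$h, consensus = consensus,
           cophenetic = coph,
           dispersion = consensus_dispersion(consensus),
           objective = tail(best$objective, 1))
    })
  })
  coph <- map_dbl(fits, "cophenetic")
  disp <- map_dbl(fits, "dispersion")
  # a rank is stable when the consensus is both hierarchical (cophenetic)
  # and crisp (dispersion): duplicated factors above the true rank leave
  # the consensus fuzzy-but-hierarchical, which cophenetic alone misses
  ok <- which(!is.na(coph) & coph >= threshold & disp >= crisp_threshold)
  if (length(ok) == 0) {
    warn("no rank reached the stability thresholds; falling back to min(k_range)")
    sel <- 1
  } else {
    sel <- max(ok)
  }
  structure(
    list(k = k_range[sel], W = fits[[sel]]$W, H = fits[[sel]]$H,
         consensus = fits[[sel]]$consensus,
         cophenetic = setNames(coph, paste0("k", k_range)),
         dispersion = setNames(disp, paste0("k", k_range)),
         fits = setNames(fits, paste0("k", k_range)),
         k_range = k_range, genes = rownames(mat)),
    class = "metagene_model"
  )
}

# dispersion coefficient of a consensus matrix: 1 for a crisp (0/1)
# consensus, towards 0 as co-assignments approach 0.5
consensus_dispersion <- function(consensus) {
  mean((4 * (consensus - 0.5)^2))
}

consensus_cophenetic <- function(consensus) {
  d <- as.dist(1 - consensus)
  if (all(d == 0) || sd(d) == 0) {
    # trivial stability: every restart puts all samples in one cluster,
    # which is no evidence for this rank
    return(NA_real_)
  }
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  if (sd(cd) == 0) return(1)
  cor(d, cd)
}

#' @method glance metagene_model
#' @export
glance.metagene_model <- function(x, ...) {
  tibble(k = x$k, cophenetic = unname(x$cophenetic[paste0("k", x$k)]),
         n_samples = ncol(x$H), n_genes = length(x$genes))
}

#' @method tidy metagene_model
#' @export
tidy.metagene_model <- function(x, ...) {
  as_tibble(t(x$H), rownames = "sample_id") |>
    pivot_longer(-"sample_id", names_to = "metagene", values_to = "activity")
}

#' Plot cophenetic scores across candidate ranks
#'
#' @param model A `metagene_model`.
#' @return A ggplot of cophenetic score versus rank.
#' @export
plot_cophenetic <- function(model) {
  df <- tibble(k = model$k_range, cophenetic = unname(model$cophenetic))
  ggplot(df, aes(x = .data$k, y = .data$cophenetic)) +
    geom_line() + geom_point() +
    geom_point(data = filter(df, .data$k == model$k), color = "red",
               size = 3) +
    labs(x = "rank k", y = "cophenetic score") +
    theme_minimal()
}

#' Designate tumor-specific metagenes
#'
#' A metagene is tumor-specific when its mean activity in tumor samples
#' exceeds its mean activity in normal samples. A manual override is
#' supported by passing the ids straight to [assign_clusters()].
#'
#' @param model A `metagene_model`.
#' @param sample_type Named character vector (or vector aligned to the H
#'   columns) with values `"tumor"` / `"normal"`.
#' @return Character vector of tumor-specific metagene names.
#' @export
designate_tumor_metagenes <- function(model, sample_type) {
  if (!is.null(names(sample_type))) {
    sample_type <- sample_type[colnames(model$H)]
  }
  if (!all(sample_type %in% c("tumor", "normal"))) {
    abort("`sample_type` values must be 'tumor' or 'normal'")
  }
  if (!any(sample_type == "normal")) return(rownames(model$H))
  mt <- rowMeans(model$H[, sample_type == "tumor", drop = FALSE])
  mn <- rowMeans(model$H[, sample_type == "normal", drop = FALSE])
  rownames(model$H)[mt > mn]
}

#' Assign samples to tumor-specific metagene clusters
#'
#' Each sample is assigned to the metagene with the largest activity in its
#' H column, provided that metagene is tumor-specific; otherwise (dominant
#' normal metagene, or an exact tie between tumor metagenes) the sample is
#' UNASSIGNED.
#'
#' @param model A `metagene_model` (or a bare H matrix).
#' @param tumor_signature_ids Non-empty subset of metagene names.
#' @return Tibble `sample_id`, `cluster` (metagene name or `"UNASSIGNED"`).
#' @export
assign_clusters <- function(model, tumor_signature_ids) {
  h <- if (inherits(model, "metagene_model")) model$H else as.matrix(model)
  if (length(tumor_signature_ids) == 0) abort("empty tumor signature set")
  if (!all(tumor_signature_ids %in% rownames(h))) {
    abort("tumor_signature_ids must name rows of H")
  }
  cluster <- vapply(seq_len(ncol(h)), function(j) {
    col <- h[, j]
    top <- which(col == max(col))
    if (length(top) > 1) {
      if (all(rownames(h)[top] %in% tumor_signature_ids)) {
        warn(sprintf("sample %s: exact tie between tumor metagenes",
                     colnames(h)[j]))
      }
      return("UNASSIGNED")
    }
    id <- rownames(h)[top]
    if (id %in% tumor_signature_ids) id else "UNASSIGNED"
  }, character(1))
  tibble(sample_id = colnames(h), cluster = cluster)
}

#' Preranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score over a ranked
#' gene list, with a gene-label permutation null. The two-sided p-value is
#' taken from the sign-matched tail of the null; the normalized ES divides
#' by the mean absolute null ES of the same sign.
#'
#' @param scores Named numeric vector of ranking scores (genes as names);
#'   ranked internally in decreasing order.
#' @param gene_set Character vector; must intersect the ranked genes.
#' @param nperm Permutations (default 1000).
#' @param weight_p Weight exponent on |score| (default 1; 0 gives the
#'   classic rank-only KS statistic).
#' @param seed Integer RNG seed.
#' @return One-row tibble: `es`, `nes`, `p`, `n_set`.
#' @export
preranked_gsea <- function(scores, gene_set, nperm = 1000, weight_p = 1,
                           seed = 1) {
  if (is.null(names(scores))) abort("`scores` must be named by gene")
  in_set <- names(scores) %in% gene_set
  if (!any(in_set)) abort("gene set is disjoint from the ranked genes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; hit <- in_set[ord]
  es_stat <- function(hit) {
    w <- abs(s)^weight_p
    nr <- sum(w[hit])
    p_hit <- cumsum(ifelse(hit, w / nr, 0))
    p_miss <- cumsum(ifelse(hit, 0, 1 / sum(!hit)))
    dev <- p_hit - p_miss
    dev[which.max(abs(dev))]
  }
  es <- es_stat(hit)
  n_hit <- sum(hit)
  null_es <- withr::with_seed(seed, {
    vapply(seq_len(nperm), function(i) {
      es_stat(seq_along(hit) %in% sample(seq_along(hit), n_hit))
    }, numeric(1))
  })
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
  p <- if (length(same) > 0) {
    (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  } else {
    1 / (1 + nperm)
  }
  tibble(es = es, nes = nes, p = p, n_set = n_hit)
}

#' Up/down gene-signature score per sample
#'
#' Genes are z-scored across samples. In `"correlation"` mode the score is
#' the Pearson correlation between a sample's z-profile restricted to the
#' signature genes and the template (+1 for up genes, -1 for down genes).
#' In `"mean_diff"` mode it is `mean(z(up)) - mean(z(down))`. `down_genes`
#' may be empty (template all +1 / mean of up only), which covers
#' average-expression scores such as EMT or metagene scores.
#'
#' @param mat Genes x samples expression matrix.
#' @param up_genes,down_genes Character vectors of signature genes.
#' @param mode `"correlation"` or `"mean_diff"`.
#' @return Tibble `sample_id`, `score`, `mode`.
#' @export
signature_score <- function(mat, up_genes, down_genes = character(0),
                            mode = c("correlation", "mean_diff")) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  sig <- intersect(c(up_genes, down_genes), rownames(mat))
  if (length(sig) == 0) abort("no signature gene present in the matrix")
  sub <- mat[sig, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d zero-variance signature gene(s)",
                 sum(sds == 0)))
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) == 0) abort("all signature genes have zero variance")
  }
  z <- t(scale(t(sub)))
  template <- ifelse(rownames(sub) %in% up_genes, 1, -1)
  score <- if (mode == "correlation") {
    if (length(unique(template)) == 1) {
      # constant template: correlation undefined; use mean z of up genes
      colMeans(z)
    } else {
      apply(z, 2, function(col) cor(col, template))
    }
  } else {
    up <- rownames(sub) %in% up_genes
    if (any(!up)) colMeans(z[up, , drop = FALSE]) -
      colMeans(z[!up, , drop = FALSE]) else colMeans(z)
  }
  tibble(sample_id = colnames(mat), score = unname(score), mode = mode)
}

#' Stratify samples and compare survival
#'
#' Stratifies samples either by given cluster labels or by the median of a
#' continuous score (samples at or below the median go to the low group),
#' runs the multi-group log-rank test, and returns Kaplan-Meier
#' step-function coordinates per group.
#'
#' @param groups Tibble `sample_id`, `cluster` (from [assign_clusters()])
#'   or `sample_id`, `score` (from [signature_score()]).
#' @param survival_data Tibble `sample_id`, `time` (> 0), `event` (0/1).
#' @return List: `test` (one-row [logrank_test()] tibble) and `km`, a
#'   tibble of Kaplan-Meier coordinates (`group`, `time`, `surv`,
#'   `n_risk`, `n_event`).
#' @export
stratify_and_survive <- function(groups, survival_data) {
  assert_cols(survival_data, c("sample_id", "time", "event"),
              "survival_data")
  if ("cluster" %in% names(groups)) {
    strat <- tibble(sample_id = groups$sample_id, group = groups$cluster)
  } else if ("score" %in% names(groups)) {
    med <- median(groups$score)
    strat <- tibble(sample_id = groups$sample_id,
                    group = ifelse(groups$score <= med, "low", "high"))
  } else {
    abort("`groups` needs a `cluster` or `score` column")
  }
  df <- inner_join(strat, survival_data, by = "sample_id")
  counts <- table(df$group)
  if (length(counts) < 2 || any(counts == 0)) {
    abort("stratification must yield >= 2 non-empty groups")
  }
  test <- logrank_test(df)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  km <- tibble(group = sub("^group=", "", strata),
               time = fit$time, surv = fit$surv,
               n_risk = fit$n.risk, n_event = fit$n.event)
  list(test = test, km = km)
}

#' Plot Kaplan-Meier curves
#'
#' @param km KM coordinate tibble from [stratify_and_survive()].
#' @return A ggplot of step survival curves per group.
#' @export
plot_km <- function(km) {
  start <- distinct(km, .data$group) |>
    mutate(time = 0, surv = 1)
  ggplot(bind_rows(start, select(km, "group", "time", "surv")),
         aes(x = .data$time, y = .data$surv, color = .data$group)) +
    geom_step() +
    labs(x = "time", y = "survival probability", color = NULL) +
    ggplot2::ylim(0, 1) +
    theme_minimal()
}
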