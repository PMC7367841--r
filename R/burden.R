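# Tumor mutational burden, purity adjustment, hypermutation calling,
# benign/malignant burden and allele-frequency comparison, and a
# context-corrected dN/dS selection surrogate.

#' Tumor mutational burden per sample
#'
#' Counts exonic mutations (silent and non-silent, SNVs and indels) per
#' sample and normalizes by the callable-region size in megabases.
#'
#' @param variants Variant tibble with `sample_id`; one row per mutation.
#' @param target_mb Callable-region size in Mb (> 0). There is no canonical
#'   canine exome size; the package default of 38 Mb is an arbitrary,
#'   documented convention.
#' @param samples Optional character vector of all cohort samples so that
#'   mutation-free samples get a zero record.
#' @return Tibble with `sample_id`, `exonic_count`, `tmb_per_mb`.
#' @export
compute_tmb <- function(variants, target_mb = 38, samples = NULL) {
  if (!is.numeric(target_mb) || target_mb <= 0) {
    abort("`target_mb` must be a positive region size in Mb")
  }
  assert_cols(variants, "sample_id", "variants")
  samples <- samples %||% unique(variants$sample_id)
  variants |>
    count(.data$sample_id, name = "exonic_count") |>
    right_join(tibble(sample_id = samples), by = "sample_id") |>
    mutate(exonic_count = coalesce(.data$exonic_count, 0L),
           tmb_per_mb = .data$exonic_count / target_mb) |>
    arrange(.data$sample_id)
}

#' Purity-adjusted mutation count
#'
#' Detected mutation counts are diluted in proportion to tumor purity (the
#' fraction of neoplastic cells); the adjusted count multiplies the observed
#' count by the correction factor `1 / purity`. The factor is pluggable.
#'
#' @param count Observed mutation count(s).
#' @param purity Tumor purity in (0, 1].
#' @param factor_fn Function mapping purity to the correction factor
#'   (default `function(p) 1 / p`).
#' @return Adjusted count(s), same length as `count`.
#' @examples
#' purity_adjust_tmb(30, 0.75) # 40
#' @export
purity_adjust_tmb <- function(count, purity, factor_fn = function(p) 1 / p) {
  if (any(!is.finite(purity) | purity <= 0 | purity > 1)) {
    abort("`purity` must lie in (0, 1]")
  }
  if (any(count < 0)) abort("`count` must be non-negative")
  count * factor_fn(purity)
}

#' Call hypermutated samples
#'
#' A sample is hypermutated when its burden strictly exceeds `cutoff`
#' mutations per Mb.
#'
#' @param tmb_per_mb Numeric vector of per-sample burdens (mutations/Mb).
#' @param cutoff Strict threshold (default 10 mutations/Mb).
#' @return Logical vector; the cohort hypermutation frequency is its mean.
#' @export
call_hypermutation <- function(tmb_per_mb, cutoff = 10) {
  if (!is.numeric(cutoff) || cutoff <= 0) abort("`cutoff` must be positive")
  tmb_per_mb > cutoff
}

#' Compare mutation burden and allele frequencies between histology groups
#'
#' Two-sided Mann-Whitney U comparisons of per-sample TMB, purity-adjusted
#' TMB, and the pooled per-mutation variant allele frequencies between
#' benign and malignant samples.
#'
#' @param variants Variant tibble with `sample_id`, `vaf`.
#' @param metadata Metadata tibble with `sample_id`, `histology`
#'   (`"benign"` / `"malignant"`), `purity`.
#' @param target_mb Callable-region size in Mb.
#' @return Tibble with one row per measure (`tmb`, `adjusted_tmb`, `vaf`)
#'   carrying the U statistic, p-value and group medians.
#' @export
compare_burden_and_maf <- function(variants, metadata, target_mb = 38) {
  assert_cols(metadata, c("sample_id", "histology", "purity"), "metadata")
  assert_cols(variants, c("sample_id", "vaf"), "variants")
  groups <- split(metadata$sample_id, metadata$histology)
  if (!all(c("benign", "malignant") %in% names(groups))) {
    abort("metadata must contain both benign and malignant samples")
  }
  burden <- compute_tmb(variants, target_mb, samples = metadata$sample_id) |>
    left_join(metadata, by = "sample_id") |>
    mutate(adjusted = purity_adjust_tmb(.data$exonic_count, .data$purity))
  pick <- function(col, hist) {
    burden[[col]][burden$histology == hist]
  }
  vafs <- variants |>
    left_join(select(metadata, "sample_id", "histology"), by = "sample_id") |>
    filter(!is.na(.data$vaf))
  measures <- list(
    tmb = list(pick("tmb_per_mb", "benign"), pick("tmb_per_mb", "malignant")),
    adjusted_tmb = list(pick("adjusted", "benign"),
                        pick("adjusted", "malignant")),
    vaf = list(vafs$vaf[vafs$histology == "benign"],
               vafs$vaf[vafs$histology == "malignant"])
  )
  imap(measures, function(xy, name) {
    if (length(xy[[1]]) < 2 || length(xy[[2]]) < 2) {
      abort(sprintf("measure '%s': each group needs >= 2 observations", name))
    }
    mann_whitney_u(xy[[1]], xy[[2]]) |>
      mutate(measure = name, .before = 1) |>
      rename(median_benign = "median_x", median_malignant = "median_y")
  }) |>
    list_rbind()
}

#' Build a mutational-opportunity model for the dN/dS surrogate
#'
#' Captures, per gene, the expected nonsynonymous (`e_n`) and synonymous
#' (`e_s`) mutational opportunity — site-by-change counts weighted by the
#' 96-channel mutation-rate weights — against which observed counts are
#' compared.
#'
#' @param genes Character vector of gene names.
#' @param e_n,e_s Positive opportunity weights per gene.
#' @param channel_weights Optional normalized 96-vector of channel rates
#'   (stored for provenance; the per-gene opportunities are assumed already
#'   weighted).
#' @return Tibble of class `opportunity_model`.
#' @export
opportunity_model <- function(genes, e_n, e_s, channel_weights = NULL) {
  if (any(e_n < 0) || any(e_s < 0)) abort("opportunities must be >= 0")
  if (!is.null(channel_weights)) {
    if (length(channel_weights) != 96 || any(channel_weights < 0)) {
      abort("`channel_weights` must be a non-negative 96-vector")
    }
    channel_weights <- channel_weights / sum(channel_weights)
  }
  out <- tibble(gene = genes, e_n = e_n, e_s = e_s)
  attr(out, "channel_weights") <- channel_weights
  class(out) <- c("opportunity_model", class(out))
  out
}

#' Context-corrected dN/dS selection surrogate
#'
#' A deliberately simple stand-in for full covariate-based dN/dS estimation:
#' per gene (or per sample), the ratio of observed nonsynonymous to
#' synonymous SNV counts (0.5 pseudocounts) normalized by the expected
#' opportunity ratio `E_N / E_S`, with a two-sided binomial test of the
#' nonsynonymous count among all classified SNVs against the neutral
#' proportion `E_N / (E_N + E_S)` and BH correction across the scope.
#' Silent SNVs count as synonymous; all other classified SNVs as
#' nonsynonymous.
#'
#' @param variants Variant tibble with `sample_id`, `gene`, `non_silent`,
#'   `variant_class` (only `"SNV"` rows are used).
#' @param model An [opportunity_model()] covering every gene present.
#' @param scope `"gene"` or `"sample"`.
#' @return Tibble with `scope_id`, `n_obs`, `s_obs`, `dnds`, `p`, `q`.
#' @export
dnds_surrogate <- function(variants, model, scope = c("gene", "sample")) {
  scope <- match.arg(scope)
  assert_cols(variants, c("sample_id", "gene", "non_silent", "variant_class"),
              "variants")
  snvs <- filter(variants, .data$variant_class == "SNV", !is.na(.data$gene))
  missing_genes <- setdiff(unique(snvs$gene), model$gene)
  if (length(missing_genes) > 0) {
    abort(paste0("opportunity model lacks gene(s): ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  bad <- model$gene[model$e_s == 0 & model$gene %in% snvs$gene]
  if (length(bad) > 0) {
    abort(paste0("zero synonymous opportunity for gene(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (scope == "gene") {
    counts <- snvs |>
      group_by(scope_id = .data$gene) |>
      summarise(n_obs = sum(.data$non_silent),
                s_obs = sum(!.data$non_silent), .groups = "drop") |>
      left_join(model |> rename(scope_id = "gene") |> as_tibble(),
                by = "scope_id")
  } else {
    e_tot <- summarise(model, e_n = sum(.data$e_n), e_s = sum(.data$e_s))
    counts <- snvs |>
      group_by(scope_id = .data$sample_id) |>
      summarise(n_obs = sum(.data$non_silent),
                s_obs = sum(!.data$non_silent), .groups = "drop") |>
      right_join(tibble(scope_id = unique(variants$sample_id)),
                 by = "scope_id") |>
      mutate(n_obs = coalesce(.data$n_obs, 0L),
             s_obs = coalesce(.data$s_obs, 0L),
             e_n = e_tot$e_n, e_s = e_tot$e_s)
  }
  res <- counts |>
    mutate(
      dnds = ((.data$n_obs + 0.5) / (.data$s_obs + 0.5)) /
        (.data$e_n / .data$e_s)
    )
  res$p <- vapply(seq_len(nrow(res)), function(i) {
    tot <- res$n_obs[i] + res$s_obs[i]
    if (tot == 0) return(1)
    pr <- res$e_n[i] / (res$e_n[i] + res$e_s[i])
    binom.test(res$n_obs[i], tot, p = pr, alternative = "two.sided")$p.value
  }, numeric(1))
  res$q <- bh_fdr(res$p)
  res |>
    mutate(dnds = ifelse(.data$n_obs + .data$s_obs == 0, 1, .data$dnds)) |>
    select("scope_id", "n_obs", "s_obs", "dnds", "p", "q") |>
    arrange(.data$q, .data$p, .data$scope_id)
}
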