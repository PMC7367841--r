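# Post-calling somatic/germline variant operations: the alignment-score
# error filter, six-class consequence mapping, recurrence tables, germline
# candidate filtering and pathway aberration fractions.

# Controlled Sequence Ontology vocabulary -> six functional classes.
# Shipped as a data file so annotation dialects can be swapped.
consequence_vocabulary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "consequence_classes.tsv",
                          package = "oncomap", mustWork = TRUE)
      cache <<- readr::read_tsv(path, show_col_types = FALSE)
    }
    cache
  }
})

#' Map consequence annotations to the six functional mutation classes
#'
#' Deterministically maps Sequence Ontology consequence terms to one of
#' missense, nonsense, frameshift, in-frame indel, splice, or silent, with a
#' non-silent flag. Terms outside the controlled vocabulary map to class
#' `"other"` (non-silent = FALSE) with a warning.
#'
#' @param consequence Character vector of annotation terms (no empty
#'   strings).
#' @return Tibble with columns `consequence`, `mutation_class`, `non_silent`.
#' @examples
#' classify_consequence(c("missense_variant", "synonymous_variant"))
#' @export
classify_consequence <- function(consequence) {
  if (length(consequence) == 0) abort("no consequence terms supplied")
  if (any(is.na(consequence) | consequence == "")) {
    abort("empty consequence string")
  }
  vocab <- consequence_vocabulary()
  out <- tibble(consequence = consequence) |>
    left_join(vocab, by = "consequence")
  unknown <- unique(out$consequence[is.na(out$mutation_class)])
  if (length(unknown) > 0) {
    warn(paste0("unknown consequence term(s) mapped to 'other': ",
                paste(unknown, collapse = ", ")))
    out$mutation_class[is.na(out$mutation_class)] <- "other"
    out$non_silent[is.na(out$non_silent)] <- FALSE
  }
  out
}

#' Attach mutation classes to a variant table
#'
#' Applies [classify_consequence()] and, for indels, overrides the annotated
#' class by the length rule: an indel whose net length change is divisible
#' by 3 is an in-frame indel, otherwise a frameshift. Ambiguous annotation
#' strings never decide indel frame.
#'
#' @param variants Tibble with at least `ref`, `alt`, `consequence`.
#' @return Input tibble with `variant_class`, `mutation_class`, `non_silent`
#'   columns added/replaced.
#' @export
annotate_mutation_class <- function(variants) {
  assert_cols(variants, c("ref", "alt", "consequence"), "variants")
  cls <- classify_consequence(variants$consequence)
  variants$mutation_class <- cls$mutation_class
  variants$non_silent <- cls$non_silent
  len_diff <- nchar(variants$alt) - nchar(variants$ref)
  variants$variant_class <- case_when(
    len_diff == 0 & nchar(variants$ref) == 1 ~ "SNV",
    len_diff > 0 ~ "insertion",
    len_diff < 0 ~ "deletion",
    .default = "SNV"
  )
  is_indel <- variants$variant_class != "SNV"
  frame_kept <- abs(len_diff) %% 3 == 0
  variants$mutation_class[is_indel & frame_kept] <- "in-frame indel"
  variants$mutation_class[is_indel & !frame_kept] <- "frameshift"
  variants$non_silent[is_indel] <- TRUE
  variants
}

#' Filter variant sites by alignment-score ratio
#'
#' Flags candidate sites as probable alignment errors when the mean
#' suboptimal alignment score (XS) of alt-supporting reads, pooled over all
#' reads of all samples sharing the site, reaches `ratio` times the mean
#' optimal alignment score (AS): rejected iff `meanXS >= ratio * meanAS`.
#' Reads with no suboptimal hit (missing XS) contribute XS = 0.
#'
#' @param variants Variant tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param scores Per-read score tibble with `chrom`, `pos`, `ref`, `alt`,
#'   `as`, `xs` (one row per alt-supporting read; `sample_id` optional).
#' @param ratio Rejection threshold on meanXS / meanAS (default 0.8).
#' @return List with `kept` and `rejected` variant tibbles (a partition of
#'   the input) and `audit`, a per-site tibble with `mean_as`, `mean_xs`,
#'   `n_reads`, `rejected`.
#' @export
alignment_error_filter <- function(variants, scores, ratio = 0.8) {
  key <- c("chrom", "pos", "ref", "alt")
  assert_cols(variants, key, "variants")
  assert_cols(scores, c(key, "as", "xs"), "scores")
  scores <- mutate(scores, xs = ifelse(is.na(.data$xs), 0, .data$xs))
  if (any(!is.finite(scores$as)) || any(!is.finite(scores$xs))) {
    abort("alignment scores must be finite")
  }
  audit <- scores |>
    group_by(across(all_of(key))) |>
    summarise(mean_as = mean(.data$as), mean_xs = mean(.data$xs),
              n_reads = n(), .groups = "drop") |>
    mutate(rejected = .data$mean_xs >= ratio * .data$mean_as)
  sites <- distinct(variants[key])
  unscored <- anti_join(sites, audit, by = key)
  if (nrow(unscored) > 0) {
    abort(paste0("variant site(s) without any scored alt read: ",
                 paste(head(paste(unscored$chrom, unscored$pos, unscored$ref,
                                  unscored$alt, sep = ":"), 5),
                       collapse = ", ")))
  }
  flagged <- left_join(variants, audit, by = key)
  list(
    kept = flagged |> filter(!.data$rejected) |>
      select(-"mean_as", -"mean_xs", -"n_reads", -"rejected"),
    rejected = flagged |> filter(.data$rejected) |>
      select(-"mean_as", -"mean_xs", -"n_reads", -"rejected"),
    audit = semi_join(audit, sites, by = key)
  )
}

#' Recurrently mutated genes and the mutation landscape matrix
#'
#' Builds the gene x sample non-silent mutation matrix and lists genes whose
#' non-silent mutation frequency strictly exceeds `min_fraction` of the
#' cohort, ordered by descending frequency (ties by gene name).
#'
#' @param variants Variant tibble with `sample_id`, `gene`, `non_silent`
#'   (see [annotate_mutation_class()]).
#' @param metadata Sample metadata tibble with `sample_id` (defines the
#'   cohort; samples without mutations count in the denominator).
#' @param min_fraction Strict lower bound on mutated fraction (default 0.05).
#' @return List: `recurrent` tibble (`gene`, `n_mutated`, `frequency`) and
#'   `matrix`, the binary genes x samples non-silent indicator matrix.
#' @export
recurrent_gene_table <- function(variants, metadata, min_fraction = 0.05) {
  assert_cols(variants, c("sample_id", "gene", "non_silent"), "variants")
  assert_cols(metadata, "sample_id", "metadata")
  samples <- unique(metadata$sample_id)
  if (length(samples) == 0) abort("empty cohort")
  hits <- variants |>
    filter(.data$non_silent, !is.na(.data$gene)) |>
    distinct(.data$gene, .data$sample_id)
  genes <- sort(unique(hits$gene))
  mat <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(hits) > 0) {
    mat[cbind(match(hits$gene, genes), match(hits$sample_id, samples))] <- 1L
  }
  recurrent <- hits |>
    count(.data$gene, name = "n_mutated") |>
    mutate(frequency = .data$n_mutated / length(samples)) |>
    filter(.data$frequency > min_fraction) |>
    arrange(desc(.data$frequency), .data$gene)
  list(recurrent = recurrent, matrix = mat)
}

#' Filter germline variants to rare, damaging candidates
#'
#' Keeps records that pass all of: sequencing depth at least `min_depth` in
#' tumor and normal (or, when tumor depth is absent, in normal alone);
#' pathogenicity in truncating / pathogenic / likely_pathogenic; population
#' minor-allele frequency missing (novel) or below `maf_cutoff`; and cohort
#' MAF below `maf_cutoff`. The filter is idempotent.
#'
#' @param records Tibble with `depth_tumor`, `depth_normal`, `pathogenicity`,
#'   `population_maf` (NA = novel), `cohort_maf`.
#' @param maf_cutoff Strict upper bound on both MAFs (default 0.05).
#' @param min_depth Minimum read depth (default 10).
#' @return The surviving rows of `records`.
#' @export
filter_germline_candidates <- function(records, maf_cutoff = 0.05,
                                       min_depth = 10) {
  assert_cols(records, c("depth_tumor", "depth_normal", "pathogenicity",
                         "population_maf", "cohort_maf"), "records")
  depths <- c(records$depth_tumor, records$depth_normal)
  if (any(depths < 0, na.rm = TRUE)) abort("negative read depth")
  damaging <- c("truncating", "pathogenic", "likely_pathogenic")
  records |>
    filter(
      ifelse(is.na(.data$depth_tumor),
             .data$depth_normal >= min_depth,
             .data$depth_tumor >= min_depth &
               .data$depth_normal >= min_depth),
      .data$pathogenicity %in% damaging,
      is.na(.data$population_maf) | .data$population_maf < maf_cutoff,
      .data$cohort_maf < maf_cutoff
    )
}

#' Fraction of samples with any aberration in a gene set
#'
#' A sample counts once if it carries at least one non-silent mutation or
#' one copy-number call in any gene of the set.
#'
#' @param mutations Tibble of non-silent mutation calls with `sample_id`,
#'   `gene` (e.g. filtered variants).
#' @param scna_calls Optional tibble of gene-level copy-number calls with
#'   `sample_id`, `gene`.
#' @param gene_set Character vector of pathway genes (non-empty).
#' @param samples Character vector: the full cohort (denominator).
#' @return One-row tibble: `n_samples`, `n_altered`, `fraction`.
#' @export
pathway_aberration_fraction <- function(mutations, scna_calls = NULL,
                                        gene_set, samples) {
  if (length(gene_set) == 0) abort("`gene_set` is empty")
  if (length(samples) == 0) abort("empty cohort")
  assert_cols(mutations, c("sample_id", "gene"), "mutations")
  hit <- mutations |> filter(.data$gene %in% gene_set)
  altered <- unique(hit$sample_id)
  if (!is.null(scna_calls)) {
    assert_cols(scna_calls, c("sample_id", "gene"), "scna_calls")
    altered <- union(altered,
                     scna_calls$sample_id[scna_calls$gene %in% gene_set])
  }
  altered <- intersect(altered, samples)
  tibble(n_samples = length(samples), n_altered = length(altered),
         fraction = length(altered) / length(samples))
}
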