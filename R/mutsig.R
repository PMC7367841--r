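# 96-channel trinucleotide spectra, de novo NMF signature deconvolution
# (generalized Kullback-Leibler objective, multiplicative updates), cosine
# matching against a reference catalog, and non-negative least-squares
# exposure fitting.

BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The canonical 96 trinucleotide channels
#'
#' Six pyrimidine-strand substitution classes (C>A, C>G, C>T, T>A, T>C,
#' T>G) times 16 flanking contexts, contexts alphabetical within each
#' class; channel labels like `"A[C>T]G"`. Catalogs are matched by channel
#' name, never by position.
#'
#' @return Character vector of length 96.
#' @export
sbs_channels <- function() {
  unlist(lapply(SUBSTITUTIONS, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(BASES, BASES, function(p5, p3) {
      paste0(p5, "[", s, "]", p3)
    })))
  }))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

#' Trinucleotide mutation spectrum per sample
#'
#' Tabulates each sample's SNVs into the 96 channels. SNVs with a purine
#' reference base are reverse-complemented to the pyrimidine-strand
#' convention; indels are skipped (count reported as an attribute), as are
#' SNVs whose context contains N.
#'
#' @param variants Variant tibble with `sample_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param reference Named character vector of chromosome sequences
#'   (A/C/G/T/N), e.g. from [read_reference_fasta()].
#' @return 96 x n_samples integer matrix with channel rownames; attribute
#'   `skipped` counts indels and N-context SNVs.
#' @export
build_spectrum <- function(variants, reference) {
  assert_cols(variants, c("sample_id", "chrom", "pos", "ref", "alt"),
              "variants")
  snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref %in% BASES & variants$alt %in% BASES
  n_indel <- sum(!snv)
  v <- variants[snv, ]
  channels <- sbs_channels()
  samples <- unique(variants$sample_id)
  spec <- matrix(0L, nrow = 96, ncol = length(samples),
                 dimnames = list(channels, samples))
  n_skipped_context <- 0L
  if (nrow(v) > 0) {
    bad_chrom <- setdiff(unique(v$chrom), names(reference))
    if (length(bad_chrom) > 0) {
      abort(paste0("reference lacks chromosome(s): ",
                   paste(bad_chrom, collapse = ", ")))
    }
    chrom_len <- nchar(reference)[v$chrom]
    if (any(v$pos < 2 | v$pos > chrom_len - 1)) {
      abort("SNV position outside the reference (needs pos +/- 1 in bounds)")
    }
    ctx <- substr(reference[v$chrom], v$pos - 1, v$pos + 1)
    ref_base <- substr(ctx, 2, 2)
    if (any(ref_base != v$ref & !str_detect(ctx, "N"))) {
      abort("variant ref allele disagrees with the reference sequence")
    }
    has_n <- str_detect(ctx, "N")
    n_skipped_context <- sum(has_n)
    v <- v[!has_n, ]; ctx <- ctx[!has_n]
  }
  if (nrow(v) > 0) {
    alt <- v$alt
    flip <- substr(ctx, 2, 2) %in% c("A", "G")
    ctx[flip] <- revcomp(ctx[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    lab <- paste0(substr(ctx, 1, 1), "[", substr(ctx, 2, 2), ">", alt, "]",
                  substr(ctx, 3, 3))
    tab <- table(factor(lab, levels = channels),
                 factor(v$sample_id, levels = samples))
    spec <- matrix(as.integer(tab), nrow = 96,
                   dimnames = list(channels, samples))
  }
  attr(spec, "skipped") <- c(indel = n_indel, n_context = n_skipped_context)
  spec
}

#' Read an indexed/plain reference FASTA
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase chromosome sequences.
#' @export
read_reference_fasta <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  names <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  setNames(unname(seqs), names)
}

kl_divergence <- function(v, wh) {
  eps <- 1e-12
  sum(v * log((v + eps) / (wh + eps)) - v + wh)
}

nmf_kl <- function(v, r, n_iter = 500, tol = 1e-6) {
  eps <- 1e-12
  m <- nrow(v); n <- ncol(v)
  w <- matrix(runif(m * r, 0.1, 1), m, r)
  h <- matrix(runif(r * n, 0.1, 1), r, n)
  obj <- numeric(0)
  for (it in seq_len(n_iter)) {
    wh <- w %*% h + eps
    w <- w * ((v / wh) %*% t(h)) / (matrix(rowSums(h), m, r, byrow = TRUE) + eps)
    wh <- w %*% h + eps
    h <- h * (t(w) %*% (v / wh)) / (matrix(colSums(w), r, n) + eps)
    obj <- c(obj, kl_divergence(v, w %*% h))
    if (it > 10 && abs(obj[it - 1] - obj[it]) < tol * abs(obj[it - 1] + eps)) {
      break
    }
  }
  list(w = w, h = h, objective = obj)
}

#' De novo mutational-signature deconvolution
#'
#' Factorizes a 96 x samples spectrum matrix into `rank` non-negative
#' channel profiles (W) and per-sample activities (H) by multiplicative
#' updates minimizing the generalized Kullback-Leibler divergence, keeping
#' the best of `restarts` random initializations. W columns are normalized
#' to sum 1 (activities rescaled accordingly). Deterministic given `seed`.
#'
#' @param spectra 96 x n_samples non-negative matrix (all-zero samples are
#'   dropped first).
#' @param rank Number of signatures, `1 <= rank < n_samples`.
#' @param restarts Random restarts (default 10).
#' @param seed Integer RNG seed.
#' @param n_iter Maximum multiplicative-update iterations per restart.
#' @return Object of class `denovo_sigs`: `W` (96 x rank, column-stochastic),
#'   `H` (rank x samples), `objective` (trace of the best restart), `rank`.
#' @export
denovo_signatures <- function(spectra, rank, restarts = 10, seed = 1,
                              n_iter = 500) {
  if (any(spectra < 0)) abort("spectra must be non-negative")
  keep <- colSums(spectra) > 0
  spectra <- spectra[, keep, drop = FALSE]
  if (rank < 1 || rank >= ncol(spectra)) {
    abort("`rank` must satisfy 1 <= rank < n_samples (after dropping zeros)")
  }
  best <- NULL
  withr::with_seed(seed, {
    for (i in seq_len(restarts)) {
      fit <- nmf_kl(spectra, rank, n_iter = n_iter)
      if (is.null(best) || tail(fit$objective, 1) < tail(best$objective, 1)) {
        best <- fit
      }
    }
  })
  scale <- colSums(best$w)
  w <- sweep(best$w, 2, scale, "/")
  h <- sweep(best$h, 1, scale, "*")
  rownames(w) <- rownames(spectra)
  colnames(w) <- rownames(h) <- paste0("DN", seq_len(rank))
  colnames(h) <- colnames(spectra)
  structure(list(W = w, H = h, objective = best$objective, rank = rank),
            class = "denovo_sigs")
}

cosine_sim <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match a signature profile against a reference catalog
#'
#' Cosine similarity between a 96-channel profile and every catalog
#' signature, computed on normalized vectors and aligned by channel name.
#'
#' @param profile Non-negative, non-zero 96-vector (named by channel, or in
#'   canonical [sbs_channels()] order).
#' @param catalog K x 96 row-stochastic matrix (signatures x channels), or
#'   its transpose with channel rownames; see [read_signature_catalog()].
#' @return Tibble `signature`, `cosine`, `rank`, sorted by descending
#'   cosine; ties broken by catalog order.
#' @export
match_catalog <- function(profile, catalog) {
  catalog <- as_catalog_matrix(catalog)
  profile <- align_channels(profile)
  if (sum(profile) == 0) abort("profile is the zero vector")
  if (any(profile < 0)) abort("profile must be non-negative")
  sims <- unname(apply(catalog, 1, function(s) cosine_sim(profile, s)))
  tibble(signature = rownames(catalog), cosine = sims,
         catalog_order = seq_len(nrow(catalog))) |>
    arrange(desc(.data$cosine), .data$catalog_order) |>
    mutate(rank = row_number()) |>
    select("signature", "cosine", "rank")
}

as_catalog_matrix <- function(catalog) {
  catalog <- as.matrix(catalog)
  if (ncol(catalog) != 96 && nrow(catalog) == 96) catalog <- t(catalog)
  if (ncol(catalog) != 96) abort("catalog must have 96 channels")
  if (!is.null(colnames(catalog))) {
    if (!setequal(colnames(catalog), sbs_channels())) {
      abort("catalog channel names do not match the 96 canonical channels")
    }
    catalog <- catalog[, sbs_channels(), drop = FALSE]
  } else {
    colnames(catalog) <- sbs_channels()
  }
  if (any(catalog < 0)) abort("catalog must be non-negative")
  rs <- rowSums(catalog)
  if (any(abs(rs - 1) > 1e-6)) abort("catalog rows must sum to 1 (within 1e-6)")
  if (is.null(rownames(catalog))) {
    rownames(catalog) <- paste0("S", seq_len(nrow(catalog)))
  }
  catalog
}

align_channels <- function(profile) {
  if (!is.null(names(profile))) {
    if (!setequal(names(profile), sbs_channels())) {
      abort("profile channel names do not match the canonical channels")
    }
    profile <- profile[sbs_channels()]
  }
  if (length(profile) != 96) abort("profile must have 96 channels")
  unname(profile)
}

#' Fit signature exposures by non-negative least squares
#'
#' Solves `min || counts - t(catalog) %*% exposures ||_2` subject to
#' `exposures >= 0`: the mutation counts attributed to each catalog
#' signature.
#'
#' @param spectrum Non-negative 96-vector of channel counts (named or in
#'   canonical order); must be non-empty.
#' @param catalog K x 96 row-stochastic signature catalog.
#' @return Object of class `exposure_fit` with `exposures` (named K-vector),
#'   `residual` (Euclidean norm of the unexplained counts) and
#'   `cosine_to_reconstruction`.
#' @export
fit_exposures <- function(spectrum, catalog) {
  catalog <- as_catalog_matrix(catalog)
  spectrum <- align_channels(spectrum)
  if (sum(spectrum) == 0) abort("empty spectrum")
  fit <- pracma::lsqnonneg(t(catalog), spectrum)
  exposures <- setNames(fit$x, rownames(catalog))
  recon <- as.numeric(t(catalog) %*% fit$x)
  cosim <- if (sum(recon) == 0) 0 else cosine_sim(spectrum, recon)
  structure(
    list(exposures = exposures,
         residual = sqrt(sum((spectrum - recon)^2)),
         cosine_to_reconstruction = cosim,
         n_mutations = sum(spectrum)),
    class = "exposure_fit"
  )
}

#' @method tidy exposure_fit
#' @export
tidy.exposure_fit <- function(x, ...) {
  tibble(signature = names(x$exposures),
         exposure = unname(x$exposures),
         proportion = if (sum(x$exposures) > 0) {
           unname(x$exposures) / sum(x$exposures)
         } else {
           rep(0, length(x$exposures))
         })
}

#' @method glance exposure_fit
#' @export
glance.exposure_fit <- function(x, ...) {
  tibble(residual = x$residual,
         cosine_to_reconstruction = x$cosine_to_reconstruction,
         n_mutations = x$n_mutations,
         n_active = sum(x$exposures > 0))
}

#' @method tidy denovo_sigs
#' @export
tidy.denovo_sigs <- function(x, ...) {
  as_tibble(x$W, rownames = "channel") |>
    pivot_longer(-"channel", names_to = "signature", values_to = "weight")
}

#' @method glance denovo_sigs
#' @export
glance.denovo_sigs <- function(x, ...) {
  tibble(rank = x$rank, objective = tail(x$objective, 1),
         n_iter = length(x$objective))
}

#' Plot a 96-channel mutation spectrum
#'
#' @param spectrum Named 96-vector of channel counts (or a column of a
#'   [build_spectrum()] matrix).
#' @return A ggplot: channels on x, counts on y, faceted by substitution
#'   class.
#' @export
plot_spectrum <- function(spectrum) {
  spectrum <- align_channels(spectrum)
  df <- tibble(channel = factor(sbs_channels(), levels = sbs_channels()),
               substitution = sub(".*\\[(.*)\\].*", "\\1", sbs_channels()),
               count = spectrum)
  ggplot(df, aes(x = .data$channel, y = .data$count)) +
    geom_col() +
    facet_grid(cols = vars(.data$substitution), scales = "free_x") +
    labs(x = NULL, y = "mutations") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Read / write a signature catalog TSV (channels x signatures)
#'
#' @param path File path. The TSV has a `channel` column with the 96 channel
#'   labels and one column per signature.
#' @return For reading: K x 96 row-stochastic matrix.
#' @export
read_signature_catalog <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(df, "channel", "catalog")
  m <- t(as.matrix(df[setdiff(names(df), "channel")]))
  colnames(m) <- df$channel
  as_catalog_matrix(m)
}

#' @rdname read_signature_catalog
#' @param catalog K x 96 matrix to write.
#' @export
write_signature_catalog <- function(catalog, path) {
  catalog <- as_catalog_matrix(catalog)
  df <- bind_cols(tibble(channel = colnames(catalog)),
                  as_tibble(t(catalog)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot fitted signature exposures
#'
#' @param object An `exposure_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of exposure proportions per signature.
#' @method autoplot exposure_fit
#' @export
autoplot.exposure_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$signature, y = .data$proportion)) +
    geom_col() +
    labs(x = NULL, y = "exposure proportion") +
    theme_minimal()
}
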