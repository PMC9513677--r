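#' Hypergeometric over-representation test with enrichment factor
#'
#' Single source of truth for every set-overlap enrichment in the package
#' (per-cluster GO enrichment and lipid class enrichment). Given `k`
#' annotated members among `n` selected items, drawn from a background of
#' `N` items of which `K` are annotated, the upper-tail hypergeometric
#' probability of observing `k` or more is reported together with the
#' enrichment factor, the ratio of observed to expected rates
#' `(k/n) / (K/N)`.
#'
#' @param k Observed annotated items in the selection.
#' @param n Selection size.
#' @param K Annotated items in the background.
#' @param N Background size.
#' @return A tibble with columns `k`, `n`, `K`, `N`, `enrichment_factor`,
#'   `p_value`. `p_value` is in (0, 1]; `k = 0` gives `p = 1`.
#' @examples
#' hypergeom_enrichment(4, 5, 10, 100)
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N <= 0) || any(k > n) || any(K > N) ||
      any(n > N) || any(k > K)) {
    stop_pt("Inconsistent counts for the hypergeometric test.",
            "peroxitools_bad_input")
  }
  tibble(
    k = k, n = n, K = K, N = N,
    enrichment_factor = ifelse(n == 0, NA_real_, (k / n) / (K / N)),
    p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  )
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT layout: set name, description, then member
#' genes, one set per line.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (set name -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  readr::write_lines(lines, path)
  invisible(path)
}

#' GO biological-process enrichment for one gene cluster
#'
#' Tests each annotation term for over-representation among the cluster's
#' genes relative to the background, adjusts p-values by Benjamini-Hochberg
#' across terms within the cluster, and selects the term with the largest
#' enrichment factor among those with adjusted p < `alpha` (or none).
#'
#' @param genes Character vector of cluster genes (must lie in
#'   `background`).
#' @param gene_sets Named list mapping term -> annotated genes (e.g. from
#'   [read_gmt()]).
#' @param background Character vector: the gene universe (e.g. all known
#'   peroxisomal genes in the run).
#' @param alpha Adjusted-p threshold for term selection.
#' @return Tibble with one row per term: counts, `enrichment_factor`,
#'   `p_value`, `p_adjusted`, `selected` (at most one `TRUE`). The selected
#'   term name (or `NA`) is in attribute `selected_term`.
#' @export
go_enrichment <- function(genes, gene_sets, background, alpha = 0.05) {
  genes <- unique(genes)
  background <- unique(background)
  if (!all(genes %in% background)) {
    stop_pt("Cluster genes must be contained in the background.",
            "peroxitools_bad_input")
  }
  N <- length(background)
  n <- length(genes)
  res <- purrr::map_dfr(names(gene_sets), function(term) {
    set_bg <- intersect(gene_sets[[term]], background)
    dplyr::mutate(
      hypergeom_enrichment(length(intersect(genes, set_bg)), n,
                           length(set_bg), N),
      term = term, .before = 1
    )
  })
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  eligible <- res$p_adjusted < alpha
  res$selected <- FALSE
  if (any(eligible)) {
    best <- which(eligible)[which.max(res$enrichment_factor[eligible])]
    res$selected[best] <- TRUE
  }
  attr(res, "selected_term") <- if (any(res$selected)) {
    res$term[res$selected]
  } else {
    NA_character_
  }
  res
}
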