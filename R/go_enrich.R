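#' GO term over-representation by Fisher's exact test
#'
#' For each annotation term the DE set is tested against the background of
#' all genes that survived QC, with the hypergeometric upper tail
#' (one-sided over-representation, the convention of DAVID-style tools).
#' Terms reaching fewer than `min_set_size` DE genes are excluded before
#' multiple-testing correction; Bonferroni and Benjamini-Hochberg
#' corrections over the tested terms are both reported.
#'
#' @name go_enrich
NULL

#' Hypergeometric over-representation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)`: the chance of drawing at
#' least `k` term-annotated genes in a DE set of size `n` from a
#' background of `N` genes of which `K` carry the term.
#'
#' @param k DE genes carrying the term.
#' @param K Background genes carrying the term.
#' @param n DE set size.
#' @param N Background size.
#' @return The upper-tail p-value (vectorized).
#' @examples
#' fisher_enrichment(4, 5, 4, 10)  # 5/210
#' @export
fisher_enrichment <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) ||
      any(k > pmin(K, n)) || any(n > N) || any(K > N)) {
    input_error("fisher_enrichment: need 0 <= k <= min(K, n), n <= N, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment of a DE gene set
#'
#' @param de_genes Character vector of DE gene ids.
#' @param annotation data.frame `gene_id`, `term_id`, optionally
#'   `term_label`.
#' @param background Character vector of background gene ids (the universe
#'   of genes that could have been called DE); must cover `de_genes`.
#' @param min_set_size Minimum number of DE genes sharing a term for the
#'   term to be tested (default 4).
#' @return data.frame sorted by `p_fisher` (ties broken by `term_id`):
#'   `term_id`, `term_label`, `k`, `K`, `n`, `N`, `p_fisher`,
#'   `p_bonferroni` (over the `m` tested terms), `q_bh`.
#' @export
enrich_terms <- function(de_genes, annotation, background,
                         min_set_size = 4) {
  assert_columns(annotation, c("gene_id", "term_id"), "annotation table")
  de_genes <- unique(as.character(de_genes))
  background <- unique(as.character(background))
  if (length(de_genes) == 0) {
    return(data.frame(term_id = character(), term_label = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_fisher = numeric(),
                      p_bonferroni = numeric(), q_bh = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!all(de_genes %in% background)) {
    input_error("enrich_terms: %d DE gene(s) absent from the background",
                sum(!de_genes %in% background))
  }
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  ann <- ann[!duplicated(paste(ann$gene_id, ann$term_id)), , drop = FALSE]
  N <- length(background)
  n <- length(de_genes)
  K_tab <- table(ann$term_id)
  k_tab <- table(ann$term_id[ann$gene_id %in% de_genes])
  terms <- names(k_tab)[as.integer(k_tab) >= min_set_size]
  if (length(terms) == 0) {
    return(data.frame(term_id = character(), term_label = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_fisher = numeric(),
                      p_bonferroni = numeric(), q_bh = numeric(),
                      stringsAsFactors = FALSE))
  }
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  p <- fisher_enrichment(k, K, n, N)
  m <- length(terms)
  label <- if ("term_label" %in% names(ann)) {
    ann$term_label[match(terms, ann$term_id)]
  } else {
    terms
  }
  out <- data.frame(
    term_id = terms, term_label = label, k = k, K = K, n = n, N = N,
    p_fisher = p,
    p_bonferroni = pmin(1, p * m),
    q_bh = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_fisher, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
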