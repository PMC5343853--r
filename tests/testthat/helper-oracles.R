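# Independent oracles used across tests. These deliberately avoid the code
# paths they check: enumeration instead of phyper, stats::anova instead of
# the vectorized F, BFS single linkage over an all-pairs predicate matrix
# instead of the greedy union-find clusterer.

# hypergeometric upper tail P(X >= k) by full enumeration of the support
oracle_hyper_upper <- function(k, K, n, N) {
  xs <- max(0, k):min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# two-group one-way ANOVA p-value via stats::anova(lm(...))
oracle_anova_p <- function(ctl, trt) {
  d <- data.frame(y = c(ctl, trt),
                  g = factor(rep(c("c", "t"), c(length(ctl), length(trt)))))
  stats::anova(stats::lm(y ~ g, data = d))[["Pr(>F)"]][1]
}

# Spearman via Pearson on average ranks
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# all-pairs single-linkage clustering: predicate from best local alignment,
# components by breadth-first search over the adjacency matrix
oracle_cluster_membership <- function(seqs, min_identity = 0.95,
                                      min_overlap = 40) {
  n <- length(seqs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[i]), Biostrings::DNAString(seqs[j]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      ok <- Biostrings::nchar(aln) >= min_overlap &&
        Biostrings::pid(aln) / 100 >= min_identity
      adj[i, j] <- adj[j, i] <- ok
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# normalize a membership vector so labelings can be compared as partitions
canonical_partition <- function(m) {
  match(m, unique(m))
}

# tiny EST data.frame builder
est_df <- function(seqs, library = "bacterial", ids = NULL) {
  data.frame(
    id = ids %||% sprintf("e%02d", seq_along(seqs)),
    sequence = seqs,
    library = rep_len(library, length(seqs)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic random DNA for fixtures
rand_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# introduce k substitutions into a sequence
substitute_at <- function(seq, positions, seed = 1) {
  chars <- strsplit(seq, "")[[1]]
  withr::with_seed(seed, {
    for (p in positions) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
  })
  paste(chars, collapse = "")
}
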