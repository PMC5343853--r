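#' EST library analysis: filtering, contig clustering and the two-library
#' enrichment rule
#'
#' ESTs from a bacterial-primed and a viral-primed cDNA library are length
#' filtered, clustered into contigs, and each contig's library composition
#' is tested against a frequency rule: a contig whose members come at more
#' than 75\% from one library (with at least `min_total` members) is called
#' enriched for that library's stimulus.
#'
#' @name est_library
NULL

#' Read an EST FASTA with per-record library labels
#'
#' The library is taken from a `lib=<label>` key in the description line;
#' alternatively a sidecar table mapping `id` to `library` can be given.
#'
#' @param path FASTA file.
#' @param library_map Optional data.frame with columns `id`, `library` used
#'   when the descriptions carry no `lib=` key.
#' @return data.frame with `id`, `sequence`, `library`, `length`.
#' @export
read_est_fasta <- function(path, library_map = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  full <- names(x)
  id <- sub("\\s.*$", "", full)
  lib <- rep(NA_character_, length(x))
  has_key <- grepl("lib=", full, fixed = TRUE)
  lib[has_key] <- sub("^.*lib=([^ ]+).*$", "\\1", full[has_key])
  if (!is.null(library_map)) {
    assert_columns(library_map, c("id", "library"), "library map")
    m <- match(id, library_map$id)
    lib[is.na(lib)] <- library_map$library[m[is.na(lib)]]
  }
  if (anyNA(lib)) {
    input_error("read_est_fasta: %d record(s) have no library label",
                sum(is.na(lib)))
  }
  data.frame(id = id, sequence = as.character(x), library = lib,
             length = Biostrings::width(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Retain ESTs strictly longer than a minimum length
#'
#' @param records EST data.frame with a `sequence` column (a `length`
#'   column is recomputed if absent).
#' @param min_len Minimum length in nucleotides; records with
#'   `length > min_len` (strict) are kept, preserving order.
#' @return The retained subset.
#' @examples
#' df <- data.frame(id = c("a", "b", "c"),
#'                  sequence = strrep("A", c(99, 100, 150)),
#'                  library = "bacterial")
#' length_filter(df)$id  # only "c"
#' @export
length_filter <- function(records, min_len = 100) {
  if (nrow(records) == 0) {
    return(records)
  }
  assert_columns(records, "sequence", "EST table")
  len <- nchar(records$sequence)
  out <- records[len > min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shared k-mers as a cheap candidate filter before alignment; two ESTs from
# the same transcript at <= 2% divergence each share many exact 16-mers,
# unrelated random sequences essentially never do
#' @noRd
kmer_candidate_pairs <- function(seqs, k = 16L) {
  n <- length(seqs)
  per_seq <- lapply(seq_len(n), function(i) {
    L <- nchar(seqs[i])
    if (L < k) return(character(0))
    starts <- seq.int(1L, L - k + 1L)
    unique(substring(seqs[i], starts, starts + k - 1L))
  })
  kmer <- unlist(per_seq, use.names = FALSE)
  est <- rep.int(seq_len(n), lengths(per_seq))
  hits <- split(est, kmer)
  hits <- hits[lengths(hits) > 1]
  codes <- unlist(lapply(hits, function(h) {
    m <- length(h)
    a <- rep(h, times = m)
    b <- rep(h, each = m)
    sel <- a < b
    (a[sel] - 1) * n + b[sel]   # encode ordered pair as one number
  }), use.names = FALSE)
  codes <- unique(codes)
  if (length(codes) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  cbind((codes - 1) %/% n + 1L, (codes - 1) %% n + 1L)
}

# best local alignment identity and overlap for given index pairs
#' @noRd
pair_alignment_ok <- function(seqs, pairs, min_identity, min_overlap) {
  if (nrow(pairs) == 0) {
    return(logical(0))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  ok <- logical(nrow(pairs))
  subjects <- unique(pairs[, 2])
  xs <- Biostrings::DNAStringSet(seqs)
  for (j in subjects) {
    rows <- which(pairs[, 2] == j)
    aln <- Biostrings::pairwiseAlignment(
      xs[pairs[rows, 1]], xs[[j]], type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2
    )
    width <- Biostrings::nchar(aln)
    ident <- Biostrings::pid(aln) / 100
    ok[rows] <- width >= min_overlap & ident >= min_identity
  }
  ok
}

#' @noRd
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), function(i) as.integer(find(i)), 1L)
  match(roots, unique(roots))
}

#' Cluster ESTs into contigs by single linkage on local alignment
#'
#' A simplified stand-in for a full assembler: two ESTs are linked when
#' their best local alignment reaches `min_identity` over at least
#' `min_overlap` nucleotides, and contigs are the connected components
#' (single linkage) of that relation. No consensus sequence is built — the
#' downstream frequency statistic needs membership only. A precomputed
#' assignment (e.g. from an external assembler) can be supplied instead via
#' `assignments`.
#'
#' Contig ids are assigned in input order of each cluster's first member,
#' which makes the output deterministic.
#'
#' @param records EST data.frame (`id`, `sequence`, `library`).
#' @param min_identity Minimum alignment identity (proportion).
#' @param min_overlap Minimum alignment length in nucleotides.
#' @param assignments Optional data.frame (`est_id`, `contig_id`) taking
#'   the place of the built-in clusterer.
#' @param prefilter Use the shared k-mer candidate filter (`TRUE`, the
#'   default) or align all pairs (used by the test oracle).
#' @return `records` with a `contig_id` column appended.
#' @export
cluster_ests <- function(records, min_identity = 0.95, min_overlap = 40,
                         assignments = NULL, prefilter = TRUE) {
  assert_columns(records, c("id", "sequence", "library"), "EST table")
  if (nrow(records) == 0) {
    input_error("cluster_ests: no records to cluster")
  }
  if (!is.null(assignments)) {
    assert_columns(assignments, c("est_id", "contig_id"), "cluster assignment")
    m <- match(records$id, assignments$est_id)
    if (anyNA(m)) {
      input_error("cluster_ests: %d record(s) missing from the supplied assignment",
                  sum(is.na(m)))
    }
    records$contig_id <- assignments$contig_id[m]
    return(records)
  }
  n <- nrow(records)
  if (prefilter) {
    pairs <- kmer_candidate_pairs(records$sequence)
  } else {
    pairs <- t(utils::combn(n, 2))
  }
  # orient as (smaller index = pattern, larger = subject)
  if (nrow(pairs) > 0) {
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]),
                   pmax(pairs[, 1], pairs[, 2]))
  }
  ok <- pair_alignment_ok(records$sequence, pairs, min_identity, min_overlap)
  comp <- union_find_components(n, pairs[ok, , drop = FALSE])
  records$contig_id <- sprintf("CTG%05d", comp)
  records
}

#' Per-contig library frequencies
#'
#' @param clustered Output of [cluster_ests()] (needs `contig_id`,
#'   `library`).
#' @return data.frame per contig: `contig_id`, `n_bacterial`, `n_viral`,
#'   `total`, `bacterial_fraction`, plus `member_ids` (comma separated).
#' @examples
#' df <- data.frame(id = c("a", "b", "c"), sequence = "ACGT",
#'                  library = c("bacterial", "bacterial", "viral"),
#'                  contig_id = "CTG00001")
#' library_frequency(df)$bacterial_fraction  # 2/3
#' @export
library_frequency <- function(clustered) {
  assert_columns(clustered, c("id", "library", "contig_id"), "clustered ESTs")
  if (nrow(clustered) == 0) {
    input_error("library_frequency: empty cluster table")
  }
  sp <- split(clustered, clustered$contig_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    nb <- sum(g$library == "bacterial")
    nv <- sum(g$library == "viral")
    data.frame(
      contig_id = g$contig_id[1],
      n_bacterial = nb,
      n_viral = nv,
      total = nb + nv,
      bacterial_fraction = nb / (nb + nv),
      member_ids = paste(g$id, collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call library enrichment for contigs
#'
#' A contig is enriched for a library's stimulus when strictly more than
#' `threshold` of its members come from that library and the contig has at
#' least `min_total` members. A 3:1 contig sits exactly at 75\% and is
#' therefore not called.
#'
#' @param freq Output of [library_frequency()] (or any data.frame with
#'   `n_bacterial` and `n_viral`).
#' @param threshold Strict enrichment fraction (default 0.75).
#' @param min_total Minimum contig size for a call (default 4); tiny
#'   contigs trivially exceed any fraction and are left uncalled.
#' @return `freq` with a `call` column in
#'   `{bacterial_enriched, viral_enriched, not_enriched}`.
#' @examples
#' enrichment_call(data.frame(n_bacterial = c(3, 36, 4),
#'                            n_viral = c(1, 6, 0)))$call
#' @export
enrichment_call <- function(freq, threshold = 0.75, min_total = 4) {
  assert_columns(freq, c("n_bacterial", "n_viral"), "frequency table")
  total <- freq$n_bacterial + freq$n_viral
  frac_b <- freq$n_bacterial / total
  call <- rep("not_enriched", nrow(freq))
  call[total >= min_total & frac_b > threshold] <- "bacterial_enriched"
  call[total >= min_total & (1 - frac_b) > threshold] <- "viral_enriched"
  freq$call <- call
  freq
}

#' Tabulate GO categories per library
#'
#' Counts contigs per functional category for each library (a contig is
#' attributed to the library providing the majority of its members; exact
#' ties count toward both). Contigs without a category fall into an
#' explicit `"unannotated"` bucket; percentages are computed over annotated
#' contigs only.
#'
#' @param contigs data.frame with `contig_id`, `n_bacterial`, `n_viral`.
#' @param categories data.frame with `contig_id`, `category` (NA or
#'   missing contigs count as unannotated).
#' @return data.frame: `library`, `category`, `count`, `percent` (of that
#'   library's annotated contigs; NA for the unannotated bucket).
#' @export
go_tabulate <- function(contigs, categories) {
  assert_columns(contigs, c("contig_id", "n_bacterial", "n_viral"),
                 "contig table")
  assert_columns(categories, c("contig_id", "category"), "category table")
  cat_of <- categories$category[match(contigs$contig_id, categories$contig_id)]
  cat_of[!is.na(cat_of) & !nzchar(cat_of)] <- NA

  rows <- list()
  for (lib in c("bacterial", "viral")) {
    own <- if (lib == "bacterial") {
      contigs$n_bacterial >= contigs$n_viral
    } else {
      contigs$n_viral >= contigs$n_bacterial
    }
    cats <- cat_of[own]
    annotated <- cats[!is.na(cats)]
    if (length(annotated) > 0) {
      tab <- table(annotated)
      rows[[length(rows) + 1]] <- data.frame(
        library = lib,
        category = names(tab),
        count = as.integer(tab),
        percent = 100 * as.integer(tab) / length(annotated),
        stringsAsFactors = FALSE
      )
    }
    n_un <- sum(is.na(cats))
    if (n_un > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        library = lib, category = "unannotated", count = n_un,
        percent = NA_real_, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(library = character(), category = character(),
                      count = integer(), percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$library, -out$count, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full contig report for two EST libraries
#'
#' Convenience wrapper: length filter, clustering, frequency analysis and
#' enrichment calls in one step.
#'
#' @inheritParams cluster_ests
#' @inheritParams enrichment_call
#' @param min_len Minimum EST length (strict).
#' @return A list with `ests` (retained, with `contig_id`) and `contigs`
#'   (frequency table with enrichment calls).
#' @export
contig_report <- function(records, min_len = 100, min_identity = 0.95,
                          min_overlap = 40, threshold = 0.75, min_total = 4,
                          assignments = NULL) {
  kept <- length_filter(records, min_len)
  clustered <- cluster_ests(kept, min_identity, min_overlap,
                            assignments = assignments)
  contigs <- enrichment_call(library_frequency(clustered),
                             threshold = threshold, min_total = min_total)
  list(ests = clustered, contigs = contigs)
}
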