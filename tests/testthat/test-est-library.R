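test_that("length filter is strictly greater-than", {
  df <- est_df(c(strrep("A", 99), strrep("C", 100), strrep("G", 150)))
  kept <- length_filter(df, min_len = 100)
  expect_equal(kept$id, "e03")
  # min_len = 0 is the identity on non-empty sequences
  expect_equal(length_filter(df, min_len = 0), df, ignore_attr = TRUE)
  # empty input is an empty output, not an error
  expect_equal(nrow(length_filter(df[0, ], 100)), 0)
})

test_that("length filter removes exactly the generator's short ESTs", {
  cfg <- synth_config(n_transcripts = 6, n_est_per_library = 150,
                      short_fraction = 0.1, seed = 17)
  ests <- generate_est_libraries(cfg)$ests
  n_short <- sum(ests$length <= 100)
  expect_gt(n_short, 0)
  expect_equal(nrow(length_filter(ests, 100)), nrow(ests) - n_short)
})

test_that("clustering groups identical and near-identical sequences", {
  s <- rand_seq(500, seed = 1)
  two <- cluster_ests(est_df(c(s, s)))
  expect_equal(length(unique(two$contig_id)), 1)

  unrelated <- cluster_ests(est_df(c(rand_seq(300, 2), rand_seq(300, 3))))
  expect_equal(length(unique(unrelated$contig_id)), 2)
})

test_that("clustering matches the brute-force all-pairs oracle", {
  # family of 5 at <= 2% mutual divergence plus 3 unrelated sequences
  anc <- rand_seq(400, seed = 10)
  family <- withr::with_seed(42, vapply(1:5, function(i) {
    substitute_at(anc, sample(400, 4), seed = i)  # 1% each, <= 2% pairwise
  }, ""))
  seqs <- c(family, rand_seq(350, 20), rand_seq(350, 21), rand_seq(350, 22))
  got <- cluster_ests(est_df(seqs))
  sizes <- sort(table(got$contig_id), decreasing = TRUE)
  expect_equal(unname(as.integer(sizes)), c(5, 1, 1, 1))

  oracle <- oracle_cluster_membership(seqs)
  expect_equal(canonical_partition(match(got$contig_id, unique(got$contig_id))),
               canonical_partition(oracle))
})

test_that("clusterer with prefilter agrees with oracle on generated libraries", {
  cfg <- synth_config(n_transcripts = 6, n_est_per_library = 20, seed = 31)
  ests <- length_filter(generate_est_libraries(cfg)$ests)
  got <- cluster_ests(ests)
  oracle <- oracle_cluster_membership(ests$sequence)
  expect_equal(canonical_partition(match(got$contig_id, unique(got$contig_id))),
               canonical_partition(oracle))
  # partition property: cluster sizes sum to retained ESTs
  expect_equal(sum(table(got$contig_id)), nrow(ests))
})

test_that("precomputed assignments can replace the clusterer", {
  df <- est_df(c("ACGTACGTAA", "ACGTACGTAA", "TTTTGGGGCC"))
  asg <- data.frame(est_id = df$id, contig_id = c("x", "x", "y"))
  got <- cluster_ests(df, assignments = asg)
  expect_equal(got$contig_id, c("x", "x", "y"))
  expect_error(cluster_ests(df, assignments = asg[1:2, ]), "missing")
})

test_that("library frequencies are exact counts and fractions", {
  df <- data.frame(
    id = sprintf("e%d", 1:6),
    library = c(rep("bacterial", 4), rep("viral", 2)),
    contig_id = c(rep("c1", 5), "c2"),
    stringsAsFactors = FALSE
  )
  freq <- library_frequency(df)
  expect_equal(freq$n_bacterial, c(4, 0))
  expect_equal(freq$n_viral, c(1, 1))
  expect_equal(freq$bacterial_fraction, c(0.8, 0))
  expect_equal(freq$total, c(5, 1))
})

test_that("the >75% enrichment rule is strict and size-gated", {
  freq <- data.frame(
    n_bacterial = c(3, 36, 4, 0, 2, 1),
    n_viral     = c(1,  6, 0, 4, 2, 0)
  )
  calls <- enrichment_call(freq)$call
  # 3:1 is exactly 75% and must NOT be called under the strict rule
  expect_equal(calls[1], "not_enriched")
  # 36:6 is 85.7% of a large contig
  expect_equal(calls[2], "bacterial_enriched")
  expect_equal(calls[3], "bacterial_enriched")
  expect_equal(calls[4], "viral_enriched")
  expect_equal(calls[5], "not_enriched")    # 50:50
  expect_equal(calls[6], "not_enriched")    # singleton below min_total
  expect_equal(library_frequency(data.frame(
    id = 1:42, library = rep(c("bacterial", "viral"), c(36, 6)),
    contig_id = "c"))$bacterial_fraction, 36 / 42)
})

test_that("enrichment calls are symmetric under library swap", {
  withr::with_seed(8, {
    freq <- data.frame(n_bacterial = rpois(50, 5), n_viral = rpois(50, 5))
  })
  freq <- freq[freq$n_bacterial + freq$n_viral > 0, ]
  fwd <- enrichment_call(freq)$call
  swapped <- enrichment_call(
    data.frame(n_bacterial = freq$n_viral, n_viral = freq$n_bacterial))$call
  map <- c(bacterial_enriched = "viral_enriched",
           viral_enriched = "bacterial_enriched",
           not_enriched = "not_enriched")
  expect_equal(unname(map[fwd]), swapped)
})

test_that("GO tabulation counts categories and an unannotated bucket", {
  contigs <- data.frame(contig_id = c("c1", "c2", "c3", "c4"),
                        n_bacterial = c(2, 3, 1, 2), n_viral = c(0, 1, 0, 0))
  cats <- data.frame(contig_id = c("c1", "c2", "c3"),
                     category = c("A", "A", "B"))
  tab <- go_tabulate(contigs, cats)
  bact <- tab[tab$library == "bacterial", ]
  expect_equal(bact$count[bact$category == "A"], 2L)
  expect_equal(bact$percent[bact$category == "A"], 100 * 2 / 3)
  expect_equal(bact$count[bact$category == "unannotated"], 1L)
  expect_true(is.na(bact$percent[bact$category == "unannotated"]))
  # percentages over annotated contigs sum to 100
  expect_equal(sum(bact$percent, na.rm = TRUE), 100)

  empty <- go_tabulate(contigs, cats[0, ])
  expect_true(all(empty$category == "unannotated"))
})

test_that("a planted category mix is recovered exactly", {
  withr::with_seed(5, {
    n <- 100
    mix <- sample(rep(c("metabolism", "transport", "signalling", NA),
                      c(24, 15, 11, 50)))
  })
  contigs <- data.frame(contig_id = sprintf("c%03d", 1:100),
                        n_bacterial = 1, n_viral = 0)
  cats <- data.frame(contig_id = contigs$contig_id, category = mix)
  tab <- go_tabulate(contigs, cats)
  bact <- tab[tab$library == "bacterial", ]
  expect_equal(bact$count[bact$category == "metabolism"], 24L)
  expect_equal(bact$percent[bact$category == "metabolism"], 100 * 24 / 50)
  expect_equal(bact$count[bact$category == "transport"], 15L)
  expect_equal(bact$count[bact$category == "signalling"], 11L)
})

test_that("EST FASTA round-trips with library labels", {
  cfg <- synth_config(n_transcripts = 4, n_est_per_library = 10, seed = 12)
  ests <- generate_est_libraries(cfg)$ests
  f <- withr::local_tempfile(fileext = ".fa")
  write_est_fasta(ests, f)
  back <- read_est_fasta(f)
  expect_equal(back$id, ests$id)
  expect_equal(back$sequence, ests$sequence)
  expect_equal(back$library, ests$library)
  expect_equal(back$length, nchar(ests$sequence))
})
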