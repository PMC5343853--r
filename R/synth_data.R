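#' Synthetic data generators
#'
#' These generators emulate the three data types the pipeline consumes —
#' two PAMP-primed EST libraries, a single-channel oligonucleotide array
#' experiment, and an RT-qPCR plate — with ground-truth tables written
#' alongside the data so every downstream stage can be scored against the
#' plant. All randomness is driven by `config$seed`; a fixed seed yields
#' byte-identical output.
#'
#' @name synth_data
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' @noRd
mutate_dna <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) {
    return(seq)
  }
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate two PAMP-primed EST libraries with planted enrichment
#'
#' Simulates single-pass cDNA reads from a bacterial-primed and a
#' viral-primed library. Each transcript has a random ancestor sequence;
#' ESTs are 3'-biased suffixes of the ancestor carrying at most
#' `mutation_rate` substitutions, so sibling ESTs stay above the default
#' clustering identity threshold. Planted library-enriched transcripts draw
#' each EST from their home library with probability
#' `enrichment_strength`, giving an expected home-library fraction above
#' the 75\% enrichment rule; all other transcripts are sampled evenly.
#'
#' @param config A [synth_config()] object.
#' @return A list with elements:
#' \describe{
#'   \item{ests}{data.frame with `id`, `sequence`, `library`, `length`
#'     and the ground-truth `transcript_id` (ignored by the pipeline).}
#'   \item{truth}{data.frame per transcript: `transcript_id`,
#'     `enriched_in` (`"bacterial"`, `"viral"` or `"none"`) and realized
#'     EST counts per library.}
#' }
#' @examples
#' out <- generate_est_libraries(synth_config(n_transcripts = 5,
#'                                            n_est_per_library = 20))
#' table(out$ests$library)
#' @export
generate_est_libraries <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::local_seed(config$seed)

  n_tx <- config$n_transcripts
  tx_ids <- sprintf("TX%04d", seq_len(n_tx))
  anc_len <- config$est_length_range[2]
  ancestors <- vapply(seq_len(n_tx), function(i) random_dna(anc_len), "")

  n_enriched <- floor(config$enriched_fraction * n_tx)
  enriched_in <- rep("none", n_tx)
  if (n_enriched > 0) {
    idx <- sample.int(n_tx, n_enriched)
    enriched_in[idx] <- rep_len(c("bacterial", "viral"), n_enriched)
  }

  abundance <- stats::rlnorm(n_tx, meanlog = 0, sdlog = 0.3)
  s <- config$enrichment_strength
  lib_weight <- function(lib) {
    w <- ifelse(enriched_in == lib, s, ifelse(enriched_in == "none", 0.5, 1 - s))
    abundance * w
  }

  make_lib <- function(lib, offset) {
    tx <- sample.int(n_tx, config$n_est_per_library, replace = TRUE,
                     prob = lib_weight(lib))
    short <- stats::runif(length(tx)) < config$short_fraction
    len <- ifelse(
      short,
      sample(60:100, length(tx), replace = TRUE),
      sample(config$est_length_range[1]:config$est_length_range[2],
             length(tx), replace = TRUE)
    )
    seqs <- vapply(seq_along(tx), function(i) {
      suffix <- substr(ancestors[tx[i]], anc_len - len[i] + 1L, anc_len)
      mutate_dna(suffix, stats::runif(1, 0, config$mutation_rate))
    }, "")
    data.frame(
      id = sprintf("EST%06d", offset + seq_along(tx)),
      sequence = seqs,
      library = lib,
      length = nchar(seqs),
      transcript_id = tx_ids[tx],
      stringsAsFactors = FALSE
    )
  }

  ests <- rbind(
    make_lib("bacterial", 0L),
    make_lib("viral", config$n_est_per_library)
  )

  counts <- table(factor(ests$transcript_id, levels = tx_ids), ests$library)
  truth <- data.frame(
    transcript_id = tx_ids,
    enriched_in = enriched_in,
    n_est_bacterial = as.integer(counts[, "bacterial"]),
    n_est_viral = as.integer(counts[, "viral"]),
    stringsAsFactors = FALSE
  )
  list(ests = ests, truth = truth)
}

#' Generate a synthetic single-channel array experiment
#'
#' Builds a spot-level scan table for `n_targets` targets across the
#' configured conditions. Annotated targets carry `n_probes_per_target`
#' probes, the rest a single probe. True log2 signal per spot is the
#' target's baseline plus the planted condition effect plus N(0, noise_sd)
#' noise; the linear signal then receives an additive per-spot background
#' which is reported in the `SB` column (so background subtraction is
#' exact, as with a well-behaved feature-extraction step). Spike-in
#' controls have fixed, condition-independent levels.
#'
#' Planted differentially expressed targets are split into a set common to
#' all treatments and sets exclusive to one treatment, controlled by
#' `common_fraction`; effect magnitudes are log-uniform on `fc_range` with
#' sign up with probability `prob_up`.
#'
#' @param config A [synth_config()] object.
#' @return A list with elements `spots` (array_id, probe_id, target_id,
#'   SI, SB, SDI, SDB), `design` (array_id, condition, replicate),
#'   `probesets` (target_id, probe_id, probe_index, annotated),
#'   `truth` (target_id, condition, true_log2fc, exclusive) and
#'   `spikes` (target_id, true_log2).
#' @examples
#' cfg <- synth_config(n_targets = 20, n_arrays_per_condition = 2)
#' ex <- generate_array_experiment(cfg)
#' head(ex$spots)
#' @export
generate_array_experiment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::local_seed(config$seed + 1L)

  n_tg <- config$n_targets
  target_ids <- sprintf("G%05d", seq_len(n_tg))
  treatments <- setdiff(config$conditions, "control")

  annotated <- stats::runif(n_tg) >= config$single_probe_fraction
  n_probes <- ifelse(annotated, config$n_probes_per_target, 1L)
  probesets <- data.frame(
    target_id = rep(target_ids, n_probes),
    probe_index = unlist(lapply(n_probes, seq_len)),
    annotated = rep(annotated, n_probes),
    stringsAsFactors = FALSE
  )
  probesets$probe_id <- sprintf("%s_p%d", probesets$target_id,
                                probesets$probe_index)
  probesets <- probesets[, c("target_id", "probe_id", "probe_index", "annotated")]

  # planted effects: a common core shared by every treatment plus
  # treatment-exclusive sets
  n_de <- round(config$de_fraction_per_condition * n_tg)
  n_common <- round(config$common_fraction * n_de)
  n_excl <- n_de - n_common
  pool <- sample(target_ids, n_common + n_excl * length(treatments))
  common_ids <- pool[seq_len(n_common)]
  rest <- setdiff(pool, common_ids)
  truth <- NULL
  draw_effect <- function(n) {
    mag <- exp(stats::runif(n, log(config$fc_range[1]), log(config$fc_range[2])))
    sgn <- ifelse(stats::runif(n) < config$prob_up, 1, -1)
    sgn * log2(mag)
  }
  for (i in seq_along(treatments)) {
    excl_ids <- rest[seq_len(n_excl) + (i - 1L) * n_excl]
    ids <- c(common_ids, excl_ids)
    if (length(ids) > 0) {
      truth <- rbind(truth, data.frame(
        target_id = ids,
        condition = treatments[i],
        true_log2fc = draw_effect(length(ids)),
        exclusive = c(rep(FALSE, length(common_ids)),
                      rep(TRUE, length(excl_ids))),
        stringsAsFactors = FALSE
      ))
    }
  }
  if (is.null(truth)) {
    truth <- data.frame(target_id = character(), condition = character(),
                        true_log2fc = numeric(), exclusive = logical(),
                        stringsAsFactors = FALSE)
  }

  design <- data.frame(
    array_id = sprintf("A%02d", seq_len(length(config$conditions) *
                                          config$n_arrays_per_condition)),
    condition = rep(config$conditions, each = config$n_arrays_per_condition),
    replicate = rep(seq_len(config$n_arrays_per_condition),
                    times = length(config$conditions)),
    stringsAsFactors = FALSE
  )

  baseline <- stats::rnorm(n_tg, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  names(baseline) <- target_ids
  effect <- matrix(0, nrow = n_tg, ncol = length(config$conditions),
                   dimnames = list(target_ids, config$conditions))
  if (nrow(truth) > 0) {
    effect[cbind(truth$target_id, truth$condition)] <- truth$true_log2fc
  }

  # spike-ins: single probe, fixed level across all conditions
  spike_ids <- character(0)
  spike_truth <- data.frame(target_id = character(), true_log2 = numeric(),
                            stringsAsFactors = FALSE)
  if (config$spike_in_count > 0) {
    spike_ids <- sprintf("SPIKE%02d", seq_len(config$spike_in_count))
    spike_levels <- seq(6, 14, length.out = config$spike_in_count)
    spike_truth <- data.frame(target_id = spike_ids, true_log2 = spike_levels,
                              stringsAsFactors = FALSE)
    probesets <- rbind(probesets, data.frame(
      target_id = spike_ids,
      probe_id = paste0(spike_ids, "_p1"),
      probe_index = 1L,
      annotated = FALSE,
      stringsAsFactors = FALSE
    ))
  }

  probe_target <- probesets$target_id
  n_spot_per_array <- nrow(probesets)
  spots <- do.call(rbind, lapply(seq_len(nrow(design)), function(a) {
    cond <- design$condition[a]
    is_spike <- probe_target %in% spike_ids
    mu <- numeric(n_spot_per_array)
    mu[is_spike] <- spike_truth$true_log2[
      match(probe_target[is_spike], spike_truth$target_id)]
    mu[!is_spike] <- baseline[probe_target[!is_spike]] +
      effect[probe_target[!is_spike], cond]
    x <- mu + stats::rnorm(n_spot_per_array, 0, config$noise_sd)
    signal <- 2^x
    bg <- pmax(stats::rnorm(n_spot_per_array, config$background_mean,
                            config$background_sd), 0)
    data.frame(
      array_id = design$array_id[a],
      probe_id = probesets$probe_id,
      target_id = probe_target,
      SI = signal + bg,
      SB = bg,
      SDI = 0.05 * (signal + bg) + 2,
      SDB = 0.2 * bg + 1,
      stringsAsFactors = FALSE
    )
  }))
  rownames(spots) <- NULL

  list(spots = spots, design = design, probesets = probesets,
       truth = truth, spikes = spike_truth)
}

#' Generate a synthetic qPCR quantification-cycle table
#'
#' Builds Cq values for a panel of genes drawn from the array truth table
#' (plus the housekeeping reference gene) such that Pfaffl
#' efficiency-corrected quantification recovers each planted fold change —
#' exactly when `noise_sd = 0`. A planted log2 fold change `f` in a
#' treatment shifts that gene's Cq by `-f / log2(E)` cycles relative to
#' control; the reference gene is flat across conditions.
#'
#' @param config A [synth_config()] object.
#' @param truth DE truth table from [generate_array_experiment()]
#'   (`target_id`, `condition`, `true_log2fc`).
#' @return A list with `cq` (gene, sample_id, condition, Cq, efficiency)
#'   and `truth` (gene, condition, true_log2fc for every gene/treatment
#'   pair, zero where no effect was planted).
#' @examples
#' cfg <- synth_config(n_targets = 50, noise_sd = 0)
#' ex <- generate_array_experiment(cfg)
#' q <- generate_qpcr(cfg, ex$truth)
#' head(q$cq)
#' @export
generate_qpcr <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  if (missing(truth) || is.null(truth)) {
    input_error("generate_qpcr: a DE truth table is required")
  }
  assert_columns(truth, c("target_id", "condition", "true_log2fc"),
                 "qPCR truth table")
  withr::local_seed(config$seed + 2L)

  treatments <- setdiff(config$conditions, "control")
  de_genes <- unique(truth$target_id)
  genes <- de_genes[seq_len(min(length(de_genes), config$n_qpcr_genes))]
  if (length(genes) == 0) {
    input_error("generate_qpcr: truth table contains no planted genes")
  }

  gene_truth <- expand.grid(gene = genes, condition = treatments,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(truth$target_id, truth$condition)
  hit <- match(paste(gene_truth$gene, gene_truth$condition), key)
  gene_truth$true_log2fc <- ifelse(is.na(hit), 0, truth$true_log2fc[hit])

  E <- config$efficiency
  base_cq <- stats::runif(length(genes), 18, 26)
  names(base_cq) <- genes
  ref_cq <- 15

  samples <- expand.grid(
    condition = config$conditions,
    replicate = seq_len(config$n_arrays_per_condition),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  samples$sample_id <- sprintf("S_%s_%d", samples$condition, samples$replicate)

  rows <- lapply(seq_len(nrow(samples)), function(i) {
    cond <- samples$condition[i]
    shift <- numeric(length(genes))
    if (cond != "control") {
      m <- match(paste(genes, cond),
                 paste(gene_truth$gene, gene_truth$condition))
      shift <- gene_truth$true_log2fc[m] / log2(E)
    }
    data.frame(
      gene = c(genes, config$reference_gene),
      sample_id = samples$sample_id[i],
      condition = cond,
      Cq = c(base_cq - shift, ref_cq) +
        stats::rnorm(length(genes) + 1, 0, config$noise_sd),
      efficiency = E,
      stringsAsFactors = FALSE
    )
  })
  cq <- do.call(rbind, rows)
  rownames(cq) <- NULL
  list(cq = cq, truth = gene_truth)
}

#' Write synthetic EST libraries as FASTA
#'
#' The library label is carried in the description line as `lib=<library>`,
#' the format [read_est_fasta()] parses.
#'
#' @param ests EST data.frame from [generate_est_libraries()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_est_fasta <- function(ests, path) {
  assert_columns(ests, c("id", "sequence", "library"), "EST table")
  x <- Biostrings::DNAStringSet(ests$sequence)
  names(x) <- sprintf("%s lib=%s", ests$id, ests$library)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Generate a synthetic GO annotation with one planted enriched term
#'
#' Assigns each background gene one to three random terms, then plants a
#' term that is strongly over-represented in the supplied DE set, so that
#' enrichment testing has a known positive.
#'
#' @param background Character vector of background gene ids.
#' @param de_genes Character vector of DE gene ids (subset of background).
#' @param n_terms Number of random terms.
#' @param planted_term Id of the planted enriched term.
#' @param planted_k Number of DE genes given the planted term.
#' @param planted_bg Number of additional non-DE background genes given
#'   the planted term.
#' @param seed Integer seed.
#' @return data.frame `gene_id`, `term_id`, `term_label`.
#' @export
generate_go_annotation <- function(background, de_genes, n_terms = 20,
                                   planted_term = "GO:PLANTED",
                                   planted_k = min(10, length(de_genes)),
                                   planted_bg = 5, seed = 1L) {
  if (!all(de_genes %in% background)) {
    input_error("generate_go_annotation: de_genes must be a subset of background")
  }
  withr::local_seed(seed)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  n_per_gene <- sample(1:3, length(background), replace = TRUE)
  ann <- data.frame(
    gene_id = rep(background, n_per_gene),
    term_id = unlist(lapply(n_per_gene, function(k) sample(terms, k))),
    stringsAsFactors = FALSE
  )
  non_de <- setdiff(background, de_genes)
  planted <- data.frame(
    gene_id = c(sample(de_genes, planted_k),
                sample(non_de, min(planted_bg, length(non_de)))),
    term_id = planted_term,
    stringsAsFactors = FALSE
  )
  out <- rbind(ann, planted)
  out <- out[!duplicated(paste(out$gene_id, out$term_id)), , drop = FALSE]
  out$term_label <- out$term_id
  rownames(out) <- NULL
  out
}
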