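#' Configuration for the synthetic-data generators
#'
#' Builds a validated configuration object shared by
#' [generate_est_libraries()], [generate_array_experiment()] and
#' [generate_qpcr()]. Defaults describe a two-library EST experiment and a
#' three-condition (control / LPS / PGN) single-channel oligonucleotide
#' array study with triplicate probes per annotated target, additive
#' background on the linear scale and log-normal signal on the log2 scale.
#'
#' @param n_transcripts Number of distinct transcripts behind the EST
#'   libraries (each gets its own random ancestor sequence).
#' @param n_est_per_library ESTs sampled per library (bacterial and viral).
#' @param enriched_fraction Fraction of transcripts planted as
#'   library-enriched (split evenly between the two libraries).
#' @param enrichment_strength Probability that an EST of a planted-enriched
#'   transcript is drawn from its home library; must exceed 0.75 for the
#'   enrichment rule to recover the plant in expectation.
#' @param est_length_range Closed interval of EST lengths in nucleotides;
#'   ESTs are 3'-biased suffixes of their transcript's ancestor.
#' @param short_fraction Fraction of ESTs truncated to 60--100 nt so the
#'   length filter has something to remove.
#' @param mutation_rate Maximum per-EST substitution rate relative to the
#'   ancestor (each EST draws its own rate uniformly below this), chosen so
#'   that sibling ESTs stay above the clusterer's 95\% identity threshold.
#' @param n_targets Number of targets represented on the synthetic array.
#' @param n_arrays_per_condition Arrays (biological replicates) per condition.
#' @param conditions Condition labels; the first is the reference (control).
#' @param n_probes_per_target Probes per annotated target (default 3).
#' @param single_probe_fraction Fraction of targets represented by a single
#'   probe (unannotated ESTs on the real platform have one probe).
#' @param de_fraction_per_condition Fraction of targets planted as
#'   differentially expressed in each treatment condition.
#' @param common_fraction Of each treatment's planted targets, the fraction
#'   shared with the other treatment (the rest are condition-exclusive).
#' @param fc_range Interval of planted linear fold-change magnitudes
#'   (log-uniform draw); lower bound must exceed 1.
#' @param prob_up Probability that a planted effect is an induction rather
#'   than a repression.
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2 expression
#'   distribution across targets.
#' @param noise_sd Per-spot (and per-Cq) noise standard deviation in log2
#'   units / cycles. Zero gives an exactly recoverable experiment.
#' @param background_mean,background_sd Additive spot background on the
#'   linear intensity scale.
#' @param spike_in_count Number of condition-independent spike-in controls.
#' @param n_qpcr_genes Number of genes carried into the synthetic qPCR table.
#' @param efficiency Amplification efficiency per cycle used for synthetic
#'   qPCR records, in (1, 2].
#' @param reference_gene Name of the housekeeping reference gene.
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#'
#' @return An object of class `synth_config` (a validated named list).
#' @examples
#' cfg <- synth_config(n_transcripts = 10, n_est_per_library = 50, seed = 1)
#' @export
synth_config <- function(n_transcripts = 30,
                         n_est_per_library = 300,
                         enriched_fraction = 0.4,
                         enrichment_strength = 0.9,
                         est_length_range = c(250L, 600L),
                         short_fraction = 0.05,
                         mutation_rate = 0.02,
                         n_targets = 2000,
                         n_arrays_per_condition = 4,
                         conditions = c("control", "LPS", "PGN"),
                         n_probes_per_target = 3,
                         single_probe_fraction = 0.25,
                         de_fraction_per_condition = 0.05,
                         common_fraction = 0.5,
                         fc_range = c(2, 16),
                         prob_up = 0.7,
                         baseline_log2_mean = 10,
                         baseline_log2_sd = 1,
                         noise_sd = 0.3,
                         background_mean = 20,
                         background_sd = 5,
                         spike_in_count = 10,
                         n_qpcr_genes = 12,
                         efficiency = 2,
                         reference_gene = "18S",
                         seed = 1L) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    n_est_per_library = as.integer(n_est_per_library),
    enriched_fraction = enriched_fraction,
    enrichment_strength = enrichment_strength,
    est_length_range = as.integer(est_length_range),
    short_fraction = short_fraction,
    mutation_rate = mutation_rate,
    n_targets = as.integer(n_targets),
    n_arrays_per_condition = as.integer(n_arrays_per_condition),
    conditions = as.character(conditions),
    n_probes_per_target = as.integer(n_probes_per_target),
    single_probe_fraction = single_probe_fraction,
    de_fraction_per_condition = de_fraction_per_condition,
    common_fraction = common_fraction,
    fc_range = as.numeric(fc_range),
    prob_up = prob_up,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    noise_sd = noise_sd,
    background_mean = background_mean,
    background_sd = background_sd,
    spike_in_count = as.integer(spike_in_count),
    n_qpcr_genes = as.integer(n_qpcr_genes),
    efficiency = efficiency,
    reference_gene = reference_gene,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

#' @noRd
validate_synth_config <- function(cfg) {
  counts <- c("n_transcripts", "n_est_per_library", "n_targets",
              "n_arrays_per_condition", "n_probes_per_target", "n_qpcr_genes")
  for (fld in counts) {
    if (length(cfg[[fld]]) != 1 || is.na(cfg[[fld]]) || cfg[[fld]] <= 0) {
      input_error("synth_config: '%s' must be a single positive count", fld)
    }
  }
  props <- c("enriched_fraction", "enrichment_strength", "short_fraction",
             "mutation_rate", "single_probe_fraction",
             "de_fraction_per_condition", "common_fraction", "prob_up")
  for (fld in props) {
    if (length(cfg[[fld]]) != 1 || is.na(cfg[[fld]]) ||
        cfg[[fld]] < 0 || cfg[[fld]] > 1) {
      input_error("synth_config: '%s' must be a proportion in [0, 1]", fld)
    }
  }
  if (length(cfg$fc_range) != 2 || cfg$fc_range[1] <= 1 ||
      diff(cfg$fc_range) < 0) {
    input_error("synth_config: 'fc_range' must be an interval with lower bound > 1")
  }
  if (length(cfg$est_length_range) != 2 ||
      cfg$est_length_range[1] < 10 || diff(cfg$est_length_range) < 0) {
    input_error("synth_config: 'est_length_range' must be an increasing interval >= 10 nt")
  }
  if (cfg$noise_sd < 0 || cfg$background_mean < 0 || cfg$background_sd < 0) {
    input_error("synth_config: noise and background parameters must be non-negative")
  }
  if (cfg$efficiency <= 1 || cfg$efficiency > 2) {
    input_error("synth_config: 'efficiency' must lie in (1, 2]")
  }
  if (!("control" %in% cfg$conditions) || cfg$conditions[1] != "control") {
    input_error("synth_config: 'conditions' must start with 'control'")
  }
  if (length(cfg$conditions) < 2 || anyDuplicated(cfg$conditions)) {
    input_error("synth_config: 'conditions' must contain control plus >= 1 distinct treatment")
  }
  if (!is.character(cfg$reference_gene) || length(cfg$reference_gene) != 1 ||
      is.na(cfg$reference_gene) || !nzchar(cfg$reference_gene)) {
    input_error("synth_config: 'reference_gene' must be a non-empty gene name")
  }
  if (is.na(cfg$seed)) {
    input_error("synth_config: 'seed' must be an integer")
  }
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synth_config:\n")
  cat(sprintf("  EST: %d transcripts, %d ESTs/library, %.0f%% planted enriched\n",
              x$n_transcripts, x$n_est_per_library, 100 * x$enriched_fraction))
  cat(sprintf("  array: %d targets x %d conditions x %d arrays, %d probes/target\n",
              x$n_targets, length(x$conditions), x$n_arrays_per_condition,
              x$n_probes_per_target))
  cat(sprintf("  effects: %.0f%% DE/condition, |FC| in [%g, %g], noise_sd %g log2\n",
              100 * x$de_fraction_per_condition, x$fc_range[1], x$fc_range[2],
              x$noise_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
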