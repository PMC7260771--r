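#' Configuration for the synthetic Poly-Ribo-Seq generator
#'
#' Bundles every tunable of the simulator: how many ORFs of each class to
#' create, the geometry of leaders and CDSs, the staged library layout, read
#' depths, the footprint length distribution, and the frame fidelities that
#' distinguish productive translation from mere ribosomal binding.
#'
#' Defaults emulate the statistical structure of staged embryonic
#' Poly-Ribo-Seq: three 8-h stages with two replicates each, footprint
#' lengths concentrated in 26--36 nt with a 32-nt mode (97% of footprints in
#' range), ~60% of footprint 5' ends in the dominant frame for translated
#' ORFs, and exactly 1/3 (no periodicity) for bound-only ORFs.
#'
#' @param n_canonical number of plain canonical genes (CDS > 303 nt).
#' @param n_short_cds number of independent short-CDS genes (CDS <= 303 nt).
#' @param uorfs_per_leader named probability vector over uORF counts per
#'   canonical leader (names "0","1",... ).
#' @param n_nested_uorf_pairs extra canonical genes whose leader carries a
#'   shorter uORF nested in frame inside a longer one (the nested one must be
#'   filtered out by the catalog).
#' @param n_outframe_uorf_pairs extra canonical genes whose leader carries
#'   two uORFs overlapping in different frames (both must survive).
#' @param n_dicistronic genes with a second annotated short CDS embedded in
#'   the main isoform's leader (reclassified into the uORF set).
#' @param n_short_isoform_genes genes with a canonical isoform plus a short
#'   in-frame isoform of the same stop (the short isoform must be discarded).
#' @param leader_length_range,canonical_codon_range,short_cds_codon_range,
#'   uorf_codon_range,utr3_length_range geometry ranges (nt for lengths,
#'   codons excluding the stop for codon ranges).
#' @param stages ordered character vector of stage labels.
#' @param replicates_per_stage replicates per stage per assay.
#' @param rna_depth,fp_depth expected total reads per RNA-Seq / Ribo-Seq
#'   library.
#' @param footprint_length_weights named probability vector over footprint
#'   lengths 26..36; must sum to 1 and peak at 32.
#' @param fp_length_outlier_fraction fraction of footprints drawn outside
#'   26--36 nt (placed at 24, 25, 37, 38 nt), so that the in-range share
#'   matches the ~97% seen in real libraries.
#' @param rna_read_length RNA-Seq read length (nt).
#' @param in_frame_fraction_translated probability that a footprint 5' end
#'   of a translated ORF falls in the dominant frame (must be in [1/3, 1]).
#' @param in_frame_fraction_bound_only same for bound-only ORFs; 1/3 means
#'   no periodicity.
#' @param dominant_frame frame class (0, 1 or 2) of in-frame footprints,
#'   relative to the ORF start.
#' @param state_probs named probabilities over the per-stage expression
#'   state of main ORFs (canonical / short CDS):
#'   untranscribed, transcribed_only, bound_only, translated.
#' @param uorf_state_probs named probabilities over uORF states given a
#'   transcribed host transcript: transcribed_only, bound_only, translated.
#' @param rna_abundance_sdlog log-SD of transcript abundance (lognormal).
#' @param te_base_sdlog log-SD of per-ORF baseline translational efficiency.
#' @param te_multipliers optional data.frame (orf_id, stage, multiplier)
#'   applying stage-specific TE shifts to named ORFs.
#' @param seed integer RNG seed; identical configs give byte-identical
#'   simulations.
#'
#' @return An object of class \code{"sim_config"} (validated list).
#' @seealso [generate_truth_catalog()], [simulate_libraries()],
#'   [simulate_ribodata()]
#' @export
sim_config <- function(n_canonical = 24,
                       n_short_cds = 8,
                       uorfs_per_leader = c("0" = 0.45, "1" = 0.35, "2" = 0.20),
                       n_nested_uorf_pairs = 1,
                       n_outframe_uorf_pairs = 1,
                       n_dicistronic = 1,
                       n_short_isoform_genes = 1,
                       leader_length_range = c(150, 300),
                       canonical_codon_range = c(120, 300),
                       short_cds_codon_range = c(20, 100),
                       uorf_codon_range = c(12, 30),
                       utr3_length_range = c(50, 150),
                       stages = c("early", "mid", "late"),
                       replicates_per_stage = 2L,
                       rna_depth = 150000,
                       fp_depth = 150000,
                       footprint_length_weights = NULL,
                       fp_length_outlier_fraction = 0.03,
                       rna_read_length = 50L,
                       in_frame_fraction_translated = 0.6,
                       in_frame_fraction_bound_only = 1 / 3,
                       dominant_frame = 2L,
                       state_probs = c(untranscribed = 0.10,
                                       transcribed_only = 0.10,
                                       bound_only = 0.15,
                                       translated = 0.65),
                       uorf_state_probs = c(transcribed_only = 0.28,
                                            bound_only = 0.61,
                                            translated = 0.11),
                       rna_abundance_sdlog = 0.75,
                       te_base_sdlog = 0.4,
                       te_multipliers = NULL,
                       seed = 1L) {
  if (is.null(footprint_length_weights)) {
    footprint_length_weights <- c(
      "26" = 0.015, "27" = 0.02, "28" = 0.03, "29" = 0.05, "30" = 0.08,
      "31" = 0.13, "32" = 0.30, "33" = 0.14, "34" = 0.10, "35" = 0.07,
      "36" = 0.065)
  }
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulator configuration
#'
#' Checks the invariants the generator relies on: footprint length weights
#' over 26..36 summing to one, frame fidelities in [1/3, 1], positive
#' depths, state probabilities summing to one, and a leader geometry able to
#' host the requested uORFs.
#'
#' @param config a [sim_config()] object.
#' @return `config`, invisibly; errors describe the violated invariant.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$footprint_length_weights
  if (!setequal(names(w), as.character(26:36)))
    .stopf("footprint_length_weights must be named with lengths 26..36")
  if (abs(sum(w) - 1) > 1e-8)
    .stopf("footprint_length_weights must sum to 1 (got %.6f)", sum(w))
  if (which.max(w[as.character(26:36)]) != which(26:36 == 32))
    .stopf("footprint_length_weights must have its mode at 32 nt")
  for (f in c(config$in_frame_fraction_translated,
              config$in_frame_fraction_bound_only))
    if (f < 1 / 3 - 1e-12 || f > 1)
      .stopf("in-frame fractions must lie in [1/3, 1] (got %g)", f)
  if (config$rna_depth <= 0 || config$fp_depth <= 0)
    .stopf("library depths must be positive")
  if (config$fp_length_outlier_fraction < 0 ||
      config$fp_length_outlier_fraction >= 1)
    .stopf("fp_length_outlier_fraction must be in [0, 1)")
  if (abs(sum(config$state_probs) - 1) > 1e-8 ||
      !setequal(names(config$state_probs),
                c("untranscribed", "transcribed_only", "bound_only",
                  "translated")))
    .stopf("state_probs must be a probability vector over the four states")
  if (abs(sum(config$uorf_state_probs) - 1) > 1e-8 ||
      !setequal(names(config$uorf_state_probs),
                c("transcribed_only", "bound_only", "translated")))
    .stopf("uorf_state_probs must be a probability vector over three states")
  if (length(config$stages) < 1 || anyDuplicated(config$stages))
    .stopf("stages must be distinct labels")
  if (!.is_count(config$replicates_per_stage))
    .stopf("replicates_per_stage must be a positive integer")
  if (!config$dominant_frame %in% 0:2)
    .stopf("dominant_frame must be 0, 1 or 2")
  if (config$uorf_codon_range[1] < 12)
    .stopf(paste0("uORFs must encode more than 10 AA beyond the initiator ",
                  "(min %d codons requested)"), config$uorf_codon_range[1])
  # smallest requested uORF motif (codons + stop) plus flanks must fit the
  # shortest leader we may draw
  wants_uorfs <- any(as.integer(names(config$uorfs_per_leader)) > 0 &
                     config$uorfs_per_leader > 0) ||
    config$n_nested_uorf_pairs > 0 || config$n_outframe_uorf_pairs > 0 ||
    config$n_dicistronic > 0
  min_motif <- 3 * (config$uorf_codon_range[1] + 1) + 4
  if (wants_uorfs && config$leader_length_range[1] < min_motif)
    .stopf(paste0("impossible geometry: shortest leader (%d nt) cannot hold ",
                  "the smallest requested uORF (%d nt needed)"),
           config$leader_length_range[1], min_motif)
  if (!is.null(config$te_multipliers)) {
    tm <- config$te_multipliers
    if (!is.data.frame(tm) ||
        !all(c("orf_id", "stage", "multiplier") %in% names(tm)))
      .stopf("te_multipliers must have columns orf_id, stage, multiplier")
    if (any(tm$multiplier <= 0)) .stopf("TE multipliers must be positive")
    if (!all(tm$stage %in% config$stages))
      .stopf("te_multipliers references unknown stages")
  }
  if (!(length(config$seed) == 1 && is.numeric(config$seed) &&
        is.finite(config$seed) && config$seed == floor(config$seed)))
    .stopf("seed must be a single integer")
  invisible(config)
}
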