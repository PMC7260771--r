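# Per-stage translation state ladder and developmental specificity.
#
# An ORF is, per stage: transcribed when RNA RPKM exceeds the threshold in
# at least one replicate; ribosome-bound when additionally the footprint
# RPKM exceeds the threshold in every replicate (reproducible binding);
# translated when additionally its binomial framing p-value beats alpha.
# The ladder is strict: translated => bound => transcribed.

#' Pipeline thresholds
#'
#' @param rna_rpkm_threshold transcription threshold (strict >, any one RNA
#'   replicate).
#' @param fp_rpkm_threshold ribosome-binding threshold (strict >, all FP
#'   replicates).
#' @param framing_alpha framing significance cutoff (binomial p < alpha).
#' @param fp_length_range footprint lengths counted (nt, inclusive).
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(rna_rpkm_threshold = 1,
                            fp_rpkm_threshold = 1,
                            framing_alpha = 0.01,
                            fp_length_range = c(26L, 36L)) {
  stopifnot(rna_rpkm_threshold > 0, fp_rpkm_threshold > 0,
            framing_alpha > 0, framing_alpha < 1,
            length(fp_length_range) == 2,
            fp_length_range[1] <= fp_length_range[2])
  structure(list(rna_rpkm_threshold = rna_rpkm_threshold,
                 fp_rpkm_threshold = fp_rpkm_threshold,
                 framing_alpha = framing_alpha,
                 fp_length_range = fp_length_range),
            class = "pipeline_config")
}

.STATES <- c("untranscribed", "transcribed_only", "bound_only", "translated")

#' Call the translation state of one ORF in one stage
#'
#' @param rna_rpkms per-replicate RNA RPKM values for the stage.
#' @param fp_rpkms per-replicate footprint RPKM values (at least one
#'   replicate, none missing; the reproducibility filter needs them all).
#' @param framing_p the ORF's binomial framing p-value for the stage (NA
#'   when no dominant-length reads map to the ORF).
#' @param config a [pipeline_config()].
#' @return one of `"untranscribed"`, `"transcribed_only"`, `"bound_only"`,
#'   `"translated"`.
#' @export
call_stage_status <- function(rna_rpkms, fp_rpkms, framing_p,
                              config = pipeline_config()) {
  if (length(rna_rpkms) < 1 || anyNA(rna_rpkms))
    .stopf("missing RNA replicate")
  if (length(fp_rpkms) < 1 || anyNA(fp_rpkms))
    .stopf("missing footprint replicate")
  transcribed <- max(rna_rpkms) > config$rna_rpkm_threshold
  if (!transcribed) return("untranscribed")
  bound <- min(fp_rpkms) > config$fp_rpkm_threshold
  if (!bound) return("transcribed_only")
  translated <- !is.na(framing_p) && framing_p < config$framing_alpha
  if (!translated) return("bound_only")
  "translated"
}

#' Classify developmental specificity of translation
#'
#' @param states character vector of per-stage states (>= 2 stages, in
#'   developmental order).
#' @return `"constitutive"` (translated at every stage), `"stage_specific"`
#'   (translated at some but not all) or `"never_translated"`.
#' @export
classify_specificity <- function(states) {
  if (length(states) < 2) .stopf("need at least 2 stages")
  if (!all(states %in% .STATES)) .stopf("unknown state label")
  tr <- states == "translated"
  if (all(tr)) "constitutive"
  else if (any(tr)) "stage_specific"
  else "never_translated"
}

#' Apply the decision ladder to all ORFs and stages
#'
#' @param quant an [quantify_orfs()] result.
#' @param framing a [framing_calls()] result.
#' @param config a [pipeline_config()].
#' @return An object of class \code{"translation_calls"}: data.frame with
#'   orf_id, class, one `state_<stage>` column per stage, and
#'   `specificity`.
#' @export
call_translation <- function(quant, framing, config = pipeline_config()) {
  stopifnot(inherits(quant, "orf_quant"))
  libs <- quant$libraries
  stages <- unique(libs$stage)
  for (s in stages) {
    if (sum(libs$assay == "FP" & libs$stage == s) < 1 ||
        sum(libs$assay == "RNA" & libs$stage == s) < 1)
      .stopf("stage %s lacks an RNA or FP library", s)
  }
  out <- data.frame(orf_id = quant$orf_id, class = quant$class,
                    stringsAsFactors = FALSE)
  for (s in stages) {
    rna_ids <- libs$library_id[libs$assay == "RNA" & libs$stage == s]
    fp_ids <- libs$library_id[libs$assay == "FP" & libs$stage == s]
    p <- framing$p_value[framing$stage == s][
      match(quant$orf_id, framing$orf_id[framing$stage == s])]
    states <- vapply(seq_along(quant$orf_id), function(i)
      call_stage_status(quant$rpkm[i, rna_ids], quant$rpkm[i, fp_ids],
                        p[i], config), "")
    out[[paste0("state_", s)]] <- states
  }
  if (length(stages) >= 2) {
    sc <- paste0("state_", stages)
    out$specificity <- apply(as.matrix(out[, sc]), 1, classify_specificity)
  } else {
    out$specificity <- NA_character_
  }
  class(out) <- c("translation_calls", "data.frame")
  out
}
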