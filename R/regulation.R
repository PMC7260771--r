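# Translational regulation between contiguous stages via TE Z-ratios.
#
# TE values are standardized per sample over the compared ORF set
# (Z = (TE - mean) / SD), and the per-ORF change between two contiguous
# stages is standardized again over all ORFs: Z-ratio = (Z_B - Z_A) /
# SD(Z_B - Z_A). |Z-ratio| >= 1.5 flags biologically significant
# regulation. This is a relative outlier test: it flags the ORFs whose TE
# change stands out against the distribution of all changes.

#' Standardize TE values within one sample
#'
#' @param te numeric TE values across ORFs (no NAs; >= 2 values with
#'   nonzero spread).
#' @return Z-scores with mean 0 and (sample) SD 1.
#' @export
te_zscores <- function(te) {
  if (anyNA(te)) .stopf("TE vector must not contain NA")
  if (length(te) < 2) .stopf("need at least 2 TE values")
  s <- sd(te)
  if (s == 0) .stopf("zero TE standard deviation: Z-scores undefined")
  (te - mean(te)) / s
}

#' Z-ratio between two paired Z-score vectors
#'
#' Per-ORF difference of Z-scores divided by the standard deviation of all
#' differences; the result always has SD 1 and is antisymmetric under
#' swapping the two stages.
#'
#' @param z_a,z_b paired Z-score vectors (same ORF order).
#' @return numeric Z-ratio vector.
#' @export
z_ratio <- function(z_a, z_b) {
  if (length(z_a) != length(z_b)) .stopf("Z-score vectors must be paired")
  if (length(z_a) < 2) .stopf("need at least 2 ORFs")
  d <- z_b - z_a
  s <- sd(d)
  if (s == 0) .stopf("zero SD of Z-score differences: Z-ratio undefined")
  d / s
}

#' Classify a Z-ratio into regulation classes
#'
#' @param zr numeric Z-ratio(s).
#' @param cutoff significance cutoff (default 1.5; both bounds inclusive).
#' @return `"up"` (zr >= cutoff), `"down"` (zr <= -cutoff) or
#'   `"unchanged"`.
#' @export
classify_regulation <- function(zr, cutoff = 1.5) {
  if (any(!is.finite(zr))) .stopf("Z-ratio must be finite")
  ifelse(zr >= cutoff, "up", ifelse(zr <= -cutoff, "down", "unchanged"))
}

#' Regulation calls across contiguous stage pairs
#'
#' For every pair of contiguous stages and every ORF class separately
#' (canonical / shortCDS / uORF, to avoid mixing their TE scales), takes
#' the ORFs with defined TE in both stages, standardizes TE per stage over
#' that set, and classifies the Z-ratios at the cutoff.
#'
#' @param quant an [quantify_orfs()] result (its `te` matrix is used).
#' @param stages ordered stage labels (default: the TE matrix's column
#'   order).
#' @param cutoff Z-ratio cutoff.
#' @return data.frame: orf_id, class, stage_a, stage_b, te_a, te_b, z_a,
#'   z_b, z_ratio, call.
#' @export
regulation_calls <- function(quant, stages = NULL, cutoff = 1.5) {
  stopifnot(inherits(quant, "orf_quant"))
  te <- quant$te
  if (is.null(stages)) stages <- colnames(te)
  if (length(stages) < 2) .stopf("need at least 2 stages")
  out <- list()
  for (k in seq_len(length(stages) - 1)) {
    a <- stages[k]; b <- stages[k + 1]
    for (cls in unique(quant$class)) {
      sel <- quant$class == cls & !is.na(te[, a]) & !is.na(te[, b])
      if (sum(sel) < 2) next
      if (sd(te[sel, a]) == 0 || sd(te[sel, b]) == 0) {
        .warnf("constant TE for class %s in %s/%s: no Z-scores, pair skipped",
               cls, a, b)
        next
      }
      za <- te_zscores(te[sel, a])
      zb <- te_zscores(te[sel, b])
      if (sd(zb - za) == 0) {
        .warnf("identical Z-scores for class %s in %s/%s: pair skipped",
               cls, a, b)
        next
      }
      zr <- z_ratio(za, zb)
      out[[length(out) + 1L]] <- data.frame(
        orf_id = quant$orf_id[sel], class = cls, stage_a = a, stage_b = b,
        te_a = te[sel, a], te_b = te[sel, b], z_a = za, z_b = zb,
        z_ratio = zr, call = classify_regulation(zr, cutoff),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(orf_id = character(0), class = character(0),
               stage_a = character(0), stage_b = character(0),
               te_a = numeric(0), te_b = numeric(0), z_a = numeric(0),
               z_b = numeric(0), z_ratio = numeric(0), call = character(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
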