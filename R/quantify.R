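# Per-ORF read counting, RPKM and translational efficiency.
#
# RPKM = count / (ORF length in kb) / (library total genome-aligned reads
# in millions). The normalizer is the library total, not the ORF-assigned
# total. Footprint counting is restricted to 26-36 nt reads; a read counts
# for an ORF when at least 1 nt of its interval overlaps the ORF, and a
# read overlapping two non-nested ORFs counts for both (framing later
# attributes translation to the right ORF).

#' Count footprints overlapping one ORF
#'
#' Counts reads whose length falls inside `length_range` (inclusive) and
#' whose interval `[five_prime_pos, five_prime_pos + length)` overlaps the
#' ORF interval by at least 1 nt, on the matching (sense) strand.
#'
#' @param reads data.frame of read records (see [simulate_libraries()] for
#'   the columns).
#' @param orf one ORF record (a one-row data.frame or list with
#'   `transcript_id`, `start`, `end`).
#' @param length_range inclusive read-length window in nt; use
#'   `c(-Inf, Inf)` to count all lengths (RNA-Seq).
#' @return integer count.
#' @export
count_footprints <- function(reads, orf, length_range = c(26L, 36L)) {
  if (orf$end <= orf$start) .stopf("empty ORF interval")
  sel <- reads$transcript_id == orf$transcript_id &
    reads$strand == "+" &
    reads$length >= length_range[1] & reads$length <= length_range[2] &
    reads$five_prime_pos < orf$end &
    reads$five_prime_pos + reads$length > orf$start
  sum(sel)
}

#' Reads per kilobase per million (RPKM)
#'
#' `count / (orf_length_nt / 1000) / (total_reads / 1e6)`, the per-ORF read
#' density scaled by ORF length and the total number of genome-aligned
#' reads in the library.
#'
#' @param count reads assigned to the ORF.
#' @param orf_length_nt ORF length in nt (> 0).
#' @param total_reads total genome-aligned reads in the library (> 0).
#' @return numeric RPKM (vectorized).
#' @export
rpkm <- function(count, orf_length_nt, total_reads) {
  if (any(orf_length_nt <= 0)) .stopf("ORF length must be positive")
  if (any(total_reads <= 0)) .stopf("library total must be positive")
  count / (orf_length_nt / 1000) / (total_reads / 1e6)
}

#' Translational efficiency
#'
#' TE = RPKM^FP / RPKM^RNA; undefined (NA) where the RNA density is zero.
#'
#' @param rpkm_fp,rpkm_rna non-negative RPKM values (vectorized).
#' @return numeric TE with NA where undefined.
#' @export
translational_efficiency <- function(rpkm_fp, rpkm_rna) {
  if (any(rpkm_fp < 0, na.rm = TRUE) || any(rpkm_rna < 0, na.rm = TRUE))
    .stopf("RPKM values must be non-negative")
  ifelse(!is.na(rpkm_rna) & rpkm_rna > 0, rpkm_fp / rpkm_rna, NA_real_)
}

#' Spearman correlation between replicate RPKM vectors
#'
#' Rank correlation with midranks for ties; a constant vector has no ranks
#' to correlate and yields NA with a warning.
#'
#' @param rpkm_a,rpkm_b equal-length vectors paired by ORF.
#' @return Spearman's rho in [-1, 1], or NA.
#' @export
replicate_correlation <- function(rpkm_a, rpkm_b) {
  if (length(rpkm_a) != length(rpkm_b)) .stopf("vectors must be paired")
  if (length(rpkm_a) < 3) .stopf("need at least 3 paired values")
  if (sd(rpkm_a) == 0 || sd(rpkm_b) == 0) {
    .warnf("constant RPKM vector: correlation undefined")
    return(NA_real_)
  }
  cor(rpkm_a, rpkm_b, method = "spearman")
}

# vectorized per-ORF x per-library counting via an interval join on a
# per-transcript global axis
.count_matrix <- function(reads, catalog, libraries, length_range) {
  tx_ids <- unique(c(reads$transcript_id, catalog$transcript_id))
  span <- 10L^(ceiling(log10(max(c(reads$five_prime_pos + reads$length,
                                   catalog$end, 1)) + 40L)))
  tx_i <- match(catalog$transcript_id, tx_ids)
  orf_ir <- IRanges::IRanges(start = (tx_i - 1L) * span + catalog$start + 1L,
                             end = (tx_i - 1L) * span + catalog$end)
  keep <- reads$strand == "+" &
    reads$length >= length_range[1] & reads$length <= length_range[2]
  r <- reads[keep, , drop = FALSE]
  r_tx <- match(r$transcript_id, tx_ids)
  r_ir <- IRanges::IRanges(
    start = (r_tx - 1L) * span + r$five_prime_pos + 1L,
    width = r$length)
  hits <- IRanges::findOverlaps(r_ir, orf_ir)
  lib_f <- factor(r$library_id[S4Vectors::queryHits(hits)],
                  levels = libraries$library_id)
  orf_f <- factor(S4Vectors::subjectHits(hits),
                  levels = seq_len(nrow(catalog)))
  m <- table(orf_f, lib_f)
  matrix(as.integer(m), nrow = nrow(catalog),
         dimnames = list(catalog$orf_id, libraries$library_id))
}

#' Quantify ORFs across libraries: counts, RPKM and per-stage TE
#'
#' Counts reads per ORF per library (footprint libraries restricted to
#' `length_range`, RNA libraries unrestricted), converts to RPKM with each
#' library's total genome-aligned reads as normalizer, and computes
#' per-stage TE as the ratio of replicate-averaged footprint RPKM over
#' replicate-averaged RNA RPKM.
#'
#' @param reads read records (data.frame or path to the TSV dialect of
#'   [write_simulation()]).
#' @param catalog an ORF catalog ([build_orf_catalog()] or any data.frame
#'   with orf_id, transcript_id, start, end, length_nt, class).
#' @param libraries library table (library_id, assay, stage, replicate,
#'   optionally total_reads; missing totals are taken from the read table).
#' @param length_range inclusive footprint length window (nt).
#' @return An object of class \code{"orf_quant"}: list with `counts` and
#'   `rpkm` (ORF x library matrices), `te` (ORF x stage matrix, NA where
#'   undefined), `libraries`, and the catalog's orf_id/class.
#' @export
quantify_orfs <- function(reads, catalog, libraries,
                          length_range = c(26L, 36L)) {
  if (is.character(reads)) reads <- read_alignments(reads)
  libraries <- .check_libraries(libraries, reads)
  if (any(catalog$end <= catalog$start)) .stopf("empty ORF interval")

  is_fp <- libraries$assay == "FP"
  counts <- matrix(0L, nrow(catalog), nrow(libraries),
                   dimnames = list(catalog$orf_id, libraries$library_id))
  fp_libs <- libraries[is_fp, , drop = FALSE]
  rna_libs <- libraries[!is_fp, , drop = FALSE]
  if (nrow(fp_libs) > 0)
    counts[, fp_libs$library_id] <- .count_matrix(
      reads[reads$library_id %in% fp_libs$library_id, , drop = FALSE],
      catalog, fp_libs, length_range)
  if (nrow(rna_libs) > 0)
    counts[, rna_libs$library_id] <- .count_matrix(
      reads[reads$library_id %in% rna_libs$library_id, , drop = FALSE],
      catalog, rna_libs, c(-Inf, Inf))

  rp <- sweep(sweep(counts, 1, catalog$length_nt / 1000, "/"),
              2, libraries$total_reads / 1e6, "/")

  stages <- unique(libraries$stage)
  te <- matrix(NA_real_, nrow(catalog), length(stages),
               dimnames = list(catalog$orf_id, stages))
  for (s in stages) {
    fp_s <- libraries$library_id[is_fp & libraries$stage == s]
    rna_s <- libraries$library_id[!is_fp & libraries$stage == s]
    if (length(fp_s) == 0 || length(rna_s) == 0) next
    mfp <- rowMeans(rp[, fp_s, drop = FALSE])
    mrna <- rowMeans(rp[, rna_s, drop = FALSE])
    te[, s] <- translational_efficiency(mfp, mrna)
  }

  structure(list(counts = counts, rpkm = rp, te = te, libraries = libraries,
                 orf_id = catalog$orf_id, class = catalog$class),
            class = "orf_quant")
}

.check_libraries <- function(libraries, reads = NULL) {
  need <- c("library_id", "assay", "stage", "replicate")
  if (!all(need %in% names(libraries)))
    .stopf("library table needs columns: %s", paste(need, collapse = ", "))
  if (!all(libraries$assay %in% c("RNA", "FP")))
    .stopf("assay must be RNA or FP")
  if (anyDuplicated(libraries$library_id)) .stopf("duplicate library_id")
  if (is.null(libraries$total_reads) || anyNA(libraries$total_reads)) {
    if (is.null(reads)) .stopf("total_reads missing and no reads given")
    tab <- table(factor(reads$library_id, levels = libraries$library_id))
    libraries$total_reads <- as.integer(tab)
  }
  if (any(libraries$total_reads <= 0))
    .stopf("library %s has no reads: total_reads must be > 0",
           paste(libraries$library_id[libraries$total_reads <= 0],
                 collapse = ", "))
  libraries
}

#' @export
print.orf_quant <- function(x, ...) {
  cat(sprintf("orf_quant: %d ORFs x %d libraries (%d stages)\n",
              nrow(x$counts), ncol(x$counts), ncol(x$te)))
  invisible(x)
}
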