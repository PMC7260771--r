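# Triplet periodicity (framing) of footprint 5' ends and the per-ORF
# binomial translation test.
#
# The frame class of a read is (five_prime_pos - orf_start) mod 3 in
# transcript space; no P-site offset is applied because the dominant frame
# is learned empirically per sample, so any constant offset cancels. Each
# footprint is an independent RNA-ribosome interaction, so under no
# periodicity a read has probability 1/3 of landing in the dominant frame;
# per ORF, x in-frame reads out of n dominant-length reads are scored with
# the upper-tail binomial probability P(X >= x), X ~ Binomial(n, 1/3).

#' Build a metagene framing profile
#'
#' Aggregates footprint 5'-end frame classes per read length over all
#' cataloged ORFs extended by a window (18 nt upstream, 15 nt downstream by
#' default, both multiples of 3 so frame classes are preserved), plus
#' per-position counts relative to the ORF start for metagene plots.
#'
#' @param reads read records (one or more footprint libraries).
#' @param catalog ORF catalog.
#' @param upstream,downstream window in nt around each ORF.
#' @return An object of class \code{"framing_profile"}: list with
#'   `frame_counts` (length x frame-class matrix), `position_counts`
#'   (named vector over positions relative to the ORF start) and the
#'   window.
#' @export
build_metagene_profile <- function(reads, catalog, upstream = 18L,
                                   downstream = 15L) {
  if (nrow(catalog) == 0) .stopf("empty ORF catalog")
  tx_ids <- unique(c(reads$transcript_id, catalog$transcript_id))
  span <- 10L^(ceiling(log10(max(c(reads$five_prime_pos, catalog$end, 1)) +
                             upstream + downstream + 41L)))
  tx_i <- match(catalog$transcript_id, tx_ids)
  win_ir <- IRanges::IRanges(
    start = (tx_i - 1L) * span + catalog$start - upstream + 1L,
    end = (tx_i - 1L) * span + catalog$end + downstream)
  r <- reads[reads$strand == "+", , drop = FALSE]
  r_tx <- match(r$transcript_id, tx_ids)
  pt_ir <- IRanges::IRanges(start = (r_tx - 1L) * span + r$five_prime_pos + 1L,
                            width = 1L)
  hits <- IRanges::findOverlaps(pt_ir, win_ir)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  rel <- r$five_prime_pos[qh] - catalog$start[sh]
  len <- r$length[qh]
  frame <- rel %% 3L

  lens <- sort(unique(len))
  frame_counts <- matrix(0L, length(lens), 3,
                         dimnames = list(lens, c("0", "1", "2")))
  if (length(len) > 0) {
    tab <- table(factor(len, levels = lens), factor(frame, levels = 0:2))
    frame_counts[] <- as.integer(tab)
  }
  position_counts <- if (length(rel) > 0) table(rel) else table(integer(0))
  structure(list(frame_counts = frame_counts,
                 position_counts = position_counts,
                 upstream = upstream, downstream = downstream),
            class = "framing_profile")
}

#' Select the dominant footprint length and its overrepresented frame
#'
#' The dominant length is the read length with the largest total count;
#' the dominant frame is its most overrepresented frame class. Ties are
#' resolved toward the smallest length, then the smallest frame index, with
#' a warning.
#'
#' @param profile a [build_metagene_profile()] result.
#' @return list with `length` and `frame`.
#' @export
select_dominant_length_frame <- function(profile) {
  fc <- profile$frame_counts
  if (nrow(fc) == 0 || sum(fc) == 0) .stopf("empty framing profile")
  totals <- rowSums(fc)
  best <- which(totals == max(totals))
  if (length(best) > 1)
    .warnf("tie between read lengths %s; choosing the smallest",
           paste(rownames(fc)[best], collapse = ", "))
  L <- as.integer(rownames(fc)[min(best)])
  row <- fc[min(best), ]
  bf <- which(row == max(row))
  if (length(bf) > 1)
    .warnf("tie between frames %s at length %d; choosing the lowest",
           paste(bf - 1L, collapse = ", "), L)
  list(length = L, frame = as.integer(min(bf) - 1L))
}

#' Binomial framing probability
#'
#' Upper-tail probability P(X >= x) with X ~ Binomial(n, 1/3): the chance
#' of observing at least the seen number of in-frame reads if footprints
#' fell on frames at random. Evaluated as
#' `pbinom(x - 1, n, 1/3, lower.tail = FALSE)`. With all reads in frame,
#' p = (1/3)^n, so 5 reads suffice for p < 0.01, and with one read out of
#' frame 7 reads are needed.
#'
#' @param x in-frame ("framed") reads, 0 <= x <= n.
#' @param n total dominant-length reads mapped to the ORF; n = 0 gives NA
#'   (no test).
#' @return the p-value (vectorized over x, n).
#' @export
binomial_framing_p <- function(x, n) {
  if (length(x) != length(n)) {
    if (length(x) == 1) x <- rep(x, length(n))
    else if (length(n) == 1) n <- rep(n, length(x))
    else .stopf("x and n must have matching lengths")
  }
  if (any(x < 0 | n < 0)) .stopf("counts must be non-negative")
  if (any(x > n)) .stopf("framed reads cannot exceed total reads")
  out <- rep(NA_real_, length(x))
  ok <- n >= 1
  out[ok] <- pbinom(x[ok] - 1, n[ok], 1 / 3, lower.tail = FALSE)
  out
}

#' Per-ORF framing call
#'
#' For one ORF and a merged set of footprint reads: n is the number of
#' dominant-length reads whose 5' end lies inside `[start, end)` (the ORF
#' body, not the metagene window), x the subset whose frame class relative
#' to the ORF's own start equals the dominant frame, and p the binomial
#' framing probability.
#'
#' @param reads merged footprint read records for one stage.
#' @param orf one ORF record.
#' @param dominant list with `length` and `frame`
#'   (see [select_dominant_length_frame()]).
#' @return list with `framed` (x), `total` (n) and `p_value` (NA when
#'   n = 0).
#' @export
orf_framing_call <- function(reads, orf, dominant) {
  sel <- reads$transcript_id == orf$transcript_id &
    reads$strand == "+" &
    reads$length == dominant$length &
    reads$five_prime_pos >= orf$start & reads$five_prime_pos < orf$end
  n <- sum(sel)
  x <- sum((reads$five_prime_pos[sel] - orf$start) %% 3L == dominant$frame)
  list(framed = x, total = n, p_value = binomial_framing_p(x, n))
}

#' Framing calls for all ORFs per stage
#'
#' Merges the footprint replicate libraries of each stage, learns the
#' dominant read length and frame from the stage's metagene profile, and
#' scores every ORF with the binomial framing test.
#'
#' @param reads read records (all libraries).
#' @param catalog ORF catalog.
#' @param libraries library table; only FP libraries are used.
#' @param upstream,downstream metagene window (nt).
#' @return data.frame: orf_id, stage, dominant_length, dominant_frame,
#'   framed, total, p_value.
#' @export
framing_calls <- function(reads, catalog, libraries, upstream = 18L,
                          downstream = 15L) {
  libraries <- .check_libraries(libraries, reads)
  stages <- unique(libraries$stage)
  out <- vector("list", length(stages))
  for (si in seq_along(stages)) {
    s <- stages[si]
    fp_ids <- libraries$library_id[libraries$assay == "FP" &
                                   libraries$stage == s]
    r <- reads[reads$library_id %in% fp_ids, , drop = FALSE]
    if (nrow(r) == 0) {
      out[[si]] <- data.frame(orf_id = catalog$orf_id, stage = s,
                              dominant_length = NA_integer_,
                              dominant_frame = NA_integer_,
                              framed = 0L, total = 0L, p_value = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    prof <- build_metagene_profile(r, catalog, upstream, downstream)
    dom <- select_dominant_length_frame(prof)
    xn <- .framing_counts(r, catalog, dom)
    out[[si]] <- data.frame(orf_id = catalog$orf_id, stage = s,
                            dominant_length = dom$length,
                            dominant_frame = dom$frame,
                            framed = xn$x, total = xn$n,
                            p_value = binomial_framing_p(xn$x, xn$n),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# vectorized per-ORF (x, n) for dominant-length reads with 5' ends inside
# the ORF body
.framing_counts <- function(reads, catalog, dominant) {
  r <- reads[reads$strand == "+" & reads$length == dominant$length, ,
             drop = FALSE]
  tx_ids <- unique(c(r$transcript_id, catalog$transcript_id))
  span <- 10L^(ceiling(log10(max(c(r$five_prime_pos, catalog$end, 1)) + 41L)))
  tx_i <- match(catalog$transcript_id, tx_ids)
  orf_ir <- IRanges::IRanges(start = (tx_i - 1L) * span + catalog$start + 1L,
                             end = (tx_i - 1L) * span + catalog$end)
  r_tx <- match(r$transcript_id, tx_ids)
  pt_ir <- IRanges::IRanges(start = (r_tx - 1L) * span + r$five_prime_pos + 1L,
                            width = 1L)
  hits <- IRanges::findOverlaps(pt_ir, orf_ir)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  in_frame <- (r$five_prime_pos[qh] - catalog$start[sh]) %% 3L ==
    dominant$frame
  orf_f <- factor(sh, levels = seq_len(nrow(catalog)))
  list(n = as.integer(table(orf_f)),
       x = as.integer(tapply(in_frame, orf_f, sum, default = 0L)))
}

#' @export
print.framing_profile <- function(x, ...) {
  fc <- x$frame_counts
  cat("framing_profile over window -", x$upstream, "/ +", x$downstream,
      "nt\n")
  if (nrow(fc) > 0) {
    tot <- rowSums(fc)
    dom <- rownames(fc)[which.max(tot)]
    cat(sprintf("  %d reads over %d lengths; dominant length %s nt\n",
                sum(fc), nrow(fc), dom))
  }
  invisible(x)
}
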