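# ORF catalog: canonical ORFs, short CDSs and AUG-start uORFs, with the
# inclusion, deduplication and overlap filters applied before any
# quantification.
#
# Class rules: a CDS longer than 303 nt (> 100 codons, stop included) is
# canonical; a CDS of at most 303 nt is a short CDS only when no isoform of
# the same gene is canonical (short isoforms of canonical loci are
# discarded). uORFs are AUG-start ORFs in annotated 5' leaders whose first
# in-frame stop lies fully inside the leader and whose peptide exceeds
# 10 AA.

.CANONICAL_NT_CUTOFF <- 303L

.orf_row <- function(txset, orf_id, class, transcript_id, gene_id, a, b,
                     strand) {
  seq <- as.character(txset$seq[[transcript_id]])
  pep <- .translate_dna(substr(seq, a + 1L, b - 3L))
  data.frame(orf_id = orf_id, class = class, transcript_id = transcript_id,
             gene_id = gene_id, start = a, end = b, length_nt = b - a,
             length_codons = (b - a) %/% 3L - 1L, strand = strand,
             blocks = .blocks_key(txset, transcript_id, a, b),
             peptide = pep, stringsAsFactors = FALSE)
}

#' Classify annotated CDSs into canonical ORFs and short CDSs
#'
#' Annotated CDSs longer than 303 nt (100 codons plus stop) are canonical;
#' CDSs of at most 303 nt are short CDSs when they arise from a locus with
#' no canonical isoform, and are discarded when another isoform of the same
#' gene is canonical (short-isoform smORFs). Transcripts flagged for a CDS
#' not divisible by 3 are skipped.
#'
#' @param txset a [load_annotation()] result.
#' @return data.frame of ORF records (class `canonical` / `shortCDS`).
#' @export
classify_cds <- function(txset) {
  stopifnot(inherits(txset, "transcript_set"))
  tx <- txset$transcripts
  tx <- tx[!is.na(tx$cds_start) & tx$cds_ok, , drop = FALSE]
  if (nrow(tx) == 0) return(.empty_orf_df())
  cds_len <- tx$cds_end - tx$cds_start
  canonical_gene <- unique(tx$gene_id[cds_len > .CANONICAL_NT_CUTOFF])
  rows <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    cls <- if (cds_len[i] > .CANONICAL_NT_CUTOFF) "canonical"
           else if (!tx$gene_id[i] %in% canonical_gene) "shortCDS"
           else next  # short isoform of a canonical locus: discarded
    rows[[i]] <- .orf_row(txset, paste0("cds_", tx$transcript_id[i]), cls,
                          tx$transcript_id[i], tx$gene_id[i], tx$cds_start[i],
                          tx$cds_end[i], tx$strand[i])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) .empty_orf_df() else out
}

.empty_orf_df <- function() {
  data.frame(orf_id = character(0), class = character(0),
             transcript_id = character(0), gene_id = character(0),
             start = integer(0), end = integer(0), length_nt = integer(0),
             length_codons = integer(0), strand = character(0),
             blocks = character(0), peptide = character(0),
             stringsAsFactors = FALSE)
}

#' Extract candidate uORFs from 5' leaders
#'
#' Scans every AUG in each annotated leader (all three frames). An AUG
#' yields a candidate when its first in-frame stop codon lies fully inside
#' the leader and the ORF encodes more than 10 AA beyond the initiator
#' (i.e. more than 10 sense codons follow the AUG). Leaders shorter than a
#' minimal uORF, or transcripts without a leader, yield no candidates.
#'
#' @param txset a [load_annotation()] result.
#' @param transcript_ids optional subset of transcripts to scan.
#' @return data.frame of candidate uORF records (not yet filtered; see
#'   [filter_orf_set()]).
#' @export
extract_uorfs <- function(txset, transcript_ids = NULL) {
  stopifnot(inherits(txset, "transcript_set"))
  tx <- txset$transcripts
  tx <- tx[!is.na(tx$cds_start), , drop = FALSE]
  if (!is.null(transcript_ids))
    tx <- tx[tx$transcript_id %in% transcript_ids, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(tx))) {
    leader_len <- tx$cds_start[i]
    if (leader_len < 39L) next  # cannot hold AUG + 11 codons + stop
    leader <- substr(as.character(txset$seq[[tx$transcript_id[i]]]), 1L,
                     leader_len)
    starts <- as.integer(gregexpr("ATG", leader, fixed = TRUE)[[1]])
    starts <- starts[starts > 0] - 1L  # 0-based
    for (p in starts) {
      hit <- .first_inframe_stop(leader, p, leader_len)
      if (is.na(hit)) next
      n_after <- (hit - p) %/% 3L - 1L  # sense codons after the AUG
      if (n_after <= 10L) next
      rows[[length(rows) + 1L]] <- .orf_row(
        txset, sprintf("uorf_%s_%d", tx$transcript_id[i], p), "uORF",
        tx$transcript_id[i], tx$gene_id[i], p, hit + 3L, tx$strand[i])
    }
  }
  if (length(rows) == 0) .empty_orf_df() else do.call(rbind, rows)
}

# 0-based position of the first in-frame stop codon after p whose 3 nt fit
# inside [0, leader_len); NA if none
.first_inframe_stop <- function(leader, p, leader_len) {
  q <- p + 3L
  while (q + 3L <= leader_len) {
    if (substr(leader, q + 1L, q + 3L) %in% .STOP_CODONS) return(q)
    q <- q + 3L
  }
  NA_integer_
}

#' Apply deduplication, overlap and dicistronic filters to an ORF set
#'
#' Within each class, exactly one record survives per unique genome-space
#' CDS coordinate set. uORFs overlapping any annotated CDS in genome space
#' are removed, as are uORFs fully included in-frame within a longer uORF;
#' uORFs overlapping in different frames are all kept. Finally, annotated
#' CDSs fully contained within another isoform's 5' leader (dicistronic
#' arrangements) are added to the uORF set. The operation is idempotent.
#'
#' @param orfs data.frame of ORF records (output of [classify_cds()] plus
#'   [extract_uorfs()], row-bound).
#' @param txset the [load_annotation()] result the records came from
#'   (needed for genome-space comparisons and the dicistronic rescue).
#' @return filtered data.frame of ORF records.
#' @export
filter_orf_set <- function(orfs, txset) {
  stopifnot(inherits(txset, "transcript_set"))
  if (nrow(orfs) == 0) return(orfs)

  # 1. class-wise dedup on the genome-space block key (deterministic
  #    survivor: lexicographically smallest orf_id)
  orfs <- orfs[order(orfs$orf_id), , drop = FALSE]
  orfs <- orfs[!duplicated(paste(orfs$class, orfs$blocks)), , drop = FALSE]

  # annotated CDS regions in genome space (all isoforms, including ones
  # discarded by classify_cds)
  tx <- txset$transcripts[!is.na(txset$transcripts$cds_start), , drop = FALSE]
  cds_gr <- .blocks_granges(lapply(seq_len(nrow(tx)), function(i)
    .tx_to_genome_blocks(txset, tx$transcript_id[i], tx$cds_start[i],
                         tx$cds_end[i])), tx$strand)

  is_u <- orfs$class == "uORF"
  if (any(is_u)) {
    u <- orfs[is_u, , drop = FALSE]
    ub <- lapply(seq_len(nrow(u)), function(i)
      .tx_to_genome_blocks(txset, u$transcript_id[i], u$start[i], u$end[i]))
    u_gr <- .blocks_granges(ub, u$strand)
    u_grp <- S4Vectors::mcols(u_gr)$group

    # 2. drop uORFs overlapping any annotated CDS (either strand's genome
    #    footprint counts as occupied coding sequence)
    ov <- GenomicRanges::countOverlaps(u_gr, cds_gr, ignore.strand = TRUE)
    drop_cds <- rep(FALSE, nrow(u))
    drop_cds[unique(u_grp[ov > 0])] <- TRUE

    # 3. drop uORFs fully included, in frame, within a longer uORF
    drop_nested <- rep(FALSE, nrow(u))
    if (nrow(u) > 1) {
      within <- GenomicRanges::findOverlaps(u_gr, u_gr, type = "within")
      qh <- u_grp[S4Vectors::queryHits(within)]
      sh <- u_grp[S4Vectors::subjectHits(within)]
      for (k in seq_along(qh)) {
        i <- qh[k]; j <- sh[k]
        if (i == j || u$length_nt[i] >= u$length_nt[j]) next
        if (u$strand[i] != u$strand[j]) next
        if (.genome_frame_anchor(ub[[i]], u$strand[i]) %% 3L ==
            .genome_frame_anchor(ub[[j]], u$strand[j]) %% 3L)
          drop_nested[i] <- TRUE
      }
    }
    orfs <- rbind(orfs[!is_u, , drop = FALSE],
                  u[!(drop_cds | drop_nested), , drop = FALSE])
  }

  # 4. dicistronic rescue: annotated CDSs fully contained within another
  #    transcript's leader become uORFs of that transcript
  resc <- .dicistronic_uorfs(txset)
  if (nrow(resc) > 0) {
    have <- paste(orfs$class, orfs$blocks)
    resc <- resc[!paste(resc$class, resc$blocks) %in% have, , drop = FALSE]
    orfs <- rbind(orfs, resc)
  }

  orfs <- orfs[order(orfs$class, orfs$orf_id), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

# GRanges over the union of per-ORF genome blocks; one range per block,
# grouped implicitly by overlap queries
.blocks_granges <- function(block_list, strands) {
  n_bl <- vapply(block_list, nrow, 0L)
  df <- do.call(rbind, block_list)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = rep(strands, n_bl))
  S4Vectors::mcols(gr)$group <- rep(seq_along(block_list), n_bl)
  gr
}

# genomic coordinate of the first (5'-most) ORF base
.genome_frame_anchor <- function(blocks, strand) {
  if (strand == "+") blocks$start[1] else blocks$end[nrow(blocks)]
}

# annotated CDSs fully contained (genome space, same strand) in the 5'
# leader of another transcript, re-expressed in that transcript's space
.dicistronic_uorfs <- function(txset) {
  tx <- txset$transcripts[!is.na(txset$transcripts$cds_start) &
                          txset$transcripts$cds_ok, , drop = FALSE]
  if (nrow(tx) == 0) return(.empty_orf_df())
  cds_blocks <- lapply(seq_len(nrow(tx)), function(i)
    .tx_to_genome_blocks(txset, tx$transcript_id[i], tx$cds_start[i],
                         tx$cds_end[i]))
  cds_lo <- vapply(cds_blocks, function(b) min(b$start), 0)
  cds_hi <- vapply(cds_blocks, function(b) max(b$end), 0)
  rows <- list()
  hosts <- which(tx$cds_start > 0)
  for (h in hosts) {
    host <- tx[h, ]
    hb <- .tx_to_genome_blocks(txset, host$transcript_id, 0L, host$cds_start)
    # cheap span prefilter, then exact per-block coverage (leader blocks are
    # intron-separated, so a contained CDS block fits one leader block)
    cand <- which(tx$strand == host$strand &
                  tx$seqnames == host$seqnames &
                  cds_lo >= min(hb$start) & cds_hi <= max(hb$end) &
                  tx$transcript_id != host$transcript_id)
    for (i in cand) {
      cb <- cds_blocks[[i]]
      covered <- all(vapply(seq_len(nrow(cb)), function(k)
        any(hb$start <= cb$start[k] & cb$end[k] <= hb$end), TRUE))
      if (!covered) next
      # map the CDS into the host transcript's coordinates
      gpos <- if (host$strand == "+") min(cb$start) else max(cb$end)
      a <- .genome_to_tx(txset$exons[[host$transcript_id]], host$strand, gpos)
      b <- a + sum(cb$end - cb$start + 1L)
      rows[[length(rows) + 1L]] <- .orf_row(
        txset, sprintf("uorf_%s_%d", host$transcript_id, a), "uORF",
        host$transcript_id, host$gene_id, a, b, host$strand)
    }
  }
  if (length(rows) == 0) .empty_orf_df() else do.call(rbind, rows)
}

#' Build the full filtered ORF catalog
#'
#' Convenience wrapper: [classify_cds()] plus [extract_uorfs()] followed by
#' [filter_orf_set()].
#'
#' @param txset a [load_annotation()] result.
#' @return An object of class \code{"orf_catalog"} (data.frame of ORF
#'   records).
#' @export
build_orf_catalog <- function(txset) {
  orfs <- rbind(classify_cds(txset), extract_uorfs(txset))
  out <- filter_orf_set(orfs, txset)
  class(out) <- c("orf_catalog", "data.frame")
  out
}

#' Write an ORF catalog as CSV and genome-space BED12
#'
#' @param catalog an [build_orf_catalog()] result.
#' @param csv,bed output paths (either may be NULL to skip).
#' @return Invisibly, the catalog.
#' @export
write_catalog <- function(catalog, csv = NULL, bed = NULL) {
  if (!is.null(csv)) write.csv(catalog, csv, row.names = FALSE)
  if (!is.null(bed)) {
    rows <- lapply(seq_len(nrow(catalog)), function(i) {
      parts <- strsplit(catalog$blocks[i], ":", fixed = TRUE)[[1]]
      ivls <- do.call(rbind, lapply(strsplit(parts[3], ";")[[1]], function(b)
        as.integer(strsplit(b, "-", fixed = TRUE)[[1]])))
      chrom_start <- min(ivls[, 1]) - 1L
      sizes <- ivls[, 2] - ivls[, 1] + 1L
      starts <- ivls[, 1] - 1L - chrom_start
      data.frame(chrom = parts[1], start = chrom_start, end = max(ivls[, 2]),
                 name = catalog$orf_id[i], score = 0, strand = parts[2],
                 thickStart = chrom_start, thickEnd = max(ivls[, 2]),
                 rgb = "0,0,0", blockCount = nrow(ivls),
                 blockSizes = paste0(paste(sizes, collapse = ","), ","),
                 blockStarts = paste0(paste(starts, collapse = ","), ","),
                 stringsAsFactors = FALSE)
    })
    write.table(do.call(rbind, rows), bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(catalog)
}
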