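# GFF3 + FASTA -> transcript models (spliced sequence, leader/CDS/3'UTR
# intervals in 0-based half-open transcript space)

#' Load transcript models from GFF3 annotation and genome FASTA
#'
#' Imports `gene`/`mRNA`/`exon`/`CDS` features, assembles each mRNA's
#' spliced sequence respecting strand and exon order, and derives the
#' transcript-space partition into 5' leader, CDS and 3' UTR from the CDS
#' features. GFF3 coordinates are 1-based inclusive; all transcript-space
#' intervals returned are 0-based half-open.
#'
#' @param gff3 path to a GFF3 file, or a GRanges already carrying
#'   `type`/`ID`/`Parent` columns.
#' @param fasta path to the genome FASTA, or a named DNAStringSet.
#' @return An object of class \code{"transcript_set"}: list with
#'   `transcripts` (data.frame: transcript_id, gene_id, seqnames, strand,
#'   tx_len, cds_start, cds_end, cds_ok), `exons` (named list of
#'   data.frames with ascending genomic `start`,`end`), and `seq`
#'   (DNAStringSet of spliced sense-strand sequences).
#' @details Transcripts whose summed CDS length is not divisible by 3 are
#'   kept but flagged (`cds_ok = FALSE`) with a warning, and are skipped by
#'   [classify_cds()]. A CDS whose Parent is not an annotated mRNA is an
#'   error, as is a feature on a sequence absent from the FASTA.
#' @export
load_annotation <- function(gff3, fasta) {
  gr <- if (methods::is(gff3, "GRanges")) gff3 else
    rtracklayer::import(gff3, format = "gff3")
  seqs <- if (methods::is(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  id <- if ("ID" %in% names(m)) as.character(m$ID) else
    rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(m)) {
    vapply(as.list(m$Parent), function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, "")
  } else rep(NA_character_, length(gr))

  missing_seq <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                         names(seqs))
  if (length(missing_seq) > 0)
    .stopf("annotation references sequences missing from FASTA: %s",
           paste(missing_seq, collapse = ", "))

  is_mrna <- type %in% c("mRNA", "transcript")
  mrna_id <- id[is_mrna]
  mrna_parent <- parent[is_mrna]
  if (anyNA(mrna_id)) .stopf("mRNA features must carry an ID")

  cds_par <- parent[type == "CDS"]
  orphan <- setdiff(cds_par[!is.na(cds_par)], mrna_id)
  if (length(orphan) > 0 || anyNA(cds_par))
    .stopf("CDS feature without parent mRNA: %s",
           paste(head(c(orphan, if (anyNA(cds_par)) "<no Parent>"), 3),
                 collapse = ", "))

  tx_rows <- vector("list", length(mrna_id))
  exon_list <- vector("list", length(mrna_id))
  names(exon_list) <- mrna_id
  spliced <- character(length(mrna_id))

  for (i in seq_along(mrna_id)) {
    tid <- mrna_id[i]
    sel_mrna <- which(is_mrna)[i]
    strand_i <- as.character(GenomicRanges::strand(gr))[sel_mrna]
    chrom <- as.character(GenomicRanges::seqnames(gr))[sel_mrna]

    ex <- which(type == "exon" & parent == tid)
    if (length(ex) == 0) ex <- sel_mrna  # exonless mRNA: use its own span
    exons <- data.frame(start = GenomicRanges::start(gr)[ex],
                        end = GenomicRanges::end(gr)[ex])
    exons <- exons[order(exons$start), , drop = FALSE]
    exon_list[[tid]] <- exons
    tx_len <- sum(exons$end - exons$start + 1L)

    # spliced sequence: ascending-exon concatenation, reverse-complemented
    # as a whole for minus-strand transcripts
    pieces <- vapply(seq_len(nrow(exons)), function(k)
      as.character(Biostrings::subseq(seqs[[chrom]], exons$start[k],
                                      exons$end[k])), "")
    s <- paste(pieces, collapse = "")
    if (strand_i == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    spliced[i] <- s

    cds_idx <- which(type == "CDS" & parent == tid)
    cds_start <- cds_end <- NA_integer_
    cds_ok <- FALSE
    if (length(cds_idx) > 0) {
      cds_len <- sum(GenomicRanges::end(gr)[cds_idx] -
                     GenomicRanges::start(gr)[cds_idx] + 1L)
      # 5'-most CDS base in transcript space
      gpos <- if (strand_i == "+") min(GenomicRanges::start(gr)[cds_idx])
              else max(GenomicRanges::end(gr)[cds_idx])
      cds_start <- .genome_to_tx(exons, strand_i, gpos)
      cds_end <- cds_start + cds_len
      cds_ok <- cds_len %% 3L == 0L
      if (!cds_ok)
        .warnf("transcript %s: CDS length %d not divisible by 3; flagged",
               tid, cds_len)
    }

    tx_rows[[i]] <- data.frame(
      transcript_id = tid, gene_id = mrna_parent[i], seqnames = chrom,
      strand = strand_i, tx_len = tx_len, cds_start = cds_start,
      cds_end = cds_end, cds_ok = cds_ok, stringsAsFactors = FALSE)
  }

  transcripts <- do.call(rbind, tx_rows)
  seqset <- Biostrings::DNAStringSet(setNames(spliced, mrna_id))
  structure(list(transcripts = transcripts, exons = exon_list, seq = seqset),
            class = "transcript_set")
}

# 1-based genomic position -> 0-based transcript position
.genome_to_tx <- function(exons, strand, gpos) {
  lens <- exons$end - exons$start + 1L
  if (strand == "+") {
    before <- 0L
    for (k in seq_len(nrow(exons))) {
      if (gpos >= exons$start[k] && gpos <= exons$end[k])
        return(before + gpos - exons$start[k])
      before <- before + lens[k]
    }
  } else {
    before <- 0L
    for (k in rev(seq_len(nrow(exons)))) {
      if (gpos >= exons$start[k] && gpos <= exons$end[k])
        return(before + exons$end[k] - gpos)
      before <- before + lens[k]
    }
  }
  .stopf("genomic position %d not inside the transcript's exons", gpos)
}

# 0-based half-open transcript interval -> genomic blocks
# (data.frame seqnames/start/end, 1-based inclusive, ascending)
.tx_to_genome_blocks <- function(txset, transcript_id, a, b) {
  row <- txset$transcripts[txset$transcripts$transcript_id == transcript_id, ]
  exons <- txset$exons[[transcript_id]]
  lens <- exons$end - exons$start + 1L
  ord <- if (row$strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  blocks <- list()
  tpos <- 0L
  for (k in ord) {
    lo <- max(a, tpos); hi <- min(b, tpos + lens[k])
    if (lo < hi) {
      if (row$strand == "+") {
        gs <- exons$start[k] + (lo - tpos); ge <- exons$start[k] + (hi - tpos) - 1L
      } else {
        ge <- exons$end[k] - (lo - tpos); gs <- exons$end[k] - (hi - tpos) + 1L
      }
      blocks[[length(blocks) + 1L]] <- c(gs, ge)
    }
    tpos <- tpos + lens[k]
  }
  bl <- do.call(rbind, blocks)
  bl <- bl[order(bl[, 1]), , drop = FALSE]
  data.frame(seqnames = row$seqnames, start = bl[, 1], end = bl[, 2],
             stringsAsFactors = FALSE)
}

# canonical string key for a genome-space block set (dedup / overlap frames)
.blocks_key <- function(txset, transcript_id, a, b) {
  row <- txset$transcripts[txset$transcripts$transcript_id == transcript_id, ]
  bl <- .tx_to_genome_blocks(txset, transcript_id, a, b)
  sprintf("%s:%s:%s", bl$seqnames[1], row$strand,
          paste(sprintf("%d-%d", bl$start, bl$end), collapse = ";"))
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts on %d sequence(s)\n",
              nrow(x$transcripts), length(unique(x$transcripts$seqnames))))
  invisible(x)
}
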