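# Synthetic Poly-Ribo-Seq generator.
#
# Sequence design: leader backgrounds are drawn from the {A,C,G} alphabet.
# Without T no AUG and no stop codon can occur outside the designed motifs,
# so the designed uORF set is, by construction, exactly the AUG-start uORF
# content of every leader. The motifs themselves only introduce T at their
# start (ATG) and stop (TAA) codons, and each motif is checked not to spell
# an accidental AUG at its boundaries.

# ---- motif builders (all coordinates 0-based within the motif) ----------

.motif_uorf <- function(n_codons) {
  list(seq = paste0("ATG", .rand_codons(n_codons - 1, .safe_codons()), "TAA"),
       orfs = data.frame(rel_start = 0L, n_codons = n_codons))
}

# a shorter uORF nested in frame inside a longer one; only the outer one
# survives the catalog filters, so only it is listed as a truth ORF
.motif_nested <- function(b1, b2) {
  seq <- paste0("ATG", .rand_codons(b1, .safe_codons()),
                "ATG", .rand_codons(b2, .safe_codons()), "TAA")
  list(seq = seq,
       orfs = data.frame(rel_start = 0L, n_codons = b1 + b2 + 2L))
}

# two uORFs overlapping in different frames; both survive.
# Layout (0-based): A starts at 0, B starts at 4 (frame +1); A has pa
# codons, B has pb codons and terminates after A's stop.
.motif_outframe <- function(pa, pb) {
  stopifnot(pb >= pa + 1)
  len <- 3L * pb + 7L
  x <- character(len)
  safe <- c("A", "C", "G")
  x[1:3] <- c("A", "T", "G")
  x[4] <- sample(safe, 1)
  x[5:7] <- c("A", "T", "G")
  if (3 * pa >= 8) x[8:(3 * pa)] <- sample(safe, 3 * pa - 7, replace = TRUE)
  x[(3 * pa + 1):(3 * pa + 3)] <- c("T", "A", "A")
  x[(3 * pa + 4):(3 * pb + 4)] <- sample(safe, 3 * pb - 3 * pa + 1,
                                         replace = TRUE)
  x[(3 * pb + 5):(3 * pb + 7)] <- c("T", "A", "A")
  list(seq = paste(x, collapse = ""),
       orfs = data.frame(rel_start = c(0L, 4L), n_codons = c(pa, pb)))
}

# place motif sequences inside a leader with gaps >= 2 nt of T-free
# background; returns the leader string and motif start offsets
.place_in_leader <- function(leader_len, motif_seqs) {
  k <- length(motif_seqs)
  if (k == 0) {
    return(list(seq = .rand_safe_nt(leader_len), starts = integer(0)))
  }
  lens <- nchar(motif_seqs)
  extra <- leader_len - sum(lens) - 2L * (k + 1L)
  if (extra < 0) .stopf("leader of %d nt cannot hold %d nt of uORF motifs",
                        leader_len, sum(lens))
  gaps <- rep(2L, k + 1L)
  if (extra > 0)
    gaps <- gaps + tabulate(sample.int(k + 1L, extra, replace = TRUE), k + 1L)
  pieces <- character(2 * k + 1)
  starts <- integer(k)
  pos <- 0L
  for (i in seq_len(k)) {
    pieces[2 * i - 1] <- .rand_safe_nt(gaps[i])
    pos <- pos + gaps[i]
    starts[i] <- pos
    pieces[2 * i] <- motif_seqs[i]
    pos <- pos + lens[i]
  }
  pieces[2 * k + 1] <- .rand_safe_nt(gaps[k + 1L])
  list(seq = paste(pieces, collapse = ""), starts = starts)
}

.cds_seq <- function(n_codons, stop = NULL) {
  if (is.null(stop)) stop <- sample(.STOP_CODONS, 1)
  paste0("ATG", .rand_codons(n_codons - 1, .sense_codons()), stop)
}

.runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

# ---- truth catalog ------------------------------------------------------

#' Generate a synthetic genome, annotation and truth ORF catalog
#'
#' Builds a single-chromosome genome carrying canonical, short-CDS and
#' uORF-bearing genes with known coordinates and classes, including the
#' awkward cases the catalog filters must handle: in-frame nested uORFs,
#' out-of-frame overlapping uORFs, dicistronic transcripts whose second
#' annotated CDS sits in the main isoform's leader, and short in-frame
#' isoforms of canonical loci. Leader backgrounds are T-free so the designed
#' uORFs are provably the complete uORF content of each leader, and the
#' truth table lists exactly the ORF records a correct catalog must recover.
#' Per-stage expression states (untranscribed, transcribed_only, bound_only,
#' translated) and true translational efficiencies are assigned here and
#' drive the read simulator.
#'
#' @param config a [sim_config()] object.
#' @return An object of class \code{"ribosim_truth"}: a list with
#'   \code{genome} (DNAStringSet), \code{annotation} (GRanges with GFF3
#'   columns), \code{transcripts}, \code{orfs} (the truth catalog),
#'   \code{truth} (per-stage states and TE) and \code{config}.
#' @seealso [simulate_libraries()], [write_simulation()]
#' @export
generate_truth_catalog <- function(config) {
  validate_sim_config(config)
  .with_seed(config$seed, .generate_truth_catalog(config))
}

.generate_truth_catalog <- function(config) {
  genes <- list()
  add <- function(g) genes[[length(genes) + 1L]] <<- g

  n_can <- config$n_canonical
  uorf_counts <- sample(as.integer(names(config$uorfs_per_leader)), n_can,
                        replace = TRUE, prob = config$uorfs_per_leader)
  for (i in seq_len(n_can))
    add(list(type = "simple", n_uorfs = uorf_counts[i],
             codon_range = config$canonical_codon_range, class = "canonical"))
  for (i in seq_len(config$n_short_cds))
    add(list(type = "simple", n_uorfs = 0L,
             codon_range = config$short_cds_codon_range, class = "shortCDS"))
  for (i in seq_len(config$n_nested_uorf_pairs))
    add(list(type = "nested", codon_range = config$canonical_codon_range,
             class = "canonical"))
  for (i in seq_len(config$n_outframe_uorf_pairs))
    add(list(type = "outframe", codon_range = config$canonical_codon_range,
             class = "canonical"))
  for (i in seq_len(config$n_dicistronic))
    add(list(type = "dicistronic", codon_range = config$canonical_codon_range,
             class = "canonical"))
  for (i in seq_len(config$n_short_isoform_genes))
    add(list(type = "short_isoform",
             codon_range = config$canonical_codon_range, class = "canonical"))

  chrom <- "chrS"
  spacer <- 100L
  seq_parts <- character(0)
  g_off <- 0L
  tx_rows <- list()
  orf_rows <- list()
  feat_rows <- list()
  append_seq <- function(s) {
    seq_parts[[length(seq_parts) + 1L]] <<- s
    g_off <<- g_off + nchar(s)
  }

  # map a transcript-space interval [a, b) (0-based) of a primary transcript
  # to 1-based inclusive genome coordinates
  g_ivl <- function(off, tx_len, strand, a, b) {
    if (strand == "+") c(off + a + 1L, off + b)
    else c(off + tx_len - b + 1L, off + tx_len - a)
  }

  feat <- function(type, ivl, strand, id = NA_character_,
                   parent = NA_character_, phase = NA_integer_) {
    feat_rows[[length(feat_rows) + 1L]] <<- data.frame(
      seqnames = chrom, start = ivl[1], end = ivl[2], strand = strand,
      type = type, ID = id, Parent = parent, phase = phase,
      stringsAsFactors = FALSE)
  }

  orf_rec <- function(orf_id, class, tx_id, gene_id, start, n_codons,
                      tx_len, off, strand, seq) {
    end <- start + 3L * n_codons + 3L
    gb <- g_ivl(off, tx_len, strand, start, end)
    pep <- .translate_dna(substr(seq, start + 1L, start + 3L * n_codons))
    orf_rows[[length(orf_rows) + 1L]] <<- data.frame(
      orf_id = orf_id, class = class, transcript_id = tx_id,
      gene_id = gene_id, start = start, end = end,
      length_nt = 3L * n_codons + 3L, length_codons = n_codons,
      strand = strand, blocks = sprintf("%s:%s:%d-%d", chrom, strand,
                                        gb[1], gb[2]),
      peptide = pep, stringsAsFactors = FALSE)
  }

  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    gene_id <- sprintf("g%03d", gi)
    t1 <- paste0(gene_id, ".t1")
    strand <- if (gi %% 2L == 1L) "+" else "-"
    append_seq(.rand_acgt(spacer))
    off <- g_off

    n_c <- .runif_int(1, g$codon_range)
    utr3_len <- .runif_int(1, config$utr3_length_range)

    motifs <- list()
    trailing <- 0L
    if (g$type == "simple" && g$n_uorfs > 0) {
      sizes <- .runif_int(g$n_uorfs, config$uorf_codon_range)
      motifs <- lapply(sizes, .motif_uorf)
    } else if (g$type == "nested") {
      motifs <- list(.motif_nested(b1 = .runif_int(1, c(3, 8)),
                                   b2 = .runif_int(1, c(11, 20))))
    } else if (g$type == "outframe") {
      pa <- .runif_int(1, c(12, 20))
      motifs <- list(.motif_outframe(pa, pa + 2L))
    } else if (g$type == "dicistronic") {
      motifs <- list(.motif_uorf(.runif_int(1, c(15, 40))))
      trailing <- 33L  # room for the second isoform's short 3'UTR
    }
    motif_seqs <- vapply(motifs, `[[`, "", "seq")
    need <- sum(nchar(motif_seqs)) + 2L * (length(motifs) + 1L) + trailing
    leader_len <- max(.runif_int(1, config$leader_length_range), need)

    cds_seq <- .cds_seq(n_c)
    tail_codons <- NA_integer_
    if (g$type == "short_isoform") {
      # force an internal in-frame AUG so a short isoform can share the stop
      tail_codons <- .runif_int(1, c(40, min(100, n_c - 10)))
      j <- n_c - tail_codons  # 0-based codon index of the internal Met
      substr(cds_seq, 3L * j + 1L, 3L * j + 3L) <- "ATG"
    }

    placed <- .place_in_leader(leader_len - trailing, motif_seqs)
    leader_seq <- paste0(placed$seq, .rand_safe_nt(trailing))
    tx_seq <- paste0(leader_seq, cds_seq, .rand_acgt(utr3_len))
    tx_len <- nchar(tx_seq)
    cds_start <- leader_len
    cds_end <- leader_len + 3L * n_c + 3L

    append_seq(if (strand == "+") tx_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx_seq))))

    tx_rows[[length(tx_rows) + 1L]] <- data.frame(
      transcript_id = t1, gene_id = gene_id, strand = strand,
      tx_len = tx_len, leader_len = leader_len, cds_start = cds_start,
      cds_end = cds_end, g_off = off, primary = TRUE,
      stringsAsFactors = FALSE)

    # annotation features for the primary transcript
    feat("gene", g_ivl(off, tx_len, strand, 0L, tx_len), strand, id = gene_id)
    feat("mRNA", g_ivl(off, tx_len, strand, 0L, tx_len), strand, id = t1,
         parent = gene_id)
    feat("exon", g_ivl(off, tx_len, strand, 0L, tx_len), strand, parent = t1)
    feat("five_prime_UTR", g_ivl(off, tx_len, strand, 0L, cds_start), strand,
         parent = t1)
    feat("CDS", g_ivl(off, tx_len, strand, cds_start, cds_end), strand,
         id = paste0(t1, ".cds"), parent = t1, phase = 0L)
    feat("three_prime_UTR", g_ivl(off, tx_len, strand, cds_end, tx_len),
         strand, parent = t1)

    # truth records: main ORF ...
    orf_rec(paste0("cds_", t1), g$class, t1, gene_id, cds_start, n_c,
            tx_len, off, strand, tx_seq)
    # ... and surviving uORFs
    for (mi in seq_along(motifs)) {
      m <- motifs[[mi]]
      for (oi in seq_len(nrow(m$orfs))) {
        u_start <- placed$starts[mi] + m$orfs$rel_start[oi]
        orf_rec(sprintf("uorf_%s_%d", t1, u_start), "uORF", t1, gene_id,
                u_start, m$orfs$n_codons[oi], tx_len, off, strand, tx_seq)
      }
    }

    # secondary isoforms
    if (g$type == "dicistronic") {
      t2 <- paste0(gene_id, ".t2")
      a0 <- placed$starts[1]
      b0 <- a0 + nchar(motif_seqs[1]) + 30L
      c0 <- a0
      d0 <- a0 + nchar(motif_seqs[1])
      feat("mRNA", g_ivl(off, tx_len, strand, a0, b0), strand, id = t2,
           parent = gene_id)
      feat("exon", g_ivl(off, tx_len, strand, a0, b0), strand, parent = t2)
      feat("CDS", g_ivl(off, tx_len, strand, c0, d0), strand,
           id = paste0(t2, ".cds"), parent = t2, phase = 0L)
      feat("three_prime_UTR", g_ivl(off, tx_len, strand, d0, b0), strand,
           parent = t2)
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        transcript_id = t2, gene_id = gene_id, strand = strand,
        tx_len = b0 - a0, leader_len = 0L, cds_start = 0L, cds_end = d0 - c0,
        g_off = NA_integer_, primary = FALSE, stringsAsFactors = FALSE)
    } else if (g$type == "short_isoform") {
      t2 <- paste0(gene_id, ".t2")
      a0 <- cds_start + 3L * (n_c - tail_codons)
      feat("mRNA", g_ivl(off, tx_len, strand, a0, tx_len), strand, id = t2,
           parent = gene_id)
      feat("exon", g_ivl(off, tx_len, strand, a0, tx_len), strand,
           parent = t2)
      feat("CDS", g_ivl(off, tx_len, strand, a0, cds_end), strand,
           id = paste0(t2, ".cds"), parent = t2, phase = 0L)
      feat("three_prime_UTR", g_ivl(off, tx_len, strand, cds_end, tx_len),
           strand, parent = t2)
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        transcript_id = t2, gene_id = gene_id, strand = strand,
        tx_len = tx_len - a0, leader_len = 0L, cds_start = 0L,
        cds_end = cds_end - a0, g_off = NA_integer_, primary = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  append_seq(.rand_acgt(spacer))

  transcripts <- do.call(rbind, tx_rows)
  orfs <- do.call(rbind, orf_rows)
  rownames(orfs) <- NULL
  feats <- do.call(rbind, feat_rows)

  genome <- Biostrings::DNAStringSet(
    structure(paste(seq_parts, collapse = ""), names = chrom))

  annotation <- GenomicRanges::GRanges(
    seqnames = feats$seqnames,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand)
  S4Vectors::mcols(annotation) <- S4Vectors::DataFrame(
    source = "ribosim", type = feats$type, score = NA_real_,
    phase = feats$phase, ID = feats$ID,
    Parent = IRanges::CharacterList(
      lapply(feats$Parent, function(p) if (is.na(p)) character(0) else p)))

  truth <- .assign_truth_states(orfs, transcripts, config)

  structure(list(genome = genome, annotation = annotation,
                 transcripts = transcripts, orfs = orfs, truth = truth,
                 config = config),
            class = "ribosim_truth")
}

# per-ORF per-stage expression states and true TE; the state ladder
# (translated => bound => transcribed) holds by construction because uORF
# states are sampled conditional on host-transcript transcription
.assign_truth_states <- function(orfs, transcripts, config) {
  stages <- config$stages
  main <- orfs$class %in% c("canonical", "shortCDS")
  tx_ids <- unique(orfs$transcript_id)

  # transcript-level state is driven by the main ORF of the transcript
  tx_state <- matrix("", nrow = length(tx_ids), ncol = length(stages),
                     dimnames = list(tx_ids, stages))
  for (tx in tx_ids) {
    tx_state[tx, ] <- sample(names(config$state_probs), length(stages),
                             replace = TRUE, prob = config$state_probs)
  }

  n <- nrow(orfs)
  te_base <- rlnorm(n, meanlog = 0, sdlog = config$te_base_sdlog)
  state <- matrix("", nrow = n, ncol = length(stages),
                  dimnames = list(orfs$orf_id, stages))
  te <- matrix(NA_real_, nrow = n, ncol = length(stages),
               dimnames = list(orfs$orf_id, stages))
  for (i in seq_len(n)) {
    for (s in seq_along(stages)) {
      st <- tx_state[orfs$transcript_id[i], s]
      if (!main[i]) {  # uORF: conditioned on host transcription
        st <- if (st == "untranscribed") "untranscribed" else
          sample(names(config$uorf_state_probs), 1,
                 prob = config$uorf_state_probs)
      }
      state[i, s] <- st
      if (st %in% c("bound_only", "translated")) te[i, s] <- te_base[i]
    }
  }

  if (!is.null(config$te_multipliers)) {
    tm <- config$te_multipliers
    bad <- setdiff(tm$orf_id, orfs$orf_id)
    if (length(bad) > 0)
      .stopf("te_multipliers references unknown orf_id: %s",
             paste(head(bad, 3), collapse = ", "))
    for (k in seq_len(nrow(tm)))
      te[tm$orf_id[k], tm$stage[k]] <-
        te[tm$orf_id[k], tm$stage[k]] * tm$multiplier[k]
  }

  truth <- data.frame(orf_id = orfs$orf_id, class = orfs$class,
                      transcript_id = orfs$transcript_id,
                      stringsAsFactors = FALSE)
  for (s in stages) {
    truth[[paste0("state_", s)]] <- state[, s]
    truth[[paste0("te_", s)]] <- te[, s]
  }
  truth
}

# ---- read simulation ----------------------------------------------------

# footprint 5'-end positions for one ORF: a uniformly chosen codon slot plus
# the dominant-frame offset with probability `fidelity`, else one of the two
# other offsets with equal probability
.sim_fp_positions <- function(n, orf_start, n_slots, fidelity,
                              dominant_frame) {
  slots <- sample.int(n_slots, n, replace = TRUE) - 1L
  in_frame <- runif(n) < fidelity
  others <- setdiff(0:2, dominant_frame)
  offs <- ifelse(in_frame, dominant_frame,
                 others[sample.int(2L, n, replace = TRUE)])
  as.integer(orf_start + 3L * slots + offs)
}

.sim_fp_lengths <- function(n, config) {
  w <- config$footprint_length_weights
  lens <- sample(as.integer(names(w)), n, replace = TRUE, prob = w)
  if (config$fp_length_outlier_fraction > 0) {
    out <- runif(n) < config$fp_length_outlier_fraction
    lens[out] <- sample(c(24L, 25L, 37L, 38L), sum(out), replace = TRUE)
  }
  lens
}

#' Simulate staged RNA-Seq and Ribo-Seq libraries from a truth catalog
#'
#' For every stage and replicate, RNA-Seq reads are placed uniformly along
#' transcribed transcripts with expected counts proportional to transcript
#' abundance times length, and ribosome footprints are placed on codon slots
#' of bound or translated ORFs with expected counts proportional to
#' true TE x transcript abundance x ORF length. Footprint 5' ends fall in
#' the dominant frame with probability `in_frame_fraction_translated` for
#' translated ORFs and `in_frame_fraction_bound_only` (1/3: no periodicity)
#' for bound-only ORFs. Footprint lengths follow the configured 26--36 nt
#' distribution with a small out-of-range fraction. Fully seeded: identical
#' config gives identical libraries.
#'
#' @param truth a [generate_truth_catalog()] result.
#' @param config the same [sim_config()]; defaults to `truth$config`.
#' @return list with `reads` (data.frame: read_id, transcript_id,
#'   five_prime_pos, length, strand, library_id) and `libraries`
#'   (data.frame: library_id, assay, stage, replicate, total_reads).
#' @export
simulate_libraries <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ribosim_truth"))
  validate_sim_config(config)
  .with_seed(config$seed + 1L, .simulate_libraries(truth, config))
}

.simulate_libraries <- function(truth, config) {
  stages <- config$stages
  reps <- seq_len(config$replicates_per_stage)
  tx <- truth$transcripts[truth$transcripts$primary, ]
  conc <- setNames(rlnorm(nrow(tx), meanlog = 0,
                          sdlog = config$rna_abundance_sdlog),
                   tx$transcript_id)
  orfs <- truth$orfs
  truth_tab <- truth$truth

  lib_rows <- list()
  read_blocks <- list()

  for (s in stages) {
    st_orf <- truth_tab[[paste0("state_", s)]]
    te_orf <- truth_tab[[paste0("te_", s)]]
    # transcript transcribed iff its main ORF is past "untranscribed"
    main <- match(tx$transcript_id, orfs$transcript_id[
      orfs$class %in% c("canonical", "shortCDS")])
    main_ids <- orfs$orf_id[orfs$class %in% c("canonical", "shortCDS")]
    tx_on <- st_orf[match(main_ids[main], truth_tab$orf_id)] != "untranscribed"

    for (r in reps) {
      # --- RNA-Seq library ---
      lib_rna <- sprintf("%s_RNA_%d", s, r)
      w <- ifelse(tx_on, conc * tx$tx_len, 0)
      lam <- if (sum(w) > 0) config$rna_depth * w / sum(w) else w
      counts <- rpois(length(lam), lam)
      rna <- NULL
      if (sum(counts) > 0) {
        tx_idx <- rep.int(seq_along(counts), counts)
        span <- tx$tx_len[tx_idx] - config$rna_read_length + 1L
        pos <- as.integer(floor(runif(length(tx_idx)) * span))
        rna <- data.frame(
          read_id = sprintf("%s_r%07d", lib_rna, seq_along(tx_idx)),
          transcript_id = tx$transcript_id[tx_idx],
          five_prime_pos = pos, length = config$rna_read_length,
          strand = "+", library_id = lib_rna, stringsAsFactors = FALSE)
      }
      read_blocks[[length(read_blocks) + 1L]] <- rna
      lib_rows[[length(lib_rows) + 1L]] <- data.frame(
        library_id = lib_rna, assay = "RNA", stage = s, replicate = r,
        total_reads = sum(counts), stringsAsFactors = FALSE)

      # --- Ribo-Seq (footprint) library ---
      lib_fp <- sprintf("%s_FP_%d", s, r)
      expressed <- st_orf %in% c("bound_only", "translated")
      w_fp <- ifelse(expressed,
                     te_orf * conc[truth_tab$transcript_id] * orfs$length_nt,
                     0)
      w_fp[is.na(w_fp)] <- 0
      lam_fp <- if (sum(w_fp) > 0) config$fp_depth * w_fp / sum(w_fp) else w_fp
      counts_fp <- rpois(length(lam_fp), lam_fp)
      fp <- NULL
      if (sum(counts_fp) > 0) {
        fp_list <- vector("list", sum(counts_fp > 0))
        k <- 0L
        for (i in which(counts_fp > 0)) {
          nr <- counts_fp[i]
          fid <- if (st_orf[i] == "translated")
            config$in_frame_fraction_translated else
            config$in_frame_fraction_bound_only
          pos <- .sim_fp_positions(nr, orfs$start[i], orfs$length_nt[i] %/% 3L,
                                   fid, config$dominant_frame)
          k <- k + 1L
          fp_list[[k]] <- data.frame(
            transcript_id = orfs$transcript_id[i], five_prime_pos = pos,
            stringsAsFactors = FALSE)
        }
        fp <- do.call(rbind, fp_list)
        fp$length <- .sim_fp_lengths(nrow(fp), config)
        fp$strand <- "+"
        fp$library_id <- lib_fp
        fp$read_id <- sprintf("%s_r%07d", lib_fp, seq_len(nrow(fp)))
        fp <- fp[, c("read_id", "transcript_id", "five_prime_pos", "length",
                     "strand", "library_id")]
      }
      read_blocks[[length(read_blocks) + 1L]] <- fp
      lib_rows[[length(lib_rows) + 1L]] <- data.frame(
        library_id = lib_fp, assay = "FP", stage = s, replicate = r,
        total_reads = sum(counts_fp), stringsAsFactors = FALSE)
    }
  }

  reads <- do.call(rbind, read_blocks[!vapply(read_blocks, is.null, TRUE)])
  rownames(reads) <- NULL
  list(reads = reads, libraries = do.call(rbind, lib_rows))
}

#' One-call synthetic dataset
#'
#' Runs [generate_truth_catalog()] and [simulate_libraries()] and returns
#' the combined object.
#'
#' @inheritParams generate_truth_catalog
#' @return A \code{"ribosim"} list: truth catalog fields plus `reads` and
#'   `libraries`.
#' @export
simulate_ribodata <- function(config = sim_config()) {
  truth <- generate_truth_catalog(config)
  libs <- simulate_libraries(truth, config)
  structure(c(unclass(truth), libs), class = "ribosim")
}

#' Simulate footprints for a single ORF
#'
#' Low-level access to the footprint placement model: `n_reads` footprints
#' of fixed length on an ORF of `orf_length_codons` codons (stop included as
#' a slot), with 5' ends in the dominant frame with probability `fidelity`.
#' Useful for building large calibration cohorts for the framing test
#' without generating genomes.
#'
#' @param n_reads number of footprints.
#' @param orf_length_codons codon slots of the ORF (including the stop).
#' @param fidelity probability of the dominant frame (1/3 = no periodicity).
#' @param read_length footprint length (nt).
#' @param dominant_frame frame class of in-frame footprints.
#' @param orf_start transcript-space start of the ORF (0-based).
#' @param transcript_id,library_id identifiers for the returned records.
#' @return data.frame of read records as in [simulate_libraries()].
#' @export
simulate_footprints <- function(n_reads, orf_length_codons, fidelity,
                                read_length = 32L, dominant_frame = 2L,
                                orf_start = 0L, transcript_id = "tx",
                                library_id = "lib") {
  stopifnot(n_reads >= 0, orf_length_codons >= 1,
            fidelity >= 1 / 3 - 1e-12, fidelity <= 1)
  pos <- .sim_fp_positions(n_reads, orf_start, orf_length_codons, fidelity,
                           dominant_frame)
  data.frame(read_id = sprintf("%s_r%07d", library_id, seq_len(n_reads)),
             transcript_id = transcript_id, five_prime_pos = pos,
             length = as.integer(read_length), strand = "+",
             library_id = library_id, stringsAsFactors = FALSE)
}

#' @export
print.ribosim_truth <- function(x, ...) {
  cat("Synthetic ribosome-profiling truth catalog\n")
  cat(sprintf("  transcripts: %d (%d primary)\n", nrow(x$transcripts),
              sum(x$transcripts$primary)))
  cat("  truth ORFs: ", paste(sprintf("%s=%d", names(table(x$orfs$class)),
                                      table(x$orfs$class)), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  stages: %s\n", paste(x$config$stages, collapse = ", ")))
  invisible(x)
}

#' @export
print.ribosim <- function(x, ...) {
  print.ribosim_truth(x, ...)
  cat(sprintf("  libraries: %d, reads: %d\n", nrow(x$libraries),
              nrow(x$reads)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the genome FASTA, annotation GFF3 (1-based inclusive), reads as a
#' TSV (`read_id transcript_id five_prime_pos length strand library_id`,
#' 0-based transcript-space 5' positions), the library table and the truth
#' CSV.
#'
#' @param sim a [simulate_ribodata()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ribosim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.gff3"),
             reads = file.path(dir, "reads.tsv"),
             libraries = file.path(dir, "libraries.csv"),
             truth = file.path(dir, "truth.csv"),
             orfs = file.path(dir, "truth_orfs.csv"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  rtracklayer::export(sim$annotation, paths["annotation"], format = "gff3")
  write.table(sim$reads, paths["reads"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(sim$libraries, paths["libraries"], row.names = FALSE)
  write.csv(sim$truth, paths["truth"], row.names = FALSE)
  write.csv(sim$orfs, paths["orfs"], row.names = FALSE)
  invisible(paths)
}
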