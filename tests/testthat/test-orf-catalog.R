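test_that("GFF3 coordinates convert to 0-based half-open transcript space", {
  seq <- paste(rep("ACGT", 160), collapse = "")  # 640 nt
  fx <- write_gff_fixture(
    list(chrA = seq),
    list(list(seqid = "chrA", type = "gene", start = 1, end = 640,
              strand = "+", ID = "gA"),
         list(seqid = "chrA", type = "mRNA", start = 1, end = 640,
              strand = "+", ID = "tA", Parent = "gA"),
         list(seqid = "chrA", type = "exon", start = 1, end = 640,
              strand = "+", Parent = "tA"),
         list(seqid = "chrA", type = "CDS", start = 100, end = 552,
              strand = "+", ID = "cA", Parent = "tA")))
  txset <- load_annotation(fx$gff3, fx$fasta)
  tx <- txset$transcripts
  expect_equal(tx$cds_start, 99)
  expect_equal(tx$cds_end, 552)
  expect_true(tx$cds_ok)
  expect_equal(as.character(txset$seq[["tA"]]), seq)
})

test_that("a CDS length not divisible by 3 is flagged with a warning", {
  seq <- paste(rep("ACGT", 160), collapse = "")
  fx <- write_gff_fixture(
    list(chrA = seq),
    list(list(seqid = "chrA", type = "mRNA", start = 1, end = 640,
              strand = "+", ID = "tA", Parent = "gA"),
         list(seqid = "chrA", type = "exon", start = 1, end = 640,
              strand = "+", Parent = "tA"),
         list(seqid = "chrA", type = "CDS", start = 100, end = 553,
              strand = "+", ID = "cA", Parent = "tA")))
  expect_warning(txset <- load_annotation(fx$gff3, fx$fasta),
                 "not divisible by 3")
  expect_false(txset$transcripts$cds_ok)
  # coordinates are still the plain conversion: [99, 553)
  expect_equal(txset$transcripts$cds_start, 99)
  expect_equal(txset$transcripts$cds_end, 553)
  # and the flagged transcript contributes no ORF records
  expect_equal(nrow(classify_cds(txset)), 0)
})

test_that("minus-strand two-exon transcripts splice to the reverse complement", {
  set.seed(4)
  e1 <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  e2 <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  rc <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  genome <- paste0(strrep("A", 10), rc(e2), strrep("C", 20), rc(e1),
                   strrep("A", 10))
  fx <- write_gff_fixture(
    list(chrB = genome),
    list(list(seqid = "chrB", type = "mRNA", start = 11, end = 90,
              strand = "-", ID = "tB", Parent = "gB"),
         list(seqid = "chrB", type = "exon", start = 61, end = 90,
              strand = "-", Parent = "tB"),
         list(seqid = "chrB", type = "exon", start = 11, end = 40,
              strand = "-", Parent = "tB"),
         # CDS = transcript interval [6, 36): spans the splice junction
         list(seqid = "chrB", type = "CDS", start = 61, end = 84,
              strand = "-", ID = "cB", Parent = "tB"),
         list(seqid = "chrB", type = "CDS", start = 35, end = 40,
              strand = "-", ID = "cB2", Parent = "tB")))
  txset <- load_annotation(fx$gff3, fx$fasta)
  expect_equal(as.character(txset$seq[["tB"]]), paste0(e1, e2))
  expect_equal(txset$transcripts$cds_start, 6)
  expect_equal(txset$transcripts$cds_end, 36)
})

test_that("a CDS without a parent mRNA is an error", {
  fx <- write_gff_fixture(
    list(chrC = strrep("ACGT", 50)),
    list(list(seqid = "chrC", type = "mRNA", start = 1, end = 200,
              strand = "+", ID = "tC", Parent = "gC"),
         list(seqid = "chrC", type = "CDS", start = 10, end = 108,
              strand = "+", ID = "cX", Parent = "ghost")))
  expect_error(load_annotation(fx$gff3, fx$fasta), "parent mRNA")
})

test_that("annotation referencing a missing sequence is an error", {
  fx <- write_gff_fixture(
    list(chrC = strrep("ACGT", 50)),
    list(list(seqid = "chrMissing", type = "mRNA", start = 1, end = 100,
              strand = "+", ID = "tC", Parent = "gC")))
  expect_error(load_annotation(fx$gff3, fx$fasta), "missing from FASTA")
})

# one chromosome with three loci exercising the 303-nt classification rule
.classify_fixture <- function() {
  mk_cds <- function(n) strrep("GCT", n)  # no stops, arbitrary frame content
  # g1: CDS 306 nt; g2: CDS 303 nt; g3: isoforms with CDS 600 and 150 nt
  s1 <- mk_cds(102); s2 <- mk_cds(101); s3 <- mk_cds(200)
  genome <- paste0(s1, s2, s3)
  feats <- list(
    list(seqid = "chrD", type = "mRNA", start = 1, end = 306, strand = "+",
         ID = "t1", Parent = "g1"),
    list(seqid = "chrD", type = "exon", start = 1, end = 306, strand = "+",
         Parent = "t1"),
    list(seqid = "chrD", type = "CDS", start = 1, end = 306, strand = "+",
         ID = "c1", Parent = "t1"),
    list(seqid = "chrD", type = "mRNA", start = 307, end = 609,
         strand = "+", ID = "t2", Parent = "g2"),
    list(seqid = "chrD", type = "exon", start = 307, end = 609,
         strand = "+", Parent = "t2"),
    list(seqid = "chrD", type = "CDS", start = 307, end = 609, strand = "+",
         ID = "c2", Parent = "t2"),
    list(seqid = "chrD", type = "mRNA", start = 610, end = 1209,
         strand = "+", ID = "t3a", Parent = "g3"),
    list(seqid = "chrD", type = "exon", start = 610, end = 1209,
         strand = "+", Parent = "t3a"),
    list(seqid = "chrD", type = "CDS", start = 610, end = 1209,
         strand = "+", ID = "c3a", Parent = "t3a"),
    list(seqid = "chrD", type = "mRNA", start = 610, end = 759,
         strand = "+", ID = "t3b", Parent = "g3"),
    list(seqid = "chrD", type = "exon", start = 610, end = 759,
         strand = "+", Parent = "t3b"),
    list(seqid = "chrD", type = "CDS", start = 610, end = 759, strand = "+",
         ID = "c3b", Parent = "t3b"))
  write_gff_fixture(list(chrD = genome), feats)
}

test_that("the 303-nt boundary separates canonical ORFs from short CDSs", {
  fx <- .classify_fixture()
  txset <- load_annotation(fx$gff3, fx$fasta)
  orfs <- classify_cds(txset)
  expect_equal(orfs$class[orfs$transcript_id == "t1"], "canonical")  # 306 nt
  expect_equal(orfs$class[orfs$transcript_id == "t2"], "shortCDS")  # 303 nt
  expect_equal(orfs$class[orfs$transcript_id == "t3a"], "canonical")
  # the 150-nt isoform of the canonical locus g3 is discarded
  expect_false("t3b" %in% orfs$transcript_id)
})

# leader scenarios for the uORF extraction rule
.uorf_leader_tx <- function(leader) {
  cds <- paste0("ATG", strrep("GCT", 120), "TAA")
  tx_seq <- paste0(leader, cds)
  fx <- write_gff_fixture(
    list(chrE = tx_seq),
    list(list(seqid = "chrE", type = "mRNA", start = 1, end = nchar(tx_seq),
              strand = "+", ID = "tE", Parent = "gE"),
         list(seqid = "chrE", type = "exon", start = 1, end = nchar(tx_seq),
              strand = "+", Parent = "tE"),
         list(seqid = "chrE", type = "five_prime_UTR", start = 1,
              end = nchar(leader), strand = "+", Parent = "tE"),
         list(seqid = "chrE", type = "CDS", start = nchar(leader) + 1,
              end = nchar(tx_seq), strand = "+", ID = "cE", Parent = "tE")))
  load_annotation(fx$gff3, fx$fasta)
}

test_that("uORF extraction needs an AUG, an in-leader stop, and > 10 AA", {
  # AUG + 11 sense codons + stop: accepted, 11 AA after the initiator
  u11 <- extract_uorfs(.uorf_leader_tx(paste0("GG", "ATG", strrep("GCC", 11),
                                              "TAA", "GG")))
  expect_equal(nrow(u11), 1)
  expect_equal(u11$start, 2)
  expect_equal(u11$end, 2 + 3 + 33 + 3)
  # AUG + 10 sense codons + stop: 10 AA, not more than 10 -> rejected
  u10 <- extract_uorfs(.uorf_leader_tx(paste0("GG", "ATG", strrep("GCC", 10),
                                              "TAA", "GGGG")))
  expect_equal(nrow(u10), 0)
  # AUG with no in-frame stop before the leader end -> rejected
  uns <- extract_uorfs(.uorf_leader_tx(paste0("GG", "ATG", strrep("GCC", 14),
                                              "GG")))
  expect_equal(nrow(uns), 0)
  # stop hanging over the leader boundary does not count
  uhang <- extract_uorfs(.uorf_leader_tx(paste0("GG", "ATG", strrep("GCC", 11),
                                                "TA")))
  expect_equal(nrow(uhang), 0)
  # the first in-frame stop terminates the scan: a long-enough tail after an
  # early stop does not rescue the AUG
  uearly <- extract_uorfs(.uorf_leader_tx(
    paste0("GG", "ATG", strrep("GCC", 3), "TAA", strrep("GCC", 12), "TAA",
           "GG")))
  expect_equal(nrow(uearly), 0)
})

test_that("filters: dedup, CDS overlap, in-frame nesting, out-of-frame overlap", {
  cfg <- sim_config(n_canonical = 3, n_short_cds = 1,
                    uorfs_per_leader = c("1" = 1),
                    n_nested_uorf_pairs = 1, n_outframe_uorf_pairs = 1,
                    n_dicistronic = 1, n_short_isoform_genes = 1, seed = 77)
  truth <- generate_truth_catalog(cfg)
  txset <- load_annotation(truth$annotation, truth$genome)
  catalog <- build_orf_catalog(txset)

  # exact truth recovery, including the designed filter cases
  a <- as.data.frame(catalog)[order(catalog$orf_id),
                              c("orf_id", "class", "start", "end", "blocks",
                                "peptide")]
  b <- truth$orfs[order(truth$orfs$orf_id), names(a)]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)

  # the nested gene contributes exactly one surviving uORF, the
  # out-of-frame gene exactly two overlapping ones
  nested_tx <- paste0(sprintf("g%03d", 3 + 1 + 1), ".t1")
  out_tx <- paste0(sprintf("g%03d", 3 + 1 + 2), ".t1")
  expect_equal(sum(catalog$class == "uORF" &
                   catalog$transcript_id == nested_tx), 1)
  ou <- catalog[catalog$class == "uORF" & catalog$transcript_id == out_tx, ]
  expect_equal(nrow(ou), 2)
  expect_true(ou$start[1] < ou$end[2] && ou$start[2] < ou$end[1])
  expect_false((ou$start[1] - ou$start[2]) %% 3 == 0)

  # dicistronic rescue: the embedded annotated CDS survives as a uORF of
  # the host transcript
  dici_tx <- paste0(sprintf("g%03d", 3 + 1 + 3), ".t1")
  expect_equal(sum(catalog$class == "uORF" &
                   catalog$transcript_id == dici_tx), 1)

  # filtering is idempotent
  f1 <- filter_orf_set(as.data.frame(catalog), txset)
  f2 <- filter_orf_set(f1, txset)
  expect_equal(f1, f2)
})

test_that("identical uORFs from two isoforms collapse to one record", {
  # two isoforms of one gene share the same leader carrying the same uORF
  leader <- paste0("GG", "ATG", strrep("GCC", 12), "TAA", "GG")
  cds <- paste0("ATG", strrep("GCT", 120), "TAA")
  tx_seq <- paste0(leader, cds)
  n <- nchar(tx_seq); nl <- nchar(leader)
  feats <- list()
  for (t in c("tX1", "tX2")) {
    feats <- c(feats, list(
      list(seqid = "chrF", type = "mRNA", start = 1, end = n, strand = "+",
           ID = t, Parent = "gF"),
      list(seqid = "chrF", type = "exon", start = 1, end = n, strand = "+",
           Parent = t),
      list(seqid = "chrF", type = "CDS", start = nl + 1, end = n,
           strand = "+", ID = paste0(t, ".c"), Parent = t)))
  }
  fx <- write_gff_fixture(list(chrF = tx_seq), feats)
  txset <- load_annotation(fx$gff3, fx$fasta)
  catalog <- build_orf_catalog(txset)
  expect_equal(sum(catalog$class == "uORF"), 1)
  # the identical canonical CDSs also dedup to one record
  expect_equal(sum(catalog$class == "canonical"), 1)
})

test_that("no surviving uORF overlaps any annotated CDS in genome space", {
  sim <- shared_sim()
  txset <- load_annotation(sim$annotation, sim$genome)
  catalog <- build_orf_catalog(txset)
  tx <- txset$transcripts[!is.na(txset$transcripts$cds_start), ]
  # except for dicistronic rescues (annotated CDSs themselves), uORFs must
  # not touch annotated CDS nucleotides
  cds_keys <- sapply(seq_len(nrow(tx)), function(i)
    ribocall:::.blocks_key(txset, tx$transcript_id[i], tx$cds_start[i],
                           tx$cds_end[i]))
  u <- catalog[catalog$class == "uORF", ]
  for (i in seq_len(nrow(u))) {
    if (u$blocks[i] %in% cds_keys) next  # rescued dicistronic ORF
    bl <- ribocall:::.tx_to_genome_blocks(txset, u$transcript_id[i],
                                          u$start[i], u$end[i])
    for (j in seq_len(nrow(tx))) {
      cb <- ribocall:::.tx_to_genome_blocks(txset, tx$transcript_id[j],
                                            tx$cds_start[j], tx$cds_end[j])
      overlap <- any(outer(bl$start, cb$end, "<=") &
                     outer(bl$end, cb$start, ">="))
      expect_false(overlap)
    }
  }
})

test_that("catalog round-trips the shared simulation exactly", {
  sim <- shared_sim()
  txset <- load_annotation(sim$annotation, sim$genome)
  catalog <- build_orf_catalog(txset)
  a <- as.data.frame(catalog)[order(catalog$orf_id),
                              c("orf_id", "class", "transcript_id", "start",
                                "end", "length_nt", "length_codons",
                                "blocks", "peptide")]
  b <- sim$orfs[order(sim$orfs$orf_id), names(a)]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})
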