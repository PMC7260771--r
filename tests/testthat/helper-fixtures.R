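# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# a moderate-depth simulated dataset shared across test files
shared_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- sim_config(n_canonical = 14, n_short_cds = 5,
                      rna_depth = 4e4, fp_depth = 8e4, seed = 101)
    .fixtures$sim <- simulate_ribodata(cfg)
  }
  .fixtures$sim
}

shared_result <- function() {
  if (is.null(.fixtures$result)) {
    sim <- shared_sim()
    .fixtures$result <- run_pipeline(sim$annotation, sim$genome, sim$reads,
                                     sim$libraries)
  }
  .fixtures$result
}

# independent enumeration oracle for the binomial framing tail:
# P(X >= x), X ~ Binomial(n, 1/3), by direct summation of the pmf
enum_binom_tail <- function(x, n) {
  if (n == 0) return(NA_real_)
  k <- seq(x, n)
  sum(choose(n, k) * (1 / 3)^k * (2 / 3)^(n - k))
}

# write a GFF3 + FASTA fixture from feature rows; returns the two paths
write_gff_fixture <- function(seqs, features) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), fa)
  gff <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3", vapply(features, function(f) {
    attrs <- character(0)
    if (!is.null(f$ID)) attrs <- c(attrs, paste0("ID=", f$ID))
    if (!is.null(f$Parent)) attrs <- c(attrs, paste0("Parent=", f$Parent))
    paste(f$seqid, "test", f$type, f$start, f$end, ".", f$strand,
          if (identical(f$type, "CDS")) "0" else ".",
          paste(attrs, collapse = ";"), sep = "\t")
  }, ""))
  writeLines(lines, gff)
  list(fasta = fa, gff3 = gff)
}

# read records laid out by hand
make_reads <- function(pos, length = 32L, transcript_id = "tx1",
                       strand = "+", library_id = "lib1") {
  n <- length(pos)
  data.frame(read_id = sprintf("r%04d", seq_len(n)),
             transcript_id = transcript_id, five_prime_pos = as.integer(pos),
             length = as.integer(length), strand = strand,
             library_id = library_id, stringsAsFactors = FALSE)
}

# a one-transcript, one-ORF catalog row for low-level framing/count tests
make_orf <- function(start, end, orf_id = "orf1", transcript_id = "tx1",
                     class = "canonical") {
  data.frame(orf_id = orf_id, class = class, transcript_id = transcript_id,
             start = as.integer(start), end = as.integer(end),
             length_nt = as.integer(end - start), strand = "+",
             stringsAsFactors = FALSE)
}

# footprint cohort: n_orfs independent ORFs, each with `reads_per_rep`
# dominant-length footprints in each of two replicate libraries
framing_cohort <- function(n_orfs, reads_per_rep, fidelity, n_codons = 50L) {
  blocks <- vector("list", 2L * n_orfs)
  for (i in seq_len(n_orfs)) {
    tid <- sprintf("tx%04d", i)
    for (r in 1:2) {
      b <- simulate_footprints(reads_per_rep, n_codons, fidelity,
                               transcript_id = tid,
                               library_id = sprintf("s1_FP_%d", r))
      blocks[[2L * (i - 1L) + r]] <- b
    }
  }
  reads <- do.call(rbind, blocks)
  catalog <- data.frame(orf_id = sprintf("orf%04d", seq_len(n_orfs)),
                        class = "canonical",
                        transcript_id = sprintf("tx%04d", seq_len(n_orfs)),
                        start = 0L, end = 3L * n_codons,
                        length_nt = 3L * n_codons, strand = "+",
                        stringsAsFactors = FALSE)
  libraries <- data.frame(library_id = c("s1_FP_1", "s1_FP_2"),
                          assay = "FP", stage = "s1", replicate = 1:2,
                          stringsAsFactors = FALSE)
  list(reads = reads, catalog = catalog, libraries = libraries)
}
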