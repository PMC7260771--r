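test_that("Kozak scores are zero when observed equals background", {
  # each scored position sees each nucleotide once: observed = background =
  # 0.25 exactly, pseudocount included
  ctx <- vapply(c("A", "C", "G", "T"), function(n)
    paste0(strrep(n, 5), "ATG", strrep(n, 3)), "")
  tab <- build_kozak_table(ctx)
  expect_true(all(abs(tab$scores) < 1e-12))
  expect_equal(unname(tab$background), rep(0.25, 4))
  # and any context then scores 0
  expect_equal(as.numeric(kozak_score("GCCGCATGGCG", tab)), 0)
})

test_that("a single training context dominates its table", {
  # against a uniform background, so the check isolates the per-position
  # frequencies (the pooled background instead standardizes against overall
  # composition, deliberately favoring locally enriched rare nucleotides)
  ctx <- "GCCGCATGGCG"
  tab <- build_kozak_table(ctx, background = "uniform")
  nts <- strsplit(ctx, "")[[1]][c(1:5, 9:11)]
  for (j in seq_along(nts)) {
    expect_equal(rownames(tab$scores)[which.max(tab$scores[, j])], nts[j])
  }
  # the training context attains the maximal achievable score
  best <- sum(apply(tab$scores, 2, max))
  expect_equal(as.numeric(kozak_score(ctx, tab)), best)
  # pseudocounts keep absent nucleotides finite (and negative)
  others <- tab$scores[setdiff(rownames(tab$scores), nts[1]), 1]
  expect_true(all(is.finite(others) & others < 0))
})

test_that("scores add position-wise and ignore the AUG itself", {
  set.seed(14)
  ctx <- vapply(1:30, function(i)
    paste0(paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE),
                 collapse = ""), "ATG",
           paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                 collapse = "")), "")
  tab <- build_kozak_table(ctx)
  probe <- "ACGTAATGGCA"
  nts <- strsplit(probe, "")[[1]][c(1:5, 9:11)]
  manual <- sum(vapply(seq_along(nts), function(j)
    tab$scores[nts[j], j], 0))
  expect_equal(as.numeric(kozak_score(probe, tab)), manual)
  # the central codon never contributes: swap it and nothing changes
  expect_equal(as.numeric(kozak_score("ACGTACCCGCA", tab)),
               as.numeric(kozak_score("ACGTAGGGGCA", tab)))
  # training order is irrelevant
  tab2 <- build_kozak_table(rev(ctx))
  expect_equal(tab$scores, tab2$scores)
})

test_that("truncated contexts score over available positions, flagged partial", {
  ctx <- vapply(1:10, function(i) "GCCGCATGGCG", "")
  tab <- build_kozak_table(ctx)
  s <- kozak_score(c("NNNGCATGGCG", "GCCGCATGGCG"), tab)
  expect_true(attr(s, "partial")[1])
  expect_false(attr(s, "partial")[2])
  manual <- sum(tab$scores[c("G", "C", "G", "C", "G"),
                           c("-2", "-1", "+4", "+5", "+6")][cbind(1:5, 1:5)])
  expect_equal(s[1], manual)
  expect_error(kozak_score("ATG", tab), "11 nt")
})

test_that("training contexts score higher than shuffled ones on average", {
  set.seed(15)
  # contexts drawn from a biased position model
  draw <- function(n) vapply(seq_len(n), function(i)
    paste0(paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE,
                        prob = c(.4, .3, .2, .1)), collapse = ""), "ATG",
           paste(sample(c("G", "C", "A", "T"), 3, replace = TRUE,
                        prob = c(.5, .3, .1, .1)), collapse = "")), "")
  train <- draw(200)
  tab <- build_kozak_table(train)
  shuffle <- vapply(train, function(x) {
    flank <- strsplit(x, "")[[1]][c(1:5, 9:11)]
    sh <- sample(flank)
    paste0(paste(sh[1:5], collapse = ""), "ATG",
           paste(sh[6:8], collapse = ""))
  }, "", USE.NAMES = FALSE)
  expect_gt(mean(kozak_score(train, tab)), mean(kozak_score(shuffle, tab)))
})

test_that("invalid training windows are skipped with a warning", {
  expect_warning(tab <- build_kozak_table(c("GCCGCATGGCG", "GCXGCATGGCG")),
                 "non-ACGU")
  expect_equal(tab$n_contexts, 1)
  expect_warning(build_kozak_table(c("GCCGCATGGCG", "ATG")), "not 11 nt")
  expect_error(suppressWarnings(build_kozak_table("bad")), "no usable")
})

test_that("amino-acid composition pools residues over the peptide set", {
  mm <- aa_composition("MM")
  expect_equal(mm[["M"]], 1)
  expect_equal(sum(mm), 1)
  comp <- aa_composition("ACDEFGHIKLMNPQRSTVWY")
  expect_equal(unname(comp), rep(0.05, 20))
  expect_equal(sum(comp), 1)
  # invariant to order and splitting
  expect_equal(aa_composition(c("MKV", "LLA")), aa_composition("LLAMKV"))
  expect_warning(c2 <- aa_composition("MKX"), "non-standard")
  expect_equal(sum(c2), 1)
  expect_error(aa_composition(character(0)), "empty")
})

test_that("tryptic digestion cleaves after K/R and counts 7-24 AA fragments", {
  d <- tryptic_peptides("MKR")
  expect_equal(d$peptides, c("MK", "R"))
  expect_equal(d$n_detectable, 0)
  # 30-AA protein, single K at position 10: fragments of 10 and 20 AA
  p <- paste0(strrep("A", 9), "K", strrep("L", 20))
  d2 <- tryptic_peptides(p)
  expect_equal(nchar(d2$peptides), c(10, 20))
  expect_equal(d2$n_detectable, 2)
  # no cleavage sites: one long undetectable fragment
  d3 <- tryptic_peptides(strrep("G", 30))
  expect_equal(d3$n_detectable, 0)
  expect_equal(length(d3$peptides), 1)
  # bounds are inclusive
  expect_equal(tryptic_peptides(paste0(strrep("A", 6), "K"))$n_detectable, 1)
  expect_equal(tryptic_peptides(strrep("A", 24))$n_detectable, 1)
  expect_equal(tryptic_peptides(strrep("A", 25))$n_detectable, 0)
  # optional proline rule
  expect_equal(length(tryptic_peptides("AAKPAA")$peptides), 2)
  expect_equal(length(tryptic_peptides("AAKPAA",
                                       skip_proline = TRUE)$peptides), 1)
})

test_that("tryptic fragments concatenate back to the protein", {
  set.seed(16)
  for (i in 1:20) {
    p <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      sample(10:80, 1), replace = TRUE), collapse = "")
    expect_equal(paste(tryptic_peptides(p)$peptides, collapse = ""), p)
  }
})

test_that("orf_features trains on canonical contexts and scores every ORF", {
  sim <- shared_sim()
  txset <- load_annotation(sim$annotation, sim$genome)
  catalog <- build_orf_catalog(txset)
  feats <- orf_features(catalog, txset)
  expect_equal(nrow(feats), nrow(catalog))
  expect_true(all(is.finite(feats$kozak_score)))
  expect_true(all(feats$n_tryptic_detectable >= 0))
  tab <- attr(feats, "kozak_table")
  expect_equal(tab$n_contexts, sum(catalog$class == "canonical"))
  # canonical ORFs all have full 5-nt upstream context in the simulation
  expect_true(!any(feats$kozak_partial[feats$class == "canonical"]))
})
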