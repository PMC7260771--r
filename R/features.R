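# ORF sequence features: start-codon (Kozak) context log-odds scoring,
# amino-acid composition, and in-silico K/R cleavage for mass-spec
# detectability.
#
# Kozak windows cover positions -5..-1 and +4..+6 around the start codon
# (the AUG itself, positions +1..+3, is excluded): 8 scored positions in an
# 11-nt window with the AUG at offsets 6-8.

.KOZAK_POSITIONS <- c("-5", "-4", "-3", "-2", "-1", "+4", "+5", "+6")
.KOZAK_OFFSETS <- c(1:5, 9:11)  # 1-based offsets of scored positions

#' Build a Kozak-context log-odds scoring table
#'
#' From training windows (canonical start contexts), computes per scored
#' position the observed nucleotide frequencies (with a pseudocount) and
#' scores each nucleotide as `log2(observed / background)`. The background
#' is the pooled nucleotide frequency over all scored positions of the
#' training windows, or uniform 0.25.
#'
#' @param contexts character vector of 11-nt windows centered on the AUG
#'   (positions -5..+6); windows containing characters other than
#'   A/C/G/T/U are skipped with a warning ('N'-padded windows from
#'   truncated leaders contribute their known positions).
#' @param pseudocount added per (position, nucleotide) cell.
#' @param background `"pooled"` or `"uniform"`.
#' @param base logarithm base.
#' @return An object of class \code{"kozak_table"}: list with `scores`
#'   (4 x 8 matrix, rows A/C/G/T), `background`, `pseudocount`,
#'   `n_contexts`.
#' @export
build_kozak_table <- function(contexts, pseudocount = 1,
                              background = c("pooled", "uniform"),
                              base = 2) {
  background <- match.arg(background)
  if (length(contexts) < 1) .stopf("need at least one training context")
  contexts <- toupper(gsub("U", "T", toupper(contexts)))
  ok_len <- nchar(contexts) == 11L
  if (any(!ok_len)) {
    .warnf("skipping %d context(s) not 11 nt long", sum(!ok_len))
    contexts <- contexts[ok_len]
  }
  bad <- grepl("[^ACGTN]", contexts)
  if (any(bad)) {
    .warnf("skipping %d context(s) with non-ACGU symbols", sum(bad))
    contexts <- contexts[!bad]
  }
  if (length(contexts) == 0) .stopf("no usable training contexts")

  nts <- c("A", "C", "G", "T")
  counts <- matrix(0, 4, length(.KOZAK_OFFSETS),
                   dimnames = list(nts, .KOZAK_POSITIONS))
  for (j in seq_along(.KOZAK_OFFSETS)) {
    col <- substr(contexts, .KOZAK_OFFSETS[j], .KOZAK_OFFSETS[j])
    tab <- table(factor(col, levels = nts))  # 'N' drops out
    counts[, j] <- as.numeric(tab)
  }
  obs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount,
               "/")
  bg <- if (background == "uniform") rep(0.25, 4) else {
    tot <- rowSums(counts) + pseudocount
    tot / sum(tot)
  }
  scores <- log(obs / bg, base = base)
  structure(list(scores = scores, background = setNames(bg, nts),
                 pseudocount = pseudocount, n_contexts = length(contexts),
                 base = base),
            class = "kozak_table")
}

#' Score start-codon contexts against a Kozak table
#'
#' The score of a context is the sum of the position-specific values of its
#' observed nucleotides over the 8 scored positions. Unknown positions
#' ('N', e.g. from a leader shorter than 5 nt upstream of the AUG) are
#' skipped and the score flagged partial.
#'
#' @param contexts character vector of 11-nt windows (see
#'   [build_kozak_table()]).
#' @param table a [build_kozak_table()] result.
#' @return numeric scores with attribute `"partial"` (logical vector).
#' @export
kozak_score <- function(contexts, table) {
  stopifnot(inherits(table, "kozak_table"))
  contexts <- toupper(gsub("U", "T", toupper(contexts)))
  if (any(nchar(contexts) != 11L))
    .stopf("contexts must be 11 nt (pad truncated leaders with N)")
  scores <- numeric(length(contexts))
  partial <- logical(length(contexts))
  for (j in seq_along(.KOZAK_OFFSETS)) {
    nt <- substr(contexts, .KOZAK_OFFSETS[j], .KOZAK_OFFSETS[j])
    known <- nt %in% rownames(table$scores)
    partial <- partial | !known
    idx <- match(nt[known], rownames(table$scores))
    scores[known] <- scores[known] + table$scores[cbind(idx, j)]
  }
  attr(scores, "partial") <- partial
  scores
}

#' Pooled amino-acid composition of a peptide set
#'
#' @param peptides non-empty character vector of peptides in the standard
#'   20-letter alphabet; non-standard letters are excluded with a warning.
#' @return named numeric vector of residue frequencies (sums to 1).
#' @export
aa_composition <- function(peptides) {
  if (length(peptides) == 0 || all(nchar(peptides) == 0))
    .stopf("empty peptide set")
  aa <- strsplit(toupper(paste(peptides, collapse = "")), "")[[1]]
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- !aa %in% standard
  if (any(bad)) {
    .warnf("excluding %d non-standard residue(s): %s", sum(bad),
           paste(unique(aa[bad]), collapse = ""))
    aa <- aa[!bad]
  }
  if (length(aa) == 0) .stopf("no standard residues in input")
  tab <- table(factor(aa, levels = standard))
  setNames(as.numeric(tab) / length(aa), standard)
}

#' In-silico K/R cleavage and mass-spec detectability
#'
#' Cleaves a protein after every lysine (K) and arginine (R) and counts the
#' fragments whose length falls in the detectable window (7--24 AA
#' inclusive by default). Optionally suppresses cleavage before proline.
#'
#' @param protein one protein sequence (non-empty).
#' @param min_len,max_len detectable fragment length bounds (AA,
#'   inclusive).
#' @param skip_proline if TRUE, K/R followed by P does not cleave.
#' @return list with `peptides` (all fragments, in order) and
#'   `n_detectable`.
#' @export
tryptic_peptides <- function(protein, min_len = 7L, max_len = 24L,
                             skip_proline = FALSE) {
  if (length(protein) != 1 || nchar(protein) == 0)
    .stopf("need one non-empty protein sequence")
  pattern <- if (skip_proline) "(?<=[KR])(?!P)" else "(?<=[KR])"
  frags <- strsplit(protein, pattern, perl = TRUE)[[1]]
  lens <- nchar(frags)
  list(peptides = frags,
       n_detectable = sum(lens >= min_len & lens <= max_len))
}

# 11-nt start-codon windows for all catalog ORFs, N-padded where the
# transcript provides fewer than 5 nt upstream
.kozak_contexts <- function(catalog, txset) {
  vapply(seq_len(nrow(catalog)), function(i) {
    seq <- as.character(txset$seq[[catalog$transcript_id[i]]])
    a <- catalog$start[i] - 5L
    b <- catalog$start[i] + 6L  # 0-based half-open [a, b)
    left <- max(0L, -a)
    right <- max(0L, b - nchar(seq))
    core <- substr(seq, max(a, 0L) + 1L, min(b, nchar(seq)))
    paste0(strrep("N", left), core, strrep("N", right))
  }, "")
}

#' Per-ORF sequence features
#'
#' Trains the Kozak table on the canonical ORFs' start contexts (the bona
#' fide initiation sites), scores every ORF's context against it, and
#' counts detectable tryptic fragments of each peptide.
#'
#' @param catalog an ORF catalog.
#' @param txset the [load_annotation()] result it came from.
#' @param kozak optional pre-built [build_kozak_table()]; by default
#'   trained on the catalog's canonical contexts.
#' @param min_len,max_len detectable tryptic fragment bounds (AA).
#' @return data.frame: orf_id, class, kozak_score, kozak_partial,
#'   n_tryptic_detectable; the Kozak table is attached as attribute
#'   `"kozak_table"`.
#' @export
orf_features <- function(catalog, txset, kozak = NULL, min_len = 7L,
                         max_len = 24L) {
  contexts <- .kozak_contexts(catalog, txset)
  if (is.null(kozak)) {
    train <- contexts[catalog$class == "canonical"]
    if (length(train) == 0) .stopf("no canonical ORFs to train on")
    kozak <- build_kozak_table(train)
  }
  sc <- kozak_score(contexts, kozak)
  ndet <- vapply(catalog$peptide, function(p)
    tryptic_peptides(p, min_len, max_len)$n_detectable, 0L,
    USE.NAMES = FALSE)
  out <- data.frame(orf_id = catalog$orf_id, class = catalog$class,
                    kozak_score = as.numeric(sc),
                    kozak_partial = attr(sc, "partial"),
                    n_tryptic_detectable = ndet, stringsAsFactors = FALSE)
  attr(out, "kozak_table") <- kozak
  out
}

#' @export
print.kozak_table <- function(x, ...) {
  cat(sprintf("kozak_table: %d training contexts, pseudocount %g, log%g\n",
              x$n_contexts, x$pseudocount, x$base))
  print(round(x$scores, 3))
  invisible(x)
}
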