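# shared internal helpers

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# all 61 sense codons
.sense_codons <- function() {
  cods <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0), c("A", "C", "G", "T"), paste0))
  setdiff(cods, .STOP_CODONS)
}

# codons over the {A,C,G} alphabet: no T, hence can never spell ATG or a stop
.safe_codons <- function() {
  as.vector(outer(outer(c("A", "C", "G"), c("A", "C", "G"), paste0),
                  c("A", "C", "G"), paste0))
}

.rand_safe_nt <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G"), n, replace = TRUE), collapse = "")
}

.rand_codons <- function(n, pool) {
  if (n <= 0) return("")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

.rand_acgt <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# evaluate expr under a fixed RNG state, restoring the caller's state after
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.is_count <- function(x, positive = TRUE) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) &&
    (if (positive) x > 0 else x >= 0)
}

.translate_dna <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                     if.fuzzy.codon = "X"))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
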