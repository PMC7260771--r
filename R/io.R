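# Plain-text I/O for read records and result tables.
#
# Read records travel as TSV with columns read_id, transcript_id,
# five_prime_pos (0-based transcript space), length, strand, library_id.
# GFF3 is 1-based inclusive; BED output is 0-based half-open; conversions
# are exact.

#' Read aligned-read records from TSV
#'
#' @param path TSV with columns read_id, transcript_id, five_prime_pos,
#'   length, strand, library_id.
#' @return data.frame of read records.
#' @export
read_alignments <- function(path) {
  r <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "transcript_id", "five_prime_pos", "length",
            "strand", "library_id")
  if (!all(need %in% names(r)))
    .stopf("alignment TSV needs columns: %s", paste(need, collapse = ", "))
  if (any(r$five_prime_pos < 0)) .stopf("negative 5' positions")
  if (!all(r$strand %in% c("+", "-"))) .stopf("strand must be + or -")
  r
}

#' Write aligned-read records to TSV
#'
#' @param reads data.frame of read records.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_alignments <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline result tables
#'
#' Emits one CSV per ORF class combining, per ORF: the per-library RPKM
#' values, per-stage framing statistics and state calls, specificity,
#' sequence features, and (separately) the regulation table, plus a JSON
#' run manifest when the jsonlite package is available.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "ribocall_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- result_table(result)
  paths <- character(0)
  for (cls in unique(tab$class)) {
    p <- file.path(dir, paste0(cls, "_orfs.csv"))
    write.csv(tab[tab$class == cls, , drop = FALSE], p, row.names = FALSE)
    paths[cls] <- p
  }
  p <- file.path(dir, "regulation.csv")
  write.csv(result$regulation, p, row.names = FALSE)
  paths["regulation"] <- p
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(dir, "manifest.json")
    jsonlite::write_json(result$manifest, p, auto_unbox = TRUE, digits = NA)
    paths["manifest"] <- p
  }
  invisible(paths)
}

#' Flatten a pipeline result into one row per ORF
#'
#' @param result a [run_pipeline()] result.
#' @return data.frame mirroring the per-class result files: identity,
#'   per-library RPKM, per-stage framing columns and states, specificity,
#'   and sequence features.
#' @export
result_table <- function(result) {
  stopifnot(inherits(result, "ribocall_result"))
  q <- result$quant
  tab <- data.frame(orf_id = q$orf_id, class = q$class,
                    stringsAsFactors = FALSE)
  rp <- as.data.frame(q$rpkm)
  names(rp) <- paste0("rpkm_", names(rp))
  tab <- cbind(tab, rp)
  stages <- colnames(q$te)
  for (s in stages) tab[[paste0("te_", s)]] <- q$te[, s]
  fr <- result$framing
  for (s in stages) {
    f <- fr[fr$stage == s, , drop = FALSE]
    i <- match(tab$orf_id, f$orf_id)
    tab[[paste0("framed_", s)]] <- f$framed[i]
    tab[[paste0("total_", s)]] <- f$total[i]
    tab[[paste0("framing_p_", s)]] <- f$p_value[i]
  }
  calls <- result$calls
  i <- match(tab$orf_id, calls$orf_id)
  for (s in stages) tab[[paste0("state_", s)]] <-
    calls[[paste0("state_", s)]][i]
  tab$specificity <- calls$specificity[i]
  j <- match(tab$orf_id, result$features$orf_id)
  tab$kozak_score <- result$features$kozak_score[j]
  tab$n_tryptic_detectable <- result$features$n_tryptic_detectable[j]
  tab
}
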