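# End-to-end orchestration: catalog -> quantification -> framing ->
# translation calls -> regulation -> sequence features.

#' Run the full translation-calling pipeline
#'
#' Builds the ORF catalog from annotation and sequence, quantifies RPKM and
#' TE per library and stage, learns dominant footprint length/frame and
#' scores per-ORF framing per stage (replicates merged), applies the
#' transcription / ribosome-binding / framing decision ladder, calls
#' translational regulation between contiguous stages, and computes
#' sequence features. Fully deterministic: rerunning on the same inputs
#' reproduces the same tables.
#'
#' @param gff3 annotation path or GRanges.
#' @param fasta genome path or DNAStringSet.
#' @param reads read records (data.frame or TSV path).
#' @param libraries library table (library_id, assay, stage, replicate,
#'   optionally total_reads). Every stage must have at least one RNA and
#'   one FP library; replicate structure must be consistent across stages.
#' @param config a [pipeline_config()].
#' @param stages optional explicit stage order (default: order of first
#'   appearance in `libraries`).
#' @return An object of class \code{"ribocall_result"}: list with
#'   `catalog`, `quant`, `framing`, `calls`, `regulation`, `features`,
#'   `config` and `manifest`.
#' @export
run_pipeline <- function(gff3, fasta, reads, libraries,
                         config = pipeline_config(), stages = NULL) {
  if (is.character(reads)) reads <- read_alignments(reads)
  libraries <- .check_libraries(libraries, reads)
  if (!is.null(stages)) {
    if (!setequal(stages, unique(libraries$stage)))
      .stopf("stages must match the library table")
    libraries <- libraries[order(match(libraries$stage, stages)), ,
                           drop = FALSE]
  }
  st <- unique(libraries$stage)
  # consistency: every stage needs both assays, with equal replicate counts
  n_fp <- vapply(st, function(s)
    sum(libraries$assay == "FP" & libraries$stage == s), 0L)
  n_rna <- vapply(st, function(s)
    sum(libraries$assay == "RNA" & libraries$stage == s), 0L)
  if (any(n_fp == 0) || any(n_rna == 0))
    .stopf("stage(s) missing an assay: %s",
           paste(st[n_fp == 0 | n_rna == 0], collapse = ", "))
  if (length(unique(n_fp)) > 1 || length(unique(n_rna)) > 1)
    .stopf("replicate structure differs across stages")

  txset <- load_annotation(gff3, fasta)
  catalog <- build_orf_catalog(txset)
  quant <- quantify_orfs(reads, catalog, libraries,
                         length_range = config$fp_length_range)
  framing <- framing_calls(reads, catalog, libraries)
  calls <- call_translation(quant, framing, config)
  regulation <- regulation_calls(quant, stages = st)
  features <- orf_features(catalog, txset)

  manifest <- list(
    tool = "ribocall",
    version = as.character(utils::packageVersion("ribocall")),
    inputs = list(
      gff3 = if (is.character(gff3)) gff3 else "<GRanges>",
      fasta = if (is.character(fasta)) fasta else "<DNAStringSet>"),
    stages = st,
    libraries = libraries,
    config = unclass(config),
    n_orfs = as.list(table(catalog$class)))

  structure(list(catalog = catalog, quant = quant, framing = framing,
                 calls = calls, regulation = regulation,
                 features = features, config = config, manifest = manifest),
            class = "ribocall_result")
}

#' @export
print.ribocall_result <- function(x, ...) {
  cat("ribocall pipeline result\n")
  tab <- table(x$catalog$class)
  cat("  ORFs: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  stages <- colnames(x$quant$te)
  for (s in stages) {
    st <- x$calls[[paste0("state_", s)]]
    cat(sprintf("  %s: %d translated, %d bound_only, %d transcribed_only, %d untranscribed\n",
                s, sum(st == "translated"), sum(st == "bound_only"),
                sum(st == "transcribed_only"), sum(st == "untranscribed")))
  }
  reg <- x$regulation
  if (nrow(reg) > 0)
    cat(sprintf("  regulation: %d up, %d down of %d tested\n",
                sum(reg$call == "up"), sum(reg$call == "down"), nrow(reg)))
  invisible(x)
}

#' Summarize a pipeline result
#'
#' @param object a [run_pipeline()] result.
#' @param ... unused.
#' @return list with per-stage state-by-class tables, specificity counts
#'   and regulation counts, invisibly printed.
#' @export
summary.ribocall_result <- function(object, ...) {
  stages <- colnames(object$quant$te)
  states <- lapply(stages, function(s)
    table(class = object$calls$class,
          state = object$calls[[paste0("state_", s)]]))
  names(states) <- stages
  out <- list(
    states = states,
    specificity = table(class = object$calls$class,
                        specificity = object$calls$specificity),
    regulation = if (nrow(object$regulation) > 0)
      table(class = object$regulation$class, call = object$regulation$call)
      else NULL)
  class(out) <- "summary.ribocall_result"
  out
}

#' @export
print.summary.ribocall_result <- function(x, ...) {
  for (s in names(x$states)) {
    cat("state calls,", s, "\n")
    print(x$states[[s]])
  }
  cat("\nspecificity\n"); print(x$specificity)
  if (!is.null(x$regulation)) { cat("\nregulation\n"); print(x$regulation) }
  invisible(x)
}

#' Metagene framing plot
#'
#' Barplot of footprint 5'-end frame-class fractions per read length from a
#' stage's merged footprint libraries, the visual check for triplet
#' periodicity.
#'
#' @param x a [run_pipeline()] result.
#' @param reads the read records used in the run.
#' @param stage stage to plot (default: first).
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the frame-fraction matrix.
#' @export
plot.ribocall_result <- function(x, reads, stage = NULL, ...) {
  libs <- x$quant$libraries
  if (is.null(stage)) stage <- libs$stage[1]
  fp_ids <- libs$library_id[libs$assay == "FP" & libs$stage == stage]
  prof <- build_metagene_profile(
    reads[reads$library_id %in% fp_ids, , drop = FALSE], x$catalog)
  fc <- prof$frame_counts
  frac <- t(fc / pmax(rowSums(fc), 1))
  graphics::barplot(frac, beside = TRUE, legend.text = paste("frame", 0:2),
                    xlab = "footprint length (nt)",
                    ylab = "fraction of 5' ends",
                    main = paste("framing,", stage), ...)
  invisible(frac)
}
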