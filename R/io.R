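# Readers and writers for the standard formats of the pipeline: FASTA
# transcriptomes and piRNA catalogs, chimera libraries (FASTQ or two-column
# TSV), pair tables and attrition reports. FASTA/FASTQ parsing is delegated
# to Biostrings.

#' Read a transcriptome FASTA
#'
#' @param path FASTA file (wrapped or unwrapped, DNA or RNA alphabet).
#' @return named character vector of canonicalized transcript sequences.
#' @export
readTranscriptome <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- rnaCanonicalize(as.character(x), validate = FALSE)
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Read a piRNA catalog FASTA
#'
#' Records whose length differs from \code{pirna_len} are dropped with a
#' message, mirroring a fixed-length catalog.
#'
#' @param path FASTA file of piRNA sequences.
#' @param pirna_len expected piRNA length (default 21).
#' @return named character vector of piRNA sequences.
#' @export
readPiRNAs <- function(path, pirna_len = 21L) {
  seqs <- readTranscriptome(path)
  keep <- nchar(seqs) == pirna_len
  if (any(!keep))
    message(sum(!keep), " catalog records dropped (length != ", pirna_len, ")")
  seqs[keep]
}

#' Read a chimera library
#'
#' Accepts FASTQ (qualities ignored) or a two-column TSV of
#' (sequence, count). Reads containing ambiguous bases are dropped and
#' counted; identical sequences are collapsed with summed counts.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"fastq"} or \code{"tsv"}.
#' @return data.frame with columns \code{sequence}, \code{read_count} plus an
#'   attribute \code{n_dropped} (ambiguous-base reads removed).
#' @export
readChimeras <- function(path, format = c("auto", "fastq", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "tsv"
  if (format == "fastq") {
    x <- as.character(Biostrings::readBStringSet(path, format = "fastq"))
    collapseReads(unname(x))
  } else {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("chimera TSV needs columns (sequence, count)")
    names(df)[1:2] <- c("sequence", "read_count")
    seqs <- rnaCanonicalize(df$sequence, validate = FALSE)
    ok <- !grepl("[^AUGC]", seqs)
    dropped <- sum(df$read_count[!ok])
    if (dropped) message(dropped, " reads dropped (ambiguous bases)")
    agg <- tapply(df$read_count[ok], seqs[ok], sum)
    out <- data.frame(sequence = names(agg), read_count = as.integer(agg),
                      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(out$sequence), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_dropped") <- dropped
    out
  }
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write / read a pair table
#'
#' Pair tables are TSV with a header line; \code{center} is the 1-based
#' target-site center on the transcript (coordinate convention noted in a
#' leading comment line).
#'
#' @param pairs data.frame of pairs (positives, negatives or both).
#' @param path file path.
#' @return \code{readPairTable} returns the data.frame.
#' @export
writePairTable <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive; center = target-site center", con)
  write.table(pairs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePairTable
#' @export
readPairTable <- function(path) {
  read.delim(path, header = TRUE, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write an attrition report as JSON
#'
#' @param report named list of per-rule exclusion counts.
#' @param path output file.
#' @export
writeAttrition <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding the configuration as JSON
#' text, the named weight tensors, the training log and a mandatory format
#' version field.
#'
#' @param model a \linkS4class{PiRBindModel}.
#' @param path checkpoint file.
#' @return \code{loadModel} returns the restored model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "PiRBindModel"))
  cfg <- model@config
  cfg_json <- jsonlite::toJSON(
    lapply(setNames(slotNames(cfg), slotNames(cfg)), function(s) slot(cfg, s)),
    auto_unbox = TRUE)
  saveRDS(list(version = model@version, config_json = as.character(cfg_json),
               params = model@params, trained = model@trained, log = model@log),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (is.null(x$version)) stop("checkpoint has no version field")
  cl <- jsonlite::fromJSON(x$config_json)
  cfg <- netConfig(pirna_len = cl$pirna_len,
                   extension_l = (cl$mrna_len - 1L) %/% 2L,
                   n_filters = cl$n_filters, kernel_size = cl$kernel_size,
                   se_reduction = cl$se_reduction, n_heads = cl$n_heads,
                   dropout_se = cl$dropout_se, dropout_attn = cl$dropout_attn,
                   dropout_cls = cl$dropout_cls, pure_cnn = cl$pure_cnn)
  new("PiRBindModel", config = cfg, params = x$params, trained = x$trained,
      log = x$log, version = x$version)
}
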