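# Attention-weight rule extraction: summarize the per-head attention
# matrices of a forward pass into a head-averaged weight matrix, a
# per-piRNA-position salience profile, and maximal consensus regions above
# a mean + c * sd salience threshold.

.summarizeWeights <- function(meanW, c_sd, trained) {
  salience <- colMeans(meanW)
  thr <- mean(salience) + c_sd * sd(salience)
  above <- salience > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  regions <- data.frame(start = starts[keep], end = ends[keep],
                        mean_salience = vapply(keep, function(i)
                          mean(salience[starts[i]:ends[i]]), 0))
  new("RuleSummary", meanWeights = meanW, salience = salience,
      regions = regions, threshold = thr, trained = trained)
}

#' Extract the binding-rule summary for one pair
#'
#' Runs a deterministic forward pass, averages the attention weight
#' matrices over the heads (rows remain stochastic), computes the salience
#' of each piRNA position as its mean attention weight over all mRNA
#' positions, and reports maximal runs of positions whose salience exceeds
#' mean + \code{c_sd} standard deviations. An untrained model is permitted
#' but flagged in the summary.
#'
#' @param model a \linkS4class{PiRBindModel} (attention architecture).
#' @param pirna_seq,mrna_seq the pair to inspect.
#' @param c_sd salience threshold multiplier (default 1).
#' @return a \linkS4class{RuleSummary}.
#' @export
extractRule <- function(model, pirna_seq, mrna_seq, c_sd = 1) {
  if (model@config@pure_cnn)
    stop("rule extraction needs the attention architecture")
  fw <- forwardFull(model, pirna_seq, mrna_seq, mode = "eval")
  meanW <- apply(fw$attention@perHead, c(1, 2), mean)
  .summarizeWeights(meanW, c_sd, isTrained(model))
}

#' Aggregate the binding-rule summary over a pair table
#'
#' Head-averaged attention matrices of every pair are averaged again over
#' the pairs before summarization, giving the population-level view of the
#' learned rule.
#'
#' @param model a \linkS4class{PiRBindModel}.
#' @param pairs data.frame with \code{pirna_seq}, \code{segment_seq}.
#' @param c_sd salience threshold multiplier.
#' @return a \linkS4class{RuleSummary}.
#' @export
aggregateRule <- function(model, pairs, c_sd = 1) {
  if (model@config@pure_cnn)
    stop("rule extraction needs the attention architecture")
  cfg <- model@config
  enc <- .encodePairs(pairs$pirna_seq, pairs$segment_seq, cfg)
  res <- nn_forward_cpp(model@params, .cfgList(cfg), enc$pi, enc$mr,
                        training = FALSE, return_attention = TRUE)
  # (mrna_len, pirna_len, heads, pairs) -> mean over heads and pairs
  meanW <- apply(res$attention, c(1, 2), mean)
  .summarizeWeights(meanW, c_sd, isTrained(model))
}

#' Export a rule summary as TSV (and optionally a heatmap image)
#'
#' The TSV holds the head-averaged weight matrix with mRNA positions as
#' rows (m1..m31) and piRNA positions as columns (pi1..pi21); it
#' round-trips losslessly through \code{\link{readHeatmap}}. When
#' \code{image} is given, a PNG heatmap is rendered as well.
#'
#' @param summary a \linkS4class{RuleSummary}.
#' @param path TSV output path.
#' @param image optional PNG output path.
#' @return \code{path}, invisibly.
#' @export
exportHeatmap <- function(summary, path, image = NULL) {
  stopifnot(is(summary, "RuleSummary"))
  m <- summary@meanWeights
  df <- as.data.frame(m)
  colnames(df) <- paste0("pi", seq_len(ncol(m)))
  rownames(df) <- paste0("m", seq_len(nrow(m)))
  write.table(df, path, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(image)) {
    grDevices::png(image, width = 640, height = 760)
    on.exit(grDevices::dev.off())
    graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                    xlab = "piRNA position", ylab = "mRNA position",
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    main = "head-averaged attention weights")
  }
  invisible(path)
}

#' @rdname exportHeatmap
#' @param path TSV written by \code{exportHeatmap}.
#' @export
readHeatmap <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Positions of consensus regions persistent across models
#'
#' Helper for the random-pair control: intersects the consensus-region
#' position sets of several rule summaries, returning piRNA positions that
#' fall inside a consensus region in every summary.
#'
#' @param summaries list of \linkS4class{RuleSummary} objects.
#' @return integer vector of persistent positions (possibly empty).
#' @export
persistentRegions <- function(summaries) {
  pos <- lapply(summaries, function(s) {
    r <- s@regions
    if (!nrow(r)) integer()
    else unlist(lapply(seq_len(nrow(r)), function(i) r$start[i]:r$end[i]))
  })
  Reduce(intersect, pos)
}
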