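#' @export
setGeneric("positives", function(x) standardGeneric("positives"))
#' @export
setGeneric("negatives", function(x) standardGeneric("negatives"))
#' @export
setGeneric("looseSet", function(x) standardGeneric("looseSet"))
#' @export
setGeneric("attrition", function(x) standardGeneric("attrition"))
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @export
setGeneric("epochLog", function(x) standardGeneric("epochLog"))
#' @export
setGeneric("isTrained", function(x) standardGeneric("isTrained"))
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))
#' @export
setGeneric("pairTable", function(x, ...) standardGeneric("pairTable"))

#' Accessors for ground-truth and model objects
#'
#' \code{positives}/\code{negatives} return the pair tables,
#' \code{looseSet} the loose binding set, \code{attrition} the per-rule
#' exclusion report. \code{pairTable} binds positives and negatives into one
#' labeled table. For models, \code{modelConfig}, \code{epochLog},
#' \code{isTrained} and \code{nParams} expose the configuration, training
#' log, training state and trainable parameter count.
#'
#' @param x a \linkS4class{GroundTruth} or \linkS4class{PiRBindModel}.
#' @param ... unused.
#' @return see individual descriptions.
#' @name accessors
#' @aliases positives negatives looseSet attrition modelConfig epochLog
#'   isTrained nParams pairTable
NULL

#' @rdname accessors
#' @export
setMethod("positives", "GroundTruth", function(x) x@positives)
#' @rdname accessors
#' @export
setMethod("negatives", "GroundTruth", function(x) x@negatives)
#' @rdname accessors
#' @export
setMethod("looseSet", "GroundTruth", function(x) x@looseSet)
#' @rdname accessors
#' @export
setMethod("attrition", "GroundTruth", function(x) x@attrition)
#' @rdname accessors
#' @export
setMethod("pairTable", "GroundTruth", function(x, ...) {
  rbind(x@positives, x@negatives)
})
#' @rdname accessors
#' @export
setMethod("modelConfig", "PiRBindModel", function(x) x@config)
#' @rdname accessors
#' @export
setMethod("epochLog", "PiRBindModel", function(x) x@log)
#' @rdname accessors
#' @export
setMethod("isTrained", "PiRBindModel", function(x) x@trained)
#' @rdname accessors
#' @export
setMethod("nParams", "PiRBindModel", function(x) {
  nm <- names(x@params)
  sum(vapply(x@params[!grepl("_rmean$|_rvar$", nm)], length, 1L))
})

setMethod("show", "NetConfig", function(object) {
  cat("NetConfig:", object@pirna_len, "nt piRNA x", object@mrna_len, "nt mRNA segment\n")
  cat("  conv", object@n_filters, "filters (kernel", object@kernel_size,
      "), SE reduction", object@se_reduction, "\n")
  if (object@pure_cnn) cat("  pure CNN ablation (attention removed)\n")
  else cat(" ", object@n_heads, "attention heads, scale sqrt(",
           object@attn_scale_d, ")\n")
  cat("  classifier", object@fc1_width, "->", object@fc2_width, "-> 2\n")
})

setMethod("show", "PiRBindModel", function(object) {
  cat(if (object@trained) "Trained" else "Untrained",
      if (object@config@pure_cnn) "pure-CNN" else "multi-head attention",
      "piRNA binding model\n")
  show(object@config)
  cat("  trainable parameters:", nParams(object), "\n")
  if (length(object@log$train_loss))
    cat("  epochs trained:", length(object@log$train_loss),
        " final val acc:", round(utils::tail(object@log$val_acc, 1), 4), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@positives), "positive /",
      nrow(object@negatives), "negative pairs;",
      nrow(object@looseSet), "loose (piRNA, transcript) pairs\n")
})

setMethod("show", "RuleSummary", function(object) {
  cat("RuleSummary over", nrow(object@meanWeights), "mRNA x",
      ncol(object@meanWeights), "piRNA positions",
      if (!object@trained) "(untrained model!)" else "", "\n")
  if (nrow(object@regions)) {
    cat("  consensus regions (piRNA positions):\n")
    for (i in seq_len(nrow(object@regions)))
      cat(sprintf("    %d-%d (mean salience %.4f)\n", object@regions$start[i],
                  object@regions$end[i], object@regions$mean_salience[i]))
  } else cat("  no consensus region above threshold\n")
})
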