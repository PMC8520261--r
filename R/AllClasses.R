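#' Network configuration
#'
#' Architecture dimensions of the piRNA binding identification network. The
#' mRNA segment length is \code{2l + 1} where \code{l} is the degradation
#' recovery extension; the two classifier widths scale with the segment
#' length (32 and 8 units per position). The attention softmax is scaled by
#' \code{sqrt(d)} with \code{d} equal to the piRNA length.
#'
#' @slot pirna_len piRNA length in nucleotides (21).
#' @slot mrna_len mRNA segment length (2l + 1; 31 for the default l = 15).
#' @slot n_filters convolution filters per branch (128).
#' @slot kernel_size convolution kernel width (5).
#' @slot se_reduction squeeze-and-excitation bottleneck reduction factor (4).
#' @slot n_heads attention heads (16); head width is n_filters / n_heads.
#' @slot ff_hidden hidden width of the residual feed-forward block (128 * 4).
#' @slot fc1_width,fc2_width classifier hidden widths (32 and 8 per mRNA position).
#' @slot attn_scale_d softmax scale divisor d (the piRNA length).
#' @slot dropout_se,dropout_attn,dropout_cls dropout rates (0.3, 0.3, 0.75).
#' @slot pure_cnn if TRUE the multi-head attention layer is removed (ablation).
#' @exportClass NetConfig
setClass("NetConfig", representation(
  pirna_len = "integer", mrna_len = "integer", n_filters = "integer",
  kernel_size = "integer", se_reduction = "integer", n_heads = "integer",
  ff_hidden = "integer", fc1_width = "integer", fc2_width = "integer",
  attn_scale_d = "numeric", dropout_se = "numeric", dropout_attn = "numeric",
  dropout_cls = "numeric", pure_cnn = "logical"))

setValidity("NetConfig", function(object) {
  msg <- character()
  if (object@n_filters %% object@n_heads != 0)
    msg <- c(msg, "n_filters must be divisible by n_heads")
  if (object@mrna_len %% 2 != 1)
    msg <- c(msg, "mrna_len must be odd (2 * extension_l + 1)")
  if (object@kernel_size %% 2 != 1)
    msg <- c(msg, "kernel_size must be odd")
  for (s in c("pirna_len", "mrna_len", "n_filters", "n_heads", "ff_hidden",
              "fc1_width", "fc2_width"))
    if (slot(object, s) < 1L) msg <- c(msg, paste(s, "must be positive"))
  for (s in c("dropout_se", "dropout_attn", "dropout_cls"))
    if (slot(object, s) < 0 || slot(object, s) >= 1)
      msg <- c(msg, paste(s, "must be in [0, 1)"))
  if (object@attn_scale_d <= 0) msg <- c(msg, "attn_scale_d must be positive")
  if (length(msg)) msg else TRUE
})

#' Model object: configuration plus parameter tensors
#'
#' Holds a \linkS4class{NetConfig} together with all named weight tensors,
#' the training log (per-epoch loss/accuracy and learning rate) and a format
#' version string.
#'
#' @slot config the \linkS4class{NetConfig}.
#' @slot params named list of weight matrices/vectors.
#' @slot trained logical; FALSE for a freshly initialized network.
#' @slot log per-epoch training log (list of numeric vectors).
#' @slot version checkpoint format version.
#' @exportClass PiRBindModel
setClass("PiRBindModel", representation(
  config = "NetConfig", params = "list", trained = "logical",
  log = "list", version = "character"))

#' Ground-truth pair collections
#'
#' Positive and negative piRNA--mRNA pair tables plus the loose binding set
#' (LBS) used to define negative candidates, and the per-rule attrition
#' bookkeeping of the construction. Pair tables carry the columns
#' \code{pirna_id, pirna_seq, transcript_id, center, segment_seq, label,
#' read_count, remaining_len, mismatches, energy} with \code{center} 1-based.
#'
#' @slot positives data.frame of verified binding pairs.
#' @slot negatives data.frame of verified non-associated pairs.
#' @slot looseSet data.frame with columns pirna_id, transcript_id (the LBS).
#' @slot attrition named list of per-rule exclusion counts and reports.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  positives = "data.frame", negatives = "data.frame",
  looseSet = "data.frame", attrition = "list"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  need <- c("pirna_id", "pirna_seq", "segment_seq", "label")
  for (s in c("positives", "negatives")) {
    df <- slot(object, s)
    if (nrow(df) && !all(need %in% names(df)))
      msg <- c(msg, paste(s, "must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(object@positives) && nrow(object@negatives)) {
    kp <- paste(object@positives$pirna_id, object@positives$segment_seq)
    kn <- paste(object@negatives$pirna_id, object@negatives$segment_seq)
    if (length(intersect(kp, kn)))
      msg <- c(msg, "positives and negatives overlap on (pirna_id, segment) keys")
  }
  if (length(msg)) msg else TRUE
})

#' Attention output of a forward pass
#'
#' @slot perHead array (mrna_len x pirna_len x n_heads) of row-stochastic
#'   attention weight matrices, one per head.
#' @slot H the multi-head attention output matrix (mrna_len x n_filters).
#' @slot R the residual feed-forward output matrix (mrna_len x n_filters).
#' @exportClass AttentionOutput
setClass("AttentionOutput", representation(
  perHead = "array", H = "matrix", R = "matrix"))

#' Attention-derived binding-rule summary
#'
#' @slot meanWeights head-averaged attention matrix (mrna_len x pirna_len);
#'   rows remain stochastic.
#' @slot salience per-piRNA-position mean attention weight (length pirna_len).
#' @slot regions data.frame of maximal runs above the salience threshold
#'   (1-based piRNA coordinates: start, end, mean_salience).
#' @slot threshold the salience threshold used (mean + c * sd).
#' @slot trained whether the model producing the weights was trained.
#' @exportClass RuleSummary
setClass("RuleSummary", representation(
  meanWeights = "matrix", salience = "numeric", regions = "data.frame",
  threshold = "numeric", trained = "logical"))

setValidity("RuleSummary", function(object) {
  rs <- rowSums(object@meanWeights)
  if (any(abs(rs - 1) > 1e-6))
    "meanWeights rows must sum to 1 (mean of stochastic rows)" else TRUE
})
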