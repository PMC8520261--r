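# Sequence primitives: canonicalization, one-hot encoding, Hamming search
# and the default hybridization-energy scorer. All sequences are RNA strings
# over {A, U, G, C}; DNA input is accepted and T is mapped to U. Coordinates
# are 0-based half-open internally; user-facing tables are 1-based inclusive.

RNA_BASES <- c("A", "U", "G", "C")

#' Canonicalize an RNA/DNA sequence
#'
#' Upper-cases and maps T to U. With \code{validate = TRUE} (default) any
#' character outside \{A, U, G, C\} raises an error naming the first
#' offending position.
#'
#' @param x character vector of sequences.
#' @param validate reject ambiguous characters (e.g. N)?
#' @param notify emit a message when DNA (T) input is converted?
#' @return canonicalized character vector.
#' @export
rnaCanonicalize <- function(x, validate = TRUE, notify = FALSE) {
  nms <- names(x)
  x <- toupper(as.character(x))
  names(x) <- nms
  if (notify && any(grepl("T", x, fixed = TRUE)))
    message("DNA input detected: T mapped to U")
  x <- chartr("T", "U", x)
  if (validate) {
    bad <- regexpr("[^AUGC]", x)
    if (any(bad > 0)) {
      i <- which(bad > 0)[1]
      stop(sprintf("invalid base '%s' at position %d of sequence %d",
                   substr(x[i], bad[i], bad[i]), bad[i], i))
    }
    if (any(!nzchar(x))) stop("empty sequence")
  }
  x
}

# integer encoding A=1 U=2 G=3 C=4 (0-based at the C++ boundary)
.seqToInt <- function(x) {
  v <- match(strsplit(x, "", fixed = TRUE)[[1]], RNA_BASES)
  if (anyNA(v)) stop("sequence contains non-AUGC characters")
  v
}

.intToSeq <- function(v) paste(RNA_BASES[v], collapse = "")

# many equal-length sequences -> integer matrix (n x L), 0-based
.seqMatrix <- function(x, L = NULL) {
  sp <- strsplit(x, "", fixed = TRUE)
  if (is.null(L)) L <- length(sp[[1]])
  if (any(lengths(sp) != L)) stop("sequences are not all of length ", L)
  m <- matrix(match(unlist(sp), RNA_BASES), ncol = L, byrow = TRUE)
  if (anyNA(m)) stop("sequences contain non-AUGC characters")
  m - 1L
}

#' One-hot encode an RNA sequence
#'
#' Encodes each base as a unit row in the fixed channel order (A, U, G, C),
#' yielding an L x 4 binary matrix. Ambiguous bases raise an error naming the
#' offending position.
#'
#' @param seq a single sequence (character scalar).
#' @return L x 4 matrix with one 1 per row; columns named A, U, G, C.
#' @examples
#' oneHotEncode("AUGC")
#' @export
oneHotEncode <- function(seq) {
  seq <- rnaCanonicalize(seq)
  v <- .seqToInt(seq)
  m <- matrix(0L, length(v), 4L, dimnames = list(NULL, RNA_BASES))
  m[cbind(seq_along(v), v)] <- 1L
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of \code{\link{oneHotEncode}} via per-row argmax.
#'
#' @param m an L x 4 one-hot matrix in channel order (A, U, G, C).
#' @return the decoded sequence string.
#' @export
oneHotDecode <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4)
  .intToSeq(max.col(m, ties.method = "first"))
}

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of sequences.
#' @return reverse-complemented sequences (A-U, G-C swapped, reversed).
#' @examples
#' rnaRevComp("AUGC")   # "GCAU"
#' @export
rnaRevComp <- function(x) {
  x <- rnaCanonicalize(x)
  comp <- chartr("AUGC", "UACG", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b sequences of equal length.
#' @return the number of mismatching positions.
#' @export
mismatchCount <- function(a, b) {
  a <- rnaCanonicalize(a); b <- rnaCanonicalize(b)
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  seq_hamming_cpp(.seqToInt(a), .seqToInt(b))
}

#' Ungapped mismatch-tolerant substring search
#'
#' Scans the query along the subject and reports every offset where the
#' ungapped Hamming distance is at most \code{max_mm}. Overlapping hits are
#' all reported. Offsets are 0-based (\code{start0}); downstream tables
#' convert to 1-based coordinates.
#'
#' @param query,subject sequences; \code{nchar(query) <= nchar(subject)}.
#' @param max_mm maximum number of mismatches (>= 0).
#' @return data.frame with columns \code{start0} and \code{mismatches},
#'   sorted by \code{start0}.
#' @export
scanWithMismatches <- function(query, subject, max_mm = 0L) {
  query <- rnaCanonicalize(query); subject <- rnaCanonicalize(subject)
  if (!nchar(query)) stop("empty query")
  if (max_mm < 0) stop("max_mm must be >= 0")
  if (nchar(query) > nchar(subject))
    return(data.frame(start0 = integer(), mismatches = integer()))
  hits <- seq_scan_cpp(.seqToInt(query), .seqToInt(subject), as.integer(max_mm))
  data.frame(start0 = hits[, 1], mismatches = hits[, 2])
}

# pairing score of aligned piRNA base x against reverse-complemented segment
# base y: x == y is a Watson-Crick pair in the original orientation
.PAIR_GC <- -3; .PAIR_AU <- -2; .PAIR_GU <- -1; .PAIR_MM <- 0.5

.duplexInternal <- function(pirna, segment) {
  p <- strsplit(pirna, "", fixed = TRUE)[[1]]
  r <- strsplit(rnaRevComp(segment), "", fixed = TRUE)[[1]]
  # x: piRNA bases, y: reverse-complemented segment bases. x == y is a
  # Watson-Crick pair in the original orientation; the two wobble pairs
  # (piRNA G : segment U, piRNA U : segment G) appear as (G, A) and (U, C).
  score <- function(x, y)
    sum(ifelse(x == y, ifelse(x %in% c("G", "C"), .PAIR_GC, .PAIR_AU),
               ifelse((x == "G" & y == "A") | (x == "U" & y == "C"),
                      .PAIR_GU, .PAIR_MM)))
  np <- length(p); nr <- length(r)
  best <- Inf
  if (np <= nr) {
    for (off in 0:(nr - np))
      best <- min(best, score(p, r[(off + 1):(off + np)]))
  } else {
    for (off in 0:(np - nr))
      best <- min(best, score(p[(off + 1):(off + nr)], r))
  }
  best
}

.rnaupAdapter <- function(pirna, segment) {
  bin <- Sys.which("RNAup")
  if (!nzchar(bin))
    stop("RNAup engine requested but the RNAup executable is not on the PATH")
  out <- tryCatch(
    system2(bin, c("-b", "--no_output_file"),
            input = paste0(segment, "&", pirna), stdout = TRUE, stderr = FALSE),
    error = function(e) stop("RNAup invocation failed: ", conditionMessage(e)))
  m <- regmatches(out, regexpr("\\(-?[0-9.]+ = ", out))
  m <- m[nzchar(m)]
  if (!length(m)) stop("could not parse RNAup output")
  as.numeric(sub(" = $", "", sub("^\\(", "", m[1])))
}

#' Hybridization energy of a piRNA--segment duplex
#'
#' Scores the stability of the antiparallel duplex between a piRNA and an
#' mRNA segment; more negative means more stable, and values below zero are
#' required by both the positive-set and negative-set physical-pairability
#' filters. The default internal scorer takes the best ungapped alignment of
#' the piRNA against the reverse complement of the segment, scoring each
#' aligned position GC = -3, AU = -2, GU wobble = -1, mismatch = +0.5. An
#' optional adapter delegates to the external RNAup program; if that engine
#' is requested but unavailable an error is raised (never a silent fallback).
#'
#' @param pirna,segment the two sequences.
#' @param engine \code{"internal"} (default) or \code{"rnaup"}.
#' @return a scalar energy score (internal scorer: dimensionless; RNAup:
#'   kcal/mol).
#' @examples
#' duplexEnergy("AAAAA", "UUUUU") < 0   # perfect antisense
#' duplexEnergy("AAAAA", "AAAAA") >= 0  # no pairing possible
#' @export
duplexEnergy <- function(pirna, segment, engine = c("internal", "rnaup")) {
  engine <- match.arg(engine)
  pirna <- rnaCanonicalize(pirna); segment <- rnaCanonicalize(segment)
  switch(engine,
         internal = .duplexInternal(pirna, segment),
         rnaup = .rnaupAdapter(pirna, segment))
}

# run expr with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
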