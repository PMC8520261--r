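# Ground-truth construction from CLASH chimeric reads: collapse raw reads,
# excise the perfectly matching catalog piRNA from each chimera, map the
# remaining segment back to the transcriptome, apply the five rigorous
# filtering rules for the positive set and the three loose rules for the
# loose binding set (LBS), and sample verified negatives from the per-piRNA
# complement of the LBS.

#' Collapse raw chimera reads
#'
#' Drops reads containing ambiguous bases (counted and reported), then
#' collapses identical sequences into one record with its multiplicity as
#' read count.
#'
#' @param raw_sequences character vector of raw read sequences.
#' @return data.frame with columns \code{sequence}, \code{read_count},
#'   sorted by sequence; attribute \code{n_dropped} counts removed reads.
#' @export
collapseReads <- function(raw_sequences) {
  if (!length(raw_sequences)) stop("empty read input")
  seqs <- rnaCanonicalize(raw_sequences, validate = FALSE)
  ok <- !grepl("[^AUGC]", seqs)
  if (any(!ok)) message(sum(!ok), " reads dropped (ambiguous bases)")
  tab <- table(seqs[ok])
  out <- data.frame(sequence = names(tab), read_count = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

# all substring matches of every catalog piRNA in every read.
# Returns, per read, the indices of matching catalog entries and the list of
# 0-based match offsets (all occurrences).
.matchCatalog <- function(seqs, catalog) {
  hits <- vector("list", length(seqs))
  for (k in seq_along(catalog)) {
    m <- gregexpr(catalog[[k]], seqs, fixed = TRUE)
    for (i in which(vapply(m, function(z) z[1] > 0, TRUE)))
      hits[[i]] <- c(hits[[i]], list(list(idx = k, starts0 = as.integer(m[[i]]) - 1L)))
  }
  hits
}

#' Split a chimera into its piRNA and remaining segment
#'
#' Searches the read for perfect substring matches of catalog piRNAs. With
#' exactly one matching piRNA the read is split and the remaining segment
#' chosen as the longer flank (ties broken toward the 3' flank); when the
#' piRNA matches at several offsets the offset maximizing that longer flank
#' is used. Zero matching piRNAs gives state \code{"no_match"}; two or more
#' distinct piRNAs give \code{"ambiguous"}.
#'
#' @param read a chimera sequence (character scalar).
#' @param catalog named character vector of piRNA sequences.
#' @return list with \code{status} ("ok", "no_match" or "ambiguous") and,
#'   for "ok", \code{pirna_id}, \code{pirna_seq}, \code{remaining}.
#' @export
splitChimera <- function(read, catalog) {
  if (!length(catalog)) stop("empty piRNA catalog")
  read <- rnaCanonicalize(read)
  h <- .matchCatalog(read, catalog)[[1]]
  if (is.null(h)) return(list(status = "no_match"))
  if (length(h) > 1) return(list(status = "ambiguous"))
  k <- h[[1]]$idx
  sp <- .splitAt(read, nchar(catalog[[k]]), h[[1]]$starts0)
  list(status = "ok", pirna_id = names(catalog)[k], pirna_seq = catalog[[k]],
       remaining = sp)
}

# choose the remaining flank for a piRNA match of length lp at offsets
# starts0 within the read: the longer of head/tail, ties toward the 3' tail;
# across offsets, the one maximizing that flank
.splitAt <- function(read, lp, starts0) {
  n <- nchar(read)
  best <- ""
  for (s0 in starts0) {
    head <- substr(read, 1L, s0)
    tail <- substr(read, s0 + lp + 1L, n)
    flank <- if (nchar(head) > nchar(tail)) head else tail
    if (nchar(flank) > nchar(best)) best <- flank
  }
  best
}

#' Map a remaining segment to the transcriptome
#'
#' Ungapped scan of the segment against every transcript, reporting all
#' hits within the mismatch tolerance.
#'
#' @param remaining the candidate mRNA fragment.
#' @param transcriptome named character vector of transcripts.
#' @param max_mm maximum mismatches.
#' @return data.frame with columns \code{transcript_id}, \code{start0},
#'   \code{mismatches}.
#' @export
mapSegment <- function(remaining, transcriptome, max_mm = 0L) {
  if (!length(transcriptome)) stop("empty transcriptome")
  if (!nchar(remaining)) stop("empty segment")
  out <- list()
  for (tx in names(transcriptome)) {
    hits <- scanWithMismatches(remaining, transcriptome[[tx]], max_mm)
    if (nrow(hits))
      out[[length(out) + 1L]] <- data.frame(transcript_id = tx, hits,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(transcript_id = character(), start0 = integer(),
                      mismatches = integer()))
  do.call(rbind, out)
}

#' Extract the extended target site around a mapped segment
#'
#' The target-site center is the floor midpoint of the mapped start and end
#' positions; the site is the window of \code{extension_l} nucleotides
#' up- and downstream of the center (2l + 1 total). Windows overrunning
#' either transcript end are rejected (never padded).
#'
#' @param transcript the transcript sequence.
#' @param start0 0-based mapped start.
#' @param seg_len mapped segment length.
#' @param extension_l extension (default 15).
#' @return list with \code{status} "ok" (fields \code{center0},
#'   \code{segment}) or "rejected" (field \code{reason}).
#' @export
siteFromAlignment <- function(transcript, start0, seg_len, extension_l = 15L) {
  n <- nchar(transcript)
  stopifnot(start0 >= 0, start0 + seg_len <= n)
  center0 <- (start0 + start0 + seg_len - 1L) %/% 2L
  lo <- center0 - extension_l; hi <- center0 + extension_l
  if (lo < 0L) return(list(status = "rejected", reason = "window_underrun"))
  if (hi > n - 1L) return(list(status = "rejected", reason = "window_overrun"))
  list(status = "ok", center0 = center0,
       segment = substr(transcript, lo + 1L, hi + 1L))
}

#' Configuration for ground-truth construction
#'
#' Rigorous positive-set thresholds (read count >= 7, remaining length >=
#' 14, exact mapping, extension 15) and the loose binding-set thresholds
#' (read count >= 1, remaining >= 7, one mismatch allowed).
#'
#' @param min_read_count,min_remaining,max_mm rigorous rule thresholds.
#' @param loose_min_read_count,loose_min_remaining,loose_max_mm LBS rules.
#' @param extension_l degradation-recovery extension (segment = 2l + 1 nt).
#' @param energy_engine energy scorer passed to \code{\link{duplexEnergy}}.
#' @return a named list of thresholds.
#' @export
prepConfig <- function(min_read_count = 7L, min_remaining = 14L, max_mm = 0L,
                       loose_min_read_count = 1L, loose_min_remaining = 7L,
                       loose_max_mm = 1L, extension_l = 15L,
                       energy_engine = "internal") {
  cfg <- list(min_read_count = min_read_count, min_remaining = min_remaining,
              max_mm = max_mm, loose_min_read_count = loose_min_read_count,
              loose_min_remaining = loose_min_remaining,
              loose_max_mm = loose_max_mm, extension_l = extension_l,
              energy_engine = energy_engine)
  if (any(unlist(cfg[1:7]) < 0)) stop("thresholds must be >= 0")
  cfg
}

# shared front end of the rigorous and loose pipelines: read-count filter,
# chimera splitting, remaining-length filter, transcriptome mapping
.prepFrontEnd <- function(chimeras, catalog, transcriptome, min_count,
                          min_remaining, max_mm) {
  n <- nrow(chimeras)
  counts <- list(input = n, low_read_count = 0L, no_pirna_match = 0L,
                 ambiguous_pirna = 0L, short_remaining = 0L, unmapped = 0L)
  rows <- vector("list", n)
  hits_by <- .matchCatalog(chimeras$sequence, catalog)
  for (i in seq_len(n)) {
    if (chimeras$read_count[i] < min_count) {
      counts$low_read_count <- counts$low_read_count + 1L; next
    }
    h <- hits_by[[i]]
    if (is.null(h)) { counts$no_pirna_match <- counts$no_pirna_match + 1L; next }
    if (length(h) > 1) { counts$ambiguous_pirna <- counts$ambiguous_pirna + 1L; next }
    k <- h[[1]]$idx
    remaining <- .splitAt(chimeras$sequence[i], nchar(catalog[[k]]), h[[1]]$starts0)
    if (nchar(remaining) < min_remaining) {
      counts$short_remaining <- counts$short_remaining + 1L; next
    }
    hits <- mapSegment(remaining, transcriptome, max_mm)
    if (!nrow(hits)) { counts$unmapped <- counts$unmapped + 1L; next }
    rows[[i]] <- list(i = i, pirna_id = names(catalog)[k],
                      pirna_seq = catalog[[k]], remaining = remaining,
                      read_count = chimeras$read_count[i], hits = hits)
  }
  list(counts = counts, rows = Filter(Negate(is.null), rows))
}

#' Build the rigorous positive pair set
#'
#' Applies the five rigorous rules in order: (1) chimera read count at least
#' 7; (2) exactly one catalog piRNA matches perfectly inside the read, and
#' the remaining segment is at least 14 nt; (3) the remaining segment maps
#' to the transcriptome with no mismatch; (4) segments found at more than
#' one location (across isoforms or within a transcript) are excluded to
#' avoid latent training weights; (5) the piRNA--segment hybridization
#' energy is below zero. Each surviving pair carries full provenance and a
#' per-rule attrition report is attached.
#'
#' @param chimeras data.frame with \code{sequence}, \code{read_count}
#'   (from \code{\link{collapseReads}} / \code{\link{readChimeras}}).
#' @param catalog named character vector of piRNA sequences.
#' @param transcriptome named character vector of transcripts.
#' @param cfg thresholds from \code{\link{prepConfig}}.
#' @return data.frame of positive pairs with attribute \code{attrition}.
#' @export
buildPositiveSet <- function(chimeras, catalog, transcriptome, cfg = prepConfig()) {
  if (is.null(chimeras) || nrow(chimeras) == 0) {
    out <- .emptyPairs()
    attr(out, "attrition") <- list(input = 0L)
    return(out)
  }
  fe <- .prepFrontEnd(chimeras, catalog, transcriptome, cfg$min_read_count,
                      cfg$min_remaining, cfg$max_mm)
  counts <- fe$counts
  counts$multi_hit <- 0L; counts$window_overrun <- 0L
  counts$nonneg_energy <- 0L; counts$survivors <- 0L
  out <- list()
  for (r in fe$rows) {
    if (nrow(r$hits) > 1) { counts$multi_hit <- counts$multi_hit + 1L; next }
    tx <- r$hits$transcript_id[1]
    site <- siteFromAlignment(transcriptome[[tx]], r$hits$start0[1],
                              nchar(r$remaining), cfg$extension_l)
    if (site$status != "ok") {
      counts$window_overrun <- counts$window_overrun + 1L; next
    }
    en <- duplexEnergy(r$pirna_seq, site$segment, engine = cfg$energy_engine)
    if (en >= 0) { counts$nonneg_energy <- counts$nonneg_energy + 1L; next }
    counts$survivors <- counts$survivors + 1L
    out[[length(out) + 1L]] <- data.frame(
      pirna_id = r$pirna_id, pirna_seq = r$pirna_seq, transcript_id = tx,
      center = site$center0 + 1L, segment_seq = site$segment,
      label = "positive", read_count = r$read_count,
      remaining_len = nchar(r$remaining), mismatches = r$hits$mismatches[1],
      energy = en, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else .emptyPairs()
  # distinct chimeras occasionally resolve to the same (piRNA, segment) pair;
  # keep one row and book the rest so attrition counts stay conserved
  dup <- duplicated(paste(res$pirna_id, res$segment_seq))
  counts$duplicate_pair <- sum(dup)
  counts$survivors <- counts$survivors - sum(dup)
  res <- res[!dup, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "attrition") <- counts
  res
}

.emptyPairs <- function() {
  data.frame(pirna_id = character(), pirna_seq = character(),
             transcript_id = character(), center = integer(),
             segment_seq = character(), label = character(),
             read_count = integer(), remaining_len = integer(),
             mismatches = integer(), energy = numeric(),
             stringsAsFactors = FALSE)
}

#' Build the loose binding set (LBS)
#'
#' Relaxed front-end rules only: read count above zero, remaining segment
#' at least 7 nt, and one alignment mismatch allowed. Every transcript hit
#' contributes a (piRNA, transcript) pair; no uniqueness or energy
#' filtering is applied. The complement of the LBS defines the negative
#' candidate sets.
#'
#' @inheritParams buildPositiveSet
#' @return data.frame with columns \code{pirna_id}, \code{transcript_id}
#'   (unique pairs) and attribute \code{attrition}.
#' @export
buildLooseSet <- function(chimeras, catalog, transcriptome, cfg = prepConfig()) {
  if (is.null(chimeras) || nrow(chimeras) == 0)
    return(data.frame(pirna_id = character(), transcript_id = character()))
  fe <- .prepFrontEnd(chimeras, catalog, transcriptome, cfg$loose_min_read_count,
                      cfg$loose_min_remaining, cfg$loose_max_mm)
  pairs <- do.call(rbind, lapply(fe$rows, function(r)
    data.frame(pirna_id = r$pirna_id, transcript_id = unique(r$hits$transcript_id),
               stringsAsFactors = FALSE)))
  if (is.null(pairs))
    return(structure(data.frame(pirna_id = character(), transcript_id = character()),
                     attrition = fe$counts))
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  attr(pairs, "attrition") <- fe$counts
  pairs
}

#' Negative candidate set for one piRNA
#'
#' All transcripts minus the piRNA's loose binding partners. Only piRNAs
#' present in the positive set have both binding and non-binding evidence,
#' so other identifiers are rejected.
#'
#' @param pirna_id a piRNA identifier from the positive set.
#' @param universe character vector of all transcript ids.
#' @param loose_set LBS data.frame (\code{pirna_id}, \code{transcript_id}).
#' @param positive_pirnas ids of piRNAs present in the positive set.
#' @return character vector of candidate transcript ids.
#' @export
negativeCandidates <- function(pirna_id, universe, loose_set, positive_pirnas) {
  if (!pirna_id %in% positive_pirnas)
    stop("piRNA '", pirna_id, "' is not in the positive set")
  setdiff(universe, loose_set$transcript_id[loose_set$pirna_id == pirna_id])
}

#' Sample the verified negative pair set
#'
#' Draws (piRNA, 31-nt window) pairs uniformly: a positive-set piRNA, a
#' transcript from its negative candidate set (all transcripts minus its
#' loose binding partners), and a valid window start. A draw is accepted
#' only if the window is at least 3 mismatches away from every positive-set
#' segment (ungapped, equal length) and the hybridization energy is below
#' zero. Deterministic given \code{seed}.
#'
#' @param positives positive pair data.frame.
#' @param loose_set LBS data.frame.
#' @param transcriptome named character vector of transcripts.
#' @param n_target number of negatives (default: one per positive).
#' @param seed RNG seed.
#' @param cfg thresholds from \code{\link{prepConfig}}.
#' @param max_draw_factor abort with diagnostics after
#'   \code{max_draw_factor * n_target} draws.
#' @return data.frame of negative pairs.
#' @export
sampleNegatives <- function(positives, loose_set, transcriptome,
                            n_target = nrow(positives), seed = 1L,
                            cfg = prepConfig(), max_draw_factor = 200L) {
  if (n_target < 1) stop("n_target must be >= 1")
  if (!nrow(positives)) stop("positive set is empty")
  seg_len <- 2L * cfg$extension_l + 1L
  pir <- unique(positives[, c("pirna_id", "pirna_seq")])
  ncs <- lapply(pir$pirna_id, negativeCandidates, universe = names(transcriptome),
                loose_set = loose_set, positive_pirnas = pir$pirna_id)
  usable <- lengths(ncs) > 0
  if (!any(usable)) stop("every piRNA has an empty negative candidate set")
  pir <- pir[usable, , drop = FALSE]; ncs <- ncs[usable]
  pos_mat <- .seqMatrix(positives$segment_seq, seg_len)
  tx_len <- nchar(transcriptome)
  .withSeed(seed, {
    out <- vector("list", n_target)
    got <- 0L; draws <- 0L
    rej <- c(too_short = 0L, near_positive = 0L, nonneg_energy = 0L, duplicate = 0L)
    seen <- character()
    while (got < n_target) {
      draws <- draws + 1L
      if (draws > max_draw_factor * n_target)
        stop("negative sampling exhausted its draw budget (",
             draws - 1L, " draws, ", got, "/", n_target, " accepted; rejections: ",
             paste(names(rej), rej, sep = "=", collapse = ", "), ")")
      i <- sample.int(nrow(pir), 1L)
      tx <- ncs[[i]][sample.int(length(ncs[[i]]), 1L)]
      L <- tx_len[[tx]]
      if (L < seg_len) { rej["too_short"] <- rej["too_short"] + 1L; next }
      start0 <- sample.int(L - seg_len + 1L, 1L) - 1L
      segment <- substr(transcriptome[[tx]], start0 + 1L, start0 + seg_len)
      key <- paste(pir$pirna_id[i], segment)
      if (key %in% seen) { rej["duplicate"] <- rej["duplicate"] + 1L; next }
      if (seq_min_hamming_cpp(.seqToInt(segment) - 1L, pos_mat) <= 2L) {
        rej["near_positive"] <- rej["near_positive"] + 1L; next
      }
      en <- duplexEnergy(pir$pirna_seq[i], segment, engine = cfg$energy_engine)
      if (en >= 0) { rej["nonneg_energy"] <- rej["nonneg_energy"] + 1L; next }
      got <- got + 1L
      seen <- c(seen, key)
      out[[got]] <- data.frame(
        pirna_id = pir$pirna_id[i], pirna_seq = pir$pirna_seq[i],
        transcript_id = tx, center = start0 + cfg$extension_l + 1L,
        segment_seq = segment, label = "negative", read_count = NA_integer_,
        remaining_len = NA_integer_, mismatches = NA_integer_, energy = en,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    attr(res, "rejections") <- rej
    res
  })
}

#' Build a complete ground truth from a chimera library
#'
#' Convenience wrapper: rigorous positives, loose binding set and sampled
#' negatives (1:1 with the positives by default).
#'
#' @inheritParams buildPositiveSet
#' @param n_negatives number of negatives (default equals positives).
#' @param seed RNG seed for negative sampling.
#' @return a \linkS4class{GroundTruth}.
#' @export
buildGroundTruth <- function(chimeras, catalog, transcriptome,
                             cfg = prepConfig(), n_negatives = NULL, seed = 1L) {
  pos <- buildPositiveSet(chimeras, catalog, transcriptome, cfg)
  lbs <- buildLooseSet(chimeras, catalog, transcriptome, cfg)
  neg <- if (nrow(pos))
    sampleNegatives(pos, lbs, transcriptome,
                    n_target = if (is.null(n_negatives)) nrow(pos) else n_negatives,
                    seed = seed, cfg = cfg)
  else .emptyPairs()
  new("GroundTruth", positives = pos, negatives = neg, looseSet = lbs,
      attrition = list(positive = attr(pos, "attrition"),
                       loose = attr(lbs, "attrition"),
                       negative_rejections = attr(neg, "rejections")))
}

#' Assemble an independent test set
#'
#' Mirrors the CSR-1-depletion protocol: positives are sampled from the
#' independent ground truth after removing any pair (keyed by piRNA id +
#' segment sequence) already observed in the wild-type positives; negatives
#' are sampled from the independent negatives. Additionally verifies that
#' no independent positive appears in the wild-type negative set and
#' reports any conflict.
#'
#' @param independent_gt,wildtype_gt \linkS4class{GroundTruth} objects
#'   built by the same procedure.
#' @param n_pos,n_neg requested sample sizes.
#' @param seed RNG seed.
#' @return a \linkS4class{GroundTruth}; \code{attrition(x)$conflicts} lists
#'   independent positives found in the wild-type negatives.
#' @export
assembleIndependentSet <- function(independent_gt, wildtype_gt, n_pos, n_neg,
                                   seed = 1L) {
  key <- function(df) paste(df$pirna_id, df$segment_seq)
  ip <- positives(independent_gt); wp <- positives(wildtype_gt)
  pool <- ip[!key(ip) %in% key(wp), , drop = FALSE]
  if (nrow(pool) < n_pos)
    stop("only ", nrow(pool), " independent positives remain after wild-type ",
         "exclusion; ", n_pos, " requested")
  inn <- negatives(independent_gt)
  if (nrow(inn) < n_neg)
    stop("only ", nrow(inn), " independent negatives available; ", n_neg,
         " requested")
  conflicts <- key(ip)[key(ip) %in% key(negatives(wildtype_gt))]
  if (length(conflicts))
    warning(length(conflicts),
            " independent positives occur in the wild-type negative set")
  .withSeed(seed, {
    pos <- pool[sample.int(nrow(pool), n_pos), , drop = FALSE]
    neg <- inn[sample.int(nrow(inn), n_neg), , drop = FALSE]
    rownames(pos) <- rownames(neg) <- NULL
    new("GroundTruth", positives = pos, negatives = neg,
        looseSet = looseSet(independent_gt),
        attrition = list(pool_size = nrow(pool), conflicts = conflicts))
  })
}
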