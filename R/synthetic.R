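# Synthetic worlds for end-to-end testing: toy transcriptomes, piRNA
# catalogs, target sites planted as reverse-complement matches under the
# C. elegans-style targeting rule (perfect 2-7 seed, a few non-seed
# mismatches, free first base), chimera libraries with degradation trimming
# and low-count random-ligation noise, and direct labeled pair datasets.

#' Specification of a synthetic world
#'
#' The planted-rule defaults encode the described targeting biology: perfect
#' complementarity over piRNA seed positions 2-7, up to
#' \code{nonseed_max_mm} mismatches at non-seed positions, and no pairing
#' constraint on the first piRNA base. Chimera read counts mix a
#' higher-count signal component with a low-count noise spike (all noise
#' counts below the rigorous read-count threshold of 7), and degradation
#' trimming draws remaining-segment lengths with mode near 14.
#'
#' @param n_transcripts,transcript_len_range transcriptome size and lengths.
#' @param n_pirnas catalog size (21-nt piRNAs).
#' @param n_planted_sites number of target sites written into transcripts.
#' @param noise_chimera_fraction fraction of the chimera library that is
#'   random-ligation noise.
#' @param seed_range piRNA positions with perfect complementarity (2-7).
#' @param nonseed_max_mm maximum planted non-seed mismatches.
#' @param first_base_free leave the position pairing piRNA base 1 random?
#' @param pirna_len,extension_l sequence geometry (21 / 15).
#' @param signal_count_mu,signal_count_size negative-binomial read-count
#'   model of true chimeras (shifted by +1).
#' @param noise_count_max noise read counts are drawn from
#'   1..\code{noise_count_max} with geometrically decaying weights.
#' @param remaining_len_mean,remaining_len_sd degradation trim model
#'   (rounded normal, clamped to [5, 2l + 1]).
#' @param trim_jitter maximum shift of the trimmed fragment center relative
#'   to the planted site center (0 = symmetric trimming).
#' @param gc_content background base composition skew knob.
#' @param seed world RNG seed.
#' @return a named list of class \code{SynthSpec}.
#' @export
synthSpec <- function(n_transcripts = 400L, transcript_len_range = c(500L, 900L),
                      n_pirnas = 400L, n_planted_sites = 4000L,
                      noise_chimera_fraction = 0.3, seed_range = c(2L, 7L),
                      nonseed_max_mm = 3L, first_base_free = TRUE,
                      pirna_len = 21L, extension_l = 15L,
                      signal_count_mu = 30, signal_count_size = 4,
                      noise_count_max = 6L, remaining_len_mean = 14.5,
                      remaining_len_sd = 2.5, trim_jitter = 1L,
                      gc_content = 0.5, seed = 1L) {
  spec <- as.list(environment())
  if (any(c(spec$n_transcripts, spec$n_pirnas, spec$n_planted_sites) < 1))
    stop("counts must be positive")
  if (spec$noise_chimera_fraction < 0 || spec$noise_chimera_fraction >= 1)
    stop("noise_chimera_fraction must be in [0, 1)")
  if (spec$seed_range[1] < 1 || spec$seed_range[2] > spec$pirna_len)
    stop("seed_range must lie within the piRNA")
  class(spec) <- "SynthSpec"
  spec
}

.randSeq <- function(n, gc = 0.5) {
  probs <- c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)
  paste(sample(RNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

# target core for a piRNA under the planted rule. Core position j pairs
# piRNA position (pirna_len + 1 - j); the core is the reverse complement of
# the piRNA with the first-base partner randomized and n_mm non-seed
# mutations.
.plantCore <- function(pirna, spec, n_mm) {
  L <- spec$pirna_len
  core <- strsplit(rnaRevComp(pirna), "", fixed = TRUE)[[1]]
  if (spec$first_base_free) core[L] <- sample(RNA_BASES, 1L)
  nonseed_core <- setdiff(seq_len(L), c(L, L + 1L - seq(spec$seed_range[1],
                                                        spec$seed_range[2])))
  if (n_mm > 0) {
    at <- sample(nonseed_core, n_mm)
    for (j in at) core[j] <- sample(setdiff(RNA_BASES, core[j]), 1L)
  }
  paste(core, collapse = "")
}

#' Generate a synthetic world
#'
#' Uniform-random transcripts and piRNAs; each planted site writes a
#' rule-respecting target core (reverse complement of its piRNA, perfect
#' over the seed, up to \code{nonseed_max_mm} mutations elsewhere, first
#' base free) into a non-overlapping transcript window. Deterministic given
#' the generator seed.
#'
#' @param spec a \code{\link{synthSpec}}.
#' @return list of class \code{SynthWorld} with \code{transcriptome},
#'   \code{pirnas} (named character vectors) and \code{truth} (data.frame:
#'   pirna_id, transcript_id, center0, core_start0, n_mm).
#' @export
genWorld <- function(spec = synthSpec()) {
  stopifnot(inherits(spec, "SynthSpec"))
  l <- spec$extension_l; L <- spec$pirna_len
  win <- 2L * l + 1L
  .withSeed(spec$seed, {
    lens <- sample(spec$transcript_len_range[1]:spec$transcript_len_range[2],
                   spec$n_transcripts, replace = TRUE)
    tx <- vapply(lens, .randSeq, "", gc = spec$gc_content)
    names(tx) <- sprintf("tx%04d", seq_along(tx))
    pirnas <- character(0)
    while (length(pirnas) < spec$n_pirnas)
      pirnas <- unique(c(pirnas, vapply(seq_len(spec$n_pirnas - length(pirnas)),
                                        function(i) .randSeq(L, spec$gc_content), "")))
    names(pirnas) <- sprintf("pir%04d", seq_along(pirnas))
    # candidate non-overlapping windows across all transcripts
    blocks <- list()
    for (t in seq_along(tx)) {
      if (lens[t] < win + 2L) next
      off <- sample.int(win, 1L) - 1L
      if (off + l > lens[t] - 1L - l) next
      centers <- seq(off + l, lens[t] - 1L - l, by = win)
      if (length(centers))
        blocks[[length(blocks) + 1L]] <- cbind(t, centers)
    }
    blocks <- do.call(rbind, blocks)
    if (is.null(blocks) || nrow(blocks) < spec$n_planted_sites)
      stop("transcripts too short to plant ", spec$n_planted_sites, " sites (",
           if (is.null(blocks)) 0 else nrow(blocks), " windows available)")
    take <- blocks[sample.int(nrow(blocks), spec$n_planted_sites), , drop = FALSE]
    pick <- sample.int(length(pirnas), spec$n_planted_sites, replace = TRUE)
    truth <- data.frame(pirna_id = names(pirnas)[pick],
                        transcript_id = names(tx)[take[, 1]],
                        center0 = as.integer(take[, 2]),
                        core_start0 = as.integer(take[, 2]) - (L - 1L) %/% 2L,
                        n_mm = sample(0:spec$nonseed_max_mm,
                                      spec$n_planted_sites, replace = TRUE),
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(truth))) {
      core <- .plantCore(pirnas[[truth$pirna_id[i]]], spec, truth$n_mm[i])
      t <- truth$transcript_id[i]
      s <- truth$core_start0[i]
      substr(tx[[t]], s + 1L, s + L) <- core
    }
    structure(list(transcriptome = tx, pirnas = pirnas, truth = truth,
                   spec = spec), class = "SynthWorld")
  })
}

.noiseCounts <- function(n, kmax) {
  sample.int(kmax, n, replace = TRUE, prob = 0.5^seq_len(kmax))
}

.trimLen <- function(n, spec) {
  pmin(pmax(round(rnorm(n, spec$remaining_len_mean, spec$remaining_len_sd)),
            5L), 2L * spec$extension_l + 1L)
}

#' Generate a chimera library from a world
#'
#' Signal chimeras ligate each planted site's piRNA to a degradation-trimmed
#' fragment of its target region (random 5'/3' order, read counts from the
#' shifted negative-binomial signal component). Noise chimeras are random
#' ligations -- a random catalog piRNA joined to a random transcript
#' fragment (or an entirely random read) -- with read counts from the
#' low-count spike. Identical sequences are collapsed with summed counts.
#'
#' @param world a \code{\link{genWorld}} result.
#' @param spec the generating spec (defaults to the world's).
#' @param seed RNG seed for trimming, ordering and counts.
#' @return list with \code{chimeras} (data.frame sequence/read_count) and
#'   \code{bookkeeping} (per signal chimera: site index, read count,
#'   remaining length, jitter, and whether it passes the rigorous read-count
#'   and length thresholds).
#' @export
genChimeraLibrary <- function(world, spec = world$spec, seed = spec$seed + 1L) {
  stopifnot(inherits(world, "SynthWorld"))
  truth <- world$truth
  if (!nrow(truth)) stop("world has no planted sites")
  l <- spec$extension_l
  .withSeed(seed, {
    n_sig <- nrow(truth)
    Lr <- .trimLen(n_sig, spec)
    jit <- if (spec$trim_jitter > 0)
      sample(seq(-spec$trim_jitter, spec$trim_jitter), n_sig, replace = TRUE)
    else rep(0L, n_sig)
    cnt <- 1L + rnbinom(n_sig, size = spec$signal_count_size,
                        mu = spec$signal_count_mu)
    seqs <- frags <- character(n_sig)
    for (i in seq_len(n_sig)) {
      tx <- world$transcriptome[[truth$transcript_id[i]]]
      c0 <- truth$center0[i] + jit[i]
      a <- (Lr[i] - 1L) %/% 2L
      s <- min(max(c0 - a, 0L), nchar(tx) - Lr[i])
      frags[i] <- substr(tx, s + 1L, s + Lr[i])
      p <- world$pirnas[[truth$pirna_id[i]]]
      seqs[i] <- if (runif(1) < 0.5) paste0(p, frags[i]) else paste0(frags[i], p)
    }
    bookkeeping <- data.frame(truth, read_count = cnt, remaining_len = Lr,
                              jitter = jit, fragment = frags,
                              passes_thresholds = cnt >= 7L & Lr >= 14L,
                              stringsAsFactors = FALSE)
    # noise component
    f <- spec$noise_chimera_fraction
    n_noise <- if (f > 0) round(f / (1 - f) * n_sig) else 0L
    nseqs <- character(n_noise)
    if (n_noise > 0) {
      nLr <- .trimLen(n_noise, spec)
      for (i in seq_len(n_noise)) {
        if (runif(1) < 0.8) {
          p <- sample(world$pirnas, 1L)
          tx <- sample(world$transcriptome, 1L)
          s <- sample.int(max(nchar(tx) - nLr[i], 1L), 1L) - 1L
          frag <- substr(tx, s + 1L, s + nLr[i])
          nseqs[i] <- if (runif(1) < 0.5) paste0(p, frag) else paste0(frag, p)
        } else {
          nseqs[i] <- .randSeq(spec$pirna_len + nLr[i], spec$gc_content)
        }
      }
    }
    ncnt <- .noiseCounts(n_noise, spec$noise_count_max)
    all <- data.frame(sequence = c(seqs, nseqs), read_count = c(cnt, ncnt),
                      stringsAsFactors = FALSE)
    agg <- tapply(all$read_count, all$sequence, sum)
    chimeras <- data.frame(sequence = names(agg), read_count = as.integer(agg),
                           stringsAsFactors = FALSE, row.names = NULL)
    list(chimeras = chimeras, bookkeeping = bookkeeping)
  })
}

#' Generate a labeled pair dataset directly from planted sites
#'
#' Positives are planted (piRNA, 31-nt target segment) pairs read straight
#' from the world; negatives pair a random catalog piRNA with a random
#' transcript window rejected whenever it contains the reverse complement
#' of that piRNA's seed (so no negative satisfies the planted rule).
#' Balanced, shuffled and deterministic given \code{seed}.
#'
#' @param world a \code{\link{genWorld}} result.
#' @param n_pos,n_neg class sizes (defaults 3500 each, supporting a
#'   5000/1000/1000 train/validation/test split).
#' @param seed RNG seed.
#' @param compute_energy attach internal duplex energies to the pairs?
#' @return a \linkS4class{GroundTruth}.
#' @export
genPairDataset <- function(world, n_pos = 3500L, n_neg = 3500L, seed = 0L,
                           compute_energy = TRUE) {
  stopifnot(inherits(world, "SynthWorld"))
  spec <- world$spec
  l <- spec$extension_l
  truth <- world$truth
  if (nrow(truth) < n_pos)
    stop("world has only ", nrow(truth), " planted sites; ", n_pos, " requested")
  .withSeed(seed, {
    take <- truth[sample.int(nrow(truth), n_pos), , drop = FALSE]
    pos <- data.frame(
      pirna_id = take$pirna_id,
      pirna_seq = unname(world$pirnas[take$pirna_id]),
      transcript_id = take$transcript_id, center = take$center0 + 1L,
      segment_seq = vapply(seq_len(nrow(take)), function(i)
        substr(world$transcriptome[[take$transcript_id[i]]],
               take$center0[i] - l + 1L, take$center0[i] + l + 1L), ""),
      label = "positive", read_count = NA_integer_,
      remaining_len = NA_integer_, mismatches = NA_integer_,
      energy = NA_real_, stringsAsFactors = FALSE)
    # negatives: random windows with no seed complementarity to their piRNA
    tx_len <- nchar(world$transcriptome)
    ok_tx <- names(world$transcriptome)[tx_len >= 2L * l + 1L]
    neg <- vector("list", n_neg)
    seen <- character()
    got <- 0L; tries <- 0L
    while (got < n_neg) {
      tries <- tries + 1L
      if (tries > 100L * n_neg) stop("negative pair sampling exhausted its budget")
      k <- sample.int(length(world$pirnas), 1L)
      p <- world$pirnas[[k]]
      t <- ok_tx[sample.int(length(ok_tx), 1L)]
      s0 <- sample.int(tx_len[[t]] - 2L * l, 1L) - 1L
      segment <- substr(world$transcriptome[[t]], s0 + 1L, s0 + 2L * l + 1L)
      seedrc <- rnaRevComp(substr(p, spec$seed_range[1], spec$seed_range[2]))
      if (grepl(seedrc, segment, fixed = TRUE)) next
      key <- paste(names(world$pirnas)[k], segment)
      if (key %in% seen) next
      seen <- c(seen, key); got <- got + 1L
      neg[[got]] <- data.frame(
        pirna_id = names(world$pirnas)[k], pirna_seq = p, transcript_id = t,
        center = s0 + l + 1L, segment_seq = segment, label = "negative",
        read_count = NA_integer_, remaining_len = NA_integer_,
        mismatches = NA_integer_, energy = NA_real_, stringsAsFactors = FALSE)
    }
    neg <- do.call(rbind, neg)
    if (compute_energy) {
      pos$energy <- vapply(seq_len(nrow(pos)), function(i)
        duplexEnergy(pos$pirna_seq[i], pos$segment_seq[i]), 0)
      neg$energy <- vapply(seq_len(nrow(neg)), function(i)
        duplexEnergy(neg$pirna_seq[i], neg$segment_seq[i]), 0)
    }
    pos <- pos[sample.int(nrow(pos)), , drop = FALSE]
    neg <- neg[sample.int(nrow(neg)), , drop = FALSE]
    rownames(pos) <- rownames(neg) <- NULL
    new("GroundTruth", positives = pos, negatives = neg,
        looseSet = data.frame(pirna_id = character(),
                              transcript_id = character()),
        attrition = list(planted_pool = nrow(truth)))
  })
}

#' Write a synthetic world to disk
#'
#' Emits transcriptome.fasta, pirnas.fasta, chimeras.tsv and truth.tsv
#' (1-based site centers) into a directory.
#'
#' @param world a \code{\link{genWorld}} result.
#' @param dir output directory (created if needed).
#' @param chimeras optional \code{\link{genChimeraLibrary}} result.
#' @return the directory, invisibly.
#' @export
writeWorld <- function(world, dir, chimeras = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(world$transcriptome, file.path(dir, "transcriptome.fasta"))
  writeFasta(world$pirnas, file.path(dir, "pirnas.fasta"))
  truth <- world$truth
  truth$center <- truth$center0 + 1L
  write.table(truth[, c("pirna_id", "transcript_id", "center", "n_mm")],
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(chimeras))
    write.table(chimeras$chimeras, file.path(dir, "chimeras.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}
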