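# Hand-built fixtures: a 9-chimera library in which each rigorous
# positive-set rule uniquely eliminates one chimera, plus small toy worlds.
# Everything is constructed in code under a fixed seed and the construction
# is asserted before use.

hand_fixture <- function() {
  set.seed(20240917)
  pir <- character(9)
  repeat {
    pir[1:5] <- vapply(1:5, function(i) rand_seq(21), "")
    pir[7:9] <- vapply(1:3, function(i) rand_seq(21), "")
    # piRNA 6 is A/G-only so that no Watson-Crick or wobble pair can form
    # against an A/G-only target window (energy filter kill)
    pir[6] <- paste(sample(c("A", "G"), 21, TRUE, prob = c(0.7, 0.3)), collapse = "")
    if (!anyDuplicated(pir)) break
  }
  names(pir) <- paste0("P", 1:9)
  rc <- rnaRevComp(pir)

  pad <- function(n) rand_seq(n)
  r1 <- substr(rc[["P1"]], 3, 18)                 # 16 nt, survivor
  r2 <- substr(rc[["P2"]], 3, 18)                 # 16 nt, read-count kill
  r3 <- substr(rc[["P3"]], 5, 17)                 # 13 nt, too short for rigorous
  b4 <- rand_seq(20)                              # mapping-mismatch kill
  r4 <- substr(b4, 3, 17)
  substr(r4, 8, 8) <- setdiff(c("A", "U", "G", "C"),
                              substr(r4, 8, 8))[1]
  r5 <- substr(rc[["P5"]], 4, 18)                 # 15 nt, planted twice
  agz <- paste(sample(c("A", "G"), 44, TRUE), collapse = "")
  r6 <- substr(agz, 16, 29)                       # 14 nt inside the A/G zone
  r9 <- substr(rc[["P9"]], 2, 19)                 # 18 nt, survivor

  tx <- c(
    TX1 = paste0(pad(60), rc[["P1"]], pad(40), rc[["P2"]], pad(60)),
    TX2 = paste0(pad(50), rc[["P3"]], pad(30), b4, pad(30), rc[["P9"]], pad(50)),
    TX3 = paste0(pad(40), r5, pad(30), r5, pad(30), agz, pad(40)))

  chim <- data.frame(
    sequence = c(paste0(pir[["P1"]], r1), paste0(pir[["P2"]], r2),
                 paste0(r3, pir[["P3"]]), paste0(pir[["P4"]], r4),
                 paste0(pir[["P5"]], r5), paste0(pir[["P6"]], r6),
                 rand_seq(30), paste0(pir[["P7"]], pir[["P8"]]),
                 paste0(r9, pir[["P9"]])),
    read_count = c(10L, 6L, 10L, 10L, 9L, 8L, 10L, 10L, 7L),
    stringsAsFactors = FALSE)

  # construction assertions: mapping multiplicities and catalog matches are
  # exactly as designed
  n_hits <- function(q, mm = 0) sum(vapply(tx, function(s)
    nrow(scanWithMismatches(q, s, mm)), 0L))
  stopifnot(n_hits(r1) == 1, n_hits(r2) == 1, n_hits(r3) == 1,
            n_hits(r4, 0) == 0, n_hits(r4, 1) == 1, n_hits(r5) == 2,
            n_hits(r6) == 1, n_hits(r9) == 1)
  in_read <- vapply(chim$sequence, function(s)
    sum(vapply(pir, function(p) grepl(p, s, fixed = TRUE), TRUE)), 0L)
  stopifnot(identical(unname(in_read), c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 2L, 1L)))

  survivor_site <- function(r, txid) {
    s0 <- scanWithMismatches(r, tx[[txid]], 0)$start0[1]
    site <- siteFromAlignment(tx[[txid]], s0, nchar(r), 15L)
    stopifnot(site$status == "ok")
    list(center = site$center0 + 1L, segment = site$segment)
  }
  s1 <- survivor_site(r1, "TX1"); s9 <- survivor_site(r9, "TX2")

  list(chimeras = chim, catalog = pir, transcriptome = tx,
       expected = list(
         survivors = data.frame(pirna_id = c("P1", "P9"),
                                transcript_id = c("TX1", "TX2"),
                                center = c(s1$center, s9$center),
                                segment_seq = c(s1$segment, s9$segment),
                                stringsAsFactors = FALSE),
         attrition = list(input = 9L, low_read_count = 1L, no_pirna_match = 1L,
                          ambiguous_pirna = 1L, short_remaining = 1L,
                          unmapped = 1L, multi_hit = 1L, window_overrun = 0L,
                          nonneg_energy = 1L, duplicate_pair = 0L,
                          survivors = 2L),
         loose_pairs = data.frame(
           pirna_id = c("P1", "P2", "P3", "P4", "P5", "P6", "P9"),
           transcript_id = c("TX1", "TX1", "TX2", "TX2", "TX3", "TX3", "TX2"),
           stringsAsFactors = FALSE)))
}

# small world for prep-pipeline properties (fast to run end to end)
small_world_spec <- function(...) {
  synthSpec(n_transcripts = 40L, transcript_len_range = c(300L, 500L),
            n_pirnas = 40L, n_planted_sites = 60L, seed = 7L, ...)
}
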