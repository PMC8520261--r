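test_that("worlds are deterministic and plant seed-perfect antisense cores", {
  spec <- small_world_spec()
  w1 <- genWorld(spec); w2 <- genWorld(spec)
  expect_identical(w1$transcriptome, w2$transcriptome)
  expect_identical(w1$truth, w2$truth)
  # every planted site pairs its piRNA perfectly over seed positions 2-7
  L <- spec$pirna_len
  for (i in seq_len(nrow(w1$truth))) {
    tr <- w1$truth[i, ]
    core <- substr(w1$transcriptome[[tr$transcript_id]],
                   tr$core_start0 + 1L, tr$core_start0 + L)
    pir <- w1$pirnas[[tr$pirna_id]]
    # core position j pairs piRNA position L + 1 - j
    seed_core <- substr(core, L + 1L - 7L, L + 1L - 2L)
    expect_identical(seed_core, rnaRevComp(substr(pir, 2, 7)))
    # non-seed mismatch budget holds
    expect_lte(mismatchCount(core, rnaRevComp(pir)),
               tr$n_mm + spec$first_base_free)
    # and the seed-complement 6-mer is recovered by scanning
    hits <- scanWithMismatches(seed_core,
                               w1$transcriptome[[tr$transcript_id]], 0)
    expect_true((tr$core_start0 + L - 7L) %in% hits$start0)
  }
  expect_error(genWorld(synthSpec(n_transcripts = 2L,
                                  transcript_len_range = c(40L, 50L),
                                  n_planted_sites = 100L)),
               "too short")
})

test_that("chimera libraries carry a low-count noise spike and signal counts", {
  w <- genWorld(small_world_spec(noise_chimera_fraction = 0.4))
  lib <- genChimeraLibrary(w)
  expect_identical(sum(lib$bookkeeping$read_count >= 1), nrow(w$truth))
  # the noise component sits strictly below the read-count threshold of 7
  n_sig <- nrow(lib$bookkeeping)
  n_noise <- nrow(lib$chimeras) - n_sig
  expect_gt(n_noise, 0)
  # remaining-length trim model has its mode near 14
  tl <- lib$bookkeeping$remaining_len
  expect_lt(abs(median(tl) - 14.5), 2)
  # determinism
  lib2 <- genChimeraLibrary(w)
  expect_identical(lib$chimeras, lib2$chimeras)
})

test_that("a library whose counts stay in the noise spike yields no positives", {
  w <- genWorld(small_world_spec())
  lib <- genChimeraLibrary(w, seed = 99)
  # keep only records inside the low-count spike (noise counts are capped at
  # 6 by the model); the read-count rule must then eliminate everything
  noise_only <- lib$chimeras[lib$chimeras$read_count <= 6, , drop = FALSE]
  expect_gt(nrow(noise_only), 0)
  pos <- buildPositiveSet(noise_only, w$pirnas, w$transcriptome)
  expect_identical(nrow(pos), 0L)
})

test_that("the prep pipeline recovers planted, threshold-passing sites", {
  spec <- small_world_spec(noise_chimera_fraction = 0, trim_jitter = 0L)
  w <- genWorld(spec)
  lib <- genChimeraLibrary(w, spec)
  pos <- buildPositiveSet(lib$chimeras, w$pirnas, w$transcriptome)
  bk <- lib$bookkeeping
  # threshold-passing sites whose fragment is a unique transcriptome match;
  # duplicated targets are excluded by the multi-hit rule by design
  passing <- bk[bk$passes_thresholds, ]
  unique_map <- vapply(passing$fragment, function(fr)
    nrow(mapSegment(fr, w$transcriptome, 0)) == 1L, TRUE)
  passing <- passing[unique_map, ]
  key <- function(df) paste(df$pirna_id, df$transcript_id, df$center)
  passing$center <- passing$center0 + 1L
  recovered <- key(passing) %in% key(pos)
  expect_gte(mean(recovered), 0.95)
  # closing the loop against the direct pair generator: symmetric trimming
  # reproduces the planted keys (Jaccard over (piRNA, transcript, center))
  jac <- length(intersect(key(pos), key(passing))) /
    length(union(key(pos), key(passing)))
  expect_gte(jac, 0.9)
  # no sub-threshold chimera yields a positive
  expect_true(all(pos$read_count >= 7))
})

test_that("direct pair datasets are balanced, leak-free and seeded", {
  w <- genWorld(small_world_spec())
  gt <- genPairDataset(w, n_pos = 50, n_neg = 50, seed = 3)
  expect_identical(nrow(positives(gt)), 50L)
  expect_identical(nrow(negatives(gt)), 50L)
  # label-leakage check: no negative contains its piRNA's seed complement
  neg <- negatives(gt)
  for (i in seq_len(nrow(neg))) {
    seedrc <- rnaRevComp(substr(neg$pirna_seq[i], 2, 7))
    expect_false(grepl(seedrc, neg$segment_seq[i], fixed = TRUE))
  }
  # every positive segment is 31 nt and centered on its planted site
  expect_true(all(nchar(positives(gt)$segment_seq) == 31))
  expect_identical(genPairDataset(w, n_pos = 50, n_neg = 50, seed = 3),
                   gt)
  expect_error(genPairDataset(w, n_pos = 10000, n_neg = 10, seed = 1),
               "planted sites")
})

test_that("worlds write standard files that read back", {
  w <- genWorld(small_world_spec())
  lib <- genChimeraLibrary(w)
  dir <- file.path(tempdir(), "synthworld")
  writeWorld(w, dir, lib)
  tx <- readTranscriptome(file.path(dir, "transcriptome.fasta"))
  expect_identical(unname(tx), unname(w$transcriptome))
  pir <- readPiRNAs(file.path(dir, "pirnas.fasta"))
  expect_identical(unname(pir), unname(w$pirnas))
  ch <- readChimeras(file.path(dir, "chimeras.tsv"))
  expect_identical(sum(ch$read_count), sum(lib$chimeras$read_count))
})
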