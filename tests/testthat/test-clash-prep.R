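test_that("read collapsing recovers multiplicities and drops ambiguous reads", {
  got <- collapseReads(c("AUG", "AUG", "GGC"))
  expect_identical(got$sequence, c("AUG", "GGC"))
  expect_identical(got$read_count, c(2L, 1L))
  # all-distinct input keeps one record each
  set.seed(8)
  seqs <- unique(replicate(20, rand_seq(15)))
  got <- collapseReads(seqs)
  expect_identical(nrow(got), length(seqs))
  expect_true(all(got$read_count == 1L))
  # N-containing reads are counted and removed
  expect_message(got <- collapseReads(c("AUG", "ANG", "AUG")), "1 reads dropped")
  expect_identical(attr(got, "n_dropped"), 1L)
  expect_identical(sum(got$read_count), 2L)
  expect_error(collapseReads(character()), "empty")
})

test_that("chimera splitting finds the unique piRNA and the longer flank", {
  set.seed(9)
  cat21 <- c(PA = rand_seq(21), PB = rand_seq(21))
  tail20 <- rand_seq(20)
  got <- splitChimera(paste0(cat21[["PA"]], tail20), cat21)
  expect_identical(got$status, "ok")
  expect_identical(got$pirna_id, "PA")
  expect_identical(got$remaining, tail20)
  # internal match: 5-nt head + piRNA + 16-nt tail -> the longer (3') flank
  head5 <- rand_seq(5); tail16 <- rand_seq(16)
  got <- splitChimera(paste0(head5, cat21[["PB"]], tail16), cat21)
  expect_identical(got$remaining, tail16)
  # equal flanks tie toward the 3' side
  t7 <- rand_seq(7); h7 <- rand_seq(7)
  got <- splitChimera(paste0(h7, cat21[["PA"]], t7), cat21)
  expect_identical(got$remaining, t7)
  expect_identical(splitChimera(rand_seq(40), cat21)$status, "no_match")
  expect_identical(splitChimera(paste0(cat21[["PA"]], cat21[["PB"]]), cat21)$status,
                   "ambiguous")
  expect_error(splitChimera("AUG", character()), "empty")
})

test_that("segment mapping recovers planted locations at the right tolerance", {
  set.seed(10)
  tx <- c(t1 = rand_seq(300), t2 = rand_seq(300))
  seg <- substr(tx[["t2"]], 101, 118)
  hits <- mapSegment(seg, tx, 0)
  expect_identical(hits$transcript_id, "t2")
  expect_identical(hits$start0, 100L)
  expect_identical(nrow(mapSegment(rand_seq(25), tx, 0)), 0L)
  segm <- seg
  substr(segm, 9, 9) <- setdiff(c("A", "U", "G", "C"), substr(segm, 9, 9))[1]
  expect_identical(nrow(mapSegment(segm, tx, 0)), 0L)
  expect_identical(mapSegment(segm, tx, 1)$start0, 100L)
  expect_error(mapSegment(seg, character()), "empty transcriptome")
})

test_that("target-site extraction centers the hit and rejects edge windows", {
  set.seed(12)
  tx <- rand_seq(100)
  # hit [40, 54): center floor((40 + 53)/2) = 46; window [31, 62) = 31 nt
  site <- siteFromAlignment(tx, 40L, 14L, 15L)
  expect_identical(site$status, "ok")
  expect_identical(site$center0, 46L)
  expect_identical(site$segment, substr(tx, 32, 62))
  expect_identical(nchar(site$segment), 31L)
  expect_identical(siteFromAlignment(tx, 0L, 14L, 15L)$status, "rejected")
  # degenerate l = 0: the single center base
  s0 <- siteFromAlignment(tx, 40L, 14L, 0L)
  expect_identical(s0$segment, substr(tx, 47, 47))
})

test_that("relaxing the rigorous thresholds can only grow the positive set", {
  fx <- hand_fixture()
  strict <- buildPositiveSet(fx$chimeras, fx$catalog, fx$transcriptome)
  relaxed <- buildPositiveSet(fx$chimeras, fx$catalog, fx$transcriptome,
                              prepConfig(min_read_count = 1, min_remaining = 7))
  k <- function(df) paste(df$pirna_id, df$segment_seq)
  expect_true(all(k(strict) %in% k(relaxed)))
  expect_gte(nrow(relaxed), nrow(strict))
  # empty input
  empty <- buildPositiveSet(fx$chimeras[0, ], fx$catalog, fx$transcriptome)
  expect_identical(nrow(empty), 0L)
  expect_error(prepConfig(min_read_count = -1), ">= 0")
})

test_that("loose-set membership follows the relaxed rules only", {
  fx <- hand_fixture()
  # a chimera with remaining length 7 and count 1 reaches the loose set but
  # never the positives
  r7 <- substr(rnaRevComp(fx$catalog[["P1"]]), 6, 12)
  extra <- rbind(fx$chimeras,
                 data.frame(sequence = paste0(fx$catalog[["P1"]], r7),
                            read_count = 1L))
  lbs <- buildLooseSet(extra, fx$catalog, fx$transcriptome)
  expect_true(any(lbs$pirna_id == "P1" & lbs$transcript_id == "TX1"))
  pos <- buildPositiveSet(extra, fx$catalog, fx$transcriptome)
  expect_false(any(pos$remaining_len == 7))
  # a remaining that only maps with 2 mismatches is excluded from the LBS
  seg <- substr(fx$transcriptome[["TX1"]], 10, 24)
  for (i in c(3, 9)) substr(seg, i, i) <-
      setdiff(c("A", "U", "G", "C"), substr(seg, i, i))[1]
  two_mm <- data.frame(sequence = paste0(fx$catalog[["P2"]], seg),
                       read_count = 5L)
  lbs2 <- buildLooseSet(two_mm, fx$catalog, fx$transcriptome)
  expect_identical(nrow(lbs2), 0L)
})

test_that("negative sampling honors the complement, the 2-mismatch guard and the seed", {
  set.seed(13)
  pir <- rand_seq(21)
  segpos <- rnaRevComp(paste0(rand_seq(5), pir, rand_seq(5)))  # 31 nt, pairs pir
  mutate_n <- function(s, n) {
    at <- sample(nchar(s), n)
    for (i in at) substr(s, i, i) <- setdiff(c("A", "U", "G", "C"),
                                             substr(s, i, i))[1]
    s
  }
  pos <- data.frame(pirna_id = "p1", pirna_seq = pir, transcript_id = "src",
                    center = 16L, segment_seq = segpos, label = "positive",
                    read_count = 10L, remaining_len = 20L, mismatches = 0L,
                    energy = -10, stringsAsFactors = FALSE)
  lbs <- data.frame(pirna_id = character(), transcript_id = character())
  # only available window is 2 substitutions from the positive -> unreachable
  tx2 <- c(near = mutate_n(segpos, 2))
  expect_error(sampleNegatives(pos, lbs, tx2, n_target = 1, seed = 1,
                               max_draw_factor = 30), "draw budget")
  # a 3-substitution window is accepted (energy still strongly negative)
  tx3 <- c(near = mutate_n(segpos, 3))
  neg <- sampleNegatives(pos, lbs, tx3, n_target = 1, seed = 1)
  expect_identical(neg$segment_seq, tx3[["near"]])
  expect_lt(neg$energy, 0)
  # transcripts excluded by the loose set never host a negative
  set.seed(14)
  tx <- c(allowed = rand_seq(200), excluded = rand_seq(200))
  lbs2 <- data.frame(pirna_id = "p1", transcript_id = "excluded")
  negs <- sampleNegatives(pos, lbs2, tx, n_target = 10, seed = 2)
  expect_true(all(negs$transcript_id == "allowed"))
  # determinism
  expect_identical(sampleNegatives(pos, lbs2, tx, n_target = 10, seed = 2),
                   negs)
})

test_that("independent-set assembly excludes wild-type pairs and reports conflicts", {
  mkgt <- function(pos, neg) new("GroundTruth", positives = pos, negatives = neg,
                                 looseSet = data.frame(pirna_id = character(),
                                                       transcript_id = character()),
                                 attrition = list())
  set.seed(15)
  row <- function(id, seg) data.frame(
    pirna_id = id, pirna_seq = rand_seq(21), transcript_id = "t", center = 16L,
    segment_seq = seg, label = "positive", read_count = 8L, remaining_len = 15L,
    mismatches = 0L, energy = -5, stringsAsFactors = FALSE)
  segs <- replicate(12, rand_seq(31))
  ind_pos <- do.call(rbind, lapply(1:8, function(i) row(paste0("p", i), segs[i])))
  ind_neg <- do.call(rbind, lapply(1:8, function(i) {
    r <- row(paste0("q", i), segs[4 + i]); r$label <- "negative"; r
  }))
  wt_pos <- do.call(rbind, lapply(1:2, function(i) row(paste0("p", i), segs[i])))
  wt_neg <- ind_neg[7:8, ]
  # disjoint case: requested sizes come back, none from the wild type
  got <- assembleIndependentSet(mkgt(ind_pos, ind_neg), mkgt(wt_pos, wt_neg[0, ]),
                                n_pos = 5, n_neg = 5, seed = 1)
  expect_identical(nrow(positives(got)), 5L)
  expect_false(any(positives(got)$pirna_id %in% c("p1", "p2")))
  # exhausted pool
  expect_error(assembleIndependentSet(mkgt(ind_pos[1:2, ], ind_neg),
                                      mkgt(ind_pos[1:2, ], wt_neg[0, ]),
                                      n_pos = 1, n_neg = 1),
               "independent positives")
  # planted conflict between independent positives and wild-type negatives
  conflict_neg <- ind_pos[5, ]; conflict_neg$label <- "negative"
  expect_warning(assembleIndependentSet(mkgt(ind_pos, ind_neg),
                                        mkgt(wt_pos, conflict_neg),
                                        n_pos = 4, n_neg = 4, seed = 1),
                 "wild-type negative")
})

test_that("positives and negatives never share a (piRNA, segment) key", {
  fx <- hand_fixture()
  gt <- buildGroundTruth(fx$chimeras, fx$catalog, fx$transcriptome, seed = 4)
  expect_s4_class(gt, "GroundTruth")   # validity enforces disjointness
  expect_identical(nrow(negatives(gt)), nrow(positives(gt)))
  kp <- paste(positives(gt)$pirna_id, positives(gt)$segment_seq)
  kn <- paste(negatives(gt)$pirna_id, negatives(gt)$segment_seq)
  expect_length(intersect(kp, kn), 0)
})
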