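test_that("one-hot encoding follows the (A, U, G, C) channel order and round-trips", {
  expect_identical(oneHotEncode("A"), matrix(c(1L, 0L, 0L, 0L), 1,
                                             dimnames = list(NULL, c("A", "U", "G", "C"))))
  m <- oneHotEncode("UGC")
  expect_identical(unname(m), rbind(c(0L, 1L, 0L, 0L), c(0L, 0L, 1L, 0L),
                                    c(0L, 0L, 0L, 1L)))
  # the published synthetic piRNA: 21 x 4 with column sums (A=4, U=10, G=5, C=2)
  syn <- oneHotEncode("UGUUUCAUAUGAUCUGGGUAU")
  expect_identical(dim(syn), c(21L, 4L))
  expect_identical(colSums(syn), c(A = 4, U = 10, G = 5, C = 2))
  expect_true(all(rowSums(syn) == 1))
  set.seed(1)
  for (i in 1:20) {
    s <- rand_seq(sample(5:40, 1))
    expect_identical(oneHotDecode(oneHotEncode(s)), s)
  }
  expect_error(oneHotEncode("AUNGC"), "position 3")
})

test_that("canonicalization maps T to U and rejects ambiguity", {
  expect_identical(rnaCanonicalize("acgt"), "ACGU")
  expect_error(rnaCanonicalize("ACGN"), "invalid base")
  expect_message(rnaCanonicalize("ACGT", notify = TRUE), "T mapped to U")
})

test_that("reverse complement is the base-swapped reversal and an involution", {
  expect_identical(rnaRevComp("AUGC"), "GCAU")
  expect_identical(rnaRevComp("AAAA"), "UUUU")
  # agrees with Biostrings on random sequences
  set.seed(2)
  for (i in 1:10) {
    s <- rand_seq(30)
    expect_identical(rnaRevComp(rnaRevComp(s)), s)
    expect_identical(rnaRevComp(s),
                     as.character(Biostrings::reverseComplement(Biostrings::RNAString(s))))
  }
})

test_that("mismatch counting is exact and matches the uniform expectation", {
  expect_identical(mismatchCount("AUGC", "AUGC"), 0L)
  expect_identical(mismatchCount("AUGC", "AUGG"), 1L)
  expect_error(mismatchCount("AUG", "AUGC"), "length")
  set.seed(3)
  mm <- replicate(3000, mismatchCount(rand_seq(31), rand_seq(31)))
  expect_lt(abs(mean(mm) - 31 * 3 / 4), 0.15)
})

test_that("mismatch scan reports all offsets and agrees with the exhaustive oracle", {
  expect_identical(scanWithMismatches("AUG", "AAUGG", 0),
                   data.frame(start0 = 1L, mismatches = 0L))
  expect_identical(scanWithMismatches("AAA", "AAAA", 0),
                   data.frame(start0 = 0L:1L, mismatches = c(0L, 0L)))
  # planted hit with one substitution
  set.seed(4)
  subj <- rand_seq(500)
  q <- substr(subj, 58, 71)
  substr(q, 5, 5) <- setdiff(c("A", "U", "G", "C"), substr(q, 5, 5))[1]
  hits1 <- scanWithMismatches(q, subj, 1)
  expect_true(any(hits1$start0 == 57 & hits1$mismatches == 1))
  # oracle agreement over 200 random pairs
  for (i in 1:200) {
    lq <- sample(3:8, 1)
    query <- rand_seq(lq); subject <- rand_seq(sample(lq:40, 1))
    mm <- sample(0:2, 1)
    got <- scanWithMismatches(query, subject, mm)
    want <- oracle_scan(query, subject, mm)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_identical(got$start0, as.integer(want[, 1]))
      expect_identical(got$mismatches, as.integer(want[, 2]))
    }
  }
  expect_error(scanWithMismatches("", "AAA"), "empty")
})

test_that("duplex energy signs: complements pair, identities do not, GC beats AU", {
  expect_lt(duplexEnergy("AAAAA", "UUUUU"), 0)
  expect_gte(duplexEnergy("AAAAA", "AAAAA"), 0)
  expect_lt(duplexEnergy("GGGG", "CCCC"), duplexEnergy("AAAA", "UUUU"))
  # deterministic for fixed inputs
  set.seed(6)
  p <- rand_seq(21); s <- rand_seq(31)
  expect_identical(duplexEnergy(p, s), duplexEnergy(p, s))
  # GU wobble scores between a full pair and a mismatch
  expect_identical(duplexEnergy("G", "U"), -1)   # G:U wobble
  expect_identical(duplexEnergy("U", "G"), -1)
  expect_identical(duplexEnergy("A", "C"), 0.5)  # plain mismatch
})

test_that("requesting an unavailable external energy engine errors loudly", {
  withr::local_envvar(PATH = tempdir())
  expect_error(duplexEnergy("AAAA", "UUUU", engine = "rnaup"), "RNAup")
  expect_error(duplexEnergy("AAAA", "UUUU", engine = "vienna"), "arg")
})
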