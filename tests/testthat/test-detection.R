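seg_sodium <- function() split_into_segments(sodium_annotation())[[1]]

test_that("the token-by-chunk matrix partitions tokens into chunks", {
  cm <- build_chunk_matrix(seg_sodium())
  expect_identical(dim(cm$matrix), c(19L, 13L))
  expect_true(all(rowSums(cm$matrix) == 1L))
  j <- which(cm$chunks$text == "sodium intake")
  expect_identical(unname(cm$matrix["intake", j]), 1L)

  one <- new_annotated_sentence("Eat", "VB", "B-VP")
  expect_identical(build_chunk_matrix(one)$matrix,
                   matrix(1L, 1, 1, dimnames = list("Eat", "Eat")))
})

test_that("chunk matrix agrees with an independent span scanner on random tags", {
  set.seed(7)
  for (rep in 1:30) {
    ann <- random_segment(sample(3:15, 1))
    got <- build_chunk_matrix(ann)$matrix
    want <- oracle_chunk_matrix(ann$chunk)
    expect_identical(unname(got), want)
  }
})

test_that("dictionary matrix reproduces the reference per-token hits", {
  gz <- default_gazetteers()
  dm <- build_dictionary_matrix(seg_sodium(), gz)
  expect_identical(dim(dm), c(19L, 3L))
  expect_identical(sum(dm), 2L)
  expect_identical(unname(dm["sodium", "Nutrient"]), 1L)
  expect_identical(unname(dm["mg", "QuantityUnit"]), 1L)

  # fiber sentence, first segment: fiber is the nutrient, both g tokens units
  seg1 <- split_into_segments(fiber_annotation())[[1]]
  dm1 <- build_dictionary_matrix(seg1, gz)
  expect_identical(unname(dm1["fiber", "Nutrient"]), 1L)
  expect_identical(sum(dm1[seg1$token == "g", "QuantityUnit"]), 2L)

  expect_true(all(build_dictionary_matrix(seg_sodium(), list()) == 0L) ||
                ncol(build_dictionary_matrix(seg_sodium(), list())) == 0)
})

test_that("the entity matrix is the chunk-by-dictionary product", {
  gz <- default_gazetteers()
  cm <- build_chunk_matrix(seg_sodium())
  dm <- build_dictionary_matrix(seg_sodium(), gz)
  ents <- build_entity_matrix(cm, dm)
  # reference matrix: 13 chunks x 3 entities, nonzero rows "sodium intake"
  # (Nutrient) and "300 mg" (Quantity/Unit)
  expect_identical(dim(ents), c(13L, 3L))
  expect_identical(unname(ents["sodium intake", "Nutrient"]), 1L)
  expect_identical(unname(ents["300 mg", "QuantityUnit"]), 1L)
  expect_identical(sum(ents), 2L)
  expect_identical(attr(ents, "resolved")[rownames(ents) == "sodium intake"],
                   "Nutrient")

  expect_error(build_entity_matrix(cm$matrix[1:5, ], dm), "mismatch")
})

test_that("matrix product equals the brute-force triple loop", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    m <- sample(2:6, 1)
    k <- 3
    A <- matrix(0L, n, m)
    for (i in seq_len(n)) A[i, sample(m, 1)] <- 1L
    B <- matrix(rbinom(n * k, 1, 0.3), n, k)
    colnames(B) <- ENTITY_TYPES
    got <- build_entity_matrix(A, B)
    want <- matrix(0L, m, k)
    for (j in seq_len(m)) for (l in seq_len(k)) for (i in seq_len(n)) {
      want[j, l] <- want[j, l] + A[i, j] * B[i, l]
    }
    expect_identical(matrix(as.integer(got), m, k), want)
  }
})

test_that("merge guard matches its conjunction form and the reference cases", {
  # Nutrient on the left, Quantity/Unit on the right: forbidden
  expect_false(merge_guard(c(0, 1, 0), c(0, 0, 1)))
  # all labels zero: allowed
  expect_true(merge_guard(c(0, 0, 0), c(0, 0, 0)))
  # Quantity/Unit left, nothing right: allowed (the "300 mg per day" merge)
  expect_true(merge_guard(c(0, 0, 1), c(0, 0, 0)))
  expect_error(merge_guard(c(0, 1), c(0, 1, 0)), "equal length")

  for (k in 2:4) {
    combos <- as.matrix(expand.grid(rep(list(0:1), k)))
    for (i in seq_len(nrow(combos))) {
      for (j in seq_len(nrow(combos))) {
        a <- combos[i, ]; b <- combos[j, ]
        expect_identical(merge_guard(a, b), oracle_merge_guard(a, b))
        expect_identical(merge_guard(a, b), merge_guard(b, a)) # symmetry
      }
    }
  }
  expect_identical(variations_without_repetition(3, 2), 6L)
  expect_identical(variations_without_repetition(4, 2), 12L)
})

test_that("first post-hoc chunking merges guarded (NP, PP, NP) trigrams", {
  gz <- default_gazetteers()
  seg <- seg_sodium()
  cm <- build_chunk_matrix(seg)
  dm <- build_dictionary_matrix(seg, gz)
  ch1 <- posthoc_chunking_1(cm$chunks, dm, seg)
  expect_identical(attr(ch1, "n_candidates"), 3L)
  expect_identical(ch1$text,
                   c("People of any age", "who", "are", "African Americans",
                     "should further reduce", "sodium intake", "to",
                     "300 mg per day", "."))
  expect_identical(ch1$phrase_type[1], "NP")
  # unchanged when no qualifying trigram exists
  flat <- new_annotated_sentence(c("Eat", "fiber"), c("VB", "NN"),
                                 c("B-VP", "B-NP"))
  fcm <- build_chunk_matrix(flat)
  fdm <- build_dictionary_matrix(flat, gz)
  expect_identical(posthoc_chunking_1(fcm$chunks, fdm, flat)$text,
                   fcm$chunks$text)
})

test_that("first post-hoc chunking chains through merged chunks", {
  gz <- default_gazetteers()
  seg1 <- split_into_segments(fiber_annotation())[[1]]
  cm <- build_chunk_matrix(seg1)
  dm <- build_dictionary_matrix(seg1, gz)
  ch1 <- posthoc_chunking_1(cm$chunks, dm, seg1)
  expect_true("The recommended intake for total fiber for adults" %in% ch1$text)
  expect_true("38 g for men" %in% ch1$text)
  expect_true("25 g for women" %in% ch1$text)
})

test_that("second post-hoc chunking needs a wh-pronoun in the first noun chunk", {
  gz <- default_gazetteers()
  seg <- seg_sodium()
  cm <- build_chunk_matrix(seg)
  dm <- build_dictionary_matrix(seg, gz)
  ch1 <- posthoc_chunking_1(cm$chunks, dm, seg)
  ch2 <- posthoc_chunking_2(ch1, seg)
  expect_identical(attr(ch2, "n_candidates"), 2L)
  expect_identical(ch2$text,
                   c("People of any age", "who are African Americans",
                     "should further reduce", "sodium intake", "to",
                     "300 mg per day", "."))
  # a plain-noun first chunk does not merge
  plain <- new_annotated_sentence(
    c("Adults", "are", "people"), c("NNS", "VBP", "NNS"),
    c("B-NP", "B-VP", "B-NP"))
  pc <- build_chunk_matrix(plain)$chunks
  expect_identical(posthoc_chunking_2(pc, plain)$text, pc$text)
  # empty chunk list passes through
  empty <- pc[0, ]
  expect_identical(nrow(posthoc_chunking_2(empty, plain)), 0L)
})

test_that("third post-hoc chunking merges compatible (NP, NP) bigrams only", {
  gz <- default_gazetteers()
  # Nutrient NP followed by an unlabeled NP: merged
  a <- new_annotated_sentence(c("sodium", "levels"), c("NN", "NNS"),
                              c("B-NP", "B-NP"))
  adm <- build_dictionary_matrix(a, gz)
  merged <- posthoc_chunking_3(build_chunk_matrix(a)$chunks, adm, a)
  expect_identical(merged$text, "sodium levels")
  # Food NP followed by Quantity/Unit NP: untouched
  b <- new_annotated_sentence(c("milk", "mg"), c("NN", "NN"),
                              c("B-NP", "B-NP"))
  bdm <- build_dictionary_matrix(b, gz)
  expect_identical(posthoc_chunking_3(build_chunk_matrix(b)$chunks, bdm, b)$text,
                   c("milk", "mg"))
  # neither labeled: untouched
  c_ <- new_annotated_sentence(c("people", "yesterday"), c("NNS", "NN"),
                               c("B-NP", "B-NP"))
  cdm <- build_dictionary_matrix(c_, gz)
  expect_identical(posthoc_chunking_3(build_chunk_matrix(c_)$chunks, cdm, c_)$text,
                   c("people", "yesterday"))
  # the sodium sentence is unchanged by the third chunking
  seg <- seg_sodium()
  dm <- build_dictionary_matrix(seg, gz)
  ch2 <- posthoc_chunking_2(posthoc_chunking_1(build_chunk_matrix(seg)$chunks,
                                               dm, seg), seg)
  expect_identical(posthoc_chunking_3(ch2, dm, seg)$text, ch2$text)
})

test_that("recalculated entity matrix keeps phrase chunks only", {
  gz <- default_gazetteers()
  det <- detect_mentions(seg_sodium(), gz)
  ents <- det$recalc$entity
  expect_identical(dim(ents), c(6L, 3L))
  expect_identical(rownames(ents),
                   c("People of any age", "who are African Americans",
                     "should further reduce", "sodium intake", "to",
                     "300 mg per day"))
  expect_identical(unname(ents["sodium intake", "Nutrient"]), 1L)
  expect_identical(unname(ents["300 mg per day", "QuantityUnit"]), 1L)
  expect_identical(sum(ents), 2L)

  # with no merges, the recalculated matrix equals the initial one minus O rows
  flat <- new_annotated_sentence(c("Eat", "fiber", "."), c("VB", "NN", "."),
                                 c("B-VP", "B-NP", "O"))
  d2 <- detect_mentions(flat, gz)
  keep <- d2$initial$chunks$phrase_type != "O"
  bare <- function(m) matrix(as.integer(m), nrow(m), ncol(m))
  expect_identical(bare(d2$recalc$entity),
                   bare(unclass(d2$initial$entity)[keep, , drop = FALSE]))
})

test_that("post-hoc chunkings conserve tokens and never grow the chunk count", {
  gz <- default_gazetteers()
  set.seed(19)
  for (rep in 1:40) {
    seg <- random_segment(sample(6:18, 1))
    cm <- build_chunk_matrix(seg)
    dm <- build_dictionary_matrix(seg, gz)
    ch1 <- posthoc_chunking_1(cm$chunks, dm, seg)
    ch2 <- posthoc_chunking_2(ch1, seg)
    ch3 <- posthoc_chunking_3(ch2, dm, seg)
    covered <- function(ch) sort(unlist(mapply(seq, ch$start, ch$end,
                                               SIMPLIFY = FALSE)))
    expect_identical(covered(ch3), seq_len(nrow(seg)))
    expect_lte(nrow(ch1), nrow(cm$chunks))
    expect_lte(nrow(ch2), nrow(ch1))
    expect_lte(nrow(ch3), nrow(ch2))
  }
})

test_that("a merge never fuses mentions of two different entity types", {
  gz <- default_gazetteers()
  set.seed(23)
  for (rep in 1:40) {
    seg <- random_segment(sample(6:18, 1))
    cm <- build_chunk_matrix(seg)
    dm <- build_dictionary_matrix(seg, gz)
    pre <- cm$chunks
    ch1 <- posthoc_chunking_1(pre, dm, seg)
    # every original (NP, PP, NP) trigram whose outer labels differ must
    # survive unmerged: its outer chunks stay in different final chunks
    for (i in seq_len(max(0, nrow(pre) - 2))) {
      if (!identical(pre$phrase_type[i:(i + 2)], c("NP", "PP", "NP"))) next
      la <- resolved_label(pre$start[i], pre$end[i], dm)
      lb <- resolved_label(pre$start[i + 2], pre$end[i + 2], dm)
      if (is.na(la) || is.na(lb) || la == lb) next
      host_a <- which(ch1$start <= pre$start[i] & ch1$end >= pre$end[i])
      host_b <- which(ch1$start <= pre$start[i + 2] & ch1$end >= pre$end[i + 2])
      expect_false(identical(host_a, host_b))
    }
  }
})
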