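test_that("the default similarity model matches the six-group definition", {
  m <- default_similarity_model()
  expect_length(m$groups, 6)
  expect_equal(sort(unlist(m$groups, use.names = FALSE)),
               sort(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                            c("A", "C", "G", "M", "P"))))
  expect_true(are_similar(m, "F", "Y")) # aromatic
  expect_true(are_similar(m, "W", "F"))
  expect_true(are_similar(m, "D", "D")) # identical counts as similar
  expect_false(are_similar(m, "A", "C")) # ungrouped
  expect_false(are_similar(m, "X", "X")) # ambiguity carries no evidence
  expect_false(are_similar(m, "-", "-"))
  expect_false(are_similar(m, "D", "K"))
})

test_that("similarity models validate disjointness and membership", {
  expect_error(similarity_model(list(c("F", "Y"), c("Y", "W"))),
               "disjoint")
  expect_error(similarity_model(list(c("F"))), "at least 2")
  expect_error(similarity_model(list(c("F", "X"))), "standard residues")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: strong-groups", "groups:",
               "  a: [F, Y, W]", "  b: ILV"), f)
  m <- read_similarity_model(f)
  expect_equal(m$name, "strong-groups")
  expect_true(are_similar(m, "I", "L"))
  expect_false(are_similar(m, "D", "E")) # not in this model
})

test_that("count_pair classifies hand-enumerated columns correctly", {
  m <- default_similarity_model()
  c1 <- count_pair(aligned_pair("a", "b", "FYW", "YFW"), m)
  expect_equal(c1$n_identical, 1) # W-W
  expect_equal(c1$n_similar, 3)   # F~Y, Y~F, W=W

  c2 <- count_pair(aligned_pair("a", "b", "ACDE", "ACDE"), m)
  expect_equal(c2$n_identical, 4)
  expect_equal(c2$n_similar, 4)

  c3 <- count_pair(aligned_pair("a", "b", "KR-D", "RKHE"), m)
  expect_equal(c3$n_identical, 0)
  expect_equal(c3$n_similar, 3)   # K~R, R~K, D~E; gap column skipped
  expect_equal(c3$n_columns, 4)
  expect_equal(c3$len1, 3)
  expect_equal(c3$len2, 4)

  # ambiguity codes: never identical/similar, but count in length
  c4 <- count_pair(aligned_pair("a", "b", "XX", "XC"), m)
  expect_equal(c4$n_identical, 0)
  expect_equal(c4$n_similar, 0)
  expect_equal(c4$len1, 2)
})

test_that("gap-in-both columns are removed at pair construction", {
  p <- aligned_pair("a", "b", "AC--D", "AC-ED")
  expect_equal(nchar(p$row1), 4)
  expect_equal(p$row1, "AC-D")
  expect_error(aligned_pair("a", "b", "ACD", "ACDE"), "differ in length")
  expect_error(aligned_pair("a", "b", "--", "--"), "no non-empty columns")
})

test_that("score_pair honours every denominator convention", {
  p <- aligned_pair("a", "b", "FYW", "YFW")
  sc <- score_pair(p)
  expect_equal(sc$I, 1 / 3)
  expect_equal(sc$S, 1)
  expect_equal(sc$arisc, 2 / 3)

  # 4 identical columns, len 4 vs 5
  q <- aligned_pair("a", "b", "ACDE-", "ACDEF")
  expect_equal(score_pair(q, denominator = "shortest")$I, 1)
  expect_equal(score_pair(q, denominator = "longest")$I, 0.8)
  expect_equal(score_pair(q, denominator = "mean")$I, 4 / 4.5)
  expect_equal(score_pair(q, denominator = "alignment")$I, 0.8)

  ident <- aligned_pair("a", "b", "ACDEFGHIKL", "ACDEFGHIKL")
  sci <- score_pair(ident)
  expect_equal(sci$I, 1)
  expect_equal(sci$S, 1)
  expect_equal(sci$category, "high")
})

test_that("single-column edits move the counters by exactly one class", {
  m <- default_similarity_model()
  base <- "FIKDSNFIKD" # all grouped residues
  partner <- "FIKDSNFIKD"
  b0 <- count_pair(aligned_pair("a", "b", base, partner), m)
  expect_equal(b0$n_identical, 10)
  # same-group substitution at one identical column
  within <- sub("^F", "Y", partner)
  b1 <- count_pair(aligned_pair("a", "b", base, within), m)
  expect_equal(b1$n_identical, b0$n_identical - 1)
  expect_equal(b1$n_similar, b0$n_similar)
  # out-of-group substitution at the same column
  out <- sub("^F", "A", partner)
  b2 <- count_pair(aligned_pair("a", "b", base, out), m)
  expect_equal(b2$n_identical, b0$n_identical - 1)
  expect_equal(b2$n_similar, b0$n_similar - 1)
})

test_that("global aligner is exact on small cases and symmetric", {
  a <- seq_record("a", "ACD")
  p <- align_pair_global(a, seq_record("b", "ACD"))
  expect_equal(p$row1, "ACD")
  expect_equal(p$row2, "ACD")
  expect_equal(p$provenance, "pairwise-aligned")

  q <- align_pair_global(seq_record("x", "MKV"), seq_record("y", "MV"))
  expect_equal(q$row1, "MKV")
  expect_equal(q$row2, "M-V") # single gap opposite the insertion

  # scoring is symmetric under argument swap
  r1 <- score_pair(align_pair_global(seq_record("x", "MKVFYWDE"),
                                     seq_record("y", "MVFYDE")))
  r2 <- score_pair(align_pair_global(seq_record("y", "MVFYDE"),
                                     seq_record("x", "MKVFYWDE")))
  expect_equal(r1$I, r2$I)
  expect_equal(r1$S, r2$S)

  # rare ambiguity letters pass through alignment unchanged
  u <- align_pair_global(seq_record("x", "ACDUE"), seq_record("y", "ACDE"))
  expect_true(grepl("U", u$row1))
})

test_that("extract_pair_from_msa drops gap-gap columns and checks ids", {
  aln <- msa_alignment(c("A", "B", "C"), c("AC-D", "AC-D", "ACED"))
  p <- extract_pair_from_msa(aln, "A", "B")
  expect_equal(p$row1, "ACD") # shared gap column dropped
  expect_equal(p$provenance, "msa-extracted")
  q <- extract_pair_from_msa(aln, "A", "C")
  expect_equal(q$row1, "AC-D") # not dropped: C has a residue there
  expect_error(extract_pair_from_msa(aln, "A", "missing"),
               "id not found.*'missing'")
})

test_that("random aligned pairs match the naive oracle and obey I <= S", {
  set.seed(401)
  m <- default_similarity_model()
  for (rep in 1:200) {
    rows <- random_aligned_rows()
    p <- aligned_pair("a", "b", rows$row1, rows$row2)
    got <- count_pair(p, m)
    want <- naive_pair_counts(p$row1, p$row2)
    expect_identical(got$n_identical, want$n_identical)
    expect_identical(got$n_similar, want$n_similar)
    expect_lte(got$n_identical, got$n_similar)
    expect_lte(got$n_similar, min(got$len1, got$len2))
    sc <- score_pair(p)
    expect_lte(sc$I, sc$S)
  }
})
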