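test_that("arisc_index is the participation-weighted identity/similarity mix", {
  expect_equal(arisc_index(0.65, 0.75), 0.70)
  expect_equal(arisc_index(0.41, 0.57), 0.49)
  expect_equal(arisc_index(1, 1), 1)
  expect_equal(arisc_index(0.3, 0.5, w = 0), 0.3)
  expect_equal(arisc_index(0.3, 0.5, w = 1), 0.5)
  # collapses to identity when nothing is similar-but-not-identical
  I <- seq(0, 1, by = 0.1)
  expect_equal(arisc_index(I, I), I)
  # monotone in both arguments
  expect_true(all(diff(arisc_index(seq(0, 0.5, 0.05), 0.6)) > 0))
  expect_true(all(diff(arisc_index(0.2, seq(0.2, 1, 0.05))) > 0))
  expect_error(arisc_index(0.5, 0.4), "cannot exceed")
  expect_error(arisc_index(-0.1, 0.4), "\\[0, 1\\]")
})

test_that("risk categories use closed lower bounds on the unrounded value", {
  expect_equal(categorize(c(0.75, 0.50, 0.25, 0.2499)),
               c("high", "medium-high", "medium-low", "low"))
  expect_equal(categorize(1), "high")
  expect_equal(categorize(0), "low")
  expect_equal(categorize(0.7468), "medium-high") # would round to 0.75
  expect_error(categorize(1.2), "\\[0, 1\\]")
})

test_that("family matrices are symmetric with unit diagonal", {
  fam <- generate_family(family_spec(n = 5, length = 150, seed = 21))
  mat <- build_family_matrix(fam, mode = "pairwise")
  expect_equal(mat$arisc, t(mat$arisc))
  expect_equal(mat$identity, t(mat$identity))
  expect_equal(unname(diag(mat$arisc)), rep(1, 5))
  expect_equal(unname(diag(mat$category)), rep("high", 5))
  expect_equal(nrow(mat$pairs), choose(5, 2))
  # category labels partition the pairs
  expect_equal(sum(table(factor(mat$pairs$category,
                                levels = c("high", "medium-high",
                                           "medium-low", "low")))),
               choose(5, 2))
})

test_that("matrix entries equal independent per-pair rescoring", {
  aln <- msa_alignment(
    c("s1", "s2", "s3"),
    c("FIKDSNFIKD", "YIKESNFIKD", "AAADSNFIKD")
  )
  mat <- build_family_matrix(aln, mode = "msa")
  for (i in 1:2) {
    for (j in (i + 1):3) {
      sc <- score_pair(extract_pair_from_msa(aln, aln$ids[i], aln$ids[j]))
      expect_equal(mat$identity[i, j], sc$I)
      expect_equal(mat$similarity[i, j], sc$S)
      expect_equal(mat$arisc[i, j], sc$arisc)
      expect_equal(mat$category[i, j], sc$category)
    }
  }
  expect_error(build_family_matrix(aln, mode = "pairwise"),
               "requires unaligned")
  expect_error(
    build_family_matrix(list(seq_record("only", "ACDE")), mode = "pairwise"),
    "at least 2")
})

test_that("two identical sequences score as a high-risk pair", {
  recs <- list(seq_record("a", "MKVFYWDEQQ"), seq_record("b", "MKVFYWDEQQ"))
  mat <- build_family_matrix(recs, mode = "pairwise")
  expect_equal(mat$arisc["a", "b"], 1)
  expect_equal(mat$category["a", "b"], "high")
})

test_that("family summaries aggregate off-diagonal pairs only", {
  fam <- generate_family(family_spec(n = 5, length = 200, seed = 33))
  mat <- build_family_matrix(fam, mode = "pairwise")
  s <- summarize_family(mat, "fixture")
  # brute force over the 10 unordered pairs from the stored matrices
  ut <- upper.tri(mat$arisc)
  expect_equal(s$mean_identity, mean(mat$identity[ut]), tolerance = 1e-12)
  expect_equal(s$mean_similarity, mean(mat$similarity[ut]), tolerance = 1e-12)
  expect_equal(s$mean_arisc, mean(mat$arisc[ut]), tolerance = 1e-12)
  expect_equal(s$min_arisc, min(mat$arisc[ut]))
  expect_equal(s$max_arisc, max(mat$arisc[ut]))
  expect_equal(s$n_pairs, 10)
  expect_lte(s$min_identity, s$mean_identity)
  expect_lte(s$mean_identity, s$max_identity)

  two <- fixture_pair_matrix(0.4, 0.6)
  s2 <- summarize_family(two, "pair")
  expect_equal(s2$mean_arisc, 0.5)
  expect_equal(s2$min_arisc, s2$max_arisc)
})

test_that("rank_families sorts by mean A-RISC with a name tie-break", {
  mk <- function(name, arisc) {
    s <- summarize_family(fixture_pair_matrix(0.4, 0.6), name)
    s$mean_arisc <- arisc
    s
  }
  ranked <- rank_families(list(mk("lipocalins", 0.26), mk("profilins", 0.80)))
  expect_equal(ranked$family, c("profilins", "lipocalins"))
  expect_equal(ranked$rank, 1:2)
  expect_equal(rank_families(list(mk("solo", 0.5)))$family, "solo")
  tied <- rank_families(list(mk("zeta", 0.5), mk("alpha", 0.5)))
  expect_equal(tied$family, c("alpha", "zeta"))
})
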