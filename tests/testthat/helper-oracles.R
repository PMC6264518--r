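# Independent oracles and small fixture builders.

# Naive column-by-column re-count, written independently of count_pair:
# group membership via substring search on hard-coded group strings.
naive_pair_counts <- function(row1, row2) {
  groups <- c("FYW", "ILV", "HKR", "DE", "ST", "NQ")
  standard <- "ACDEFGHIKLMNPQRSTVWY"
  a <- strsplit(row1, "")[[1]]
  b <- strsplit(row2, "")[[1]]
  n_id <- 0L
  n_sim <- 0L
  for (k in seq_along(a)) {
    x <- a[k]
    y <- b[k]
    if (x == "-" || y == "-") next
    x_std <- grepl(x, standard, fixed = TRUE)
    y_std <- grepl(y, standard, fixed = TRUE)
    if (x_std && y_std && x == y) {
      n_id <- n_id + 1L
      n_sim <- n_sim + 1L
    } else {
      for (g in groups) {
        if (grepl(x, g, fixed = TRUE) && grepl(y, g, fixed = TRUE)) {
          n_sim <- n_sim + 1L
          break
        }
      }
    }
  }
  list(n_identical = n_id, n_similar = n_sim,
       len1 = sum(a != "-"), len2 = sum(b != "-"))
}

# random gapped aligned pair; both rows keep at least one residue and at
# least one column is residue-residue
random_aligned_rows <- function(max_len = 50, gap_prob = 0.15,
                                ambig_prob = 0.05) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ambig <- c("X", "B", "Z", "J", "U", "O")
  repeat {
    len <- sample(2:max_len, 1)
    draw <- function() {
      vapply(seq_len(len), function(i) {
        u <- stats::runif(1)
        if (u < gap_prob) "-"
        else if (u < gap_prob + ambig_prob) sample(ambig, 1)
        else sample(alphabet, 1)
      }, character(1))
    }
    a <- draw()
    b <- draw()
    keep <- !(a == "-" & b == "-")
    a <- a[keep]
    b <- b[keep]
    if (length(a) > 0 && sum(a != "-") > 0 && sum(b != "-") > 0 &&
        any(a != "-" & b != "-")) {
      return(list(row1 = paste(a, collapse = ""),
                  row2 = paste(b, collapse = "")))
    }
  }
}

write_tmp_fasta <- function(lines, envir = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".fasta", .local_envir = envir)
  writeLines(lines, f)
  f
}

# score equal-length ungapped records through a gap-free alignment (the
# generator guarantees its targets only for gap-free scoring)
gapfree_matrix <- function(records, ...) {
  build_family_matrix(
    msa_alignment(vapply(records, `[[`, character(1), "id"),
                  vapply(records, `[[`, character(1), "seq")),
    mode = "msa", ...)
}

# two-sequence family matrix with a controlled (I, S) target, via the
# synthetic generator and a gap-free alignment
fixture_pair_matrix <- function(identity, similarity, length = 100,
                                seed = 11) {
  pr <- generate_pair(length, identity, similarity, seed = seed,
                      ids = c("seqA", "seqB"))
  aln <- msa_alignment(c("seqA", "seqB"), c(pr[[1]]$seq, pr[[2]]$seq))
  build_family_matrix(aln, mode = "msa")
}
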