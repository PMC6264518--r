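# Pairwise identity/similarity scoring under the similarity-group model.
#
# The unit of comparison is an aligned pair: two equal-length gapped rows
# with no gap-in-both column. Per column, identical standard residues
# count toward identity and similarity; different residues sharing a
# similarity group count toward similarity only; a gap opposite a residue
# counts toward neither. Ambiguity codes are never identical or similar
# but do contribute to ungapped sequence length, so they dilute scores —
# an unknown residue cannot support an epitope-level match claim.

#' Construct an aligned sequence pair
#'
#' Columns that are gaps in both rows are removed at construction.
#'
#' @param id1,id2 Identifiers.
#' @param row1,row2 Equal-length gapped strings (gap = "-" or ".").
#' @param provenance `"msa-extracted"` or `"pairwise-aligned"`.
#' @return An object of class `aligned_pair`.
#' @export
aligned_pair <- function(id1, id2, row1, row2,
                         provenance = c("msa-extracted",
                                        "pairwise-aligned")) {
  provenance <- match.arg(provenance)
  row1 <- toupper(gsub(".", "-", row1, fixed = TRUE))
  row2 <- toupper(gsub(".", "-", row2, fixed = TRUE))
  if (nchar(row1) != nchar(row2)) {
    stop("aligned rows differ in length (", nchar(row1), " vs ",
         nchar(row2), ")", call. = FALSE)
  }
  c1 <- strsplit(row1, "")[[1]]
  c2 <- strsplit(row2, "")[[1]]
  keep <- !(c1 == "-" & c2 == "-")
  c1 <- c1[keep]; c2 <- c2[keep]
  if (length(c1) < 1) {
    stop("aligned pair has no non-empty columns", call. = FALSE)
  }
  structure(
    list(id1 = id1, id2 = id2,
         row1 = paste(c1, collapse = ""),
         row2 = paste(c2, collapse = ""),
         provenance = provenance),
    class = "aligned_pair"
  )
}

#' Count identical and similar columns of an aligned pair
#'
#' "Similar" includes "identical": an identical column increments both
#' counters, a similar-but-not-identical column increments only
#' `n_similar`. Columns with a gap in either row count toward neither.
#' Identity requires both residues to be equal standard residues.
#'
#' @param pair An `aligned_pair`.
#' @param model A `similarity_model` (default [default_similarity_model()]).
#' @return A list of class `pair_counts` with `n_identical`, `n_similar`,
#'   `n_columns` (alignment length after gap-gap removal) and the ungapped
#'   lengths `len1`, `len2`.
#' @export
count_pair <- function(pair, model = default_similarity_model()) {
  stopifnot(inherits(pair, "aligned_pair"),
            inherits(model, "similarity_model"))
  c1 <- strsplit(pair$row1, "")[[1]]
  c2 <- strsplit(pair$row2, "")[[1]]
  gap <- c1 == "-" | c2 == "-"
  std1 <- c1 %in% AA_STANDARD
  std2 <- c2 %in% AA_STANDARD
  ident <- !gap & std1 & std2 & c1 == c2
  g1 <- unname(model$group_of[c1])
  g2 <- unname(model$group_of[c2])
  samegrp <- !gap & !is.na(g1) & !is.na(g2) & g1 == g2
  structure(
    list(n_identical = sum(ident),
         n_similar = sum(ident | samegrp),
         n_columns = length(c1),
         len1 = sum(c1 != "-"),
         len2 = sum(c2 != "-")),
    class = "pair_counts"
  )
}

#' Score an aligned pair: identity, similarity, A-RISC and risk category
#'
#' Identity I and similarity S are the identical / similar column counts
#' divided by the chosen denominator. The denominator convention defaults
#' to the shorter ungapped sequence length; the longest / mean /
#' alignment-length conventions are selectable because percent-identity
#' tools differ on this point.
#'
#' @param pair An `aligned_pair`.
#' @param model A `similarity_model`.
#' @param denominator One of `"shortest"`, `"longest"`, `"mean"`,
#'   `"alignment"`.
#' @param w Participation weight passed to [arisc_index()].
#' @return A list of class `homology_score` with `I`, `S`, `arisc`,
#'   `category`, `counts` and `denominator`.
#' @export
score_pair <- function(pair, model = default_similarity_model(),
                       denominator = c("shortest", "longest", "mean",
                                       "alignment"),
                       w = 0.5) {
  denominator <- match.arg(denominator)
  counts <- count_pair(pair, model)
  denom <- switch(denominator,
    shortest  = min(counts$len1, counts$len2),
    longest   = max(counts$len1, counts$len2),
    mean      = (counts$len1 + counts$len2) / 2,
    alignment = counts$n_columns
  )
  I <- counts$n_identical / denom
  S <- counts$n_similar / denom
  a <- arisc_index(I, S, w = w)
  structure(
    list(I = I, S = S, arisc = a, category = categorize(a),
         counts = counts, denominator = denominator, w = w),
    class = "homology_score"
  )
}

#' @export
print.homology_score <- function(x, ...) {
  cat(sprintf("identity %.1f%%  similarity %.1f%%  A-RISC %.2f (%s)\n",
              100 * x$I, 100 * x$S, x$arisc, x$category))
  invisible(x)
}

#' Default parameters for the internal global aligner
#'
#' BLOSUM62 with affine gaps (open 10, extend 0.5) — classic global
#' protein alignment defaults. Note that family analyses meant to mirror
#' an MSA-based workflow should score pairs extracted from the family
#' alignment instead; pairwise re-alignment of each pair is a different
#' procedure and can shift values for distant pairs.
#'
#' @param substitution_matrix Name of a matrix shipped with Biostrings.
#' @param gap_open,gap_extend Non-negative penalties,
#'   `gap_extend <= gap_open`.
#' @return A list of class `align_params`.
#' @export
align_params <- function(substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  stopifnot(gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

#' Globally align two sequences
#'
#' Needleman–Wunsch global alignment with affine gap penalties via
#' Biostrings. Deterministic: repeated calls return the same traceback.
#'
#' @param a,b `seq_record` objects.
#' @param params An `align_params`.
#' @return An `aligned_pair` with provenance `"pairwise-aligned"`.
#' @export
align_pair_global <- function(a, b, params = align_params()) {
  stopifnot(inherits(a, "seq_record"), inherits(b, "seq_record"))
  # substitution matrices cover the standard alphabet plus B, Z, X;
  # J/U/O are aligned as X and the original letters restored afterwards
  sub_unknown <- function(s) chartr("JUO", "XXX", s)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sub_unknown(a$seq)),
    Biostrings::AAString(sub_unknown(b$seq)),
    type = "global",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open,
    gapExtension = params$gap_extend
  )
  r1 <- as.character(Biostrings::alignedPattern(aln))
  r2 <- as.character(Biostrings::alignedSubject(aln))
  # restore original letters where X was substituted
  restore <- function(gapped, orig) {
    g <- strsplit(gapped, "")[[1]]
    g[g != "-"] <- strsplit(orig, "")[[1]]
    paste(g, collapse = "")
  }
  aligned_pair(a$id, b$id, restore(r1, a$seq), restore(r2, b$seq),
               provenance = "pairwise-aligned")
}

#' Extract one pair of rows from a multiple sequence alignment
#'
#' @param aln An `msa_alignment`.
#' @param id1,id2 Row identifiers; unknown ids are an error naming the id.
#' @return An `aligned_pair` (gap-in-both columns removed) with provenance
#'   `"msa-extracted"`.
#' @export
extract_pair_from_msa <- function(aln, id1, id2) {
  stopifnot(inherits(aln, "msa_alignment"))
  for (id in c(id1, id2)) {
    if (!(id %in% aln$ids)) {
      stop("id not found in alignment: '", id, "'", call. = FALSE)
    }
  }
  aligned_pair(id1, id2,
               aln$rows[match(id1, aln$ids)],
               aln$rows[match(id2, aln$ids)],
               provenance = "msa-extracted")
}
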