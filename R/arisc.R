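# The A-RISC index, risk categories, family matrices, summaries, ranking.
#
# A-RISC (Allergens' Relative Identity, Similarity and Cross-reactivity)
# condenses a pair's identity I and similarity S into one number,
#
#   A-RISC = I + w (S - I),   w = 0.5 by default,
#
# read as the fraction of residues potentially able to support binding of
# a cross-reactive antibody: identical residues always count, similar but
# not identical residues count with probability w. At the default w the
# index is simply (I + S) / 2.

ARISC_CATEGORIES <- c("high", "medium-high", "medium-low", "low")

#' The A-RISC index of a sequence pair
#'
#' @param I Identity fraction in \[0, 1\].
#' @param S Similarity fraction in \[0, 1\]; similarity includes identity,
#'   so `I > S` is a domain error.
#' @param w Participation weight in \[0, 1\]: the assumed probability that
#'   a similar-but-not-identical residue takes part in antibody binding.
#'   The default 0.5 is the convention used throughout; it is exposed
#'   because it is an explicit modelling assumption, not a fitted value.
#' @return `I + w * (S - I)`, a value in `[I, S]`. Vectorized over `I`
#'   and `S`.
#' @export
#' @examples
#' arisc_index(0.65, 0.75) # 0.70
#' arisc_index(0.41, 0.57) # 0.49
arisc_index <- function(I, S, w = 0.5) {
  stopifnot(length(w) == 1, w >= 0, w <= 1)
  if (any(I < 0 | S > 1 | is.na(I) | is.na(S))) {
    stop("I and S must lie in [0, 1]", call. = FALSE)
  }
  if (any(I > S + 1e-12)) {
    stop("identity cannot exceed similarity (similar includes identical)",
         call. = FALSE)
  }
  I + w * (S - I)
}

#' Cross-reactivity risk category of an A-RISC value
#'
#' Four tiers with closed lower bounds: high (A-RISC >= 0.75),
#' medium-high (0.75 > A-RISC >= 0.50), medium-low (0.50 > A-RISC >=
#' 0.25), low (A-RISC < 0.25). Categorization uses the unrounded value;
#' rounding for display happens afterwards, so e.g. 0.7468 is
#' medium-high even though it prints as 0.75.
#'
#' @param arisc Numeric vector of A-RISC values in \[0, 1\].
#' @return Character vector of category labels.
#' @export
#' @examples
#' categorize(c(0.75, 0.50, 0.25, 0.2499))
categorize <- function(arisc) {
  if (any(arisc < 0 | arisc > 1 | is.na(arisc))) {
    stop("A-RISC values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(arisc >= 0.75, "high",
  ifelse(arisc >= 0.50, "medium-high",
  ifelse(arisc >= 0.25, "medium-low", "low")))
}

#' Build the pairwise homology matrix of a protein family
#'
#' Scores every unordered pair of family members once and stores the
#' results in symmetric matrices. In `msa` mode pairs are extracted from
#' a family multiple sequence alignment (the workflow used for allergen
#' family analyses); in `pairwise` mode each pair is globally re-aligned
#' with the internal aligner.
#'
#' @param input An `msa_alignment` (mode `"msa"`) or a list of
#'   `seq_record` (mode `"pairwise"`).
#' @param mode `"msa"` or `"pairwise"`.
#' @param model A `similarity_model`.
#' @param denominator Denominator convention, see [score_pair()].
#' @param w Participation weight.
#' @param params `align_params` for pairwise mode.
#' @return An object of class `family_matrix`: sequence `ids` plus
#'   symmetric `identity`, `similarity`, `arisc` (numeric) and `category`
#'   (character) matrices, a long `pairs` data frame of per-pair scores,
#'   and the scoring configuration. Diagonal entries are the self-scores
#'   I = S = A-RISC = 1, category "high".
#' @export
build_family_matrix <- function(input, mode = c("msa", "pairwise"),
                                model = default_similarity_model(),
                                denominator = "shortest", w = 0.5,
                                params = align_params()) {
  mode <- match.arg(mode)
  if (mode == "msa") {
    if (!inherits(input, "msa_alignment")) {
      stop("mode 'msa' requires an msa_alignment input", call. = FALSE)
    }
    ids <- input$ids
  } else {
    if (inherits(input, "msa_alignment")) {
      stop("mode 'pairwise' requires unaligned seq_record input",
           call. = FALSE)
    }
    if (inherits(input, "seq_record")) input <- list(input)
    stopifnot(all(vapply(input, inherits, logical(1), "seq_record")))
    ids <- vapply(input, `[[`, character(1), "id")
    if (anyDuplicated(ids)) {
      stop("duplicate sequence ids in family input", call. = FALSE)
    }
  }
  n <- length(ids)
  if (n < 2) stop("a family needs at least 2 sequences", call. = FALSE)

  mk <- function(diag_val) {
    m <- matrix(diag_val, n, n, dimnames = list(ids, ids))
    m
  }
  Im <- mk(1); Sm <- mk(1); Am <- mk(1)
  Cm <- matrix("high", n, n, dimnames = list(ids, ids))
  pairs <- vector("list", n * (n - 1) / 2)
  k <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pair <- if (mode == "msa") {
        extract_pair_from_msa(input, ids[i], ids[j])
      } else {
        align_pair_global(input[[i]], input[[j]], params)
      }
      sc <- score_pair(pair, model, denominator = denominator, w = w)
      Im[i, j] <- Im[j, i] <- sc$I
      Sm[i, j] <- Sm[j, i] <- sc$S
      Am[i, j] <- Am[j, i] <- sc$arisc
      Cm[i, j] <- Cm[j, i] <- sc$category
      k <- k + 1
      pairs[[k]] <- data.frame(
        id1 = ids[i], id2 = ids[j],
        identity = sc$I, similarity = sc$S, arisc = sc$arisc,
        category = sc$category,
        n_identical = sc$counts$n_identical,
        n_similar = sc$counts$n_similar,
        n_columns = sc$counts$n_columns,
        len1 = sc$counts$len1, len2 = sc$counts$len2,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(ids = ids, identity = Im, similarity = Sm, arisc = Am,
         category = Cm, pairs = do.call(rbind, pairs), mode = mode,
         model = model$name, denominator = denominator, w = w),
    class = "family_matrix"
  )
}

#' @export
print.family_matrix <- function(x, ...) {
  cat("Family matrix: ", length(x$ids), " sequences, ",
      nrow(x$pairs), " pairs (mode ", x$mode, ", denominator ",
      x$denominator, ")\n", sep = "")
  cat("  mean A-RISC ", sprintf("%.2f", mean(x$pairs$arisc)), "\n", sep = "")
  invisible(x)
}

#' Summarise a family matrix
#'
#' Means and ranges of identity, similarity and A-RISC over the
#' n(n-1)/2 unordered off-diagonal pairs; self-comparisons are excluded
#' (including them would pull every mean toward 1).
#'
#' @param matrix A `family_matrix`.
#' @param family_name Label for the family.
#' @return A one-row data frame of class `family_summary` with columns
#'   `family`, `n`, `n_pairs`, and mean/min/max of the three quantities.
#' @export
summarize_family <- function(matrix, family_name = "family") {
  stopifnot(inherits(matrix, "family_matrix"))
  p <- matrix$pairs
  out <- data.frame(
    family = family_name,
    n = length(matrix$ids),
    n_pairs = nrow(p),
    mean_identity = mean(p$identity),
    min_identity = min(p$identity),
    max_identity = max(p$identity),
    mean_similarity = mean(p$similarity),
    min_similarity = min(p$similarity),
    max_similarity = max(p$similarity),
    mean_arisc = mean(p$arisc),
    min_arisc = min(p$arisc),
    max_arisc = max(p$arisc),
    stringsAsFactors = FALSE
  )
  class(out) <- c("family_summary", class(out))
  out
}

#' @export
print.family_summary <- function(x, ...) {
  with(x, cat(sprintf(
    paste0("%s: n=%d, identity %.0f%% (%.0f-%.0f%%), similarity %.0f%% ",
           "(%.0f-%.0f%%), mean A-RISC %.2f\n"),
    family, n, 100 * mean_identity, 100 * min_identity, 100 * max_identity,
    100 * mean_similarity, 100 * min_similarity, 100 * max_similarity,
    mean_arisc)))
  invisible(x)
}

#' Rank families by propensity for cross-reactivity
#'
#' Orders family summaries by descending mean A-RISC; ties break by
#' family name, ascending, so the ordering is deterministic.
#'
#' @param summaries A list of `family_summary` rows (or a data frame of
#'   stacked summaries).
#' @return A data frame of the summaries in rank order, with a `rank`
#'   column prepended.
#' @export
rank_families <- function(summaries) {
  if (is.data.frame(summaries)) {
    df <- summaries
  } else {
    stopifnot(length(summaries) >= 1)
    df <- do.call(rbind, summaries)
  }
  ord <- order(-df$mean_arisc, df$family)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Write a family summary as JSON
#'
#' @param summary A `family_summary` (or ranked summary data frame).
#' @param path Output path.
#' @param provenance Optional named list recorded under `"provenance"`.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, provenance = NULL) {
  payload <- list(summary = as.data.frame(summary))
  if (!is.null(provenance)) payload$provenance <- provenance
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
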