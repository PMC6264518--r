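# Synthetic homolog families with exactly controlled identity/similarity.
#
# A pair with targets (I, S) at length L is built by mutating a seed
# sequence at exactly round-half-up((S - I) * L) positions within their
# similarity group and exactly round-half-up((1 - S) * L) positions to a
# residue sharing no group. Scoring the gap-free pair with the shortest-
# sequence denominator then recovers the rounded targets exactly, which
# is what makes the generator usable as a test oracle. No indels, no
# substitution-rate model: this is position-class structure, not
# evolution.

round_half_up <- function(x) floor(x + 0.5)

# sample() expands a length-1 numeric x to 1:x; always index instead
sample_from <- function(x, n) x[sample.int(length(x), n)]

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# one mutated copy of seed_chars hitting the given substitution counts;
# assumes the RNG state is already seeded by the caller
mutate_sequence <- function(seed_chars, n_within, n_nonsim, model) {
  L <- length(seed_chars)
  grouped_pos <- which(!is.na(model$group_of[seed_chars]))
  if (length(grouped_pos) < n_within) {
    stop("seed sequence has too few grouped residues for the requested ",
         "similarity target", call. = FALSE)
  }
  pos_within <- sample_from(grouped_pos, n_within)
  pool <- setdiff(seq_len(L), pos_within)
  pos_nonsim <- sample_from(pool, n_nonsim)
  out <- seed_chars
  for (p in pos_within) {
    grp <- model$groups[[model$group_of[seed_chars[p]]]]
    out[p] <- sample_from(setdiff(grp, seed_chars[p]), 1)
  }
  for (p in pos_nonsim) {
    g <- model$group_of[seed_chars[p]]
    banned <- if (is.na(g)) seed_chars[p] else model$groups[[g]]
    out[p] <- sample_from(setdiff(AA_STANDARD, banned), 1)
  }
  out
}

# seed sequence with at least min_grouped grouped residues: draw
# uniformly, then top up by rewriting ungrouped positions with grouped
# residues if the draw fell short (large similar-not-identical targets
# can demand more grouped positions than a uniform draw ever yields)
draw_seed_sequence <- function(length, min_grouped, model) {
  chars <- sample(AA_STANDARD, length, replace = TRUE)
  grouped <- !is.na(model$group_of[chars])
  deficit <- min_grouped - sum(grouped)
  if (deficit > 0) {
    fix_at <- sample_from(which(!grouped), deficit)
    pool <- unlist(model$groups, use.names = FALSE)
    chars[fix_at] <- sample(pool, deficit, replace = TRUE)
  }
  chars
}

#' Generate a sequence pair with exact identity/similarity targets
#'
#' @param length Sequence length (>= 1); both sequences have this length
#'   and no gaps.
#' @param target_identity,target_similarity Fractions with
#'   `0 <= target_identity <= target_similarity <= 1`. The realized
#'   values are the targets rounded to multiples of 1/length
#'   (substitution counts are integers).
#' @param seed RNG seed; same seed, same pair.
#' @param model A `similarity_model`.
#' @param ids Identifiers for the two records.
#' @return A list of two `seq_record`s. Scoring their gap-free alignment
#'   with `denominator = "shortest"` under `model` returns exactly the
#'   rounded targets.
#' @export
generate_pair <- function(length, target_identity, target_similarity,
                          seed = 1L, model = default_similarity_model(),
                          ids = c("synth_seed", "synth_member")) {
  stopifnot(length >= 1)
  if (is.na(target_identity) || is.na(target_similarity) ||
      target_identity < 0 || target_similarity > 1 ||
      target_identity > target_similarity) {
    stop("targets must satisfy 0 <= identity <= similarity <= 1",
         call. = FALSE)
  }
  n_within <- round_half_up((target_similarity - target_identity) * length)
  n_nonsim <- round_half_up((1 - target_similarity) * length)
  if (n_within + n_nonsim > length) {
    # interaction of the two roundings can overshoot by one at tiny lengths
    n_nonsim <- length - n_within
  }
  with_seed(seed, {
    seed_chars <- draw_seed_sequence(length, n_within, model)
    out <- mutate_sequence(seed_chars, n_within, n_nonsim, model)
    list(seq_record(ids[1], paste(seed_chars, collapse = "")),
         seq_record(ids[2], paste(out, collapse = "")))
  })
}

#' Specification of a synthetic homolog family
#'
#' @param n Number of sequences (>= 2). The first sequence is the seed;
#'   members 2..n are mutated copies of it.
#' @param length Residues per sequence.
#' @param pair_targets Either `NULL` (member-vs-seed identities sampled
#'   uniformly in `identity_range`, similarity in
#'   `[identity, min(identity + similarity_margin, 1)]`) or a data frame
#'   with columns `identity` and `similarity`, one row per non-seed
#'   member.
#' @param identity_range,similarity_margin Sampling controls used when
#'   `pair_targets` is `NULL`.
#' @param seed RNG seed.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n = 5L, length = 200L, pair_targets = NULL,
                        identity_range = c(0.2, 0.9),
                        similarity_margin = 0.25, seed = 1L) {
  if (n < 2) stop("a family needs at least 2 sequences", call. = FALSE)
  if (!is.null(pair_targets)) {
    pt <- as.data.frame(pair_targets)
    if (nrow(pt) != n - 1) {
      stop("pair_targets needs one row per non-seed member (", n - 1,
           "), got ", nrow(pt), call. = FALSE)
    }
    bad <- pt$identity > pt$similarity | pt$identity < 0 |
      pt$similarity > 1
    if (any(bad)) {
      stop("infeasible pair_targets at row(s) ",
           paste(which(bad), collapse = ", "),
           ": need 0 <= identity <= similarity <= 1", call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), length = as.integer(length),
                 pair_targets = pair_targets,
                 identity_range = identity_range,
                 similarity_margin = similarity_margin,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Read a family spec from a YAML/JSON config file
#'
#' Keys mirror [family_spec()] arguments; `pair_targets` may be a list of
#' `{identity, similarity}` mappings.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return A `family_spec`.
#' @export
read_family_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path, handlers = yaml_keep_bool_strings)
  pt <- cfg$pair_targets
  if (!is.null(pt)) {
    pt <- do.call(rbind, lapply(pt, function(x)
      data.frame(identity = x$identity, similarity = x$similarity)))
  }
  family_spec(
    n = cfg$n %||% 5L,
    length = cfg$length %||% 200L,
    pair_targets = pt,
    identity_range = unlist(cfg$identity_range %||% c(0.2, 0.9)),
    similarity_margin = cfg$similarity_margin %||% 0.25,
    seed = cfg$seed %||% 1L
  )
}

#' Generate a synthetic homolog family
#'
#' Members 2..n are independent mutated copies of the seed sequence
#' (member 1), each hitting its member-vs-seed identity/similarity
#' target exactly after rounding. Member-vs-member values are emergent:
#' guaranteeing every pairwise target simultaneously would be
#' over-constrained.
#'
#' @param spec A `family_spec`.
#' @param model A `similarity_model`.
#' @param id_prefix Prefix for the generated identifiers.
#' @return A list of `seq_record`s; fully reproducible from `spec$seed`.
#'   The attribute `"targets"` carries the realized (rounded)
#'   member-vs-seed targets.
#' @export
generate_family <- function(spec = family_spec(),
                            model = default_similarity_model(),
                            id_prefix = "synth") {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    if (is.null(spec$pair_targets)) {
      I <- stats::runif(spec$n - 1, spec$identity_range[1],
                        spec$identity_range[2])
      S <- pmin(I + stats::runif(spec$n - 1, 0, spec$similarity_margin), 1)
      targets <- data.frame(identity = I, similarity = S)
    } else {
      targets <- as.data.frame(spec$pair_targets)
    }
    n_within <- round_half_up(
      (targets$similarity - targets$identity) * spec$length)
    n_nonsim <- round_half_up((1 - targets$similarity) * spec$length)
    over <- n_within + n_nonsim > spec$length
    n_nonsim[over] <- spec$length - n_within[over]
    seed_chars <- draw_seed_sequence(spec$length, max(n_within), model)
    records <- vector("list", spec$n)
    records[[1]] <- seq_record(paste0(id_prefix, "_1"),
                               paste(seed_chars, collapse = ""))
    for (m in seq_len(spec$n - 1)) {
      chars <- mutate_sequence(seed_chars, n_within[m], n_nonsim[m], model)
      records[[m + 1]] <- seq_record(paste0(id_prefix, "_", m + 1),
                                     paste(chars, collapse = ""))
    }
    realized <- data.frame(
      member = vapply(records[-1], `[[`, character(1), "id"),
      identity = (spec$length - n_within - n_nonsim) / spec$length,
      similarity = (spec$length - n_nonsim) / spec$length
    )
    attr(records, "targets") <- realized
    records
  })
}
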