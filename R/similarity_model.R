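# Amino-acid similarity-group model.
#
# Two residues are "similar" when they are identical standard residues or
# when they belong to the same physicochemical group. The default grouping
# follows the SIAS server convention; alternative groupings (e.g. the less
# conservative Clustal strong groups) can be loaded from a YAML file.

AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_AMBIGUITY <- c("X", "B", "Z", "J", "U", "O")
AA_ALLOWED <- c(AA_STANDARD, AA_AMBIGUITY)

#' Construct an amino-acid similarity model
#'
#' A similarity model is a set of disjoint residue groups; residues in the
#' same group count as "similar, but not identical" when they differ.
#' Residues outside every group (and the ambiguity codes) are only ever
#' similar to themselves — and ambiguity codes not even that, since an
#' unknown residue carries no evidence for an epitope-level match.
#'
#' @param groups List of character vectors, each a disjoint set of at least
#'   two standard one-letter residue codes.
#' @param name Label for the model.
#' @return An object of class `similarity_model`.
#' @export
similarity_model <- function(groups, name = "custom") {
  stopifnot(is.list(groups), length(groups) >= 1, is.character(name))
  groups <- lapply(groups, function(g) toupper(as.character(g)))
  for (g in groups) {
    if (length(g) < 2) {
      stop("every similarity group needs at least 2 members", call. = FALSE)
    }
    bad <- setdiff(g, AA_STANDARD)
    if (length(bad) > 0) {
      stop(
        "similarity groups may only contain the 20 standard residues; found: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  all_members <- unlist(groups)
  if (anyDuplicated(all_members)) {
    stop(
      "similarity groups must be pairwise disjoint; residue(s) repeated: ",
      paste(unique(all_members[duplicated(all_members)]), collapse = ", "),
      call. = FALSE
    )
  }
  # group id per residue, NA for ungrouped / ambiguity codes
  group_of <- rep(NA_integer_, length(AA_ALLOWED))
  names(group_of) <- AA_ALLOWED
  for (i in seq_along(groups)) group_of[groups[[i]]] <- i
  structure(
    list(groups = groups, name = name, group_of = group_of),
    class = "similarity_model"
  )
}

#' The default similarity-group model
#'
#' Six groups: aromatic (F, Y, W), aliphatic (I, L, V), positively charged
#' (H, K, R), negatively charged (D, E), small with a hydroxyl group (S, T)
#' and neutral polar (N, Q). The five remaining residues (A, C, G, M, P)
#' belong to no group, so for them only identity counts.
#'
#' @return A `similarity_model` with six groups covering 15 residues.
#' @export
#' @examples
#' m <- default_similarity_model()
#' are_similar(m, "F", "Y") # TRUE: both aromatic
#' are_similar(m, "A", "C") # FALSE: ungrouped
default_similarity_model <- function() {
  similarity_model(
    groups = list(
      aromatic  = c("F", "Y", "W"),
      aliphatic = c("I", "L", "V"),
      positive  = c("H", "K", "R"),
      negative  = c("D", "E"),
      hydroxyl  = c("S", "T"),
      polar     = c("N", "Q")
    ),
    name = "sias-default"
  )
}

#' Read a similarity model from a YAML file
#'
#' The file must have a `name` scalar and a `groups` mapping of group label
#' to a list (or string) of one-letter residue codes, e.g.
#' `groups: {aromatic: [F, Y, W], aliphatic: "ILV"}`.
#'
#' @param path Path to a YAML model file.
#' @return A `similarity_model`.
#' @export
read_similarity_model <- function(path) {
  if (!file.exists(path)) {
    stop("similarity model file not found: ", path, call. = FALSE)
  }
  spec <- yaml::read_yaml(path, handlers = yaml_keep_bool_strings)
  if (is.null(spec$groups)) {
    stop("model file has no 'groups' entry: ", path, call. = FALSE)
  }
  groups <- lapply(spec$groups, function(g) {
    g <- as.character(g)
    if (length(g) == 1 && nchar(g) > 1) g <- strsplit(g, "")[[1]]
    g
  })
  similarity_model(groups, name = spec$name %||% "file-model")
}

#' Are two residues similar under a model?
#'
#' TRUE iff the residues are equal standard residues, or differ but share a
#' similarity group. Gap characters and ambiguity codes (X, B, Z, J, U, O)
#' are never similar, not even to themselves. Total function: any other
#' character simply returns FALSE.
#'
#' @param model A `similarity_model`.
#' @param a,b Single characters.
#' @return Logical scalar.
#' @export
are_similar <- function(model, a, b) {
  stopifnot(inherits(model, "similarity_model"))
  a <- toupper(a); b <- toupper(b)
  if (a %in% AA_STANDARD && identical(a, b)) return(TRUE)
  ga <- model$group_of[a]; gb <- model$group_of[b]
  isTRUE(!is.na(ga) && !is.na(gb) && ga == gb)
}

#' @export
print.similarity_model <- function(x, ...) {
  cat("Similarity model '", x$name, "': ", length(x$groups), " groups\n",
      sep = "")
  labs <- names(x$groups)
  for (i in seq_along(x$groups)) {
    lab <- if (!is.null(labs) && nzchar(labs[i])) labs[i] else paste0("g", i)
    cat("  ", lab, ": {", paste(x$groups[[i]], collapse = ", "), "}\n",
        sep = "")
  }
  ungrouped <- setdiff(AA_STANDARD, unlist(x$groups))
  cat("  ungrouped: {", paste(ungrouped, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML 1.1 reads bare Y/N/F/n/... as booleans; residue letters and the
# field name "n" must stay literal
yaml_keep_bool_strings <- list(
  "bool#yes" = function(x) x,
  "bool#no" = function(x) x
)
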