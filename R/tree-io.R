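#' Read and validate a Newick tree
#'
#' Parses a Newick string or file into an [ape::phylo] object and enforces the
#' invariants the rest of the pipeline relies on: unique, non-empty leaf
#' labels; non-negative branch lengths; a single connected tree. Labels are
#' kept verbatim (no underscore/space translation, quotes preserved as read by
#' ape) so that leaf labels can be joined byte-exactly against screen-table
#' keys. Internal-node labels, when present, are treated as support strings
#' and carried along but never used in any computation.
#'
#' Branch lengths absent from the text default to 0 with a warning (patristic
#' distances are then lower bounds); negative branch lengths are a hard error
#' because patristic distances are undefined for them.
#'
#' @param text A Newick string (must end in `;`). Exactly one of `text`/`file`.
#' @param file Path to a Newick file.
#' @return A `phylo` object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:2):1,(C:3,D:1):2);")
#' tr$tip.label
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`", call. = FALSE)
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("tree file not found: ", file, call. = FALSE)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: unparseable tree text", call. = FALSE)
  validate_tree(tree)
}

# Cheap structural scan so malformed input is reported with a character
# offset instead of an opaque downstream failure.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unmatched ')' at character ", i, call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' (text ends at character ",
         length(chars), ")", call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop("Newick parse error: missing terminal ';' at character ",
         nchar(trimws(text)) + 1L, call. = FALSE)
  }
  invisible(text)
}

#' Validate tree invariants
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly modified only in that missing branch lengths
#'   are replaced by 0 (with a warning).
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object", call. = FALSE)
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("leaf labels must be non-empty", call. = FALSE)
  dup <- unique(labs[duplicated(labs)])
  if (length(dup) > 0L) {
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning(sum(is.na(tree$edge.length)),
            " missing branch length(s) set to 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length(s); patristic distances are undefined",
         call. = FALSE)
  }
  tree
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Patristic distance matrix
#'
#' Computes the symmetric leaf-by-leaf matrix of patristic distances (sum of
#' branch lengths on the unique path between two leaves, in expected
#' substitutions per site for an ML tree). The matrix drives clustering,
#' subsampling, representativeness checks and phenotype association; rooting
#' does not affect it.
#'
#' @param tree A `phylo` object (validated).
#' @return A dense numeric matrix with leaf labels as dimnames, zero diagonal.
#' @export
#' @examples
#' m <- patristic_matrix(read_newick("((A:1,B:2):1,(C:3,D:1):2);"))
#' m["A", "C"] # 7
patristic_matrix <- function(tree) {
  tree <- validate_tree(tree)
  if (ape::Ntip(tree) == 1L) {
    return(matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label)))
  }
  m <- ape::cophenetic.phylo(tree)
  # cophenetic.phylo returns tips in tip.label order already; enforce anyway
  m[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Patristic distances in long (tidy) form
#'
#' @param matrix A patristic matrix from [patristic_matrix()], or a tree.
#' @return A tibble with columns `leaf_a`, `leaf_b`, `distance`, one row per
#'   unordered leaf pair (`leaf_a` earlier in matrix order).
#' @export
patristic_tbl <- function(matrix) {
  m <- as_patristic(matrix)
  labs <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    leaf_a = labs[idx[, 1]],
    leaf_b = labs[idx[, 2]],
    distance = m[idx]
  )
}

# Accept either a phylo or an already computed matrix.
as_patristic <- function(x) {
  if (inherits(x, "phylo")) return(patristic_matrix(x))
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("patristic matrix must carry leaf labels as dimnames", call. = FALSE)
    }
    return(x)
  }
  stop("expected a phylo object or a labeled distance matrix", call. = FALSE)
}

#' Distances from a focal leaf
#'
#' Extracts the patristic distances of every other leaf from a focal leaf
#' (e.g. the host ortholog). The focal leaf's zero self-distance is excluded,
#' so a tree with n leaves yields n - 1 distances — matching the convention
#' under which a 192-ortholog tree gives 191 host distances.
#'
#' @param matrix A patristic matrix or a `phylo` tree.
#' @param focal A leaf label present in the matrix.
#' @return A tibble with columns `leaf` and `distance`, in matrix order.
#' @export
#' @examples
#' m <- patristic_matrix(read_newick("((A:1,B:2):1,(C:3,D:1):2);"))
#' distances_from(m, "A")
distances_from <- function(matrix, focal) {
  m <- as_patristic(matrix)
  labs <- rownames(m)
  if (!focal %in% labs) {
    near <- agrep(focal, labs, max.distance = 0.3, value = TRUE,
                  ignore.case = TRUE)
    hint <- if (length(near)) paste0("; near matches: ", paste(utils::head(near, 5), collapse = ", ")) else ""
    stop("focal leaf '", focal, "' not found in tree", hint, call. = FALSE)
  }
  keep <- labs != focal
  tibble::tibble(leaf = labs[keep], distance = unname(m[focal, keep]))
}

#' Write a patristic matrix to TSV
#'
#' @param matrix A patristic matrix.
#' @param file Output path.
#' @param format `"square"` (labeled header row/column) or `"long"`
#'   (`leaf_a`, `leaf_b`, `distance`).
#' @return `file`, invisibly.
#' @export
write_patristic_tsv <- function(matrix, file, format = c("square", "long")) {
  format <- match.arg(format)
  m <- as_patristic(matrix)
  if (format == "square") {
    df <- data.frame(leaf = rownames(m), m, check.names = FALSE)
    readr::write_tsv(df, file)
  } else {
    readr::write_tsv(patristic_tbl(m), file)
  }
  invisible(file)
}
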