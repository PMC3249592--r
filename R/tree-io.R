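#' Parse a Newick string into a rooted phylogenetic tree
#'
#' Parses one rooted tree in Newick format and validates it: leaf labels must
#' be unique and nonempty, branch lengths (if present) must be nonnegative,
#' and parentheses must balance. Quoted labels and scientific-notation branch
#' lengths are accepted; internal-node labels are parsed but ignored by all
#' algorithms. The tree is taken to be rooted as written: the node outside
#' the outermost parentheses is the root, whatever its out-degree (so
#' \code{"(a,b,c);"} is a rooted star, not an unrooted triple). Use
#' [root_at_outgroup()] to root a tree that is only implicitly rooted.
#'
#' @param text A single Newick string terminated by a semicolon.
#' @return An object of class \code{"phylo"} (see \pkg{ape}).
#' @examples
#' tr <- parse_newick("((a:1,b:1):1,c:2);")
#' leaf_labels(tr)
#' @seealso [read_newick()], [write_newick()]
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single character string")
  text <- trimws(text)
  # locate unbalanced parentheses before handing off to the reader, so the
  # error can carry a character offset
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error: unmatched ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf(
      "Newick parse error: %d unclosed '(' at end of string (length %d)",
      depth, length(chars)))
  if (!endsWith(text, ";"))
    stop(sprintf(
      "Newick parse error: missing terminating ';' at character %d",
      nchar(text)))
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr))
    stop("Newick parse error: reader returned no tree")
  validate_tree(tr)
}

#' Read rooted trees from a Newick file
#'
#' Reads one tree per line (blank lines ignored) and validates each as in
#' [parse_newick()].
#'
#' @param file Path to a Newick file.
#' @return A list of \code{"phylo"} objects.
#' @export
read_newick <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no trees found in ", file)
  lapply(lines, parse_newick)
}

#' Write trees in Newick format
#'
#' Branch lengths are written with 10 significant digits so that a
#' write/parse round trip preserves topology, labels, and lengths.
#'
#' @param trees A \code{"phylo"} object or a list of them.
#' @param file Optional output path; if \code{NULL} the Newick strings are
#'   returned invisibly-printed as a character vector.
#' @param digits Significant digits for branch lengths.
#' @return A character vector of Newick strings (invisibly when writing to
#'   file).
#' @export
write_newick <- function(trees, file = NULL, digits = 10L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  out <- vapply(trees, function(tr) {
    ape::write.tree(tr, digits = digits)
  }, character(1))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Leaf labels of a tree
#'
#' @param tree A \code{"phylo"} object.
#' @return Character vector of leaf labels.
#' @export
leaf_labels <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$tip.label
}

# Validate the rooted-tree invariants: unique nonempty leaf labels,
# nonnegative branch lengths, no non-root singleton (out-degree-1) chains.
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (anyNA(labs) || any(!nzchar(labs)))
    stop("validation error: empty leaf label")
  if (anyDuplicated(labs)) {
    dup <- unique(labs[duplicated(labs)])
    stop("validation error: duplicate leaf label(s): ",
         paste(dup, collapse = ", "))
  }
  if (!is.null(tree$edge.length)) {
    if (all(is.na(tree$edge.length))) {
      tree$edge.length <- NULL      # topology-only tree
    } else if (any(tree$edge.length < 0, na.rm = TRUE)) {
      stop("validation error: negative branch length")
    }
  }
  if (length(labs) >= 2L) {
    out_deg <- tabulate(tree$edge[, 1], nbins = max(tree$edge))
    internals <- sort(unique(tree$edge[, 1]))
    if (any(out_deg[internals] < 2L)) tree <- ape::collapse.singles(tree)
  }
  tree
}

#' Root a tree at an outgroup taxon
#'
#' Roots (or re-roots) a tree on the pendant branch of \code{outgroup} and
#' returns the rooted ingroup-plus-outgroup tree. Intended for inputs whose
#' Newick representation does not carry a meaningful root.
#'
#' @param tree A \code{"phylo"} object containing \code{outgroup}.
#' @param outgroup Leaf label to root on.
#' @return A rooted \code{"phylo"} object.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
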