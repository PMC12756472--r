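#' Read a dated phylogeny from a Newick file
#'
#' Parses a single rooted tree with branch lengths in Ma (mega-annum) and
#' validates it as a dated tree: branch lengths present on every non-root
#' edge and non-negative, tip labels unique and non-empty. Node ages are
#' measured backwards from the tips: the deepest tip sits at age 0 and the
#' root at age = tree depth (see [node_ages()]).
#'
#' Dated trees cut from calibrated mega-trees are usually only
#' near-ultrametric because of rounding; if tip depths differ from the tree
#' depth by more than a relative `1e-6`, a warning (not an error) is issued.
#'
#' A root edge, if present in the file, is kept on the `phylo` object but is
#' never counted in PD sums or path lengths (the root anchors all paths).
#'
#' @param path Path to a Newick file containing exactly one tree.
#' @return An [ape::read.tree()] `phylo` object that passed validation.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) {
    stop("tree file not found: ", path)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_syntax(txt)
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("Newick parse failure in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse failure in '", path, "'")
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected a single tree, found ", length(tree))
    tree <- tree[[1L]]
  }
  validate_dated_tree(tree)
  tree
}

# Cheap structural scan so malformed input is reported with a byte offset
# (ape's own errors do not locate the problem).
check_newick_syntax <- function(txt) {
  bytes <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(bytes)) {
    if (bytes[i] == "(") depth <- depth + 1L
    if (bytes[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick format error: unbalanced ')' at byte offset ", i)
      }
    }
  }
  if (depth > 0L) {
    stop("Newick format error: ", depth,
         " unclosed '(' by byte offset ", length(bytes))
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    stop("Newick format error: missing terminating ';' (byte offset ",
         length(bytes), ")")
  }
  invisible(TRUE)
}

#' Validate a phylo object as a dated tree
#'
#' Checks the invariants assumed throughout the package: single root,
#' branch lengths defined and non-negative on all non-root edges, unique
#' non-empty tip labels. Near-ultrametricity is advisory only.
#'
#' @param tree A `phylo` object.
#' @param ultra_rtol Relative tolerance on tip-depth spread before the
#'   ultrametricity warning fires.
#' @return `tree`, invisibly.
#' @export
validate_dated_tree <- function(tree, ultra_rtol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip label")
  if (anyDuplicated(labs)) {
    stop("duplicate tip label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; a dated tree is required")
  }
  if (length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop("missing branch length on a non-root edge")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  # exactly one root: node never appearing as a child
  kids <- tree$edge[, 2L]
  roots <- setdiff(unique(tree$edge[, 1L]), kids)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  dev <- ultrametric_deviation(tree)
  if (dev > ultra_rtol) {
    warning(sprintf(
      "tree is not ultrametric: relative tip-depth spread %.3g (tips should be contemporaneous at age 0)",
      dev))
  }
  invisible(tree)
}

#' Relative spread of tip depths
#'
#' `(max tip depth - min tip depth) / max tip depth`; 0 for an exactly
#' ultrametric tree.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A non-negative scalar.
#' @export
ultrametric_deviation <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (max(depths) == 0) return(0)
  (max(depths) - min(depths)) / max(depths)
}

#' Node ages of a dated tree
#'
#' Ages in Ma for all nodes (tips then internal nodes, in `phylo` node
#' numbering). The tree depth is the maximum tip depth, so the deepest tips
#' sit at age 0 and the root at age = depth; in a slightly non-ultrametric
#' tree shallow tips get small positive ages rather than forcing every tip
#' to 0, which keeps internal-node ages consistent with branch lengths.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_along(tree$tip.label)]) - depths
}

#' Total depth (root age) of a dated tree
#' @param tree A `phylo` object with branch lengths.
#' @return Tree depth in Ma.
#' @export
tree_depth <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Total branch length of a tree
#'
#' Sum over all non-root edges; a root edge, if any, is excluded.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Total branch length in Ma.
#' @export
total_branch_length <- function(tree) {
  sum(tree$edge.length)
}
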