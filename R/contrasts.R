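#' Parse a Newick tree for contrast analysis
#'
#' Thin wrapper around [ape::read.tree()] that enforces what Felsenstein's
#' contrast algorithm needs: a single rooted tree with branch lengths on
#' every edge, fully binary.  Polytomies are resolved deterministically in
#' input order ([ape::multi2di()] with `random = FALSE`) and any
#' zero-length branch -- pre-existing or created by the resolution -- is
#' replaced by a small epsilon with a warning, so contrast variances stay
#' strictly positive.
#'
#' @param text a Newick string, or `NULL` if `file` is given.
#' @param file path to a Newick file; if it holds several trees the first
#'   is used with a warning.
#' @param epsilon replacement length for zero-length branches.
#' @return an [ape::phylo] object, binary with positive branch lengths.
#' @export
parse_newick <- function(text = NULL, file = NULL, epsilon = 1e-8) {
  stopifnot(xor(is.null(text), is.null(file)))
  tr <- tryCatch(
    suppressWarnings(
      if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file)),
    error = function(e) stop("malformed Newick: ", conditionMessage(e),
                             call. = FALSE))
  if (inherits(tr, "multiPhylo")) {
    warning("input holds ", length(tr), " trees; using the first")
    tr <- tr[[1]]
  }
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick: no tree could be parsed",
         if (!is.null(text)) paste0(" (near character ",
                                    newick_error_offset(text), ")"))
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; contrasts need them")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!ape::is.binary(tr) || !ape::is.rooted(tr))
    tr <- ape::multi2di(tr, random = FALSE)
  if (any(tr$edge.length <= 0)) {
    n_zero <- sum(tr$edge.length <= 0)
    tr$edge.length[tr$edge.length <= 0] <- epsilon
    warning(n_zero, " non-positive branch length(s) replaced by ", epsilon)
  }
  tr
}

# first position where the parenthesis balance goes negative, else the
# position after the string -- a coarse but useful diagnostic
newick_error_offset <- function(text) {
  bal <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1,
                       ifelse(strsplit(text, "")[[1]] == ")", -1, 0)))
  neg <- which(bal < 0)
  if (length(neg)) neg[1] else nchar(text) + 1
}

#' Prune a tree to a set of species
#'
#' Induced subtree on the requested tips; branches through suppressed
#' degree-2 nodes are summed, so tip-to-tip path lengths are conserved.
#'
#' @param tree an [ape::phylo].
#' @param species character vector of tip labels to keep.
#' @return the pruned [ape::phylo].
#' @export
prune_to_species <- function(tree, species) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(species, tree$tip.label)
  if (length(miss))
    stop("species absent from tree: ", paste(miss, collapse = ", "))
  if (setequal(species, tree$tip.label)) return(tree)
  ape::keep.tip(tree, species)
}

#' Phylogenetically independent contrasts for one trait
#'
#' Felsenstein's pruning recursion: at each internal node with daughter
#' values x1, x2 on (adjusted) branches v1, v2 the standardized contrast
#' is (x1 - x2)/sqrt(v1 + v2), the nodal value is the
#' precision-weighted mean (x1/v1 + x2/v2)/(1/v1 + 1/v2), and the branch
#' above the node is lengthened by v1*v2/(v1 + v2).  Computation is
#' delegated to [ape::pic()]; this wrapper fixes the row order to a
#' postorder traversal (daughters before parents) so output is
#' bit-for-bit reproducible, and keeps the subtraction direction
#' "first daughter minus second daughter" in input order.  Under
#' Brownian-motion evolution with rate sigma^2 the n - 1 contrasts are
#' i.i.d. Normal(0, sigma^2).
#'
#' @param tree a binary [ape::phylo] with positive branch lengths.
#' @param values named numeric vector, one value per tip.
#' @return A `data.frame` (class `"contrast_table"`): `node` (internal
#'   node id, postorder), `contrast` (standardized), `sd` (sqrt of the
#'   contrast variance v1 + v2 after branch adjustment).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' pic_table(tr, c(A = 1, B = 3, C = 10))
#' @export
pic_table <- function(tree, values) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) stop("tree must be binary; see parse_newick()")
  miss <- setdiff(tree$tip.label, names(values))
  if (length(miss))
    stop("tip(s) without a trait value: ", paste(miss, collapse = ", "))
  x <- values[tree$tip.label]
  res <- ape::pic(x, tree, scaled = TRUE, var.contrasts = TRUE)
  ord <- postorder_nodes(tree)
  out <- data.frame(node = ord,
                    contrast = res[as.character(ord), "contrasts"],
                    sd = sqrt(res[as.character(ord), "variance"]))
  rownames(out) <- NULL
  class(out) <- c("contrast_table", "data.frame")
  out
}

# internal node ids in postorder (every daughter before its parent)
postorder_nodes <- function(tree) {
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  unique(edge[, 1])
}

#' Contrast matrix for a whole trait table
#'
#' Computes independent contrasts for every trait column against one
#' tree, with the identical node order and subtraction direction in each
#' column (so cross-products between columns are meaningful).  The tree
#' is pruned to the table's species first; tree and table must contain
#' the same species.
#'
#' @param tree an [ape::phylo].
#' @param t a `trait_table` (usually transformed; see
#'   [apply_transforms()]).
#' @return A list with `contrasts` (matrix, n_species - 1 rows by 9 trait
#'   columns), `node` (internal node ids, postorder) and `sd` (matrix of
#'   contrast standard deviations).
#' @export
contrasts_for_table <- function(tree, t) {
  stopifnot(inherits(t, "trait_table"))
  extra <- setdiff(t$species, tree$tip.label)
  if (length(extra))
    stop("species missing from tree: ", paste(extra, collapse = ", "))
  tree <- prune_to_species(tree, t$species)
  vars <- trait_variables()
  cols <- lapply(vars, function(v) {
    pic_table(tree, stats::setNames(t[[v]], t$species))
  })
  contrasts <- sapply(cols, function(d) d$contrast)
  sds <- sapply(cols, function(d) d$sd)
  colnames(contrasts) <- colnames(sds) <- vars
  list(contrasts = contrasts, node = cols[[1]]$node, sd = sds)
}
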