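#' Species tree objects
#'
#' A species tree is a rooted binary phylogeny of genomes. Internally it is
#' stored in an indexed form: per-node label, parent index and child indices,
#' so that reconciled gene trees can refer to species by integer index.
#'
#' @param label character vector of node labels (unique).
#' @param parent integer vector of parent indices (`NA` for the root).
#' @param children list of integer vectors (length 0 for leaves, 2 otherwise).
#' @return An object of class `species_tree`.
#' @keywords internal
new_species_tree <- function(label, parent, children) {
  stopifnot(length(label) == length(parent), length(label) == length(children))
  root <- which(is.na(parent))
  if (length(root) != 1L)
    stop("species tree must have exactly one root", call. = FALSE)
  x <- structure(
    list(label = label, parent = as.integer(parent), children = children,
         root = root),
    class = "species_tree")
  validate_species_tree(x)
  x
}

validate_species_tree <- function(x) {
  nc <- lengths(x$children)
  if (any(!nc %in% c(0L, 2L))) {
    bad <- x$label[which(!nc %in% c(0L, 2L))[1L]]
    stop("species tree is not binary at node '", bad, "'", call. = FALSE)
  }
  if (anyDuplicated(x$label)) {
    stop("duplicate species label '", x$label[duplicated(x$label)][1L], "'",
         call. = FALSE)
  }
  # reachability from root (also excludes cycles)
  seen <- logical(length(x$label))
  stack <- x$root
  while (length(stack)) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[i]) stop("cycle detected in species tree", call. = FALSE)
    seen[i] <- TRUE
    stack <- c(stack, x$children[[i]])
  }
  if (!all(seen)) {
    stop("species node '", x$label[which(!seen)[1L]],
         "' not reachable from root", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree:", sum(lengths(x$children) == 0L), "extant genomes,",
      length(x$label), "nodes, root '", x$label[x$root], "'\n", sep = " ")
  invisible(x)
}

sp_index <- function(tree, labels) {
  i <- match(labels, tree$label)
  if (anyNA(i)) {
    stop("unknown species label '", labels[which(is.na(i))[1L]], "'",
         call. = FALSE)
  }
  i
}

sp_is_leaf <- function(tree, i) lengths(tree$children[i]) == 0L

sp_ancestors <- function(tree, i) {
  out <- integer(0)
  while (!is.na(tree$parent[i])) {
    i <- tree$parent[i]
    out <- c(out, i)
  }
  out
}

sp_depths <- function(tree) {
  d <- integer(length(tree$label))
  stack <- tree$root
  while (length(stack)) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tree$children[[i]]
    d[kids] <- d[i] + 1L
    stack <- c(stack, kids)
  }
  d
}

#' Lowest common ancestor of two species
#' @keywords internal
sp_lca <- function(tree, i, j) {
  ai <- c(i, sp_ancestors(tree, i))
  aj <- c(j, sp_ancestors(tree, j))
  ai[ai %in% aj][1L]
}

sp_is_desc_or_equal <- function(tree, i, anc) {
  if (i == anc) return(TRUE)
  anc %in% sp_ancestors(tree, i)
}

#' Path of species from an ancestor down to a descendant
#' @return integer vector starting at `from` and ending at `to`.
#' @keywords internal
sp_path_down <- function(tree, from, to) {
  up <- c(to, sp_ancestors(tree, to))
  k <- match(from, up)
  if (is.na(k)) stop("'", tree$label[from], "' is not an ancestor of '",
                     tree$label[to], "'", call. = FALSE)
  rev(up[1:k])
}
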