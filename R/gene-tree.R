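#' Reconciled gene tree objects
#'
#' A reconciled gene tree is a rooted binary gene phylogeny in which every node
#' g carries a species assignment s(g) (an index into a [species_tree]) and an
#' evolutionary event e(g): `"Spec"` (speciation) or `"GDup"` (gene
#' duplication) at internal nodes, `"Extant"` or `"GLoss"` (gene loss) at
#' leaves. Loss leaves are materialized so that every speciation node has one
#' child lineage per species child.
#'
#' @param label character vector of node labels; missing internal labels are
#'   generated.
#' @param species integer vector of species indices.
#' @param event character vector of events.
#' @param parent integer parent indices (`NA` at the root).
#' @param children list of integer child vectors (0 or 2 children).
#' @param species_tree the [species_tree] the assignments refer to.
#' @return An object of class `recon_tree`.
#' @keywords internal
new_recon_tree <- function(label, species, event, parent, children,
                           species_tree, name = "G") {
  n <- length(species)
  if (is.null(label)) label <- rep(NA_character_, n)
  miss <- is.na(label) | label == ""
  if (any(miss)) label[miss] <- paste0(name, ".", which(miss))
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("gene tree must have exactly one root",
                               call. = FALSE)
  structure(
    list(label = label, species = as.integer(species), event = event,
         parent = as.integer(parent), children = children, root = root,
         species_tree = species_tree),
    class = "recon_tree")
}

#' @export
print.recon_tree <- function(x, ...) {
  nl <- sum(lengths(x$children) == 0L)
  cat("Reconciled gene tree: ", nl, " leaves (",
      sum(x$event == "Extant"), " extant, ", sum(x$event == "GLoss"),
      " losses), root at species '",
      x$species_tree$label[x$species[x$root]], "'\n", sep = "")
  invisible(x)
}

gt_postorder <- function(tree) {
  out <- integer(0)
  rec <- function(i) {
    for (k in tree$children[[i]]) rec(k)
    out[[length(out) + 1L]] <<- i
  }
  rec(tree$root)
  unlist(out)
}

gt_n_leaves <- function(tree) sum(lengths(tree$children) == 0L)

#' Number of leaves below (and including) each node
#' @keywords internal
gt_subtree_leaves <- function(tree) {
  n <- length(tree$label)
  cnt <- integer(n)
  for (i in gt_postorder(tree)) {
    kids <- tree$children[[i]]
    cnt[i] <- if (length(kids)) sum(cnt[kids]) else 1L
  }
  cnt
}

#' Leaf indices below (and including) each node, as a list
#' @keywords internal
gt_subtree_leafsets <- function(tree) {
  n <- length(tree$label)
  sets <- vector("list", n)
  for (i in gt_postorder(tree)) {
    kids <- tree$children[[i]]
    sets[[i]] <- if (length(kids)) c(sets[[kids[1L]]], sets[[kids[2L]]]) else i
  }
  sets
}

#' Check every reconciled-gene-tree invariant
#'
#' Re-checks, node by node, that leaf/internal events are legal, that a
#' speciation node's children map to the two species children of its own
#' species, that a duplication node's children stay within its species, and
#' that child species are descendants of parent species. Returns a character
#' vector of diagnostics, empty when the tree is valid.
#'
#' @param tree a `recon_tree`.
#' @param species the species tree; defaults to the one the gene tree carries.
#' @return character vector of human-readable violations (empty if valid).
#' @export
validate_reconciliation <- function(tree, species = tree$species_tree) {
  bad <- character(0)
  slab <- species$label
  for (i in seq_along(tree$label)) {
    kids <- tree$children[[i]]
    ev <- tree$event[i]
    lab <- tree$label[i]
    if (length(kids) == 0L) {
      if (!ev %in% c("Extant", "GLoss"))
        bad <- c(bad, paste0("leaf '", lab, "' has internal event ", ev))
      if (ev == "Extant" && !sp_is_leaf(species, tree$species[i]))
        bad <- c(bad, paste0("extant gene '", lab,
                             "' assigned to ancestral species '",
                             slab[tree$species[i]], "'"))
      next
    }
    if (length(kids) != 2L) {
      bad <- c(bad, paste0("internal node '", lab, "' has ", length(kids),
                           " children (must be 2)"))
      next
    }
    if (!ev %in% c("Spec", "GDup")) {
      bad <- c(bad, paste0("internal node '", lab, "' has leaf event ", ev))
      next
    }
    s <- tree$species[i]
    cs <- sort(tree$species[kids])
    if (ev == "Spec") {
      want <- sort(species$children[[s]])
      if (length(want) == 0L || !identical(cs, want))
        bad <- c(bad, paste0("speciation node '", lab, "' at species '",
                             slab[s], "' has children in {",
                             paste(slab[cs], collapse = ","),
                             "} instead of the species children"))
    } else {
      if (!all(cs == s))
        bad <- c(bad, paste0("duplication node '", lab, "' at species '",
                             slab[s], "' has children outside its species"))
    }
    for (k in kids) {
      if (!sp_is_desc_or_equal(species, tree$species[k], s))
        bad <- c(bad, paste0("child '", tree$label[k],
                             "' maps above its parent's species"))
    }
  }
  bad
}

assert_valid_reconciliation <- function(tree, species = tree$species_tree) {
  bad <- validate_reconciliation(tree, species)
  if (length(bad)) stop("invalid reconciled gene tree: ", bad[1L],
                        call. = FALSE)
  invisible(tree)
}
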