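#' LCA reconciliation of a plain gene tree
#'
#' Maps every node of an unannotated binary gene tree to a species and an
#' event under the most-parsimonious (lowest-common-ancestor) reconciliation:
#' s(g) is the LCA in the species tree of the species below g, and e(g) is a
#' duplication exactly when s(g) equals the species of one of its children.
#' Loss leaves are then materialized so that every speciation node has one
#' child lineage per species child and every lineage descends one species
#' step at a time — the output satisfies every reconciled-tree invariant.
#'
#' @param tree a plain Newick string, or an internal topology list with
#'   fields `label`, `parent`, `children`.
#' @param species a `species_tree`.
#' @param map named character vector: gene leaf label -> species label.
#' @param name prefix used for generated internal labels.
#' @return A `recon_tree`.
#' @examples
#' sp <- parse_species_tree("(A,B)R;")
#' lca_reconcile("((a1,b1),(a2,b2));", sp,
#'               c(a1 = "A", b1 = "B", a2 = "A", b2 = "B"))
#' @export
lca_reconcile <- function(tree, species, map, name = "G") {
  if (is.character(tree)) {
    tree <- plain_to_gene_topology(parse_nhx_string(tree), name)
  }
  n_old <- length(tree$label)
  is_leaf <- lengths(tree$children) == 0L
  sp_of <- rep(NA_integer_, n_old)
  for (i in which(is_leaf)) {
    lab <- tree$label[i]
    if (is.na(lab) || !lab %in% names(map))
      stop("gene leaf '", lab, "' has no species mapping", call. = FALSE)
    sp_of[i] <- sp_index(species, map[[lab]])
  }
  # postorder species assignment + event calls
  post <- local({
    out <- integer(0)
    rec <- function(i) {
      for (k in tree$children[[i]]) rec(k)
      out[[length(out) + 1L]] <<- i
    }
    root <- which(is.na(tree$parent))
    rec(root)
    unlist(out)
  })
  ev_of <- ifelse(is_leaf, "Extant", NA_character_)
  for (i in post) {
    kids <- tree$children[[i]]
    if (length(kids) == 0L) next
    if (length(kids) != 2L)
      stop("gene tree node '", tree$label[i], "' is not binary", call. = FALSE)
    sp_of[i] <- sp_lca(species, sp_of[kids[1L]], sp_of[kids[2L]])
    ev_of[i] <- if (sp_of[i] %in% sp_of[kids]) "GDup" else "Spec"
  }
  # smallest leaf label below each old node, for deterministic child order
  minlab <- rep(NA_character_, n_old)
  for (i in post) {
    kids <- tree$children[[i]]
    minlab[i] <- if (length(kids)) min(minlab[kids]) else tree$label[i]
  }

  label <- character(0); spc <- integer(0); event <- character(0)
  parent <- integer(0); children <- list()
  n_loss <- 0L
  add_node <- function(lab, s, ev, par) {
    i <- length(label) + 1L
    label[i] <<- lab; spc[i] <<- s; event[i] <<- ev; parent[i] <<- par
    children[[i]] <<- integer(0)
    if (!is.na(par)) children[[par]] <<- c(children[[par]], i)
    i
  }
  add_loss <- function(s, par) {
    n_loss <<- n_loss + 1L
    add_node(paste0("LOSS_", species$label[s], "_", n_loss), s, "GLoss", par)
  }
  # walk down the species path from `from` to `to`, inserting a speciation
  # node (with a loss leaf on the off-path side) per intermediate species;
  # returns the new parent the gene subtree should attach to
  descend <- function(par, from, to) {
    path <- sp_path_down(species, from, to)
    j <- 1L
    while (j < length(path)) {
      u <- path[j]
      nxt <- path[j + 1L]
      spn <- add_node(NA_character_, u, "Spec", par)
      off <- setdiff(species$children[[u]], nxt)
      add_loss(off, spn)  # surviving side is appended by the next step
      par <- spn
      j <- j + 1L
    }
    par
  }
  rec <- function(i, par) {
    kids <- tree$children[[i]]
    if (length(kids) == 0L) {
      add_node(tree$label[i], sp_of[i], "Extant", par)
      return(invisible(NULL))
    }
    me <- add_node(tree$label[i], sp_of[i], ev_of[i], par)
    if (ev_of[i] == "Spec") {
      ord <- order(match(
        vapply(kids, function(k) {
          p <- sp_path_down(species, sp_of[i], sp_of[k])
          p[2L]
        }, integer(1L)),
        species$children[[sp_of[i]]]))
      kids <- kids[ord]
      for (k in kids) {
        start <- sp_path_down(species, sp_of[i], sp_of[k])[2L]
        at <- descend(me, start, sp_of[k])
        rec(k, at)
      }
    } else {
      kids <- kids[order(minlab[kids])]
      for (k in kids) {
        at <- descend(me, sp_of[i], sp_of[k])
        rec(k, at)
      }
    }
    invisible(NULL)
  }
  rec(which(is.na(tree$parent)), NA_integer_)
  out <- new_recon_tree(label, spc, event, parent, children, species, name)
  assert_valid_reconciliation(out)
  out
}
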