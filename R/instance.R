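#' DeCo instances
#'
#' A DeCo instance is a pair of reconciled gene trees over one species tree,
#' together with the observed extant adjacencies linking leaves of the first
#' tree to leaves of the second. All ensemble computations operate per
#' instance.
#'
#' @param g1,g2 `recon_tree` objects over the same species tree.
#' @param adjacencies tibble/data.frame with columns `gene1`, `gene2`; each
#'   row pairs an extant leaf of `g1` (either column) with an extant leaf of
#'   `g2`. When `oriented = TRUE`, `gene1` is taken to lie in `g1` as given.
#' @param oriented skip automatic orientation of pairs (used for
#'   self-instances where both trees carry the same labels).
#' @return An object of class `deco_instance`.
#' @export
deco_instance <- function(g1, g2, adjacencies, oriented = FALSE) {
  stopifnot(inherits(g1, "recon_tree"), inherits(g2, "recon_tree"))
  if (!identical(g1$species_tree$label, g2$species_tree$label))
    stop("gene trees reconcile against different species trees",
         call. = FALSE)
  if (nrow(adjacencies) < 1L)
    stop("a DeCo instance needs at least one extant adjacency", call. = FALSE)
  l1 <- g1$label[g1$event == "Extant"]
  l2 <- g2$label[g2$event == "Extant"]
  a <- character(nrow(adjacencies)); b <- character(nrow(adjacencies))
  for (i in seq_len(nrow(adjacencies))) {
    x <- adjacencies$gene1[i]; y <- adjacencies$gene2[i]
    if (oriented || (x %in% l1 && !x %in% l2)) {
      a[i] <- x; b[i] <- y
    } else if (y %in% l1 && x %in% l2) {
      a[i] <- y; b[i] <- x
    } else if (x %in% l1 && y %in% l2) {
      a[i] <- x; b[i] <- y
    } else {
      stop("adjacency (", x, ",", y, ") does not link a leaf of G1 to a ",
           "leaf of G2", call. = FALSE)
    }
    if (!a[i] %in% l1 || !b[i] %in% l2)
      stop("adjacency (", x, ",", y, ") does not link a leaf of G1 to a ",
           "leaf of G2", call. = FALSE)
  }
  i1 <- match(a, g1$label); i2 <- match(b, g2$label)
  if (any(g1$species[i1] != g2$species[i2]))
    stop("adjacency pairs genes from different species", call. = FALSE)
  adj <- tibble::tibble(gene1_g1 = a, gene2_g2 = b,
                        node1 = i1, node2 = i2,
                        species = g1$species_tree$label[g1$species[i1]])
  dup <- duplicated(paste(adj$gene1_g1, adj$gene2_g2, sep = "\t"))
  adj <- adj[!dup, ]
  id <- paste0(g1$label[g1$root], "~", g2$label[g2$root], "~",
               nrow(adj), "~",
               paste(adj$gene1_g1, adj$gene2_g2, sep = ":", collapse = "|"))
  structure(list(g1 = g1, g2 = g2, adjacencies = adj, id = id),
            class = "deco_instance")
}

#' @export
print.deco_instance <- function(x, ...) {
  cat("DeCo instance: G1 with", gt_n_leaves(x$g1), "leaves, G2 with",
      gt_n_leaves(x$g2), "leaves,", nrow(x$adjacencies),
      "extant adjacencies\n")
  invisible(x)
}

#' Group gene trees and adjacencies into DeCo instances
#'
#' One instance is created per unordered pair of trees linked by at least one
#' extant adjacency, carrying all the adjacencies that link that pair. An
#' adjacency between two leaves of the same tree yields a self-instance in
#' which the second tree is a working copy of the first (the
#' lexicographically smaller gene of each pair is placed on the G1 side).
#'
#' @param trees list of `recon_tree` objects.
#' @param adjacencies tibble from [parse_adjacencies()] (columns `gene1`,
#'   `gene2`).
#' @return A list of `deco_instance` objects, ordered by tree indices.
#' @export
build_instances <- function(trees, adjacencies) {
  idx <- gene_leaf_index(trees)
  t1 <- idx$tree[adjacencies$gene1]
  t2 <- idx$tree[adjacencies$gene2]
  if (anyNA(t1) || anyNA(t2)) {
    miss <- c(adjacencies$gene1, adjacencies$gene2)[which(is.na(c(t1, t2)))[1L]]
    stop("adjacency gene '", miss, "' is not a leaf of any tree",
         call. = FALSE)
  }
  lo <- pmin(t1, t2); hi <- pmax(t1, t2)
  key <- paste(lo, hi, sep = "~")
  out <- list()
  for (k in unique(key[order(lo, hi)])) {
    rows <- which(key == k)
    ta <- lo[rows[1L]]; tb <- hi[rows[1L]]
    pairs <- adjacencies[rows, c("gene1", "gene2")]
    if (ta == tb) {
      out[[length(out) + 1L]] <-
        deco_instance(trees[[ta]], trees[[ta]], pairs, oriented = TRUE)
    } else {
      # orient each pair so that its gene in tree `ta` comes first
      swap <- idx$tree[pairs$gene1] != ta
      tmp <- pairs$gene1[swap]
      pairs$gene1[swap] <- pairs$gene2[swap]
      pairs$gene2[swap] <- tmp
      out[[length(out) + 1L]] <-
        deco_instance(trees[[ta]], trees[[tb]], pairs, oriented = TRUE)
    }
  }
  out
}
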