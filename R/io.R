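## Readers and writers: Newick species trees, NHX-annotated reconciled gene
## trees, two-column adjacency lists, adjacency forests, probability matrices.

#' Parse a species tree from Newick text
#'
#' All nodes, internal ones included, must be labelled (species assignments of
#' gene-tree nodes refer to these labels), labels must be unique, and every
#' internal node must have exactly two children.
#'
#' @param text a Newick string, e.g. `"(A,B)C;"`. The degenerate single-leaf
#'   tree `"A;"` is allowed.
#' @return A `species_tree` object.
#' @examples
#' parse_species_tree("(A,B)C;")
#' @export
parse_species_tree <- function(text) {
  text <- trimws(text)
  if (!grepl("\\(", text)) {
    lab <- sub(";$", "", text)
    if (!nzchar(lab)) stop("empty species tree", call. = FALSE)
    return(new_species_tree(lab, NA_integer_, list(integer(0))))
  }
  ph <- ape::read.tree(text = text)
  if (is.null(ph)) stop("malformed Newick species tree", call. = FALSE)
  labs <- c(ph$tip.label, ph$node.label)
  n_tip <- length(ph$tip.label)
  n_all <- n_tip + ph$Nnode
  if (length(labs) != n_all || any(is.na(labs)) || any(labs == ""))
    stop("species tree requires a label on every node", call. = FALSE)
  parent <- rep(NA_integer_, n_all)
  children <- rep(list(integer(0)), n_all)
  for (r in seq_len(nrow(ph$edge))) {
    p <- ph$edge[r, 1L]; k <- ph$edge[r, 2L]
    parent[k] <- p
    children[[p]] <- c(children[[p]], k)
  }
  new_species_tree(labs, parent, children)
}

## ---- Newick + NHX recursive-descent parser ------------------------------
## ape strips [] comments, so NHX tags (S=species, Ev=event) need a dedicated
## parser. Returns nested lists: list(label=, tags=named character, children=).

parse_nhx_string <- function(text) {
  text <- trimws(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  pos <- 1L
  n <- length(chars)
  peek <- function() if (pos <= n) chars[pos] else ""
  advance <- function() pos <<- pos + 1L
  fail <- function(msg) stop("Newick parse error at character ", pos, ": ",
                             msg, call. = FALSE)
  read_label <- function() {
    out <- character(0)
    while (pos <= n && !chars[pos] %in% c("(", ")", ",", ":", ";", "[")) {
      out <- c(out, chars[pos]); advance()
    }
    paste(out, collapse = "")
  }
  read_comment <- function() {
    if (peek() != "[") return(NULL)
    advance()
    out <- character(0)
    while (pos <= n && chars[pos] != "]") { out <- c(out, chars[pos]); advance() }
    if (peek() != "]") fail("unterminated [ comment")
    advance()
    com <- paste(out, collapse = "")
    if (!startsWith(com, "&&NHX")) return(NULL)
    body <- sub("^&&NHX:?", "", com)
    if (!nzchar(body)) return(character(0))
    kv <- strsplit(strsplit(body, ":", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    tags <- vapply(kv, function(p) if (length(p) > 1L) p[2L] else "", "")
    names(tags) <- vapply(kv, `[[`, "", 1L)
    tags
  }
  read_node <- function() {
    children <- list()
    if (peek() == "(") {
      advance()
      repeat {
        children[[length(children) + 1L]] <- read_node()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        fail("expected ',' or ')'")
      }
    }
    label <- read_label()
    if (peek() == ":") {  # branch length, ignored
      advance(); read_label()
    }
    tags <- read_comment()
    if (peek() == ":") { advance(); read_label() }
    list(label = label, tags = tags, children = children)
  }
  node <- read_node()
  if (peek() != ";") fail("expected ';'")
  node
}

nhx_to_recon_tree <- function(nested, species, name = "G") {
  label <- character(0); spec <- integer(0); event <- character(0)
  parent <- integer(0); children <- list()
  rec <- function(nd, par) {
    i <- length(label) + 1L
    label[i] <<- if (nzchar(nd$label)) nd$label else NA_character_
    tags <- nd$tags
    if (is.null(tags) || !all(c("S", "Ev") %in% names(tags)))
      stop("node '", nd$label,
           "' lacks NHX tags S= and Ev= required for a reconciled tree",
           call. = FALSE)
    spec[i] <<- sp_index(species, tags[["S"]])
    ev <- tags[["Ev"]]
    if (!ev %in% c("Spec", "GDup", "GLoss", "Extant"))
      stop("unknown event '", ev, "' at node '", nd$label, "'", call. = FALSE)
    event[i] <<- ev
    parent[i] <<- par
    children[[i]] <<- integer(0)
    for (ch in nd$children) {
      k <- rec(ch, i)
      children[[i]] <<- c(children[[i]], k)
    }
    i
  }
  rec(nested, NA_integer_)
  tr <- new_recon_tree(label, spec, event, parent, children, species, name)
  assert_valid_reconciliation(tr)
  tr
}

plain_to_gene_topology <- function(nested, name = "G") {
  # unannotated tree: labels + topology only; unary chains collapsed
  label <- character(0); parent <- integer(0); children <- list()
  rec <- function(nd, par) {
    while (length(nd$children) == 1L) nd <- nd$children[[1L]]
    i <- length(label) + 1L
    label[i] <<- if (nzchar(nd$label)) nd$label else NA_character_
    parent[i] <<- par
    children[[i]] <<- integer(0)
    for (ch in nd$children) {
      k <- rec(ch, i)
      children[[i]] <<- c(children[[i]], k)
    }
    i
  }
  rec(nested, NA_integer_)
  list(label = label, parent = parent, children = children)
}

#' Parse reconciled gene trees
#'
#' Reads one tree per non-empty line. Two dialects are accepted: Newick with
#' NHX annotations (`[&&NHX:S=<species>:Ev=<Spec|GDup|GLoss|Extant>]` on every
#' node), or plain Newick without annotations, in which case `map` must give
#' the species of every leaf and the tree is LCA-reconciled with
#' [lca_reconcile()].
#'
#' @param text character scalar (possibly multi-line) or vector of lines.
#' @param species a `species_tree`.
#' @param map optional named character vector, gene leaf label -> species
#'   label, for unannotated input.
#' @return A list of `recon_tree` objects.
#' @export
parse_reconciled_gene_trees <- function(text, species, map = NULL) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    nested <- parse_nhx_string(lines[i])
    name <- paste0("G", i)
    if (grepl("&&NHX", lines[i], fixed = TRUE)) {
      out[[i]] <- nhx_to_recon_tree(nested, species, name)
    } else {
      if (is.null(map))
        stop("tree on line ", i, " has no NHX annotations; ",
             "a leaf-to-species map is required", call. = FALSE)
      topo <- plain_to_gene_topology(nested, name)
      out[[i]] <- lca_reconcile(topo, species, map, name = name)
    }
  }
  out
}

#' Parse an extant adjacency list
#'
#' Each non-empty, non-comment (`#`) line holds two gene labels separated by
#' whitespace. Pairs are unordered and deduplicated; both genes must resolve
#' to extant leaves of the supplied trees and live in the same extant species.
#'
#' @param text character scalar or vector of lines.
#' @param trees list of `recon_tree` objects the labels refer to.
#' @return A tibble with columns `gene1`, `gene2` (lexicographically ordered
#'   within each pair) and `species`.
#' @export
parse_adjacencies <- function(text, trees) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  idx <- gene_leaf_index(trees)
  g1 <- character(length(lines)); g2 <- character(length(lines))
  sp <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "[ \t]+")[[1L]]
    if (length(f) != 2L)
      stop("adjacency line ", i, " ('", lines[i],
           "') must have exactly two gene labels", call. = FALSE)
    if (f[1L] == f[2L])
      stop("adjacency line ", i, " pairs gene '", f[1L], "' with itself",
           call. = FALSE)
    for (lab in f) {
      if (!lab %in% names(idx$species))
        stop("adjacency line ", i, ": unknown or non-extant gene '", lab, "'",
             call. = FALSE)
    }
    s1 <- idx$species[[f[1L]]]; s2 <- idx$species[[f[2L]]]
    if (s1 != s2)
      stop("adjacency line ", i, ": genes '", f[1L], "' and '", f[2L],
           "' belong to different species (", s1, " vs ", s2, ")",
           call. = FALSE)
    o <- order(f)
    g1[i] <- f[o][1L]; g2[i] <- f[o][2L]; sp[i] <- s1
  }
  out <- tibble::tibble(gene1 = g1, gene2 = g2, species = sp)
  out <- out[!duplicated(paste(out$gene1, out$gene2, sep = "\t")), ]
  out[order(out$gene1, out$gene2, method = "radix"), ]
}

# label -> (tree number, species label) lookup over extant leaves
gene_leaf_index <- function(trees) {
  labs <- character(0); tree_of <- integer(0); spl <- character(0)
  for (t in seq_along(trees)) {
    tr <- trees[[t]]
    leaves <- which(tr$event == "Extant")
    labs <- c(labs, tr$label[leaves])
    tree_of <- c(tree_of, rep(t, length(leaves)))
    spl <- c(spl, tr$species_tree$label[tr$species[leaves]])
  }
  if (anyDuplicated(labs))
    stop("duplicate extant gene label '", labs[duplicated(labs)][1L],
         "' across trees", call. = FALSE)
  list(tree = stats::setNames(tree_of, labs),
       species = stats::setNames(spl, labs))
}

#' Write a species tree as Newick
#' @param tree a `species_tree`.
#' @return A Newick string.
#' @export
write_species_tree <- function(tree) {
  rec <- function(i) {
    kids <- tree$children[[i]]
    if (length(kids) == 0L) return(tree$label[i])
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")",
           tree$label[i])
  }
  paste0(rec(tree$root), ";")
}

#' Write a reconciled gene tree as NHX-annotated Newick
#' @param tree a `recon_tree`.
#' @return A single Newick+NHX line parseable by
#'   [parse_reconciled_gene_trees()].
#' @export
write_gene_tree <- function(tree) {
  spl <- tree$species_tree$label
  rec <- function(i) {
    kids <- tree$children[[i]]
    tag <- paste0("[&&NHX:S=", spl[tree$species[i]], ":Ev=", tree$event[i],
                  "]")
    if (length(kids) == 0L) return(paste0(tree$label[i], tag))
    paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")",
           tree$label[i], tag)
  }
  paste0(rec(tree$root), ";")
}

## ---- Forest serialization ------------------------------------------------

forest_node_string <- function(node) {
  flag <- if (isTRUE(node$gain)) "|gain" else if (!node$present) "|absent" else ""
  lab <- paste0(node$lab1, "|", node$lab2, "|", node$event, flag)
  if (length(node$children) == 0L) return(lab)
  kids <- vapply(node$children, forest_node_string, "")
  paste0("(", paste(kids, collapse = ","), ")", lab)
}

#' Serialize an adjacency forest to text
#'
#' One Newick-like line per adjacency tree with node labels
#' `gene1|gene2|event` (plus `|gain` on gain-flagged roots and `|absent` on
#' break leaves recording a transmission break), preceded by a header line
#' with the forest's gain/break counts. `write_forest()` and
#' [parse_forest()] are mutually inverse on valid forests.
#'
#' @param forest an `adjacency_forest`.
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @return The character vector of lines, invisibly when `file` is given.
#' @export
write_forest <- function(forest, file = NULL) {
  stopifnot(inherits(forest, "adjacency_forest"))
  header <- paste0("# adjacency forest: trees=", length(forest$trees),
                   " gains=", forest$gains, " breaks=", forest$breaks)
  lines <- c(header,
             vapply(forest$trees,
                    function(tr) paste0(forest_node_string(tr), ";"), ""))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Parse an adjacency forest written by [write_forest()]
#'
#' @param lines character vector of lines (header line optional).
#' @return An `adjacency_forest`.
#' @export
parse_forest <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  to_node <- function(nd) {
    f <- strsplit(nd$label, "|", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("forest node label '", nd$label,
           "' is not of the form gene1|gene2|event", call. = FALSE)
    node <- list(lab1 = f[1L], lab2 = f[2L], event = f[3L],
                 present = !(length(f) > 3L && f[4L] == "absent"),
                 gain = length(f) > 3L && f[4L] == "gain",
                 children = lapply(nd$children, to_node))
    node
  }
  trees <- lapply(lines, function(ln) to_node(parse_nhx_string(ln)))
  new_adjacency_forest(trees)
}

## ---- Tabular writers -----------------------------------------------------

#' Write an adjacency probability matrix as TSV
#'
#' Columns `gene1`, `gene2`, `species`, `probability`; probabilities are
#' printed with 10 significant digits and rows are sorted lexicographically,
#' so output is byte-stable across runs.
#'
#' @param matrix a tibble as returned by [adjacency_probability_matrix()].
#' @param file optional output path.
#' @return The lines, invisibly when `file` is given.
#' @export
write_probability_matrix <- function(matrix, file = NULL) {
  p <- matrix$probability
  if (any(p < 0 | p > 1))
    stop("probabilities outside [0,1]; refusing to write", call. = FALSE)
  ord <- order(matrix$gene1, matrix$gene2, method = "radix")
  m <- matrix[ord, ]
  lines <- c("gene1\tgene2\tspecies\tprobability",
             sprintf("%s\t%s\t%s\t%.10g", m$gene1, m$gene2, m$species,
                     m$probability))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Parse a probability matrix TSV back into a tibble
#' @param lines character vector as produced by [write_probability_matrix()].
#' @return tibble with columns gene1, gene2, species, probability.
#' @export
parse_probability_matrix <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Write an ensemble summary table as TSV
#'
#' Lays the long summary out with one row per probability threshold and one
#' column group (ancestral genes / ancestral adjacencies / syntenic conflicts)
#' per pseudo-temperature.
#'
#' @param summary tibble from [summarize_ensemble()].
#' @param file optional output path.
#' @return The lines, invisibly when `file` is given.
#' @export
write_summary <- function(summary, file = NULL) {
  kts <- unique(summary$kT)
  ths <- sort(unique(summary$threshold))
  hdr <- c("threshold",
           paste0("genes_kT", kts), paste0("adjacencies_kT", kts),
           paste0("conflicts_kT", kts))
  rows <- vapply(ths, function(th) {
    sub <- summary[summary$threshold == th, ]
    sub <- sub[match(kts, sub$kT), ]
    paste(c(format(th), sub$ancestral_genes, sub$ancestral_adjacencies,
            sub$syntenic_conflicts), collapse = "\t")
  }, "")
  lines <- c(paste(hdr, collapse = "\t"), rows)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
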