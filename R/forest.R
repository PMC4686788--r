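#' Adjacency forests
#'
#' An adjacency forest describes one evolutionary scenario for a gene
#' adjacency: a forest of trees whose nodes are pairs (g1, g2) of gene-tree
#' nodes in the same species. Internal events are `Spec` (the adjacency
#' passes a speciation), `GDup` (one gene duplicates, the adjacency follows),
#' `ADup` (both genes duplicate simultaneously and the adjacency duplicates
#' with them); leaf events are `Extant`, `GLoss`/`ALoss` (history truncated
#' by gene loss of one/both genes) and `ABreak` (the adjacency is broken by a
#' rearrangement). Gains are flagged on the roots of gained trees; the forest
#' parsimony score charges AG per flagged gain and AB per break.
#'
#' Nodes carry a `present` flag: `ABreak` leaves with `present = FALSE`
#' record a break charged on the transmission into the pair (e.g. after a
#' speciation), while `present = TRUE` break leaves record an adjacency that
#' existed at the pair and was broken there, coincident with a gene
#' duplication. The canonical serialization keeps the two apart so that
#' distinct scenarios never collapse onto one string.
#'
#' @name adjacency_forest
NULL

forest_count_events <- function(trees) {
  gains <- 0L; breaks <- 0L
  walk <- function(nd) {
    if (isTRUE(nd$gain)) gains <<- gains + 1L
    if (nd$event == "ABreak") breaks <<- breaks + 1L
    for (ch in nd$children) walk(ch)
  }
  for (tr in trees) walk(tr)
  c(gains = gains, breaks = breaks)
}

new_adjacency_forest <- function(trees, instance_id = NA_character_) {
  sig <- vapply(trees, forest_node_string, "")
  trees <- trees[order(sig, method = "radix")]  # locale-independent
  ev <- forest_count_events(trees)
  structure(list(trees = trees, gains = ev[["gains"]],
                 breaks = ev[["breaks"]], instance_id = instance_id),
            class = "adjacency_forest")
}

#' @export
print.adjacency_forest <- function(x, ...) {
  cat("Adjacency forest:", length(x$trees), "tree(s),", x$gains, "gain(s),",
      x$breaks, "break(s)\n")
  for (ln in write_forest(x)[-1L]) cat(" ", ln, "\n")
  invisible(x)
}

#' Canonical serialization of a forest
#'
#' Injective over distinct forests: trees are sorted by their serialized
#' form, children keep construction order, and node strings include the
#' event, gain flag and presence flag.
#'
#' @param forest an `adjacency_forest`.
#' @return A single string.
#' @export
forest_signature <- function(forest) {
  paste(vapply(forest$trees, forest_node_string, ""), collapse = ";")
}

#' Parsimony score of an adjacency forest
#'
#' The score is `AG * (number of gain-flagged roots) + AB * (number of
#' ABreak leaves)`; with unit costs this is the number of adjacency gains
#' and breaks. An adjacency present at the instance root pair is not charged
#' a gain.
#'
#' @param forest an `adjacency_forest`.
#' @param costs a [cost_params()] object.
#' @return A nonnegative number.
#' @export
score_forest <- function(forest, costs = cost_params()) {
  if (!inherits(forest, "adjacency_forest"))
    stop("not an adjacency forest", call. = FALSE)
  costs$AG * forest$gains + costs$AB * forest$breaks
}

#' Boltzmann factor of an adjacency forest
#'
#' `exp(-s / kT)` with `s` the forest's parsimony score under `costs`.
#'
#' @inheritParams score_forest
#' @param params an [ensemble_params()] object (uses its `kT`).
#' @return A number in (0, 1].
#' @export
boltzmann_factor <- function(forest, costs = cost_params(),
                             params = ensemble_params()) {
  exp(-score_forest(forest, costs) / params$kT)
}

#' Adjacency gain/break penalties
#'
#' @param AG nonnegative adjacency-gain penalty (default 1).
#' @param AB nonnegative adjacency-break penalty (default 1).
#' @return A list of class `cost_params`.
#' @export
cost_params <- function(AG = 1, AB = 1) {
  stopifnot(is.numeric(AG), AG >= 0, is.numeric(AB), AB >= 0)
  structure(list(AG = AG, AB = AB), class = "cost_params")
}

#' Ensemble parameters
#'
#' `kT` is the dimensionless pseudo-temperature of the Boltzmann
#' distribution over adjacency forests: small values concentrate the
#' distribution on co-optimal forests, large values approach the uniform
#' distribution over the whole space. `alpha` is the homogeneous rescaling
#' factor guarding the partition-function recursion against floating-point
#' under/overflow; `alpha = 1` disables rescaling.
#'
#' @param kT positive pseudo-temperature (default 0.1).
#' @param alpha positive rescaling factor (default 1).
#' @return A list of class `ensemble_params`.
#' @export
ensemble_params <- function(kT = 0.1, alpha = 1) {
  stopifnot(is.numeric(kT), kT > 0, is.numeric(alpha), alpha > 0)
  structure(list(kT = kT, alpha = alpha), class = "ensemble_params")
}

#' Validate a forest against a DeCo instance
#'
#' Structural model checks, independent of any dynamic program: species
#' agreement within every node, event compatibility with the underlying gene
#' nodes (an `ADup` must pair two co-specific duplication nodes, a `Spec`
#' adjacency two speciation nodes, ...), extant forest leaves exactly
#' matching the observed extant adjacencies, and no pair used twice.
#'
#' @param forest an `adjacency_forest`.
#' @param instance a `deco_instance`.
#' @return Character vector of violations; empty when the forest is valid.
#' @export
validate_forest_against_instance <- function(forest, instance) {
  g1 <- instance$g1; g2 <- instance$g2
  sp <- g1$species_tree
  i1 <- stats::setNames(seq_along(g1$label), g1$label)
  i2 <- stats::setNames(seq_along(g2$label), g2$label)
  bad <- character(0)
  seen_pairs <- character(0)
  extant_seen <- character(0)
  walk <- function(nd, is_root) {
    key <- paste0(nd$lab1, "\t", nd$lab2)
    if (key %in% seen_pairs)
      bad <<- c(bad, paste0("pair (", nd$lab1, ",", nd$lab2,
                            ") appears more than once"))
    seen_pairs <<- c(seen_pairs, key)
    if (!nd$lab1 %in% names(i1) || !nd$lab2 %in% names(i2)) {
      bad <<- c(bad, paste0("node (", nd$lab1, ",", nd$lab2,
                            ") does not name nodes of G1 x G2"))
      return(invisible(NULL))
    }
    x <- i1[[nd$lab1]]; y <- i2[[nd$lab2]]
    e1 <- g1$event[x]; e2 <- g2$event[y]
    if (g1$species[x] != g2$species[y])
      bad <<- c(bad, paste0("node (", nd$lab1, ",", nd$lab2,
                            ") pairs genes from different species"))
    n_ch <- length(nd$children)
    if (n_ch == 0L) {
      if (!nd$event %in% c("Extant", "GLoss", "ALoss", "ABreak"))
        bad <<- c(bad, paste0("leaf (", nd$lab1, ",", nd$lab2,
                              ") has internal event ", nd$event))
      if (nd$event == "Extant") {
        if (e1 != "Extant" || e2 != "Extant")
          bad <<- c(bad, paste0("Extant adjacency leaf (", nd$lab1, ",",
                                nd$lab2, ") pairs non-extant genes"))
        extant_seen <<- c(extant_seen, key)
      }
      if (nd$event == "ALoss" && !(e1 == "GLoss" && e2 == "GLoss"))
        bad <<- c(bad, paste0("ALoss leaf (", nd$lab1, ",", nd$lab2,
                              ") requires both genes lost"))
      if (nd$event == "GLoss" && !(e1 == "GLoss" || e2 == "GLoss"))
        bad <<- c(bad, paste0("GLoss leaf (", nd$lab1, ",", nd$lab2,
                              ") requires a lost gene"))
    } else {
      if (!nd$event %in% c("Spec", "GDup", "ADup"))
        bad <<- c(bad, paste0("internal node (", nd$lab1, ",", nd$lab2,
                              ") has leaf event ", nd$event))
      if (nd$event == "ADup" &&
          !(e1 == "GDup" && e2 == "GDup"))
        bad <<- c(bad, paste0("ADup node (", nd$lab1, ",", nd$lab2,
                              ") requires both genes to be duplications"))
      if (nd$event == "Spec" && !(e1 == "Spec" && e2 == "Spec"))
        bad <<- c(bad, paste0("Spec adjacency node (", nd$lab1, ",", nd$lab2,
                              ") requires two speciation genes"))
      if (nd$event == "GDup" && !(e1 == "GDup" || e2 == "GDup"))
        bad <<- c(bad, paste0("GDup adjacency node (", nd$lab1, ",", nd$lab2,
                              ") requires a duplicated gene"))
    }
    for (ch in nd$children) walk(ch, FALSE)
    invisible(NULL)
  }
  for (tr in forest$trees) walk(tr, TRUE)
  adj_keys <- paste0(instance$adjacencies$gene1_g1, "\t",
                     instance$adjacencies$gene2_g2)
  missing <- setdiff(adj_keys, extant_seen)
  extra <- setdiff(extant_seen, adj_keys)
  for (k in missing)
    bad <- c(bad, paste0("observed extant adjacency (",
                         sub("\t", ",", k), ") missing from forest"))
  for (k in extra)
    bad <- c(bad, paste0("forest asserts unobserved extant adjacency (",
                         sub("\t", ",", k), ")"))
  bad
}
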