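## Forward simulation of synthetic DeCo instances: a random species tree,
## two gene trees evolved along it with per-branch duplication and loss, and
## an adjacency history evolved on top with gains, breaks and simultaneous
## duplications. Drives the whole test surface; no real data are required.

#' Simulation parameters
#'
#' Defaults describe a small vertebrate-like toy clade: a handful of genomes,
#' occasional gene duplication and loss, and rare adjacency gains/breaks —
#' rearrangements are rare evolutionary events, which is what makes parsimony
#' a sensible criterion for adjacencies in the first place.
#'
#' @param n_species number of extant genomes (>= 1).
#' @param p_dup per-branch gene duplication probability.
#' @param p_loss per-branch gene loss probability.
#' @param p_gain per-pair adjacency gain probability (on adjacency-free
#'   pairs).
#' @param p_break per-transmission adjacency break probability.
#' @param seed integer seed; the generator is fully reproducible.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_species = 4L, p_dup = 0.15, p_loss = 0.1,
                       p_gain = 0.03, p_break = 0.05, seed = 1L) {
  stopifnot(n_species >= 1L,
            p_dup >= 0, p_dup <= 1, p_loss >= 0, p_loss <= 1,
            p_gain >= 0, p_gain <= 1, p_break >= 0, p_break <= 1)
  structure(list(n_species = as.integer(n_species), p_dup = p_dup,
                 p_loss = p_loss, p_gain = p_gain, p_break = p_break,
                 seed = as.integer(seed)),
            class = "sim_params")
}

random_species_tree <- function(n_species) {
  if (n_species == 1L) return(parse_species_tree("S1;"))
  # random sequence of joins over the leaf set
  label <- paste0("S", seq_len(n_species))
  parent <- rep(NA_integer_, n_species)
  children <- rep(list(integer(0)), n_species)
  open <- seq_len(n_species)
  k <- n_species
  while (length(open) > 1L) {
    pickx <- sample(length(open), 2L)
    k <- k + 1L
    label[k] <- paste0("S", k)
    parent[k] <- NA_integer_
    children[[k]] <- open[pickx]
    parent[open[pickx]] <- k
    open <- c(open[-pickx], k)
  }
  new_species_tree(label, parent, children)
}

# evolve one gene tree along the species tree; returns NULL if the family
# dies out entirely
evolve_gene_tree <- function(species, p_dup, p_loss, name) {
  label <- character(0); spc <- integer(0); event <- character(0)
  parent <- integer(0); children <- list()
  n_ext <- 0L; n_loss <- 0L
  add <- function(lab, s, ev, par) {
    i <- length(label) + 1L
    label[i] <<- lab; spc[i] <<- s; event[i] <<- ev; parent[i] <<- par
    children[[i]] <<- integer(0)
    if (!is.na(par)) children[[par]] <<- c(children[[par]], i)
    i
  }
  # a lineage arriving on the branch above species s
  enter <- function(s, par, at_root = FALSE) {
    if (!at_root && stats::runif(1) < p_loss) {
      n_loss <<- n_loss + 1L
      return(add(paste0("LOSS_", species$label[s], "_", n_loss), s,
                 "GLoss", par))
    }
    live(s, par)
  }
  # a lineage alive within species s (post loss-check)
  live <- function(s, par) {
    if (stats::runif(1) < p_dup) {
      me <- add(NA_character_, s, "GDup", par)
      live(s, me)
      live(s, me)
      return(me)
    }
    kids <- species$children[[s]]
    if (length(kids) == 0L) {
      n_ext <<- n_ext + 1L
      return(add(paste0(species$label[s], "_", name, "_", n_ext), s,
                 "Extant", par))
    }
    me <- add(NA_character_, s, "Spec", par)
    enter(kids[1L], me)
    enter(kids[2L], me)
    me
  }
  enter(species$root, NA_integer_, at_root = TRUE)
  if (n_ext == 0L) return(NULL)
  new_recon_tree(label, spc, event, parent, children, species, name)
}

#' Simulate a synthetic DeCo instance with known history
#'
#' Generates a random binary species tree, evolves two reconciled gene trees
#' along it (per-branch duplication and loss), then evolves an adjacency
#' between the two root genes top-down: it persists through speciations and
#' one-sided duplications (following one copy), duplicates at simultaneous
#' duplications under a random matching, breaks with probability `p_break`
#' per transmission, and new adjacencies are gained on adjacency-free pairs
#' with probability `p_gain`. Everything is reproducible from the seed.
#'
#' @param params a [sim_params()] object.
#' @param max_retry how many times to redraw when a gene family dies out or
#'   no extant adjacency survives.
#' @return A list with `species` (the species tree), `instance` (a
#'   `deco_instance`), and `truth`: a tibble of the pairs that truly carried
#'   the adjacency (`gene1`, `gene2`, `species`, `ancestral` = both genes
#'   pre-speciation, `witnessed` = at least one surviving extant adjacency
#'   below the pair, hence recoverable in principle).
#' @export
simulate_instance <- function(params = sim_params(), max_retry = 50L) {
  local_rng(params$seed, {
    sim <- NULL
    for (try_i in seq_len(max_retry)) {
      sim <- simulate_once(params)
      if (!is.null(sim)) break
    }
    if (is.null(sim))
      stop("no extant adjacency survived after ", max_retry, " attempts; ",
           "lower the loss/break rates", call. = FALSE)
    sim
  })
}

simulate_once <- function(params) {
  species <- random_species_tree(params$n_species)
  g1 <- evolve_gene_tree(species, params$p_dup, params$p_loss, "g1")
  g2 <- evolve_gene_tree(species, params$p_dup, params$p_loss, "g2")
  if (is.null(g1) || is.null(g2)) return(NULL)

  present_pairs <- list()   # list of c(x, y)
  extant <- list()
  # states propagate over the same pair structure the model defines
  state <- function(x, y, present) {
    e1 <- g1$event[x]; e2 <- g2$event[y]
    if (present) present_pairs[[length(present_pairs) + 1L]] <<- c(x, y)
    if (e1 == "GLoss" || e2 == "GLoss") {
      return(invisible(NULL))
    }
    if (e1 == "Extant" && e2 == "Extant") {
      if (present) extant[[length(extant) + 1L]] <<- c(x, y)
      return(invisible(NULL))
    }
    transmit <- function(xx, yy) {
      state(xx, yy, present && stats::runif(1) >= params$p_break)
    }
    maybe_gain <- function(xx, yy) {
      state(xx, yy, stats::runif(1) < params$p_gain)
    }
    if (e1 == "Spec" && e2 == "Spec") {
      k1 <- g1$children[[x]]; k2 <- g2$children[[y]]
      for (i in 1:2) {
        j <- which(g2$species[k2] == g1$species[k1[i]])
        if (present) transmit(k1[i], k2[j]) else maybe_gain(k1[i], k2[j])
      }
    } else if (e1 == "GDup" && e2 != "GDup") {
      k <- g1$children[[x]]
      keep <- sample(2L, 1L)
      if (present) transmit(k[keep], y) else maybe_gain(k[keep], y)
      maybe_gain(k[3L - keep], y)
    } else if (e1 != "GDup" && e2 == "GDup") {
      k <- g2$children[[y]]
      keep <- sample(2L, 1L)
      if (present) transmit(x, k[keep]) else maybe_gain(x, k[keep])
      maybe_gain(x, k[3L - keep])
    } else {
      k1 <- g1$children[[x]]; k2 <- g2$children[[y]]
      match1 <- sample(2L, 1L)  # a1 pairs with this child of y
      for (i in 1:2) {
        j <- if (i == 1L) match1 else 3L - match1
        if (present) transmit(k1[i], k2[j]) else maybe_gain(k1[i], k2[j])
        if (present) maybe_gain(k1[i], k2[3L - j])
      }
    }
    invisible(NULL)
  }
  state(g1$root, g2$root, TRUE)
  if (length(extant) == 0L) return(NULL)

  adj <- tibble::tibble(
    gene1 = vapply(extant, function(p) g1$label[p[1L]], ""),
    gene2 = vapply(extant, function(p) g2$label[p[2L]], ""))
  inst <- deco_instance(g1, g2, adj, oriented = TRUE)

  leaves1 <- gt_subtree_leafsets(g1)
  leaves2 <- gt_subtree_leafsets(g2)
  ext1 <- vapply(extant, `[[`, 0L, 1L)
  ext2 <- vapply(extant, `[[`, 0L, 2L)
  pp <- unique(do.call(rbind, present_pairs))
  witnessed <- vapply(seq_len(nrow(pp)), function(i) {
    any(ext1 %in% leaves1[[pp[i, 1L]]] & ext2 %in% leaves2[[pp[i, 2L]]])
  }, TRUE)
  truth <- tibble::tibble(
    gene1 = g1$label[pp[, 1L]],
    gene2 = g2$label[pp[, 2L]],
    species = species$label[g1$species[pp[, 1L]]],
    ancestral = g1$event[pp[, 1L]] == "Spec" & g2$event[pp[, 2L]] == "Spec",
    witnessed = witnessed)
  list(species = species, instance = inst, truth = truth)
}
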