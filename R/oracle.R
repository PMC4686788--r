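## Exhaustive enumeration of the adjacency-forest space on small instances.
## This is the brute-force oracle the dynamic program is tested against: the
## same generating scheme interpreted under (union, Cartesian product)
## semantics, implemented as direct recursion over the gene trees — no DP
## tables, no transition records.

enum_overflow <- function(n, max_count) {
  structure(
    class = c("adjensemble_enum_overflow", "error", "condition"),
    list(message = paste0("forest space exceeds max_count = ", max_count),
         call = NULL, n = n))
}

#' Enumerate every adjacency forest of an instance
#'
#' Materializes the full solution space F(G1, G2) — every forest the
#' generating scheme can produce, with its parsimony score. Intended for
#' small instances only; the space grows exponentially.
#'
#' @param instance a `deco_instance`.
#' @param costs [cost_params()].
#' @param max_count hard cap on the number of forests (error beyond it).
#' @return A list of class `forest_space` with fields `forests` (list of
#'   `adjacency_forest`) and `scores` (numeric vector).
#' @export
enumerate_forests <- function(instance, costs = cost_params(),
                              max_count = 1e6) {
  g1 <- instance$g1; g2 <- instance$g2
  spl <- g1$species_tree$label
  AG <- costs$AG; AB <- costs$AB
  obs <- matrix(FALSE, length(g1$label), length(g2$label))
  obs[cbind(instance$adjacencies$node1, instance$adjacencies$node2)] <- TRUE
  memo <- new.env(parent = emptyenv())

  node_at <- function(x, y, event, present) {
    list(lab1 = g1$label[x], lab2 = g2$label[y],
         species = spl[g1$species[x]], event = event, present = present,
         gain = FALSE, children = list())
  }
  guard <- function(res) {
    if (length(res) > max_count) stop(enum_overflow(length(res), max_count))
    res
  }
  # cartesian combination of per-call result lists
  cross <- function(lists) {
    out <- list(list())
    for (l in lists) {
      nxt <- vector("list", length(out) * length(l))
      k <- 0L
      for (o in out) for (e in l) {
        k <- k + 1L
        nxt[[k]] <- c(o, list(e))
      }
      out <- guard(nxt)
    }
    out
  }
  as_gain <- function(r1) {  # turn a presence result into a gained tree root
    nd <- r1$node; nd$gain <- TRUE
    list(extras = c(list(nd), r1$extras), cost = r1$cost)
  }

  enum1 <- function(x, y) {
    key <- paste0("p", x, "_", y)
    if (!is.null(memo[[key]])) return(memo[[key]])
    e1 <- g1$event[x]; e2 <- g2$event[y]
    res <- list()
    add <- function(node, parts, extra_cost) {
      # parts: list of (children-or-extras results); node children already set
      res[[length(res) + 1L]] <<- list(node = node,
                                       extras = parts$extras,
                                       cost = parts$cost + extra_cost)
    }
    if (e1 == "GLoss" || e2 == "GLoss") {
      ev <- if (e1 == "GLoss" && e2 == "GLoss") "ALoss" else "GLoss"
      res <- list(list(node = node_at(x, y, ev, TRUE), extras = list(),
                       cost = 0))
    } else if (e1 == "Extant" && e2 == "Extant") {
      if (obs[x, y])
        res <- list(list(node = node_at(x, y, "Extant", TRUE),
                         extras = list(), cost = 0))
    } else if (e1 == "Spec" && e2 == "Spec") {
      m <- spec_matched_children(x, y)
      res <- spec_like(x, y, "Spec", m[[1L]], m[[2L]])
    } else if (e1 == "GDup" && e2 != "GDup") {
      k <- g1$children[[x]]
      res <- one_sided(x, y, k[1L], y, k[2L], y, left_child = TRUE)
    } else if (e1 != "GDup" && e2 == "GDup") {
      k <- g2$children[[y]]
      res <- one_sided(x, y, x, k[1L], x, k[2L], left_child = FALSE)
    } else {
      k1 <- g1$children[[x]]; k2 <- g2$children[[y]]
      res <- c(
        adup(x, y, c(k1[1L], k2[1L]), c(k1[2L], k2[2L]),
             c(k1[1L], k2[2L]), c(k1[2L], k2[1L])),
        adup(x, y, c(k1[1L], k2[2L]), c(k1[2L], k2[1L]),
             c(k1[1L], k2[1L]), c(k1[2L], k2[2L])),
        cascade(x, y, k1[1L], y, k1[2L], y),
        cascade(x, y, x, k2[1L], x, k2[2L]),
        break_here(x, y, k1[1L], y, k1[2L], y))
    }
    res <- guard(res)
    memo[[key]] <- res
    res
  }

  enum0 <- function(x, y) {
    key <- paste0("a", x, "_", y)
    if (!is.null(memo[[key]])) return(memo[[key]])
    e1 <- g1$event[x]; e2 <- g2$event[y]
    res <-
      if (e1 == "GLoss" || e2 == "GLoss") {
        list(list(extras = list(), cost = 0))
      } else if (e1 == "Extant" && e2 == "Extant") {
        if (obs[x, y]) list() else list(list(extras = list(), cost = 0))
      } else if (e1 == "Spec" && e2 == "Spec") {
        m <- spec_matched_children(x, y)
        absent_pair(m[[1L]][1L], m[[1L]][2L], m[[2L]][1L], m[[2L]][2L])
      } else if (e1 == "GDup" && e2 != "GDup") {
        k <- g1$children[[x]]
        absent_pair(k[1L], y, k[2L], y)
      } else if (e1 != "GDup" && e2 == "GDup") {
        k <- g2$children[[y]]
        absent_pair(x, k[1L], x, k[2L])
      } else {
        k1 <- g1$children[[x]]
        absent_pair(k1[1L], y, k1[2L], y)
      }
    res <- guard(res)
    memo[[key]] <- res
    res
  }

  spec_matched_children <- function(x, y) {
    k1 <- g1$children[[x]]; k2 <- g2$children[[y]]
    lapply(1:2, function(i) {
      j <- which(g2$species[k2] == g1$species[k1[i]])
      c(k1[i], k2[j])
    })
  }

  # Spec / matched-side construction: each side persists or breaks
  spec_like <- function(x, y, event, pa, pb) {
    out <- list()
    for (ka in c(1L, 0L)) for (kb in c(1L, 0L)) {
      la <- if (ka == 1L) enum1(pa[1L], pa[2L]) else enum0(pa[1L], pa[2L])
      lb <- if (kb == 1L) enum1(pb[1L], pb[2L]) else enum0(pb[1L], pb[2L])
      for (tuple in cross(list(la, lb))) {
        ra <- tuple[[1L]]; rb <- tuple[[2L]]
        nd <- node_at(x, y, event, TRUE)
        nd$children <- c(
          if (ka == 1L) list(ra$node) else
            list(node_at(pa[1L], pa[2L], "ABreak", FALSE)),
          if (kb == 1L) list(rb$node) else
            list(node_at(pb[1L], pb[2L], "ABreak", FALSE)))
        out[[length(out) + 1L]] <- list(
          node = nd, extras = c(ra$extras, rb$extras),
          cost = ra$cost + rb$cost + AB * ((ka == 0L) + (kb == 0L)))
      }
      out <- guard(out)
    }
    out
  }

  # one-sided duplication presence block over child pairs (xa,ya), (xb,yb)
  one_sided <- function(x, y, xa, ya, xb, yb, left_child) {
    c(cascade(x, y, xa, ya, xb, yb),
      break_here(x, y, xa, ya, xb, yb))
  }
  cascade <- function(x, y, xa, ya, xb, yb) {
    out <- list()
    combos <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L))
    for (cmb in combos) {
      la <- if (cmb[1L] == 1L) enum1(xa, ya) else enum0(xa, ya)
      lb <- if (cmb[2L] == 1L) enum1(xb, yb) else enum0(xb, yb)
      for (tuple in cross(list(la, lb))) {
        ra <- tuple[[1L]]; rb <- tuple[[2L]]
        nd <- node_at(x, y, "GDup", TRUE)
        extras <- list(); cost <- ra$cost + rb$cost
        if (all(cmb == c(1L, 0L))) {
          nd$children <- list(ra$node)
          extras <- c(ra$extras, rb$extras)
        } else if (all(cmb == c(0L, 1L))) {
          nd$children <- list(rb$node)
          extras <- c(ra$extras, rb$extras)
        } else {  # both copies adjacent: second one is a gained root
          nd$children <- list(ra$node)
          gb <- as_gain(rb)
          extras <- c(ra$extras, gb$extras)
          cost <- ra$cost + gb$cost + AG
        }
        out[[length(out) + 1L]] <- list(node = nd, extras = extras,
                                        cost = cost)
      }
      out <- guard(out)
    }
    out
  }
  break_here <- function(x, y, xa, ya, xb, yb) {
    out <- list()
    for (tuple in cross(list(enum0(xa, ya), enum0(xb, yb)))) {
      ra <- tuple[[1L]]; rb <- tuple[[2L]]
      out[[length(out) + 1L]] <- list(
        node = node_at(x, y, "ABreak", TRUE),
        extras = c(ra$extras, rb$extras),
        cost = ra$cost + rb$cost + AB)
    }
    guard(out)
  }
  # simultaneous duplication under one matching; the cross pairs stay absent
  adup <- function(x, y, ma, mb, cr1, cr2) {
    out <- list()
    for (ka in c(1L, 0L)) for (kb in c(1L, 0L)) {
      la <- if (ka == 1L) enum1(ma[1L], ma[2L]) else enum0(ma[1L], ma[2L])
      lb <- if (kb == 1L) enum1(mb[1L], mb[2L]) else enum0(mb[1L], mb[2L])
      lc1 <- enum0(cr1[1L], cr1[2L]); lc2 <- enum0(cr2[1L], cr2[2L])
      for (tuple in cross(list(la, lb, lc1, lc2))) {
        ra <- tuple[[1L]]; rb <- tuple[[2L]]
        rc1 <- tuple[[3L]]; rc2 <- tuple[[4L]]
        nd <- node_at(x, y, "ADup", TRUE)
        nd$children <- c(
          if (ka == 1L) list(ra$node) else
            list(node_at(ma[1L], ma[2L], "ABreak", FALSE)),
          if (kb == 1L) list(rb$node) else
            list(node_at(mb[1L], mb[2L], "ABreak", FALSE)))
        out[[length(out) + 1L]] <- list(
          node = nd,
          extras = c(ra$extras, rb$extras, rc1$extras, rc2$extras),
          cost = ra$cost + rb$cost + rc1$cost + rc2$cost +
            AB * ((ka == 0L) + (kb == 0L)))
      }
      out <- guard(out)
    }
    out
  }
  # absence: per child pair, stay absent or gain a new adjacency tree
  absent_pair <- function(xa, ya, xb, yb) {
    out <- list()
    combos <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    for (cmb in combos) {
      la <- if (cmb[1L] == 1L) lapply(enum1(xa, ya), as_gain) else
        enum0(xa, ya)
      lb <- if (cmb[2L] == 1L) lapply(enum1(xb, yb), as_gain) else
        enum0(xb, yb)
      for (tuple in cross(list(la, lb))) {
        ra <- tuple[[1L]]; rb <- tuple[[2L]]
        out[[length(out) + 1L]] <- list(
          extras = c(ra$extras, rb$extras),
          cost = ra$cost + rb$cost + AG * sum(cmb))
      }
      out <- guard(out)
    }
    out
  }

  rx <- g1$root; ry <- g2$root
  forests <- list(); scores <- numeric(0)
  for (r in enum1(rx, ry)) {
    forests[[length(forests) + 1L]] <-
      new_adjacency_forest(c(list(r$node), r$extras), instance_id = instance$id)
    scores[length(forests)] <- r$cost
  }
  for (r in enum0(rx, ry)) {
    forests[[length(forests) + 1L]] <-
      new_adjacency_forest(r$extras, instance_id = instance$id)
    scores[length(forests)] <- r$cost
  }
  guard(forests)
  structure(list(forests = forests, scores = scores,
                 instance_id = instance$id),
            class = "forest_space")
}

#' @export
print.forest_space <- function(x, ...) {
  cat("Forest space:", length(x$forests), "forests, scores in [",
      min(x$scores), ",", max(x$scores), "]\n")
  invisible(x)
}

# keys "lab1\tlab2" of the pairs at which the forest holds an adjacency
forest_present_pairs <- function(forest) {
  keys <- character(0)
  walk <- function(nd) {
    if (nd$present) keys[[length(keys) + 1L]] <<- paste0(nd$lab1, "\t",
                                                         nd$lab2)
    for (ch in nd$children) walk(ch)
  }
  for (tr in forest$trees) walk(tr)
  unlist(keys)
}

#' Exact ensemble quantities from an enumerated forest space
#'
#' Sums Boltzmann factors over the whole space: the partition function and,
#' for every pair ever holding an adjacency, the Boltzmann-weighted fraction
#' of forests containing it.
#'
#' @param space a `forest_space` from [enumerate_forests()].
#' @param kT pseudo-temperature (may be `Inf` for uniform counting).
#' @return A list with `Z` and `probabilities`, a tibble (`gene1`, `gene2`,
#'   `probability`).
#' @export
oracle_probabilities <- function(space, kT = 0.1) {
  stopifnot(length(space$forests) >= 1L)
  s0 <- min(space$scores)  # shift by the optimum: the distribution is
  w <- exp(-(space$scores - s0) / kT)  # invariant, the arithmetic is not
  Z <- sum(w) * exp(-s0 / kT)
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(space$forests)) {
    for (k in forest_present_pairs(space$forests[[i]])) {
      acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + w[i]
    }
  }
  keys <- sort(ls(acc), method = "radix")
  W <- sum(w)
  probs <- vapply(keys, function(k) acc[[k]] / W, 0)
  parts <- strsplit(keys, "\t", fixed = TRUE)
  list(Z = Z,
       probabilities = tibble::tibble(
         gene1 = vapply(parts, `[[`, "", 1L),
         gene2 = vapply(parts, `[[`, "", 2L),
         probability = unname(probs)))
}
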