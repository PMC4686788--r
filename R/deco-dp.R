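## The DeCo dynamic program over pairs of reconciled gene trees, in a
## pluggable algebra: (min,+) for parsimony, (sum,*) for the Boltzmann
## partition function (with homogeneous alpha-rescaling), and counting
## (sum,* at kT = Inf) for the unambiguity certificate.
##
## For every pair (g1,g2) with s(g1) = s(g2) two quantities c1 and c0 are
## computed: the best score (resp. total Boltzmann weight) of adjacency
## forests for the subtree pair under presence (c1) or absence (c0) of an
## adjacency between g1 and g2. Every alternative of every recurrence case
## is materialized as a transition record (constant cost + recursive calls),
## which drives deterministic backtracking, stochastic backtracking and the
## generic inside-outside inversion alike.

lhs1 <- function(pid) 2L * pid
lhs0 <- function(pid) 2L * pid - 1L
lhs_pid <- function(lhs) (lhs + 1L) %/% 2L
lhs_state <- function(lhs) lhs %% 2L == 0L

## ---- valid pairs, double post-order, rescaling exponents -----------------

deco_pairs <- function(instance) {
  g1 <- instance$g1; g2 <- instance$g2
  post1 <- gt_postorder(g1); post2 <- gt_postorder(g2)
  n1 <- length(g1$label); n2 <- length(g2$label)
  pid_map <- matrix(0L, n1, n2)
  px <- integer(0); py <- integer(0)
  for (x in post1) {
    sx <- g1$species[x]
    for (y in post2) {
      if (g2$species[y] == sx) {
        px <- c(px, x); py <- c(py, y)
      }
    }
  }
  P <- length(px)
  pid_map[cbind(px, py)] <- seq_len(P)
  e1 <- g1$event[px]; e2 <- g2$event[py]
  cnt1 <- gt_subtree_leaves(g1); cnt2 <- gt_subtree_leaves(g2)

  # kappa: per-solution number of alpha occurrences below (and at) each pair;
  # provably execution-independent for the homogeneous scheme (asserted).
  kappa <- integer(P)
  ks <- integer(P)  # exponent applied to the pair's own table value
  for (p in seq_len(P)) {
    x <- px[p]; y <- py[p]
    if (e1[p] == "GLoss" || e2[p] == "GLoss") {
      kappa[p] <- if (e1[p] == "GLoss") cnt2[y] else cnt1[x]
      ks[p] <- kappa[p]
    } else if (e1[p] == "Extant" && e2[p] == "Extant") {
      kappa[p] <- 1L; ks[p] <- 1L
    } else if (e1[p] == "Spec" && e2[p] == "Spec") {
      m <- spec_matched_pids(g1, g2, x, y, pid_map)
      kappa[p] <- 1L + kappa[m[1L]] + kappa[m[2L]]
      ks[p] <- 1L
    } else if (e1[p] == "GDup" && e2[p] != "GDup") {
      k <- g1$children[[x]]
      kappa[p] <- kappa[pid_map[k[1L], y]] + kappa[pid_map[k[2L], y]]
    } else if (e1[p] != "GDup" && e2[p] == "GDup") {
      k <- g2$children[[y]]
      kappa[p] <- kappa[pid_map[x, k[1L]]] + kappa[pid_map[x, k[2L]]]
    } else {
      k1 <- g1$children[[x]]; k2 <- g2$children[[y]]
      via1 <- kappa[pid_map[k1[1L], y]] + kappa[pid_map[k1[2L], y]]
      via2 <- kappa[pid_map[x, k2[1L]]] + kappa[pid_map[x, k2[2L]]]
      via_adup <- kappa[pid_map[k1[1L], k2[1L]]] +
        kappa[pid_map[k1[2L], k2[2L]]] +
        kappa[pid_map[k1[1L], k2[2L]]] + kappa[pid_map[k1[2L], k2[1L]]]
      if (via1 != via2 || via1 != via_adup)
        stop("internal error: rescaling exponent not homogeneous at pair (",
             g1$label[x], ",", g2$label[y], ")", call. = FALSE)
      kappa[p] <- via1
    }
  }
  root_pid <- pid_map[g1$root, g2$root]
  if (root_pid == 0L)
    stop("internal error: root pair has mismatched species", call. = FALSE)
  list(px = px, py = py, e1 = e1, e2 = e2, pid_map = pid_map, P = P,
       kappa = kappa, ks = ks, root_pid = root_pid)
}

# the two species-matched child pairs of a Spec x Spec pair, G1-child order
spec_matched_pids <- function(g1, g2, x, y, pid_map) {
  k1 <- g1$children[[x]]; k2 <- g2$children[[y]]
  m <- integer(2L)
  for (i in 1:2) {
    j <- which(g2$species[k2] == g1$species[k1[i]])
    m[i] <- pid_map[k1[i], k2[j]]
  }
  if (any(m == 0L))
    stop("internal error: unmatched speciation children", call. = FALSE)
  m
}

## ---- transition records --------------------------------------------------

alt_rec <- function(cost, calls, node = "none", attach = integer(0),
                    breaks = integer(0), gains = integer(0)) {
  list(cost = cost, calls = as.integer(calls), node = node,
       attach = as.integer(attach), breaks = as.integer(breaks),
       gains = as.integer(gains))
}

build_transitions <- function(instance, pairs, costs) {
  g1 <- instance$g1; g2 <- instance$g2
  AG <- costs$AG; AB <- costs$AB
  pm <- pairs$pid_map
  obs <- matrix(FALSE, length(g1$label), length(g2$label))
  obs[cbind(instance$adjacencies$node1, instance$adjacencies$node2)] <- TRUE
  alts0 <- vector("list", pairs$P)
  alts1 <- vector("list", pairs$P)

  # the standard one-sided block over two child pairs (pa, pb):
  # presence follows one copy, both (one gain), or is broken at the pair
  one_sided_c1 <- function(pa, pb) list(
    alt_rec(0, c(lhs1(pa), lhs0(pb)), node = "GDup", attach = 1L),
    alt_rec(0, c(lhs0(pa), lhs1(pb)), node = "GDup", attach = 2L),
    alt_rec(AG, c(lhs1(pa), lhs1(pb)), node = "GDup", attach = 1L,
            gains = 2L),
    alt_rec(AB, c(lhs0(pa), lhs0(pb)), node = "ABreak"))
  absent_c0 <- function(pa, pb) list(
    alt_rec(0, c(lhs0(pa), lhs0(pb))),
    alt_rec(AG, c(lhs1(pa), lhs0(pb)), gains = 1L),
    alt_rec(AG, c(lhs0(pa), lhs1(pb)), gains = 2L),
    alt_rec(2 * AG, c(lhs1(pa), lhs1(pb)), gains = c(1L, 2L)))

  for (p in seq_len(pairs$P)) {
    x <- pairs$px[p]; y <- pairs$py[p]
    e1 <- pairs$e1[p]; e2 <- pairs$e2[p]
    if (e1 == "GLoss" || e2 == "GLoss") {
      ev <- if (e1 == "GLoss" && e2 == "GLoss") "ALoss" else "GLoss"
      alts1[[p]] <- list(alt_rec(0, integer(0), node = ev))
      alts0[[p]] <- list(alt_rec(0, integer(0)))
    } else if (e1 == "Extant" && e2 == "Extant") {
      if (obs[x, y]) {
        alts1[[p]] <- list(alt_rec(0, integer(0), node = "Extant"))
        alts0[[p]] <- list()
      } else {
        alts1[[p]] <- list()
        alts0[[p]] <- list(alt_rec(0, integer(0)))
      }
    } else if (e1 == "Spec" && e2 == "Spec") {
      m <- spec_matched_pids(g1, g2, x, y, pm)
      pa <- m[1L]; pb <- m[2L]
      alts1[[p]] <- list(
        alt_rec(0, c(lhs1(pa), lhs1(pb)), node = "Spec", attach = c(1L, 2L)),
        alt_rec(AB, c(lhs1(pa), lhs0(pb)), node = "Spec", attach = 1L,
                breaks = 2L),
        alt_rec(AB, c(lhs0(pa), lhs1(pb)), node = "Spec", attach = 2L,
                breaks = 1L),
        alt_rec(2 * AB, c(lhs0(pa), lhs0(pb)), node = "Spec",
                breaks = c(1L, 2L)))
      alts0[[p]] <- absent_c0(pa, pb)
    } else if (e1 == "GDup" && e2 != "GDup") {
      k <- g1$children[[x]]
      pa <- pm[k[1L], y]; pb <- pm[k[2L], y]
      alts1[[p]] <- one_sided_c1(pa, pb)
      alts0[[p]] <- absent_c0(pa, pb)
    } else if (e1 != "GDup" && e2 == "GDup") {
      k <- g2$children[[y]]
      pa <- pm[x, k[1L]]; pb <- pm[x, k[2L]]
      alts1[[p]] <- one_sided_c1(pa, pb)
      alts0[[p]] <- absent_c0(pa, pb)
    } else {
      # both genes duplicate: simultaneous adjacency duplication under either
      # matching (with c0 calls on the cross pairs, required for homogeneous
      # rescaling), or one gene duplicates first; the broken-at-the-pair
      # alternative is emitted once to keep the scheme unambiguous, and c0
      # descends the G1 side only for the same reason.
      k1 <- g1$children[[x]]; k2 <- g2$children[[y]]
      paa <- pm[k1[1L], k2[1L]]; pab <- pm[k1[1L], k2[2L]]
      pba <- pm[k1[2L], k2[1L]]; pbb <- pm[k1[2L], k2[2L]]
      pA1 <- pm[k1[1L], y]; pB1 <- pm[k1[2L], y]
      pA2 <- pm[x, k2[1L]]; pB2 <- pm[x, k2[2L]]
      adup <- function(pa, pb, cr1, cr2) list(
        alt_rec(0, c(lhs1(pa), lhs1(pb), lhs0(cr1), lhs0(cr2)),
                node = "ADup", attach = c(1L, 2L)),
        alt_rec(AB, c(lhs1(pa), lhs0(pb), lhs0(cr1), lhs0(cr2)),
                node = "ADup", attach = 1L, breaks = 2L),
        alt_rec(AB, c(lhs0(pa), lhs1(pb), lhs0(cr1), lhs0(cr2)),
                node = "ADup", attach = 2L, breaks = 1L),
        alt_rec(2 * AB, c(lhs0(pa), lhs0(pb), lhs0(cr1), lhs0(cr2)),
                node = "ADup", breaks = c(1L, 2L)))
      cascade <- function(pa, pb) list(
        alt_rec(0, c(lhs1(pa), lhs0(pb)), node = "GDup", attach = 1L),
        alt_rec(0, c(lhs0(pa), lhs1(pb)), node = "GDup", attach = 2L),
        alt_rec(AG, c(lhs1(pa), lhs1(pb)), node = "GDup", attach = 1L,
                gains = 2L))
      alts1[[p]] <- c(
        adup(paa, pbb, pab, pba),
        adup(pab, pba, paa, pbb),
        cascade(pA1, pB1),
        cascade(pA2, pB2),
        list(alt_rec(AB, c(lhs0(pA1), lhs0(pB1)), node = "ABreak")))
      alts0[[p]] <- absent_c0(pA1, pB1)
    }
  }
  list(alts0 = alts0, alts1 = alts1)
}

## ---- table evaluation ----------------------------------------------------

eval_minplus <- function(pairs, trans) {
  v <- rep(Inf, 2L * pairs$P)
  for (p in seq_len(pairs$P)) {
    for (st in 0:1) {
      alts <- if (st == 0L) trans$alts0[[p]] else trans$alts1[[p]]
      lhs <- if (st == 0L) lhs0(p) else lhs1(p)
      best <- Inf
      for (a in alts) {
        val <- a$cost + sum(v[a$calls])
        if (!is.nan(val) && val < best) best <- val
      }
      v[lhs] <- best
    }
  }
  v
}

rescale_failure <- function(pairs, instance, p, lhs, kind, s_min) {
  structure(
    class = c("adjensemble_rescale", "error", "condition"),
    list(message = paste0("partition-function ", kind, " at pair (",
                          instance$g1$label[pairs$px[p]], ",",
                          instance$g2$label[pairs$py[p]],
                          "); rescaling (alpha) needed"),
         call = NULL, pid = p, lhs = lhs, kind = kind, s_min = s_min))
}

eval_sumtimes <- function(pairs, trans, instance, kT, alpha, v_min) {
  P <- pairs$P
  v <- numeric(2L * P)
  aw <- vector("list", 2L * P)
  la <- log(alpha)
  for (p in seq_len(P)) {
    selff <- exp(pairs$ks[p] * la)
    for (st in 0:1) {
      alts <- if (st == 0L) trans$alts0[[p]] else trans$alts1[[p]]
      lhs <- if (st == 0L) lhs0(p) else lhs1(p)
      if (length(alts) == 0L) { v[lhs] <- 0; aw[[lhs]] <- numeric(0); next }
      w <- vapply(alts, function(a) {
        selff * exp(-a$cost / kT) * prod(v[a$calls])
      }, 0)
      tot <- sum(w)
      if (!is.finite(tot))
        stop(rescale_failure(pairs, instance, p, lhs, "overflow",
                             v_min[lhs]))
      if (tot == 0 && is.finite(v_min[lhs]))
        stop(rescale_failure(pairs, instance, p, lhs, "underflow",
                             v_min[lhs]))
      v[lhs] <- tot
      aw[[lhs]] <- w
    }
  }
  list(v = v, aw = aw)
}

#' Compute DeCo dynamic-programming tables
#'
#' Fills the quantities c0/c1 for every species-matched pair of gene-tree
#' nodes in double post-order, and records every recurrence alternative as a
#' transition (constant cost + recursive calls). Under `"min-plus"` the
#' tables hold parsimony scores; under `"sum-times"` they hold (rescaled)
#' partition-function values at pseudo-temperature `params$kT`, with a factor
#' `alpha` applied once per call whose pair has both events != GDup (the
#' homogeneous rescaling of the scheme).
#'
#' @param instance a `deco_instance`.
#' @param costs [cost_params()].
#' @param algebra `"min-plus"` or `"sum-times"`.
#' @param params [ensemble_params()] (used by `"sum-times"` only).
#' @return An object of class `deco_tables`.
#' @export
compute_tables <- function(instance, costs = cost_params(),
                           algebra = c("min-plus", "sum-times"),
                           params = ensemble_params()) {
  algebra <- match.arg(algebra)
  pairs <- deco_pairs(instance)
  trans <- build_transitions(instance, pairs, costs)
  v_min <- eval_minplus(pairs, trans)
  out <- list(instance = instance, pairs = pairs, trans = trans,
              costs = costs, params = params, algebra = algebra,
              v_min = v_min, root_pid = pairs$root_pid)
  if (algebra == "sum-times") {
    st <- eval_sumtimes(pairs, trans, instance, params$kT, params$alpha,
                        v_min)
    out$v <- st$v
    out$aw <- st$aw
  } else {
    out$v <- v_min
  }
  structure(out, class = "deco_tables")
}

#' @export
print.deco_tables <- function(x, ...) {
  r <- x$root_pid
  cat("DeCo tables (", x$algebra, "): ", x$pairs$P, " pairs; root c1 = ",
      format(x$v[lhs1(r)]), ", c0 = ", format(x$v[lhs0(r)]), "\n", sep = "")
  invisible(x)
}

#' Parsimony score of an instance
#'
#' `min(c1(r1, r2), c0(r1, r2))` at the two roots of min-plus tables.
#'
#' @param tables `deco_tables` computed with the `"min-plus"` algebra.
#' @return The minimum number (weighted sum) of adjacency gains and breaks.
#' @export
parsimony_score <- function(tables) {
  if (!inherits(tables, "deco_tables") || tables$algebra != "min-plus")
    stop("parsimony_score() needs min-plus tables", call. = FALSE)
  r <- tables$root_pid
  min(tables$v[lhs1(r)], tables$v[lhs0(r)])
}

## ---- backtracking --------------------------------------------------------

# Shared forest construction: `pick(lhs)` returns the index of the chosen
# alternative; gains open new trees, breaks become ABreak leaves.
build_forest_from_picks <- function(tables, root_state, pick) {
  inst <- tables$instance
  g1 <- inst$g1; g2 <- inst$g2
  spl <- g1$species_tree$label
  pairs <- tables$pairs
  roots <- list()
  mk_node <- function(pid, event, present) {
    x <- pairs$px[pid]; y <- pairs$py[pid]
    list(lab1 = g1$label[x], lab2 = g2$label[y],
         species = spl[g1$species[x]], event = event, present = present,
         gain = FALSE, children = list())
  }
  rec1 <- function(pid, gain) {
    a_list <- tables$trans$alts1[[pid]]
    a <- a_list[[pick(lhs1(pid))]]
    children <- list()
    for (pos in seq_along(a$calls)) {
      q <- a$calls[pos]; qpid <- lhs_pid(q)
      if (pos %in% a$attach) {
        children[[length(children) + 1L]] <- rec1(qpid, FALSE)
      } else if (pos %in% a$breaks) {
        children[[length(children) + 1L]] <- mk_node(qpid, "ABreak", FALSE)
        rec0(qpid)
      } else if (pos %in% a$gains) {
        roots[[length(roots) + 1L]] <<- rec1(qpid, TRUE)
      } else {
        rec0(qpid)
      }
    }
    nd <- mk_node(pid, a$node, TRUE)
    nd$gain <- gain
    nd$children <- children
    nd
  }
  rec0 <- function(pid) {
    a <- tables$trans$alts0[[pid]][[pick(lhs0(pid))]]
    for (pos in seq_along(a$calls)) {
      qpid <- lhs_pid(a$calls[pos])
      if (pos %in% a$gains) {
        roots[[length(roots) + 1L]] <<- rec1(qpid, TRUE)
      } else {
        rec0(qpid)
      }
    }
    invisible(NULL)
  }
  if (root_state == 1L) {
    roots[[length(roots) + 1L]] <- rec1(tables$root_pid, FALSE)
  } else {
    rec0(tables$root_pid)
  }
  new_adjacency_forest(roots, instance_id = inst$id)
}

#' Deterministic backtrack of one parsimonious adjacency forest
#'
#' Ties are broken deterministically: the first minimal alternative in
#' transcription order, and the presence state is preferred at the root on
#' equality.
#'
#' @param tables min-plus `deco_tables`.
#' @param instance the instance the tables were computed from (defaults to
#'   the one stored in the tables).
#' @return An `adjacency_forest` achieving [parsimony_score()].
#' @export
backtrack_optimal <- function(tables, instance = tables$instance) {
  if (tables$algebra != "min-plus")
    stop("backtrack_optimal() needs min-plus tables", call. = FALSE)
  v <- tables$v
  pick <- function(lhs) {
    pid <- lhs_pid(lhs)
    alts <- if (lhs_state(lhs)) tables$trans$alts1[[pid]] else
      tables$trans$alts0[[pid]]
    vals <- vapply(alts, function(a) a$cost + sum(v[a$calls]), 0)
    which.min(vals)
  }
  r <- tables$root_pid
  root_state <- if (v[lhs1(r)] <= v[lhs0(r)]) 1L else 0L
  build_forest_from_picks(tables, root_state, pick)
}
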