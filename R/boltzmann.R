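## Partition function, homogeneous rescaling, Boltzmann sampling and the
## inside-outside algorithm for exact adjacency probabilities.

#' Partition function over all adjacency forests
#'
#' Runs the DeCo scheme under the (sum, *) algebra: the returned value equals
#' the sum of `exp(-s/kT)` over every adjacency forest of the instance. With
#' `alpha != 1` the computation is carried on alpha-rescaled values and the
#' true value is recovered as `Z = Z_alpha / alpha^kappa_root` (reported on
#' the log scale as well, since the de-rescaled value may leave the double
#' range).
#'
#' @param instance a `deco_instance`.
#' @param costs [cost_params()].
#' @param params [ensemble_params()] (pseudo-temperature `kT`, rescaling
#'   factor `alpha`).
#' @param tables optionally, precomputed sum-times `deco_tables`.
#' @return An object of class `partition_result` with fields `Z`, `log_Z`,
#'   `Z_alpha`, `kappa_root`, `kT`, `alpha`.
#' @export
partition_function <- function(instance, costs = cost_params(),
                               params = ensemble_params(), tables = NULL) {
  if (is.null(tables))
    tables <- compute_tables(instance, costs, "sum-times", params)
  if (tables$algebra != "sum-times")
    stop("partition_function() needs sum-times tables", call. = FALSE)
  r <- tables$root_pid
  z_alpha <- tables$v[lhs1(r)] + tables$v[lhs0(r)]
  kr <- tables$pairs$kappa[r]
  log_z <- log(z_alpha) - kr * log(tables$params$alpha)
  z <- if (tables$params$alpha == 1) z_alpha else exp(log_z)
  structure(list(Z = z, log_Z = log_z, Z_alpha = z_alpha,
                 kappa_root = kr, kT = tables$params$kT,
                 alpha = tables$params$alpha, tables = tables),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Partition function: Z =", format(x$Z), "(log Z =", format(x$log_Z),
      ") at kT =", x$kT, "\n")
  if (x$alpha != 1)
    cat("  rescaled: Z_alpha =", format(x$Z_alpha), "alpha =", x$alpha,
        "kappa_root =", x$kappa_root, "\n")
  invisible(x)
}

#' Choose a rescaling factor avoiding numerical over/underflow
#'
#' Returns `alpha = 1` when the plain computation stays within floating
#' range. Otherwise the factor is inferred from a partial computation: at the
#' first failing table cell, the cell's min-plus score s and rescaling
#' exponent kappa suggest `alpha = exp(s / (kT * kappa))`, which centres the
#' rescaled cell near 1; the proposal is refined (bisection in log space)
#' until the whole table is finite and nonzero.
#'
#' @inheritParams partition_function
#' @param alpha optional prescribed value, returned as is.
#' @param max_iter iteration cap for the refinement loop.
#' @return A positive scalar usable as `ensemble_params(..., alpha = )`.
#' @export
choose_rescaling <- function(instance, costs = cost_params(),
                             params = ensemble_params(), alpha = NULL,
                             max_iter = 30L) {
  if (!is.null(alpha)) {
    stopifnot(is.numeric(alpha), alpha > 0)
    return(alpha)
  }
  kT <- params$kT
  la <- 0       # current log(alpha)
  lo <- -Inf    # log-alpha known too small (underflow seen)
  hi <- Inf     # log-alpha known too large (overflow seen)
  for (it in seq_len(max_iter)) {
    p <- ensemble_params(kT = kT, alpha = exp(la))
    res <- tryCatch({
      compute_tables(instance, costs, "sum-times", p)
      NULL
    }, adjensemble_rescale = function(e) e)
    if (is.null(res)) return(exp(la))
    kap <- max(1L, deco_pairs(instance)$kappa[res$pid])
    s <- res$s_min
    cand <- if (is.finite(s)) s / (kT * kap) else la + log(2) * 64 / kap
    if (res$kind == "underflow") {
      lo <- max(lo, la)
      la <- if (cand > lo + 1e-9 && cand < hi) cand else
        if (is.finite(hi)) (max(lo, la) + hi) / 2 else
          max(cand, la + log(2) * 64 / kap)
    } else {
      hi <- min(hi, la)
      la <- if (cand < hi - 1e-9 && cand > lo) cand else
        if (is.finite(lo)) (lo + min(hi, la)) / 2 else
          min(cand, la - log(2) * 64 / kap)
    }
  }
  stop("could not find a rescaling factor within ", max_iter, " attempts; ",
       "the feasible window of a single homogeneous factor may be empty ",
       "for this instance at kT = ", kT, call. = FALSE)
}

#' Sample adjacency forests from the Boltzmann distribution
#'
#' Stochastic backtracking: at every left-hand side the alternative t_i is
#' selected with probability t_i / (sum of alternatives), which draws each
#' forest F with probability `exp(-s(F)/kT) / Z`. Rescaling leaves the
#' distribution unchanged. One seeded generator is used per call, so equal
#' seeds give identical samples; the caller's RNG state is left untouched.
#'
#' @inheritParams partition_function
#' @param n number of independent samples (`0` gives an empty list).
#' @param seed integer seed.
#' @return A list of `n` `adjacency_forest` objects.
#' @export
sample_forests <- function(instance, costs = cost_params(),
                           params = ensemble_params(), n = 1L,
                           seed = 1L, tables = NULL) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  n <- as.integer(n)
  if (n < 0L) stop("n must be nonnegative", call. = FALSE)
  if (n == 0L) return(list())
  if (is.null(tables))
    tables <- compute_tables(instance, costs, "sum-times", params)
  if (tables$algebra != "sum-times")
    stop("sample_forests() needs sum-times tables", call. = FALSE)
  cw <- lapply(tables$aw, cumsum)
  pick <- function(lhs) {
    w <- cw[[lhs]]
    k <- length(w)
    if (k == 1L) return(1L)
    u <- stats::runif(1L) * w[k]
    min(findInterval(u, w) + 1L, k)
  }
  r <- tables$root_pid
  v1 <- tables$v[lhs1(r)]; v0 <- tables$v[lhs0(r)]
  out <- vector("list", n)
  local_rng(seed, {
    for (i in seq_len(n)) {
      root_state <- if (stats::runif(1L) * (v1 + v0) < v1) 1L else 0L
      out[[i]] <- build_forest_from_picks(tables, root_state, pick)
    }
  })
  out
}

# evaluate `expr` under a private RNG stream seeded with `seed`
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  eval.parent(substitute(expr))
}

#' Outside tables of the DeCo scheme
#'
#' For every pair and state, the total (rescaled) Boltzmann weight of all
#' truncated contexts above that call: `d = 1` at the root pair, and every
#' transition l -> r propagates `d(l) * exp(-C_r/kT) * prod(values of the
#' other calls)` to each call of its right-hand side, in reverse double
#' post-order.
#'
#' @param tables sum-times `deco_tables`.
#' @return Numeric vector of outside values indexed like the inside tables
#'   (two states per pair), with attribute `"Z_alpha"`.
#' @export
outside_tables <- function(tables) {
  if (tables$algebra != "sum-times")
    stop("outside_tables() needs sum-times tables", call. = FALSE)
  P <- tables$pairs$P
  v <- tables$v
  kT <- tables$params$kT
  la <- log(tables$params$alpha)
  d <- numeric(2L * P)
  r <- tables$root_pid
  d[lhs1(r)] <- 1
  d[lhs0(r)] <- 1
  for (p in rev(seq_len(P))) {
    selff <- exp(tables$pairs$ks[p] * la)
    for (st in 0:1) {
      lhs <- if (st == 0L) lhs0(p) else lhs1(p)
      dl <- d[lhs]
      if (dl == 0) next
      alts <- if (st == 0L) tables$trans$alts0[[p]] else
        tables$trans$alts1[[p]]
      for (a in alts) {
        m <- length(a$calls)
        if (m == 0L) next
        w <- dl * selff * exp(-a$cost / kT)
        if (w == 0) next
        vals <- v[a$calls]
        for (i in seq_len(m)) {
          contrib <- w * prod(vals[-i])
          q <- a$calls[i]
          d[q] <- d[q] + contrib
        }
      }
    }
  }
  attr(d, "Z_alpha") <- v[lhs1(r)] + v[lhs0(r)]
  d
}

#' Exact Boltzmann probabilities of DP transitions
#'
#' For every reachable left-hand side l and alternative r, the probability
#' that a Boltzmann-distributed forest's derivation uses l -> r:
#' `P(l -> r) = d(l) * exp(-C_r/kT) * prod(inside values of r) / Z`. Per
#' left-hand side these sum to the probability of reaching l at all.
#'
#' @param tables sum-times `deco_tables`.
#' @param outside result of [outside_tables()] (computed if missing).
#' @return A tibble with one row per transition: `state`, `gene1`, `gene2`,
#'   `alternative`, `probability` and `reach_probability`.
#' @export
transition_probabilities <- function(tables, outside = NULL) {
  if (is.null(outside)) outside <- outside_tables(tables)
  Z <- attr(outside, "Z_alpha")
  g1 <- tables$instance$g1; g2 <- tables$instance$g2
  kT <- tables$params$kT
  la <- log(tables$params$alpha)
  rows <- list()
  for (p in seq_len(tables$pairs$P)) {
    selff <- exp(tables$pairs$ks[p] * la)
    for (st in 0:1) {
      lhs <- if (st == 0L) lhs0(p) else lhs1(p)
      alts <- if (st == 0L) tables$trans$alts0[[p]] else
        tables$trans$alts1[[p]]
      if (length(alts) == 0L) next
      dl <- outside[lhs]
      pr <- vapply(alts, function(a) {
        dl * selff * exp(-a$cost / kT) * prod(tables$v[a$calls])
      }, 0) / Z
      rows[[length(rows) + 1L]] <- tibble::tibble(
        state = st,
        gene1 = g1$label[tables$pairs$px[p]],
        gene2 = g2$label[tables$pairs$py[p]],
        alternative = seq_along(alts),
        probability = pr,
        reach_probability = dl * tables$v[lhs] / Z)
    }
  }
  do.call(rbind, rows)
}

#' Exact Boltzmann probability of every candidate adjacency
#'
#' Inside-outside product: the probability that the ensemble contains an
#' adjacency between g1 and g2 is `c1(g1,g2) * d1(g1,g2) / Z` (each
#' derivation enters a pair at most once, so no multiplicity correction is
#' needed). Observed extant adjacencies come out with probability 1.
#'
#' @inheritParams partition_function
#' @return A tibble with one row per species-matched pair: `gene1`, `gene2`,
#'   `species`, `probability`, `ancestral` (TRUE for pre-speciation,
#'   non-duplicated candidate pairs) and `extant` (TRUE for observed extant
#'   adjacencies); attributes `kT`, `alpha`, `instance_id`.
#' @export
adjacency_probability_matrix <- function(instance, costs = cost_params(),
                                         params = ensemble_params(),
                                         tables = NULL) {
  if (is.null(tables))
    tables <- compute_tables(instance, costs, "sum-times", params)
  d <- outside_tables(tables)
  Z <- attr(d, "Z_alpha")
  pr <- tables$pairs
  g1 <- tables$instance$g1; g2 <- tables$instance$g2
  prob <- numeric(pr$P)
  for (p in seq_len(pr$P))
    prob[p] <- tables$v[lhs1(p)] * d[lhs1(p)] / Z
  slack <- 1e-9
  if (any(prob < -slack | prob > 1 + slack))
    stop("internal error: adjacency probability outside [0,1] beyond ",
         "numerical slack", call. = FALSE)
  prob <- pmin(pmax(prob, 0), 1)
  obs <- rep(FALSE, pr$P)
  adj <- tables$instance$adjacencies
  obs[pr$pid_map[cbind(adj$node1, adj$node2)]] <- TRUE
  out <- tibble::tibble(
    gene1 = g1$label[pr$px],
    gene2 = g2$label[pr$py],
    species = g1$species_tree$label[g1$species[pr$px]],
    probability = prob,
    ancestral = pr$e1 == "Spec" & pr$e2 == "Spec",
    extant = obs)
  attr(out, "kT") <- tables$params$kT
  attr(out, "alpha") <- tables$params$alpha
  attr(out, "instance_id") <- tables$instance$id
  out
}
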