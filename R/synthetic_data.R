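#' @name synthetic_data
#' @title Simulators for fossil trees and discrete morphological matrices
#' @description
#' Generators that emulate the statistical structure the analyses assume:
#' fossil trees from a forward fossilized birth-death process with
#' \eqn{\rho = 0} (all samples are fossils, samples with sampled
#' descendants become sampled ancestors), and discrete character matrices
#' evolved under the symmetric Mk process with gamma rate variation,
#' optional ordered morphoclines (stepwise nearest-neighbour chains) and
#' optional variable-only ascertainment. All generators are fully
#' determined by (seed, configuration).
NULL

#' Simulation configuration
#'
#' @param seed integer seed
#' @param origin origin time (Mya) of the FBD process
#' @param lambda,mu,psi FBD rates (1/My)
#' @param min_samples,max_samples rejection-sampling bounds on the number of
#'   fossil samples
#' @param n_char number of characters
#' @param state_counts possible per-character state counts
#' @param state_probs sampling weights for \code{state_counts}
#' @param rate evolutionary rate (expected changes per My at gamma mean 1)
#' @param gamma_shape gamma shape for across-character rates
#' @param ordered_fraction fraction of characters evolved as ordered
#'   morphoclines
#' @param variable_only redraw constant characters
#' @return a \code{sim_config}
#' @export
sim_config <- function(seed = 1L, origin = 100, lambda = 0.06, mu = 0.04, psi = 0.03,
                       min_samples = 2L, max_samples = 60L,
                       n_char = 50L, state_counts = c(2L, 3L, 4L),
                       state_probs = c(0.7, 0.2, 0.1), rate = 0.02,
                       gamma_shape = 1, ordered_fraction = 0.15,
                       variable_only = TRUE) {
  stopifnot(lambda >= 0, mu >= 0, psi >= 0, n_char >= 1L, rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a fossilized birth-death tree
#'
#' Forward simulation from the origin: lineages branch at rate
#' \eqn{\lambda}, die at rate \eqn{\mu}, and are sampled at rate
#' \eqn{\psi}; at time 0 unsampled lineages are pruned (\eqn{\rho = 0}).
#' Samples with later sampled descendants become sampled-ancestor nodes.
#' Rejection-sampled until the sample count lies in
#' \code{[min_samples, max_samples]}.
#'
#' @param config a \code{\link{sim_config}}
#' @param max_tries rejection cap (error when exceeded)
#' @return a \code{\link{dated_tree}} with fossil tip ages and SA flags
#' @export
simulate_fbd_tree <- function(config, max_tries = 10000L) {
  if (config$psi == 0) stop("psi = 0: no fossil can ever be sampled (always rejected)")
  set.seed(config$seed)
  for (try in seq_len(max_tries)) {
    lin <- sim_fbd_lineage(config$origin, config)
    red <- fbd_reduce(lin)
    if (is.null(red)) next
    n_samp <- fbd_count_tips(red)
    if (n_samp < config$min_samples || n_samp > config$max_samples) next
    return(fbd_build_dated(red, config$origin))
  }
  stop("simulate_fbd_tree: ", max_tries, " consecutive rejections; adjust lambda/mu/psi/origin")
}

# recursive forward simulation of one lineage starting at time t (Mya)
sim_fbd_lineage <- function(t, config, depth = 0L) {
  if (depth > 4000L) stop("simulate_fbd_tree: runaway radiation; lower lambda or origin")
  l <- config$lambda; m <- config$mu; s <- config$psi
  tot <- l + m + s
  samples <- numeric(0)
  repeat {
    t <- t - stats::rexp(1L, tot)
    if (t <= 0) return(list(samples = samples, fate = "present"))
    u <- stats::runif(1L)
    if (u < s / tot) {
      samples <- c(samples, t)
    } else if (u < (s + m) / tot) {
      return(list(samples = samples, fate = "extinct"))
    } else {
      return(list(samples = samples, fate = "split", at = t,
                  left = sim_fbd_lineage(t, config, depth + 1L),
                  right = sim_fbd_lineage(t, config, depth + 1L)))
    }
  }
}

# reduce to the sampled tree: nested list {age, sa_tip(logical), children}
fbd_reduce <- function(lin) {
  tail <- NULL
  if (identical(lin$fate, "split")) {
    L <- fbd_reduce(lin$left)
    R <- fbd_reduce(lin$right)
    if (!is.null(L) && !is.null(R)) {
      tail <- list(age = lin$at, tip = FALSE, children = list(L, R))
    } else if (!is.null(L)) tail <- L else if (!is.null(R)) tail <- R
  }
  # attach this lineage's samples, youngest first
  for (a in sort(lin$samples)) {
    if (is.null(tail)) {
      tail <- list(age = a, tip = TRUE, sa = FALSE, children = list())
    } else {
      tip <- list(age = a, tip = TRUE, sa = TRUE, children = list())
      tail <- list(age = a, tip = FALSE, children = list(tip, tail))
    }
  }
  tail
}

fbd_count_tips <- function(node) {
  if (node$tip) return(1L)
  sum(vapply(node$children, fbd_count_tips, 1L))
}

fbd_build_dated <- function(node, origin) {
  n <- fbd_count_tips(node)
  parent <- integer(2L * n - 1L)
  age <- numeric(2L * n - 1L)
  sa <- logical(n)
  labels <- character(n)
  tip_i <- 0L; int_i <- n
  build <- function(nd, par) {
    if (nd$tip) {
      tip_i <<- tip_i + 1L
      parent[tip_i] <<- par
      age[tip_i] <<- nd$age
      sa[tip_i] <<- isTRUE(nd$sa)
      labels[tip_i] <<- ""
      return(tip_i)
    }
    int_i <<- int_i + 1L
    me <- int_i
    parent[me] <<- par
    age[me] <<- nd$age
    for (chn in nd$children) build(chn, me)
    me
  }
  build(node, 0L)
  labels <- sprintf("fossil_%02d", seq_len(n))
  dated_tree(parent, age, labels, sa, origin = origin)
}

# transition matrix of the stepwise (tridiagonal) ordered-morphocline chain
ordered_pmat <- function(k, v) {
  Q <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) { Q[i, i + 1L] <- 1; Q[i + 1L, i] <- 1 }
  diag(Q) <- -rowSums(Q)
  # normalize to one expected change per unit v at the uniform distribution
  Q <- Q / (sum(-diag(Q)) / k)
  eig <- eigen(Q, symmetric = TRUE)
  eig$vectors %*% diag(exp(eig$values * v)) %*% t(eig$vectors)
}

#' Simulate an Mk character matrix on a dated tree
#'
#' Characters evolve independently: root state uniform, transitions along
#' each branch from the symmetric k-state chain (or the stepwise
#' nearest-neighbour chain for ordered morphoclines), branch "length" =
#' duration x rate x per-character gamma multiplier. With
#' \code{config$variable_only}, constant characters are redrawn (bounded).
#'
#' @param dt a \code{\link{dated_tree}} (or \code{phylo} with branch
#'   lengths, converted internally with equal rates)
#' @param config a \code{\link{sim_config}}
#' @return a \code{\link{character_matrix}}; attribute \code{ordered}
#'   holds the 1-based indices of morphocline characters
#' @export
simulate_mk_matrix <- function(dt, config) {
  set.seed(config$seed + 1L)
  n <- dt$n_tip
  po <- rev(dated_postorder(dt))           # preorder: parents before children
  durs <- branch_durations(dt)
  n_ord <- round(config$ordered_fraction * config$n_char)
  ordered_idx <- if (n_ord > 0) seq_len(n_ord) else integer(0)
  cells <- lapply(seq_len(n), function(i) vector("list", config$n_char))
  for (j in seq_len(config$n_char)) {
    is_ord <- j %in% ordered_idx
    k <- if (length(config$state_counts) == 1L) config$state_counts else
      sample(config$state_counts, 1L, prob = config$state_probs)
    if (is_ord) k <- max(k, 3L)            # a morphocline needs >= 3 states
    for (try in seq_len(1000L)) {
      g <- if (config$gamma_shape > 0) stats::rgamma(1L, config$gamma_shape, config$gamma_shape) else 1
      states <- integer(length(dt$parent))
      states[dt$root] <- sample.int(k, 1L) - 1L
      for (v in po) {
        if (v == dt$root) next
        vbr <- durs[v] * config$rate * g
        P <- if (is_ord) ordered_pmat(k, vbr) else mk_pmat(k, vbr)
        p <- P[states[dt$parent[v]] + 1L, ]
        states[v] <- sample.int(k, 1L, prob = pmax(p, 0)) - 1L
      }
      tip_states <- states[seq_len(n)]
      if (!config$variable_only || length(unique(tip_states)) > 1L) break
      if (try == 1000L) stop("cannot produce a variable character ",
                             "(rate too low for variable_only)")
    }
    for (i in seq_len(n)) cells[[i]][[j]] <- tip_states[i]
  }
  m <- character_matrix(cells, dt$labels)
  attr(m, "ordered") <- ordered_idx
  m
}

#' Deterministic weak-spot fixture
#'
#' A 12-taxon matrix built so that a floating taxon Q is pulled toward
#' clade P by two binary characters but toward clade R by three planted
#' morphoclines whose intermediate states only count under ordered
#' (additive) scoring. The node-based name "Fragilia" (internals P1 and Q,
#' qualifying external R1) therefore APPLIES under unordered scoring and
#' SELF-DESTRUCTS under ordered scoring; the node-based "Stabilia" (R1,
#' R3) applies under every weighting regime. \code{seed} only permutes the
#' character columns; the scenario itself is deterministic.
#'
#' @param seed integer
#' @return list: \code{matrix}, \code{ordered} (indices of the morphocline
#'   characters after permutation), \code{definitions}, \code{expected}
#'   (data.frame of name x regime expected statuses), \code{taxa_groups}
#' @export
make_weakspot_fixture <- function(seed = 1L) {
  taxa <- c("OUT1", "OUT2", "P1", "P2", "P3", "Q", "R1", "R2", "R3", "M1", "M2", "M3")
  grp <- function(members, state = 1L) ifelse(taxa %in% members, state, 0L)
  cols <- list()
  add <- function(x, times = 1L) for (i in seq_len(times)) cols[[length(cols) + 1L]] <<- x
  ingroup <- setdiff(taxa, c("OUT1", "OUT2"))
  add(grp(ingroup), 3L)
  add(grp(setdiff(taxa, "OUT1")), 2L)
  add(grp(c("P1", "P2", "P3")), 4L)
  add(grp(c("R1", "R2", "R3")), 4L)
  add(grp(c("M1", "M2", "M3")), 4L)
  add(grp(c("R1", "R2", "R3", "M1", "M2", "M3")), 3L)
  add(grp(c("P1", "P2")), 2L)
  add(grp(c("R1", "R2")), 2L)
  add(grp(c("M1", "M2")), 2L)
  add(grp(c("Q", "P1", "P2", "P3")), 2L)            # pulls Q toward P
  # morphocline: R+M clade = 1, Q = 2, rest 0; the intermediate state only
  # links Q to the R+M stem when scored additively
  morpho <- grp(c("R1", "R2", "R3", "M1", "M2", "M3")) + 2L * grp("Q")
  add(morpho, 3L)
  n_char <- length(cols)
  set.seed(seed)
  perm <- sample.int(n_char)
  ordered_idx <- which(perm %in% (n_char - 2L):n_char) # the 3 morphoclines
  cells <- lapply(seq_along(taxa), function(i)
    lapply(perm, function(j) cols[[j]][i]))
  m <- character_matrix(cells, taxa)
  defs <- list(
    phylo_definition("Fragilia", "node", internal = list("P1", "Q"), external = list("R1")),
    phylo_definition("Stabilia", "node", internal = list("R1", "R3"))
  )
  expected <- data.frame(
    name = c("Fragilia", "Fragilia", "Stabilia", "Stabilia"),
    regime = c("unordered", "ordered", "unordered", "ordered"),
    status = c("APPLIES", "SELF_DESTRUCTS", "APPLIES", "APPLIES")
  )
  list(matrix = m, ordered = sort(ordered_idx), definitions = defs,
       expected = expected,
       taxa_groups = list(outgroup = c("OUT1", "OUT2"), P = c("P1", "P2", "P3"),
                          Q = "Q", R = c("R1", "R2", "R3"), M = c("M1", "M2", "M3")))
}
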