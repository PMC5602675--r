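#' @name tree_search
#' @title Heuristic parsimony tree search
#' @description
#' Search operates on unrooted trees held in a light edge-list structure
#' (tips are ids \code{1..n} in matrix order). Replicated random-addition
#' starting trees are refined by greedy SPR or TBR descent that accepts
#' equal-or-better trees, exploring each optimal plateau ("island") to
#' closure. Constraint-aware variants support converse-constraint (Bremer)
#' searches. Implied-weighting searches minimize total distortion instead of
#' length; ties are compared at absolute tolerance 1e-8.
NULL

SCORE_TOL <- 1e-8

# ---- light unrooted tree structure ---------------------------------------

ts_tree <- function(edges, n_tip) {
  structure(list(edges = edges, n_tip = n_tip), class = "ts_tree")
}

ts_start <- function(tips3, n_tip) {
  w <- n_tip + 1L
  ts_tree(cbind(rep(w, 3L), tips3), n_tip)
}

ts_next_id <- function(tr) max(tr$edges) + 1L

# insert `tip` on edge row `i`, creating one new internal node
ts_add_tip <- function(tr, tip, i) {
  e <- tr$edges
  w <- max(e, tip) + 1L
  u <- e[i, 1L]; v <- e[i, 2L]
  e <- e[-i, , drop = FALSE]
  ts_tree(rbind(e, c(u, w), c(w, v), c(w, tip)), tr$n_tip)
}

ts_adjacency <- function(tr) {
  ids <- sort(unique(as.vector(tr$edges)))
  adj <- vector("list", max(ids))
  for (r in seq_len(nrow(tr$edges))) {
    a <- tr$edges[r, 1L]; b <- tr$edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# component containing `from` after deleting edge row `cut`
ts_component <- function(tr, from, cut) {
  e <- tr$edges[-cut, , drop = FALSE]
  seen <- from
  frontier <- from
  while (length(frontier)) {
    hit <- e[, 1L] %in% frontier | e[, 2L] %in% frontier
    nodes <- unique(as.vector(e[hit, , drop = FALSE]))
    frontier <- setdiff(nodes, seen)
    seen <- c(seen, frontier)
    e <- e[!hit, , drop = FALSE]
  }
  seen
}

# convert to ape::phylo, rooting at the internal neighbour of the smallest tip
ts_to_phylo <- function(tr, taxa) {
  n <- tr$n_tip
  if (n == 2L) stop("trees need at least 3 tips")
  adj <- ts_adjacency(tr)
  present <- sort(unique(as.vector(tr$edges)))
  tips <- present[present <= n]
  root <- adj[[tips[1L]]][1L]
  newid <- integer(max(present))
  newid[tips] <- seq_along(tips)
  nn <- length(tips)
  # preorder DFS over internal nodes
  nxt <- nn + 1L
  edge_par <- integer(0); edge_ch <- integer(0)
  stack_node <- root; stack_par <- 0L
  while (length(stack_node)) {
    v <- stack_node[1L]; p <- stack_par[1L]
    stack_node <- stack_node[-1L]; stack_par <- stack_par[-1L]
    if (v > n) { newid[v] <- nxt; nxt <- nxt + 1L }
    if (p != 0L) { edge_par <- c(edge_par, newid[p]); edge_ch <- c(edge_ch, v) }
    kids <- setdiff(adj[[v]], p)
    if (v > n && length(kids)) {
      stack_node <- c(kids, stack_node)
      stack_par <- c(rep(v, length(kids)), stack_par)
    }
  }
  # children recorded by original id; map now that all internals are numbered
  edge_ch <- newid[edge_ch]
  phy <- list(edge = cbind(edge_par, edge_ch), tip.label = taxa[tips],
              Nnode = nxt - nn - 1L + 1L)
  phy$Nnode <- nxt - 1L - nn
  dimnames(phy$edge) <- NULL
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

phylo_to_ts <- function(tree, taxa) {
  n_all <- length(taxa)
  tipid <- match(tree$tip.label, taxa)
  if (anyNA(tipid)) stop("tree contains taxa absent from the matrix")
  n <- length(tree$tip.label)
  e <- tree$edge
  map <- integer(n + tree$Nnode)
  map[seq_len(n)] <- tipid
  map[(n + 1L):(n + tree$Nnode)] <- n_all + seq_len(tree$Nnode)
  # suppress a degree-2 root if the input was rooted
  ed <- cbind(map[e[, 1L]], map[e[, 2L]])
  tr <- ts_tree(ed, n_all)
  deg <- tabulate(as.vector(ed), nbins = max(ed))
  two <- which(deg == 2L & seq_len(max(ed)) > n_all)
  for (v in two) {
    rows <- which(ed[, 1L] == v | ed[, 2L] == v)
    nbrs <- setdiff(as.vector(ed[rows, , drop = FALSE]), v)
    ed <- rbind(ed[-rows, , drop = FALSE], nbrs)
  }
  ts_tree(ed, n_all)
}

# canonical topology signature from non-trivial splits
ts_signature <- function(tr) {
  sig <- character(0)
  for (i in seq_len(nrow(tr$edges))) {
    u <- tr$edges[i, 1L]; v <- tr$edges[i, 2L]
    if (u <= tr$n_tip || v <= tr$n_tip) next
    comp <- ts_component(tr, v, i)
    tips <- sort(comp[comp <= tr$n_tip])
    all_tips <- sort(unique(as.vector(tr$edges)))
    all_tips <- all_tips[all_tips <= tr$n_tip]
    if (!(all_tips[1L] %in% tips)) side <- tips else side <- setdiff(all_tips, tips)
    if (length(side) >= 2L && length(side) <= length(all_tips) - 2L)
      sig <- c(sig, paste(side, collapse = "."))
  }
  paste(sort(unique(sig)), collapse = "|")
}

ts_splits <- function(tr) {
  # list of integer tip-id vectors, one per internal edge (side not holding
  # the smallest tip)
  out <- list()
  all_tips <- sort(unique(as.vector(tr$edges)))
  all_tips <- all_tips[all_tips <= tr$n_tip]
  for (i in seq_len(nrow(tr$edges))) {
    u <- tr$edges[i, 1L]; v <- tr$edges[i, 2L]
    if (u <= tr$n_tip || v <= tr$n_tip) next
    comp <- ts_component(tr, v, i)
    tips <- sort(comp[comp <= tr$n_tip])
    side <- if (all_tips[1L] %in% tips) setdiff(all_tips, tips) else tips
    if (length(side) >= 2L && length(side) <= length(all_tips) - 2L)
      out[[length(out) + 1L]] <- side
  }
  unique(out)
}

ts_has_clade <- function(tr, clade_ids) {
  # does the unrooted tree contain the split {clade | rest}? trivial clades
  # (single tips, all tips, all-but-one) are always present
  all_tips <- sort(unique(as.vector(tr$edges)))
  all_tips <- all_tips[all_tips <= tr$n_tip]
  clade_ids <- sort(clade_ids)
  if (length(clade_ids) <= 1L || length(clade_ids) >= length(all_tips) - 1L) return(TRUE)
  side <- if (all_tips[1L] %in% clade_ids) sort(setdiff(all_tips, clade_ids)) else clade_ids
  key <- paste(side, collapse = ".")
  any(vapply(ts_splits(tr), function(s) paste(s, collapse = ".") == key, TRUE))
}

# ---- SPR / TBR neighbourhoods --------------------------------------------

ts_neighbors <- function(tr, swap = c("SPR", "TBR")) {
  swap <- match.arg(swap)
  out <- list()
  ne <- nrow(tr$edges)
  for (i in seq_len(ne)) {
    for (orient in 1:2) {
      u <- tr$edges[i, orient]          # stays
      v <- tr$edges[i, 3L - orient]     # pruned side
      # prune component containing v; suppress u if it becomes degree-2
      comp_v <- ts_component(tr, v, i)
      comp_u <- ts_component(tr, u, i)
      if (length(comp_u) < 3L) next     # nothing to regraft onto
      e <- tr$edges[-i, , drop = FALSE]
      in_u <- e[, 1L] %in% comp_u & e[, 2L] %in% comp_u
      eu <- e[in_u, , drop = FALSE]
      ev <- e[!in_u, , drop = FALSE]
      fused <- NULL
      if (u > tr$n_tip) {
        rows <- which(eu[, 1L] == u | eu[, 2L] == u)
        if (length(rows) == 2L) {
          nbrs <- setdiff(as.vector(eu[rows, , drop = FALSE]), u)
          eu <- rbind(eu[-rows, , drop = FALSE], nbrs)
          fused <- nrow(eu)
        }
      }
      attach_pts <- if (swap == "SPR" || nrow(ev) == 0L) list(v) else c(list(v), ts_tbr_points(ev, v, tr$n_tip))
      for (j in seq_len(nrow(eu))) {
        if (!is.null(fused) && j == nrow(eu) && length(attach_pts) == 1L) next # recreates input
        for (ap in attach_pts) {
          out[[length(out) + 1L]] <- ts_regraft(eu, ev, tr$n_tip, j, ap, v)
        }
      }
    }
  }
  out
}

# TBR: alternative attachment points inside the pruned component are made by
# splitting one of its edges with a fresh node
ts_tbr_points <- function(ev, v, n_tip) {
  lapply(seq_len(nrow(ev)), function(r) c(ev[r, 1L], ev[r, 2L]))
}

ts_regraft <- function(eu, ev, n_tip, j, attach, v) {
  top <- max(c(eu, ev, n_tip))
  w <- top + 1L
  u1 <- eu[j, 1L]; u2 <- eu[j, 2L]
  eu2 <- rbind(eu[-j, , drop = FALSE], c(u1, w), c(w, u2))
  if (length(attach) == 1L) {
    ts_tree(rbind(eu2, ev, c(w, attach)), n_tip)
  } else {
    # split pruned-side edge (a,b) with node x, connect w-x (TBR reconnection)
    x <- w + 1L
    a <- attach[1L]; b <- attach[2L]
    r <- which(ev[, 1L] == a & ev[, 2L] == b | ev[, 1L] == b & ev[, 2L] == a)[1L]
    ev2 <- rbind(ev[-r, , drop = FALSE], c(a, x), c(x, b))
    # suppress v's old attachment point if it became degree-2
    tr <- ts_tree(rbind(eu2, ev2, c(w, x)), n_tip)
    ts_suppress_degree2(tr)
  }
}

ts_suppress_degree2 <- function(tr) {
  ed <- tr$edges
  repeat {
    deg <- tabulate(as.vector(ed), nbins = max(ed))
    two <- which(deg == 2L)
    two <- two[two > tr$n_tip]
    if (!length(two)) break
    v <- two[1L]
    rows <- which(ed[, 1L] == v | ed[, 2L] == v)
    nbrs <- setdiff(as.vector(ed[rows, , drop = FALSE]), v)
    ed <- rbind(ed[-rows, , drop = FALSE], nbrs)
  }
  ts_tree(ed, tr$n_tip)
}

# ---- configuration and scoring wrappers ----------------------------------

#' Search configuration
#'
#' @param n_replicates number of random-addition + swap replicates
#' @param seed integer RNG seed for the whole battery
#' @param swap branch-swapping neighbourhood, \code{"SPR"} or \code{"TBR"}
#' @param max_saved_trees plateau-size cap; exceeding it flags truncation
#' @param collapse_rule \code{"MIN_LENGTH_ZERO"} (TNT-style) or \code{"NONE"}
#' @param constraint optional \code{list(clade = taxa, mode = "forbid"|"enforce")}
#' @param root taxon used to root output trees (the designated outgroup)
#' @return a \code{search_config} list
#' @export
search_config <- function(n_replicates = 100L, seed = 1L, swap = c("SPR", "TBR"),
                          max_saved_trees = 10000L,
                          collapse_rule = c("MIN_LENGTH_ZERO", "NONE"),
                          constraint = NULL, root = NULL) {
  swap <- match.arg(swap)
  collapse_rule <- match.arg(collapse_rule)
  stopifnot(n_replicates >= 1L, max_saved_trees >= 1L)
  structure(list(n_replicates = as.integer(n_replicates), seed = as.integer(seed),
                 swap = swap, max_saved_trees = as.integer(max_saved_trees),
                 collapse_rule = collapse_rule, constraint = constraint, root = root),
            class = "search_config")
}

CONSTRAINT_PENALTY <- 1e7

ts_score <- function(tr, m, settings, mn = NULL, constraint_ids = NULL,
                     constraint_mode = "none") {
  phy <- ts_to_phylo(tr, m$taxa)
  sub <- if (length(phy$tip.label) == length(m$taxa)) m else subset_taxa(m, phy$tip.label)
  sc <- search_objective(phy, sub, settings,
                         mn = if (length(phy$tip.label) == length(m$taxa)) mn else NULL)
  if (constraint_mode == "forbid" && ts_has_clade(tr, constraint_ids))
    sc <- sc + CONSTRAINT_PENALTY
  if (constraint_mode == "enforce" && !ts_has_clade(tr, constraint_ids))
    sc <- sc + CONSTRAINT_PENALTY
  sc
}

# ---- operations -----------------------------------------------------------

#' Random-addition starting tree
#'
#' Taxa are inserted in seeded random order, each at the attachment point
#' that minimizes the current objective (first-best tie break).
#'
#' @param m a \code{\link{character_matrix}}
#' @param settings a \code{\link{parsimony_settings}}
#' @param seed integer seed; \code{NULL} uses the current RNG state
#' @return an unrooted \code{phylo}
#' @export
random_addition_tree <- function(m, settings = parsimony_settings(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- random_addition_ts(m, settings)
  ts_to_phylo(tr, m$taxa)
}

random_addition_ts <- function(m, settings) {
  n <- length(m$taxa)
  if (n < 3L) stop("need at least 3 taxa")
  ord <- sample.int(n)
  tr <- ts_start(ord[1:3], n)
  if (n > 3L) for (tip in ord[4:n]) {
    best <- NULL; best_sc <- Inf
    for (i in seq_len(nrow(tr$edges))) {
      cand <- ts_add_tip(tr, tip, i)
      sc <- ts_score(cand, m, settings)
      if (sc < best_sc - SCORE_TOL) { best_sc <- sc; best <- cand }
    }
    tr <- best
  }
  tr
}

#' Greedy branch swapping to a local optimum set
#'
#' SPR/TBR descent from \code{start}, accepting strictly better trees and
#' collecting all distinct equal-best topologies in the island, up to
#' \code{config$max_saved_trees} (overflow is flagged, not silent).
#'
#' @param start starting tree (\code{phylo})
#' @param m a \code{\link{character_matrix}}
#' @param settings a \code{\link{parsimony_settings}}
#' @param config a \code{\link{search_config}}
#' @return a \code{tree_set}: list(trees, best_score, truncated, provenance)
#' @export
swap_to_optimum <- function(start, m, settings = parsimony_settings(),
                            config = search_config()) {
  tr <- phylo_to_ts(start, m$taxa)
  res <- swap_island(tr, m, settings, config)
  tree_set_from_ts(res, m, config)
}

swap_island <- function(tr, m, settings, config) {
  cids <- if (!is.null(config$constraint)) match(config$constraint$clade, m$taxa) else NULL
  cmode <- if (!is.null(config$constraint)) config$constraint$mode else "none"
  mn <- if (settings$weighting == "implied") active_min_steps(m, settings) else NULL
  sc0 <- ts_score(tr, m, settings, mn, cids, cmode)
  found <- new.env(parent = emptyenv())
  assign(ts_signature(tr), tr, envir = found)
  queue <- list(tr)
  best <- sc0
  truncated <- FALSE
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (nb in ts_neighbors(cur, config$swap)) {
      sc <- ts_score(nb, m, settings, mn, cids, cmode)
      if (sc < best - SCORE_TOL) {
        best <- sc
        found <- new.env(parent = emptyenv())
        assign(ts_signature(nb), nb, envir = found)
        queue <- list(nb)
        break
      } else if (sc < best + SCORE_TOL) {
        sig <- ts_signature(nb)
        if (!exists(sig, envir = found, inherits = FALSE)) {
          if (length(ls(found)) >= config$max_saved_trees) {
            truncated <- TRUE
          } else {
            assign(sig, nb, envir = found)
            queue <- c(queue, list(nb))
          }
        }
      }
    }
  }
  list(trees = mget(ls(found), envir = found), best = best, truncated = truncated)
}

tree_set_from_ts <- function(res, m, config, provenance = NULL) {
  trees <- lapply(res$trees, ts_to_phylo, taxa = m$taxa)
  if (!is.null(config$root)) trees <- lapply(trees, root_on_taxon, taxon = config$root)
  structure(list(trees = trees, best_score = res$best, truncated = res$truncated,
                 provenance = provenance), class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat("tree_set:", length(x$trees), "trees at score", x$best_score,
      if (isTRUE(x$truncated)) "(TRUNCATED)" else "", "\n")
  invisible(x)
}

#' Root a tree on a designated outgroup taxon
#' @param tree \code{phylo}
#' @param taxon outgroup tip label
#' @return rooted \code{phylo}
#' @export
root_on_taxon <- function(tree, taxon) {
  if (!(taxon %in% tree$tip.label)) stop("unknown root taxon: ", taxon)
  ape::root(tree, outgroup = taxon, resolve.root = TRUE)
}

#' Replicated heuristic search
#'
#' Runs \code{config$n_replicates} independent seeded random-addition +
#' swapping replicates, pools all trees at the global best score, then
#' re-swaps from every pooled tree until closure. Deterministic for a fixed
#' \code{config$seed}.
#'
#' @inheritParams swap_to_optimum
#' @return a \code{tree_set}
#' @export
search_battery <- function(m, settings = parsimony_settings(), config = search_config()) {
  validate_matrix(m)
  cids <- if (!is.null(config$constraint)) match(config$constraint$clade, m$taxa) else NULL
  if (!is.null(cids) && anyNA(cids))
    stop("constraint names unknown taxa: ",
         paste(config$constraint$clade[is.na(cids)], collapse = ", "))
  if (!is.null(cids) && length(cids) >= length(m$taxa))
    stop("constraint clade must be a proper subset of the taxa")
  pool <- new.env(parent = emptyenv())
  best <- Inf
  truncated <- FALSE
  prov <- list()
  for (rep in seq_len(config$n_replicates)) {
    set.seed(config$seed + rep * 977L)
    tr0 <- random_addition_ts(m, settings)
    res <- swap_island(tr0, m, settings, config)
    truncated <- truncated || res$truncated
    if (res$best < best - SCORE_TOL) {
      best <- res$best
      rm(list = ls(pool), envir = pool)
    }
    if (res$best < best + SCORE_TOL) {
      for (tr in res$trees) {
        sig <- ts_signature(tr)
        if (!exists(sig, envir = pool, inherits = FALSE)) {
          assign(sig, tr, envir = pool)
          prov[[sig]] <- data.frame(replicate = rep, score = res$best)
        }
      }
    }
  }
  # island closure from the pooled set
  repeat {
    grew <- FALSE
    for (sig in ls(pool)) {
      res <- swap_island(get(sig, envir = pool), m, settings, config)
      truncated <- truncated || res$truncated
      if (res$best < best - SCORE_TOL) {
        best <- res$best
        rm(list = ls(pool), envir = pool)
        grew <- TRUE
      }
      for (tr in res$trees) {
        s2 <- ts_signature(tr)
        if (!exists(s2, envir = pool, inherits = FALSE)) {
          if (length(ls(pool)) >= config$max_saved_trees) { truncated <- TRUE; next }
          assign(s2, tr, envir = pool)
          grew <- TRUE
        }
      }
      if (grew) break
    }
    if (!grew) break
  }
  provdf <- do.call(rbind, prov[ls(pool)[ls(pool) %in% names(prov)]])
  tree_set_from_ts(list(trees = mget(ls(pool), envir = pool), best = best,
                        truncated = truncated), m, config, provenance = provdf)
}

#' Best trees lacking (or forced to contain) a clade
#'
#' Converse-constraint search used for Bremer decay: with mode
#' \code{"forbid"}, returns the best trees among those NOT containing the
#' clade as a monophyletic group.
#'
#' @inheritParams search_battery
#' @param clade character vector of taxa (proper subset)
#' @param mode \code{"forbid"} or \code{"enforce"}
#' @return a \code{tree_set}
#' @export
constrained_search <- function(m, settings = parsimony_settings(),
                               config = search_config(), clade, mode = "forbid") {
  config$constraint <- list(clade = clade, mode = mode)
  res <- search_battery(m, settings, config)
  if (res$best_score >= CONSTRAINT_PENALTY / 2)
    stop("no tree satisfying the constraint was found")
  res
}

#' Collapse branches of ambiguous support (minimum length zero)
#'
#' TNT-style collapsing: an internal branch is removed when doing so leaves
#' the tree's parsimony score unchanged, i.e. some most-parsimonious
#' reconstruction assigns it zero changes. Used for reporting MPT counts,
#' which are collapse-rule-sensitive and therefore logged, not asserted.
#'
#' @param tree \code{phylo}
#' @param m a \code{\link{character_matrix}}
#' @param settings a \code{\link{parsimony_settings}}
#' @return a possibly polytomous \code{phylo}
#' @export
collapse_min_length_zero <- function(tree, m, settings = parsimony_settings()) {
  base <- search_objective(tree, m, settings)
  root <- sort(tree$tip.label)[1L]
  repeat {
    cls <- tree_clades(tree, root)
    collapsed <- FALSE
    for (cl in cls) {
      cand <- tree_from_clades(Filter(function(x) !identical(x, cl), cls),
                               sort(tree$tip.label))
      if (search_objective(cand, m, settings) <= base + SCORE_TOL) {
        tree <- cand
        collapsed <- TRUE
        break
      }
    }
    if (!collapsed) break
  }
  tree
}

# number of distinct topologies after collapsing zero-length branches
collapsed_topology_count <- function(ts, m, settings) {
  keys <- vapply(ts$trees, function(t) {
    ct <- collapse_min_length_zero(t, m, settings)
    paste(sort(vapply(tree_clades(ct, sort(ct$tip.label)[1L]), paste, "",
                      collapse = ";")), collapse = "|")
  }, "")
  length(unique(keys))
}

#' Enumerate all unrooted binary topologies on a taxon set
#'
#' Exhaustive stepwise-addition enumeration; (2n-5)!! topologies. Intended
#' as a brute-force oracle for up to ~8 taxa.
#'
#' @param taxa character vector (>= 3)
#' @return list of unrooted \code{phylo} trees
#' @export
all_unrooted_topologies <- function(taxa) {
  n <- length(taxa)
  if (n < 3L) stop("need >= 3 taxa")
  trees <- list(ts_start(1:3, n))
  if (n > 3L) for (tip in 4:n) {
    nxt <- list()
    for (tr in trees) for (i in seq_len(nrow(tr$edges)))
      nxt[[length(nxt) + 1L]] <- ts_add_tip(tr, tip, i)
    trees <- nxt
  }
  lapply(trees, ts_to_phylo, taxa = taxa)
}

#' Exhaustive-search optimum (oracle)
#'
#' Scores every unrooted topology; returns all optima. Only sensible for
#' small taxon sets.
#'
#' @inheritParams search_battery
#' @param forbid_clade optional taxa vector: restrict to trees lacking it
#' @param enforce_clade optional taxa vector: restrict to trees containing it
#' @return a \code{tree_set}
#' @export
exhaustive_search <- function(m, settings = parsimony_settings(),
                              forbid_clade = NULL, enforce_clade = NULL) {
  trees <- all_unrooted_topologies(m$taxa)
  keep_tr <- list(); best <- Inf
  for (phy in trees) {
    tr <- phylo_to_ts(phy, m$taxa)
    if (!is.null(forbid_clade) && ts_has_clade(tr, match(forbid_clade, m$taxa))) next
    if (!is.null(enforce_clade) && !ts_has_clade(tr, match(enforce_clade, m$taxa))) next
    sc <- search_objective(phy, m, settings)
    if (sc < best - SCORE_TOL) { best <- sc; keep_tr <- list(phy) }
    else if (sc < best + SCORE_TOL) keep_tr <- c(keep_tr, list(phy))
  }
  structure(list(trees = keep_tr, best_score = best, truncated = FALSE,
                 provenance = NULL), class = "tree_set")
}
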