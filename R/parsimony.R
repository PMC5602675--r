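#' @name parsimony
#' @title Parsimony scoring of discrete characters on trees
#' @description
#' Unordered characters are scored with set-based Fitch optimization,
#' bit-parallel across characters (state sets live in integer bitmasks).
#' Ordered (additive) characters, and any tree containing polytomies, are
#' scored by generalized Sankoff dynamic programming with linear step costs
#' \code{|i - j|} (ordered) or unit costs (unordered). Parsimony length is a
#' property of the unrooted tree; the functions accept rooted or unrooted
#' \code{phylo} objects.
NULL

# postorder edge traversal; returns list(edge matrix, root id, n_node)
postorder_edges <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  list(edge = tree$edge, n_tip = n_tip,
       root = tree$edge[nrow(tree$edge), 1L],
       n_node = n_tip + tree$Nnode, labels = tree$tip.label)
}

tree_is_binaryish <- function(tree) {
  # binary everywhere except possibly a trifurcation at the basal node
  # (ape's representation of an unrooted binary tree)
  kids <- tabulate(tree$edge[, 1L], nbins = max(tree$edge))
  inner <- kids[kids > 0L]
  if (all(inner <= 2L)) return(TRUE)
  tri <- which(kids > 2L)
  length(tri) == 1L && kids[tri] == 3L && tri == length(tree$tip.label) + 1L
}

# bit-parallel Fitch over all characters in `cols`; exact for binary trees
# (a trifurcating root is resolved sequentially, i.e. re-rooted on an edge,
# which leaves the unrooted length unchanged)
fitch_steps_all <- function(tree, m, cols) {
  po <- postorder_edges(tree)
  idx <- match(po$labels, m$taxa)
  if (anyNA(idx)) stop("leaf absent from matrix: ", po$labels[which(is.na(idx))[1L]])
  nc <- length(cols)
  state <- matrix(0L, po$n_node, nc)
  state[seq_len(po$n_tip), ] <- m$mask[idx, cols, drop = FALSE]
  steps <- numeric(nc)
  seen <- logical(po$n_node)
  e <- po$edge
  for (r in seq_len(nrow(e))) {
    par <- e[r, 1L]; ch <- e[r, 2L]
    if (!seen[par]) {
      state[par, ] <- state[ch, ]
      seen[par] <- TRUE
    } else {
      inter <- bitwAnd(state[par, ], state[ch, ])
      empty <- inter == 0L
      steps <- steps + empty
      state[par, ] <- ifelse(empty, bitwOr(state[par, ], state[ch, ]), inter)
    }
  }
  steps
}

# generalized Sankoff for the characters in `cols` sharing state count k;
# exact on any (multifurcating) tree; cost |i-j| if ordered else 0/1
sankoff_steps_group <- function(tree, m, cols, k, ordered) {
  po <- postorder_edges(tree)
  idx <- match(po$labels, m$taxa)
  if (anyNA(idx)) stop("leaf absent from matrix: ", po$labels[which(is.na(idx))[1L]])
  nc <- length(cols)
  BIG <- 1e9
  cost <- if (ordered) abs(outer(0:(k - 1L), 0:(k - 1L), "-")) else
    1 - diag(k)
  # cost arrays: list over nodes is too slow; use k x (n_node*nc) matrix
  C <- matrix(0, k, po$n_node * nc)
  dim_at <- function(v) ((v - 1L) * nc + 1L):(v * nc)
  # tips
  tipmask <- m$mask[idx, cols, drop = FALSE]
  for (v in seq_len(po$n_tip)) {
    block <- matrix(BIG, k, nc)
    mk <- tipmask[v, ]
    for (s in 0:(k - 1L)) block[s + 1L, bitwAnd(mk, bitwShiftL(1L, s)) != 0L] <- 0
    C[, dim_at(v)] <- block
  }
  seen <- logical(po$n_node)
  e <- po$edge
  for (r in seq_len(nrow(e))) {
    par <- e[r, 1L]; ch <- e[r, 2L]
    chC <- C[, dim_at(ch), drop = FALSE]
    # min over child state t of chC[t,] + cost[s,t]
    contrib <- matrix(BIG, k, nc)
    for (s in seq_len(k)) {
      v <- chC[1L, ] + cost[s, 1L]
      if (k > 1L) for (t in 2:k) v <- pmin(v, chC[t, ] + cost[s, t])
      contrib[s, ] <- v
    }
    if (!seen[par]) {
      C[, dim_at(par)] <- contrib
      seen[par] <- TRUE
    } else {
      C[, dim_at(par)] <- C[, dim_at(par), drop = FALSE] + contrib
    }
  }
  rootC <- C[, dim_at(po$root), drop = FALSE]
  apply(rootC, 2L, min)
}

#' Per-character parsimony steps on a tree
#'
#' @param tree \code{phylo}; leaves must be scored in \code{m}
#' @param m a \code{\link{character_matrix}}
#' @param settings a \code{\link{parsimony_settings}} (controls which
#'   characters are additive)
#' @param cols character indices to score (default: all)
#' @return numeric vector of minimum step counts, one per requested character
#' @export
parsimony_steps <- function(tree, m, settings = parsimony_settings(), cols = seq_len(m$n_char)) {
  ordered <- is_ordered_char(settings, m$n_char)[cols]
  k_of <- pmax(m$state_count[cols], 1L)
  steps <- numeric(length(cols))
  use_fitch <- !ordered & tree_is_binaryish(tree)
  if (any(use_fitch))
    steps[use_fitch] <- fitch_steps_all(tree, m, cols[use_fitch])
  rest <- which(!use_fitch)
  if (length(rest)) {
    grp <- split(rest, list(k_of[rest], ordered[rest]), drop = TRUE)
    for (g in grp) {
      k <- k_of[g[1L]]
      steps[g] <- sankoff_steps_group(tree, m, cols[g], max(k, 1L), ordered[g[1L]])
    }
  }
  steps
}

#' Minimum steps of one character on one tree
#'
#' @inheritParams parsimony_steps
#' @param char_index 1-based character index
#' @param ordered score the character as additive (cost \code{|i - j|})?
#' @return integer number of state changes
#' @export
char_steps <- function(tree, m, char_index, ordered = FALSE) {
  settings <- parsimony_settings(ordered = if (ordered) char_index else integer(0))
  as.integer(round(parsimony_steps(tree, m, settings, cols = char_index)))
}

# --- step bounds -----------------------------------------------------------

# minimum steps attainable on ANY tree for character j
char_min_steps <- function(m, j, ordered) {
  k <- m$state_count[j]
  full <- bitwShiftL(1L, k) - 1L
  masks <- m$mask[, j]
  masks <- masks[masks != full]          # fully ambiguous cells never force steps
  if (length(masks) == 0L) return(0L)
  sets <- lapply(masks, mask_to_states)
  states <- sort(unique(unlist(sets)))
  if (!ordered) {
    # minimum hitting set over the state sets, minus 1
    for (size in 1:length(states)) {
      combs <- utils::combn(states, size, simplify = FALSE)
      for (cb in combs) {
        if (all(vapply(sets, function(s) any(s %in% cb), TRUE))) return(size - 1L)
      }
    }
    length(states) - 1L
  } else {
    # shortest interval [a,b] intersecting every state set
    best <- max(states) - min(states)
    for (a in states) for (b in states[states >= a]) {
      if (all(vapply(sets, function(s) any(s >= a & s <= b), TRUE)))
        best <- min(best, b - a)
    }
    best
  }
}

# maximum steps: star-tree bound for character j
char_max_steps <- function(m, j, ordered) {
  k <- m$state_count[j]
  full <- bitwShiftL(1L, k) - 1L
  masks <- m$mask[, j]
  masks <- masks[masks != full]
  if (length(masks) == 0L) return(0L)
  sets <- lapply(masks, mask_to_states)
  if (!ordered) {
    counts <- vapply(0:(k - 1L), function(s) sum(vapply(sets, function(x) s %in% x, TRUE)), 1L)
    length(sets) - max(counts)
  } else {
    # centre state minimizing the summed distances to the nearest set member
    tot <- vapply(0:(k - 1L), function(c0)
      sum(vapply(sets, function(x) min(abs(x - c0)), 1)), 1)
    as.integer(min(tot))
  }
}

#' Full parsimony score breakdown of a tree
#'
#' @inheritParams parsimony_steps
#' @return a \code{score_breakdown}: \code{total_length} (weighted step sum),
#'   \code{per_char_steps}, \code{per_char_min}, \code{per_char_max} (star
#'   bound), \code{homoplasy} and the implied-weighting distortion
#'   \code{iw_distortion} at \code{settings$K}
#' @export
tree_length <- function(tree, m, settings = parsimony_settings()) {
  cols <- which(m$active)
  s <- parsimony_steps(tree, m, settings, cols)
  ordered <- is_ordered_char(settings, m$n_char)[cols]
  mn <- vapply(seq_along(cols), function(i) char_min_steps(m, cols[i], ordered[i]), 1L)
  mx <- vapply(seq_along(cols), function(i) char_max_steps(m, cols[i], ordered[i]), 1L)
  h <- s - mn
  structure(list(
    total_length = sum(m$weight[cols] * s),
    per_char_steps = stats::setNames(s, cols),
    per_char_min = stats::setNames(mn, cols),
    per_char_max = stats::setNames(mx, cols),
    homoplasy = stats::setNames(h, cols),
    iw_distortion = sum(h / (h + settings$K)),
    K = settings$K
  ), class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("parsimony score: L =", x$total_length,
      "| homoplasy =", sum(x$homoplasy),
      "| D(K=", x$K, ") =", round(x$iw_distortion, 4), "\n")
  invisible(x)
}

#' Ensemble consistency and retention indices
#'
#' \code{CI = sum(m_i) / L}, \code{RI = (sum(g_i) - L) / (sum(g_i) - sum(m_i))}
#' with \code{m_i} the per-character minimum (any-tree) steps and \code{g_i}
#' the star-tree maximum. Values are conventionally reported to 4 decimals.
#'
#' @param best_length observed (optimal) tree length, > 0
#' @param m a \code{\link{character_matrix}}
#' @param settings a \code{\link{parsimony_settings}}
#' @param informative_only drop parsimony-uninformative characters from the
#'   sums (the alternative reporting convention)
#' @return list with elements \code{CI} and \code{RI}
#' @export
ensemble_indices <- function(best_length, m, settings = parsimony_settings(),
                             informative_only = FALSE) {
  if (best_length <= 0) stop("best_length must be positive")
  cols <- which(m$active)
  ordered <- is_ordered_char(settings, m$n_char)[cols]
  mn <- vapply(seq_along(cols), function(i) char_min_steps(m, cols[i], ordered[i]), 1L)
  mx <- vapply(seq_along(cols), function(i) char_max_steps(m, cols[i], ordered[i]), 1L)
  L <- best_length
  if (informative_only) {
    keep <- mx > mn
    # drop each uninformative character's invariant contribution from L too
    L <- L - sum(m$weight[cols][!keep] * mn[!keep])
    mn <- mn[keep]; mx <- mx[keep]
  }
  sm <- sum(mn); sg <- sum(mx)
  if (sg == sm) stop("RI undefined: no potential homoplasy (sum(g) == sum(m))")
  list(CI = round(sm / L, 4), RI = round((sg - L) / (sg - sm), 4))
}

#' Implied-weighting distortion of a tree
#'
#' \code{D = sum_i h_i / (h_i + K)} over active characters; lower is better.
#' Search under implied weighting minimizes \code{D}.
#'
#' @inheritParams parsimony_steps
#' @return non-negative real distortion
#' @export
iw_score <- function(tree, m, settings) {
  if (settings$weighting != "implied") stop("settings$weighting must be 'implied'")
  tree_length(tree, m, settings)$iw_distortion
}

# scalar search objective given settings; `mn` lets callers precompute the
# per-active-character minimum steps once per search
search_objective <- function(tree, m, settings, mn = NULL) {
  cols <- which(m$active)
  s <- parsimony_steps(tree, m, settings, cols)
  if (settings$weighting == "implied") {
    if (is.null(mn)) mn <- active_min_steps(m, settings)
    sum((s - mn) / ((s - mn) + settings$K))
  } else {
    sum(m$weight[cols] * s)
  }
}

active_min_steps <- function(m, settings) {
  cols <- which(m$active)
  ordered <- is_ordered_char(settings, m$n_char)[cols]
  vapply(seq_along(cols), function(i) char_min_steps(m, cols[i], ordered[i]), 1L)
}
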