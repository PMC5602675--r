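#' @name support_consensus
#' @title Consensus trees, Bremer decay and bootstrap supports
#' @description
#' Consensus construction is done by direct bipartition tallying: every
#' input tree is decomposed into splits, splits are oriented away from a
#' designated root taxon (so they read as rooted clades), counted, and the
#' retained laminar family is reassembled into a tree. Bremer decay values
#' come from converse-constraint searches; bootstrap proportions from
#' character resampling with a reduced search per pseudo-replicate.
NULL

# oriented clade list (character vectors of taxon labels) for one tree
tree_clades <- function(tree, root) {
  taxa <- sort(tree$tip.label)
  tr <- phylo_to_ts(tree, taxa)
  splits <- ts_splits(tr)
  lapply(splits, function(s) {
    side <- taxa[s]
    if (root %in% side) side <- setdiff(taxa, side)
    sort(side)
  })
}

#' Clade frequencies across a set of trees
#'
#' @param trees list of \code{phylo} with identical leaf sets
#' @param root taxon the clades are oriented away from (defaults to the
#'   alphabetically first tip)
#' @return data.frame with columns \code{clade} (taxa pasted with ";"),
#'   \code{count}, \code{freq}
#' @export
clade_frequencies <- function(trees, root = NULL) {
  if (length(trees) == 0L) stop("need at least one tree")
  leaf0 <- sort(trees[[1L]]$tip.label)
  if (is.null(root)) root <- leaf0[1L]
  counts <- new.env(parent = emptyenv())
  for (tree in trees) {
    if (!identical(sort(tree$tip.label), leaf0)) stop("trees have mismatched leaf sets")
    for (cl in unique(vapply(tree_clades(tree, root), paste, "", collapse = ";"))) {
      counts[[cl]] <- (if (is.null(counts[[cl]])) 0L else counts[[cl]]) + 1L
    }
  }
  keys <- ls(counts)
  data.frame(clade = keys,
             count = vapply(keys, function(k) counts[[k]], 1L),
             freq = vapply(keys, function(k) counts[[k]], 1L) / length(trees),
             row.names = NULL, stringsAsFactors = FALSE)
}

# assemble a rooted tree from a laminar family of clades (character vectors)
tree_from_clades <- function(clades, taxa, labels = NULL) {
  n <- length(taxa)
  ord <- order(vapply(clades, length, 1L), decreasing = TRUE)
  clades <- clades[ord]
  if (!is.null(labels)) labels <- labels[ord]
  edge_par <- integer(0); edge_ch <- integer(0)
  node_of <- c(list(taxa), clades)        # node 1 = root (the full leaf set)
  parent <- integer(length(node_of)); parent[1L] <- 0L
  # parent of a clade = smallest strictly-containing set (laminar family)
  for (i in seq_along(node_of)[-1L]) {
    best <- 1L
    for (j in seq_along(node_of)) {
      if (j == i) next
      if (length(node_of[[j]]) > length(node_of[[i]]) &&
          all(node_of[[i]] %in% node_of[[j]]) &&
          length(node_of[[j]]) < length(node_of[[best]])) best <- j
    }
    parent[i] <- best
  }
  # node numbering: tips 1..n, internal nodes n+1..n+n_int (root first)
  node_id <- n + seq_len(length(node_of))
  for (i in seq_along(node_of)[-1L]) {
    edge_par <- c(edge_par, node_id[parent[i]]); edge_ch <- c(edge_ch, node_id[i])
  }
  # attach each tip to the smallest clade containing it
  for (t in seq_len(n)) {
    best <- 1L
    for (j in seq_along(node_of))
      if (taxa[t] %in% node_of[[j]] && length(node_of[[j]]) < length(node_of[[best]])) best <- j
    edge_par <- c(edge_par, node_id[best]); edge_ch <- c(edge_ch, t)
  }
  phy <- list(edge = cbind(edge_par, edge_ch), tip.label = taxa, Nnode = length(node_of))
  class(phy) <- "phylo"
  if (!is.null(labels)) phy$node.label <- c("", labels)
  ape::reorder.phylo(phy, "cladewise")
}

#' Strict consensus of a tree set
#'
#' Contains exactly the clades present in every input tree (oriented away
#' from \code{root}).
#'
#' @param trees a \code{tree_set} or list of \code{phylo}
#' @param root taxon used to orient clades (default: alphabetically first)
#' @return a rooted, possibly polytomous \code{phylo}
#' @export
strict_consensus <- function(trees, root = NULL) {
  trees <- as_tree_list(trees)
  leaf0 <- sort(trees[[1L]]$tip.label)
  if (is.null(root)) root <- leaf0[1L]
  fr <- clade_frequencies(trees, root)
  keep <- fr$clade[fr$count == length(trees)]
  tree_from_clades(strsplit(keep, ";", fixed = TRUE), leaf0)
}

#' Majority-rule consensus with clade frequencies
#'
#' Retains clades whose frequency exceeds \code{cutoff}; frequencies are
#' annotated as node labels.
#'
#' @inheritParams strict_consensus
#' @param cutoff retention threshold, >= 0.5 (strictly-greater rule)
#' @return a rooted \code{phylo} with node labels holding frequencies
#' @export
majority_consensus <- function(trees, cutoff = 0.5, root = NULL) {
  if (cutoff < 0.5) stop("cutoff must be >= 0.5 (smaller cutoffs can retain incompatible clades)")
  trees <- as_tree_list(trees)
  leaf0 <- sort(trees[[1L]]$tip.label)
  if (is.null(root)) root <- leaf0[1L]
  fr <- clade_frequencies(trees, root)
  keep <- fr[fr$freq > cutoff, , drop = FALSE]
  tree_from_clades(strsplit(keep$clade, ";", fixed = TRUE), leaf0,
                   labels = formatC(keep$freq, digits = 3, format = "f"))
}

as_tree_list <- function(trees) {
  if (inherits(trees, "tree_set")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("need at least one tree")
  trees
}

#' Does a rooted (or root-oriented) tree contain a clade?
#' @param tree \code{phylo}
#' @param clade character vector of taxa
#' @param root taxon orienting the splits
#' @return logical
#' @export
has_clade <- function(tree, clade, root = NULL) {
  if (is.null(root)) root <- sort(tree$tip.label)[1L]
  if (length(clade) <= 1L) return(all(clade %in% tree$tip.label))
  cls <- tree_clades(tree, root)
  key <- paste(sort(clade), collapse = ";")
  any(vapply(cls, function(x) paste(x, collapse = ";") == key, TRUE))
}

#' Bremer (decay) supports via converse-constraint searches
#'
#' For each clade of the strict consensus of \code{optima} (or the supplied
#' clades), \code{DI = best score among trees lacking the clade - best
#' score}. A constrained search that overflowed \code{max_saved_trees}
#' yields a censored value reported as \code{">X"}.
#'
#' @param m a \code{\link{character_matrix}}
#' @param settings a \code{\link{parsimony_settings}}
#' @param optima \code{tree_set} of unconstrained optima
#' @param clades list of taxon vectors; default: all strict-consensus clades
#' @param config \code{\link{search_config}} for the constrained searches
#' @param root orientation taxon
#' @return data.frame: clade, taxa, DI, censored
#' @export
bremer_support <- function(m, settings, optima, clades = NULL,
                           config = search_config(n_replicates = 10L), root = NULL) {
  if (is.null(root)) root <- sort(optima$trees[[1L]]$tip.label)[1L]
  if (is.null(clades)) {
    fr <- clade_frequencies(optima$trees, root)
    clades <- strsplit(fr$clade[fr$count == length(optima$trees)], ";", fixed = TRUE)
  }
  if (length(clades) == 0L)
    return(data.frame(clade = character(0), DI = numeric(0),
                      censored = logical(0), DI_label = character(0)))
  out <- lapply(clades, function(cl) {
    in_strict <- all(vapply(optima$trees, has_clade, TRUE, clade = cl, root = root))
    if (!in_strict)   # clade absent from the strict consensus decays at no cost
      return(data.frame(clade = paste(sort(cl), collapse = ";"),
                        DI = 0, censored = FALSE))
    cs <- constrained_search(m, settings, config, clade = cl, mode = "forbid")
    data.frame(clade = paste(sort(cl), collapse = ";"),
               DI = cs$best_score - optima$best_score,
               censored = isTRUE(cs$truncated))
  })
  res <- do.call(rbind, out)
  res$DI_label <- ifelse(res$censored, paste0(">", res$DI), as.character(res$DI))
  res
}

#' Nonparametric character bootstrap
#'
#' Characters are resampled with replacement per replicate; a reduced
#' search battery is run on each pseudo-matrix; a clade's proportion is the
#' fraction of replicates whose strict consensus of best trees contains it
#' (absolute frequencies, TNT-style).
#'
#' @inheritParams bremer_support
#' @param n_reps number of bootstrap replicates (>= 100 for reporting)
#' @param seed RNG seed
#' @param clades list of taxon vectors to report; default: every clade seen
#' @return data.frame: clade, bootstrap, n_reps
#' @export
bootstrap_support <- function(m, settings = parsimony_settings(),
                              config = search_config(n_replicates = 3L),
                              n_reps = 500L, seed = 1L, clades = NULL, root = NULL) {
  if (is.null(root)) root <- sort(m$taxa)[1L]
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(n_reps)) {
    set.seed(seed + 7919L * b)
    mb <- resample_characters(m)
    cfg <- config; cfg$seed <- seed + 7919L * b
    ts <- search_battery(mb, settings, cfg)
    cons <- strict_consensus(ts, root)
    for (cl in tree_clades(cons, root)) {
      key <- paste(cl, collapse = ";")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  if (is.null(clades)) {
    keys <- ls(counts)
  } else {
    keys <- vapply(clades, function(cl) paste(sort(cl), collapse = ";"), "")
  }
  data.frame(clade = keys,
             bootstrap = vapply(keys, function(k)
               (if (is.null(counts[[k]])) 0L else counts[[k]]), 1L) / n_reps,
             n_reps = n_reps, row.names = NULL, stringsAsFactors = FALSE)
}
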