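#' @name dated_tree
#' @title Dated binary trees with sampled ancestors
#' @description
#' The tip-dating machinery works on a dedicated array-based structure: a
#' rooted binary tree whose every node carries an age (Mya, increasing
#' rootward). Fossil tips have fixed ages. A tip flagged as a sampled
#' ancestor sits at the end of a zero-length branch: its parent's age equals
#' the tip age, so the parent is effectively a degree-2 point on the spine
#' through which the lineage continues.
NULL

#' Construct a dated tree
#'
#' @param parent integer vector, length \code{2n-1}; \code{parent[root] = 0}
#' @param age numeric ages (Mya) per node; tips first (\code{1..n})
#' @param labels tip labels
#' @param sa logical per tip: sampled-ancestor flag
#' @param origin origin time (stem age, \code{>= root age}); defaults to the
#'   root age
#' @return a \code{dated_tree}
#' @export
dated_tree <- function(parent, age, labels, sa = NULL, origin = NULL) {
  n <- length(labels)
  N <- length(parent)
  if (N != 2L * n - 1L) stop("binary tree expected: length(parent) must be 2n-1")
  if (is.null(sa)) sa <- logical(n)
  root <- which(parent == 0L)
  if (length(root) != 1L) stop("exactly one root required")
  if (is.null(origin)) origin <- age[root]
  dt <- structure(list(n_tip = n, parent = as.integer(parent), age = as.numeric(age),
                       labels = labels, sa = as.logical(sa), root = root,
                       origin = as.numeric(origin)), class = "dated_tree")
  validate_dated_tree(dt)
  dt
}

children_of <- function(dt) {
  ch <- vector("list", length(dt$parent))
  for (i in seq_along(dt$parent)) {
    p <- dt$parent[i]
    if (p > 0L) ch[[p]] <- c(ch[[p]], i)
  }
  ch
}

validate_dated_tree <- function(dt) {
  n <- dt$n_tip
  ch <- children_of(dt)
  nk <- vapply(ch, length, 1L)
  if (any(nk[seq_len(n)] != 0L)) stop("tips must be leaves")
  if (any(nk[-seq_len(n)] != 2L)) stop("internal nodes must be binary")
  bad <- which(dt$parent > 0L & dt$age > dt$age[pmax(dt$parent, 1L)] + 1e-9)
  if (length(bad)) stop("ages must not increase tipward (node ", bad[1L], ")")
  if (dt$origin < dt$age[dt$root] - 1e-9) stop("origin must not predate the root age... (origin < root age)")
  for (i in which(dt$sa)) {
    if (abs(dt$age[i] - dt$age[dt$parent[i]]) > 1e-9)
      stop("sampled-ancestor tip ", dt$labels[i], " must attach at its own age")
  }
  invisible(TRUE)
}

# postorder node ordering (children before parents)
dated_postorder <- function(dt) {
  ch <- children_of(dt)
  out <- integer(0)
  stack <- dt$root
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    out <- c(v, out)
    stack <- c(ch[[v]], stack)
  }
  out
}

#' Branch durations (My), indexed by child node
#' @param dt a \code{dated_tree}
#' @return numeric vector length \code{2n-1}; the root entry is the stem
#'   duration \code{origin - root age}
#' @export
branch_durations <- function(dt) {
  d <- numeric(length(dt$parent))
  has_par <- dt$parent > 0L
  d[has_par] <- dt$age[dt$parent[has_par]] - dt$age[has_par]
  d[dt$root] <- dt$origin - dt$age[dt$root]
  pmax(d, 0)
}

#' Number of sampled ancestors in a dated tree
#' @param dt a \code{dated_tree}
#' @return integer count
#' @export
count_sampled_ancestors <- function(dt) sum(dt$sa)

#' Convert a dated tree to \code{phylo}
#'
#' Branch lengths are durations; attributes \code{node_ages} (in phylo node
#' numbering) and \code{sampled_ancestor} (per tip) are attached.
#'
#' @param dt a \code{dated_tree}
#' @return \code{phylo}
#' @export
dated_to_phylo <- function(dt) {
  n <- dt$n_tip
  ints <- setdiff(seq_along(dt$parent), seq_len(n))
  # phylo numbering: tips keep 1..n; root -> n+1; remaining internals follow
  newid <- integer(length(dt$parent))
  newid[seq_len(n)] <- seq_len(n)
  ord <- c(dt$root, setdiff(ints, dt$root))
  newid[ord] <- n + seq_along(ord)
  has_par <- which(dt$parent > 0L)
  edge <- cbind(newid[dt$parent[has_par]], newid[has_par])
  len <- branch_durations(dt)[has_par]
  phy <- list(edge = edge, edge.length = len, tip.label = dt$labels, Nnode = length(ints))
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  ages <- numeric(n + length(ints))
  ages[newid] <- dt$age
  attr(phy, "node_ages") <- ages
  attr(phy, "sampled_ancestor") <- dt$sa
  phy
}

#' Convert a (binary, rooted) \code{phylo} with tip ages to a dated tree
#' @param tree rooted binary \code{phylo} with branch lengths (durations)
#' @param tip_ages named numeric vector of tip ages (Mya)
#' @param sa_tol zero-length tolerance for the sampled-ancestor convention
#' @return a \code{dated_tree}
#' @export
phylo_to_dated <- function(tree, tip_ages, sa_tol = 1e-8) {
  n <- length(tree$tip.label)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) stop("need a rooted binary tree")
  depth <- ape::node.depth.edgelength(tree)
  a0 <- tip_ages[tree$tip.label]
  if (anyNA(a0)) stop("missing tip ages for: ",
                      paste(tree$tip.label[is.na(a0)], collapse = ", "))
  root_age <- unname(a0[1L]) + depth[1L]
  age <- root_age - depth
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  term_edge <- match(seq_len(n), tree$edge[, 2L])
  sa <- tree$edge.length[term_edge] <= sa_tol
  # exact SA age locking
  age[seq_len(n)] <- unname(a0)
  for (i in which(sa)) age[parent[i]] <- age[i]
  dated_tree(parent, age, tree$tip.label, sa)
}

clade_table <- function(dt) {
  # leaf-label sets per internal node (sorted, ';'-joined); SA attachment
  # nodes are degree-2 points, still listed
  ch <- children_of(dt)
  sets <- vector("list", length(dt$parent))
  for (v in dated_postorder(dt)) {
    if (v <= dt$n_tip) sets[[v]] <- dt$labels[v]
    else sets[[v]] <- sort(c(sets[[ch[[v]][1L]]], sets[[ch[[v]][2L]]]))
  }
  vapply(sets[-seq_len(dt$n_tip)], paste, "", collapse = ";")
}
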