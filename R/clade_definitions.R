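#' @name clade_definitions
#' @title Evaluate phylogenetic clade definitions and detect self-destruction
#' @description
#' Implements node-based ("least inclusive clade containing ...") and
#' branch-based ("most inclusive clade containing ... but not ...")
#' definitions in the style of phylogenetic nomenclature, with qualifying
#' external specifiers and composite (clade-valued) specifiers. A name
#' SELF-DESTRUCTS on a topology when an external specifier falls inside the
#' would-be clade; a specifier that cannot be mapped onto the tree's leaves
#' makes the definition NOT_EVALUABLE (never a guess).
NULL

#' Composite (clade-valued) specifier
#' @param taxa the species whose most recent common ancestor anchors the
#'   specifier clade
#' @return a \code{node_of} specifier object
#' @export
node_of <- function(taxa) structure(list(taxa = as.character(taxa)), class = "node_of")

#' A named phylogenetic definition
#'
#' @param name clade name
#' @param kind \code{"node"} or \code{"branch"}
#' @param internal list of specifiers (taxon labels or \code{\link{node_of}})
#' @param external list of specifiers, possibly empty
#' @param authorship free-text attribution
#' @return a \code{phylo_definition}
#' @export
phylo_definition <- function(name, kind = c("node", "branch"), internal,
                             external = list(), authorship = "") {
  kind <- match.arg(kind)
  if (!is.list(internal)) internal <- as.list(internal)
  if (!is.list(external)) external <- as.list(external)
  if (length(internal) == 0L) stop("definition '", name, "': internal specifiers must be non-empty")
  if (kind == "node" && length(internal) < 2L && length(external) == 0L)
    stop("definition '", name, "': a node-based definition needs >= 2 internal specifiers ",
         "or a qualifying external clause")
  plain <- unlist(lapply(c(internal, external), function(s) if (is.character(s)) s else s$taxa))
  if (anyDuplicated(plain)) stop("definition '", name, "': specifier taxa must be distinct")
  structure(list(name = name, kind = kind, internal = internal,
                 external = external, authorship = authorship),
            class = "phylo_definition")
}

#' @export
print.phylo_definition <- function(x, ...) {
  fmt <- function(s) if (is.character(s)) s else paste0("node_of(", paste(s$taxa, collapse = ", "), ")")
  cat(x$name, " [", x$kind, "-based]\n  internal: ",
      paste(vapply(x$internal, fmt, ""), collapse = "; "), "\n  external: ",
      if (length(x$external)) paste(vapply(x$external, fmt, ""), collapse = "; ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' Resolve specifier species onto the leaves of a tree
#'
#' A specifier resolves to itself if present verbatim among the leaves;
#' otherwise through the proxy map; otherwise by genus-level fallback (a
#' unique leaf sharing the genus, i.e. the first whitespace/underscore
#' token). Ambiguous fallbacks (two or more same-genus leaves) and misses
#' stay unresolved.
#'
#' @param def a \code{\link{phylo_definition}}
#' @param tree \code{phylo}
#' @param proxy_map named character vector (specifier -> OTU or "NONE")
#' @return list with \code{internal}, \code{external} (lists of resolved
#'   leaf-label vectors; composites keep all members) and
#'   \code{unresolved} (character vector of specifier names)
#' @export
resolve_specifiers <- function(def, tree, proxy_map = NULL) {
  leaves <- tree$tip.label
  genus <- function(x) sub("[ _].*$", "", x)
  leaf_genus <- genus(leaves)
  resolve_one <- function(sp) {
    if (sp %in% leaves) return(sp)
    if (!is.null(proxy_map) && sp %in% names(proxy_map)) {
      tgt <- proxy_map[[sp]]
      if (identical(tgt, "NONE") || !(tgt %in% leaves)) return(NA_character_)
      return(tgt)
    }
    hit <- which(leaf_genus == genus(sp))
    if (length(hit) == 1L) return(leaves[hit])
    NA_character_
  }
  do_side <- function(side) lapply(side, function(s) {
    sp <- if (is.character(s)) s else s$taxa
    vapply(sp, resolve_one, "", USE.NAMES = TRUE)
  })
  int <- do_side(def$internal)
  ext <- do_side(def$external)
  unresolved <- names(unlist(c(int, ext)))[is.na(unlist(c(int, ext)))]
  list(internal = int, external = ext,
       unresolved = unique(unresolved),
       composite = list(internal = vapply(def$internal, function(s) !is.character(s), TRUE),
                        external = vapply(def$external, function(s) !is.character(s), TRUE)))
}

# rooted-tree clade table: for each node, its leaf set
node_leafsets <- function(tree) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  for (r in seq_len(nrow(po$edge))) {
    par <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  lapply(sets, sort)
}

mrca_node <- function(tree, leaves) {
  sets <- node_leafsets(tree)
  sizes <- vapply(sets, length, 1L)
  cand <- which(vapply(sets, function(s) all(leaves %in% s), TRUE))
  cand[which.min(sizes[cand])]
}

#' Evaluate a definition on a rooted tree
#'
#' Node-based: the clade is the leaf set of the MRCA of the internal
#' specifiers; it self-destructs if an external specifier falls inside it.
#' Branch-based: starting at that MRCA, walk rootward to the last node
#' whose leaf set still excludes every external specifier; self-destructs
#' if already the MRCA contains one. A composite external specifier stands
#' for the clade subtended by the MRCA of its members: it intrudes when
#' that clade and the candidate clade overlap. Polytomies are read as hard
#' (the MRCA at a polytomy includes all its children).
#'
#' @param def a \code{\link{phylo_definition}}
#' @param tree rooted \code{phylo}
#' @param proxy_map see \code{\link{resolve_specifiers}}
#' @return a \code{definition_outcome}: list(status, clade, reason) with
#'   status one of \code{"APPLIES"}, \code{"SELF_DESTRUCTS"},
#'   \code{"NOT_EVALUABLE"}
#' @export
evaluate_definition <- function(def, tree, proxy_map = NULL) {
  rs <- resolve_specifiers(def, tree, proxy_map)
  internal_missing <- names(unlist(rs$internal))[is.na(unlist(rs$internal))]
  if (length(internal_missing))
    return(outcome("NOT_EVALUABLE", reason = paste("unresolved internal specifier:",
                                                   paste(internal_missing, collapse = ", "))))
  int_leaves <- unique(unlist(rs$internal))
  sets <- node_leafsets(tree)
  sizes <- vapply(sets, length, 1L)
  mrca_set <- function(leaves) {
    cand <- which(vapply(sets, function(s) all(leaves %in% s), TRUE))
    sets[[cand[which.min(sizes[cand])]]]
  }
  # external constraints as leaf sets: plain specifier -> itself (dropped if
  # unresolved: an absent external cannot intrude); composite -> MRCA leaf set
  ext_sets <- list()
  for (i in seq_along(rs$external)) {
    v <- rs$external[[i]]
    if (rs$composite$external[i]) {
      v2 <- v[!is.na(v)]
      if (length(v2) < 2L) next            # composite needs >= 2 resolved anchors
      ext_sets[[length(ext_sets) + 1L]] <- list(set = mrca_set(v2), label = paste(names(v), collapse = "+"))
    } else {
      if (is.na(v)) next
      ext_sets[[length(ext_sets) + 1L]] <- list(set = v, label = names(v))
    }
  }
  intrudes <- function(clade) {
    for (e in ext_sets) if (any(e$set %in% clade)) return(e$label)
    NULL
  }
  base <- mrca_set(int_leaves)
  if (def$kind == "node") {
    who <- intrudes(base)
    if (!is.null(who))
      return(outcome("SELF_DESTRUCTS", reason = paste("external specifier inside clade:", who)))
    return(outcome("APPLIES", clade = base))
  }
  # branch-based
  who <- intrudes(base)
  if (!is.null(who))
    return(outcome("SELF_DESTRUCTS", reason = paste("external specifier inside minimal clade:", who)))
  best <- base
  node <- mrca_node(tree, int_leaves)
  repeat {
    par_edge <- which(tree$edge[, 2L] == node)
    if (length(par_edge) == 0L) break       # reached the root
    par <- tree$edge[par_edge, 1L]
    cand <- sets[[par]]
    if (!is.null(intrudes(cand))) break
    best <- cand
    node <- par
  }
  outcome("APPLIES", clade = best)
}

outcome <- function(status, clade = character(0), reason = "") {
  structure(list(status = status, clade = clade, reason = reason),
            class = "definition_outcome")
}

#' @export
print.definition_outcome <- function(x, ...) {
  cat(x$status, if (x$status == "APPLIES") paste0("(", length(x$clade), " taxa)") else x$reason, "\n")
  invisible(x)
}

#' Brute-force oracle: all clades of a rooted tree satisfying a definition
#'
#' Direct enumeration of the definitional predicate over every clade of the
#' tree; used to cross-check \code{\link{evaluate_definition}}. Returns the
#' leaf sets (sorted) of all satisfying clades.
#'
#' @inheritParams evaluate_definition
#' @return list of character vectors (possibly empty)
#' @export
satisfying_clades <- function(def, tree, proxy_map = NULL) {
  rs <- resolve_specifiers(def, tree, proxy_map)
  if (any(is.na(unlist(rs$internal)))) return(NULL)
  sets <- node_leafsets(tree)
  sizes <- vapply(sets, length, 1L)
  mrca_set <- function(leaves) {
    cand <- which(vapply(sets, function(s) all(leaves %in% s), TRUE))
    sets[[cand[which.min(sizes[cand])]]]
  }
  int_ok <- function(clade) all(unique(unlist(rs$internal)) %in% clade)
  ext_ok <- function(clade) {
    for (i in seq_along(rs$external)) {
      v <- rs$external[[i]]
      if (rs$composite$external[i]) {
        v2 <- v[!is.na(v)]
        if (length(v2) < 2L) next
        if (any(mrca_set(v2) %in% clade)) return(FALSE)
      } else {
        if (!is.na(v) && v %in% clade) return(FALSE)
      }
    }
    TRUE
  }
  ok <- Filter(function(s) int_ok(s) && ext_ok(s), sets)
  unique(ok)
}

#' Tabulate definition statuses across analysis runs
#'
#' Produces the consolidated weak-spot report: one row per clade name, one
#' column block per run, each cell the evaluation status on that run's
#' consensus tree, plus (optionally) the fraction of the run's underlying
#' optimal trees on which the name applies, and a per-name summary:
#' \code{CONSISTENT} (applies everywhere), \code{UNSUPPORTED} (applies
#' nowhere), else \code{STRATEGY_DEPENDENT}.
#'
#' @param defs list of \code{\link{phylo_definition}}
#' @param runs named list; each element a list with \code{consensus} (a
#'   rooted \code{phylo}) and optionally \code{trees} (list of underlying
#'   optimal/posterior trees) and \code{supports} (data.frame)
#' @param proxy_map see \code{\link{resolve_specifiers}}
#' @return a \code{weak_spot_report}: list(status (name x run character
#'   matrix), applies_fraction, summary, outcomes)
#' @export
weak_spot_report <- function(defs, runs, proxy_map = NULL) {
  nm <- vapply(defs, function(d) d$name, "")
  run_ids <- names(runs)
  if (is.null(run_ids) || any(!nzchar(run_ids))) stop("runs must be a named list")
  status <- matrix(NA_character_, length(defs), length(runs), dimnames = list(nm, run_ids))
  fracs <- matrix(NA_real_, length(defs), length(runs), dimnames = list(nm, run_ids))
  outcomes <- list()
  for (j in seq_along(runs)) {
    run <- runs[[j]]
    for (i in seq_along(defs)) {
      oc <- evaluate_definition(defs[[i]], run$consensus, proxy_map)
      status[i, j] <- oc$status
      outcomes[[paste(nm[i], run_ids[j], sep = "@")]] <- oc
      if (!is.null(run$trees) && length(run$trees)) {
        ap <- vapply(run$trees, function(t)
          evaluate_definition(defs[[i]], t, proxy_map)$status == "APPLIES", TRUE)
        fracs[i, j] <- mean(ap)
      }
    }
  }
  summary <- apply(status, 1L, function(s) {
    if (all(s == "APPLIES")) "CONSISTENT"
    else if (!any(s == "APPLIES")) "UNSUPPORTED"
    else "STRATEGY_DEPENDENT"
  })
  structure(list(status = status, applies_fraction = fracs,
                 summary = summary), class = "weak_spot_report")
}

#' @export
print.weak_spot_report <- function(x, ...) {
  cat("weak-spot report:", nrow(x$status), "names x", ncol(x$status), "runs\n")
  short <- substr(x$status, 1, 4)
  dim(short) <- dim(x$status); dimnames(short) <- dimnames(x$status)
  print(cbind(short, summary = x$summary), quote = FALSE)
  invisible(x)
}

#' Write a weak-spot report as TSV
#' @param report a \code{weak_spot_report}
#' @param path output TSV path
#' @return invisibly, the path
#' @export
write_weak_spot_tsv <- function(report, path) {
  df <- data.frame(name = rownames(report$status), report$status,
                   summary = report$summary, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
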