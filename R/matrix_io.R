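#' Read a TNT (xread) morphological matrix
#'
#' Parses the \code{xread} dialect: an optional quoted title, the character
#' and taxon counts, then whitespace-separated taxon rows whose state strings
#' may contain \code{?}/\code{-} (full ambiguity) and bracketed polymorphic
#' codings in either \code{[..]} or \code{\{..\}} style. Interleaved blocks
#' (a taxon appearing more than once) are concatenated. Single-quoted
#' comments and \code{nstates} directives are ignored. Continuous and
#' step-matrix characters are not supported.
#'
#' @param path path to a TNT file
#' @return a \code{\link{character_matrix}}
#' @export
read_tnt_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parse_tnt_text(lines)
}

parse_tnt_text <- function(lines) {
  # strip single-quoted comments/titles (may span a line), keep line structure
  txt <- gsub("'[^']*'", " ", lines)
  # drop nstates directives
  txt <- sub("^\\s*nstates[^;]*;?\\s*$", "", txt, ignore.case = TRUE)
  tok_line <- integer(0)
  toks <- character(0)
  for (i in seq_along(txt)) {
    tl <- strsplit(trimws(txt[i]), "\\s+")[[1]]
    tl <- tl[nzchar(tl)]
    if (length(tl)) {
      toks <- c(toks, tl)
      tok_line <- c(tok_line, rep(i, length(tl)))
    }
  }
  k <- which(tolower(toks) == "xread")
  if (length(k) == 0L) stop("parse error: no 'xread' block found")
  k <- k[1L]
  if (length(toks) < k + 2L) stop("parse error at line ", tok_line[k], ": truncated xread header")
  n_char <- suppressWarnings(as.integer(toks[k + 1L]))
  n_taxa <- suppressWarnings(as.integer(toks[k + 2L]))
  if (is.na(n_char) || is.na(n_taxa))
    stop("parse error at line ", tok_line[k + 1L], ": expected '<nchar> <ntaxa>' after xread")

  taxa <- character(0)
  rows <- list()   # per taxon: character vector of cell strings accumulated
  i <- k + 3L
  while (i <= length(toks)) {
    tk <- toks[i]
    if (tk == ";" ) break
    if (grepl(";$", tk)) { toks[i] <- sub(";$", "", tk); tk <- toks[i]; toks <- append(toks, ";", after = i); tok_line <- append(tok_line, tok_line[i], after = i) }
    if (!nzchar(tk)) { i <- i + 1L; next }
    name <- tk
    if (i + 1L > length(toks) || toks[i + 1L] == ";")
      stop("parse error at line ", tok_line[i], ": taxon '", name, "' has no character data")
    states <- toks[i + 1L]
    cells <- split_tnt_states(states, tok_line[i + 1L])
    if (!(name %in% taxa)) {
      taxa <- c(taxa, name)
      rows[[name]] <- cells
    } else {
      rows[[name]] <- c(rows[[name]], cells)
    }
    i <- i + 2L
  }
  if (length(taxa) != n_taxa)
    stop("parse error: header declares ", n_taxa, " taxa but ", length(taxa), " were read")
  lens <- vapply(rows, length, 1L)
  if (any(lens != n_char))
    stop("parse error: ragged rows; taxon '", taxa[which(lens != n_char)[1L]],
         "' has ", lens[which(lens != n_char)[1L]], " characters, expected ", n_char)

  cells <- lapply(taxa, function(tx) lapply(rows[[tx]], tnt_cell_states))
  character_matrix(cells, taxa)
}

# split a contiguous state string into per-character cell strings
split_tnt_states <- function(s, line) {
  out <- character(0)
  chars <- strsplit(s, "")[[1]]
  j <- 1L
  while (j <= length(chars)) {
    c0 <- chars[j]
    if (c0 %in% c("[", "{")) {
      close <- if (c0 == "[") "]" else "}"
      k <- j + 1L
      while (k <= length(chars) && chars[k] != close) k <- k + 1L
      if (k > length(chars)) stop("parse error at line ", line, ": unclosed '", c0, "' bracket")
      out <- c(out, paste(chars[j:k], collapse = ""))
      j <- k + 1L
    } else {
      out <- c(out, c0)
      j <- j + 1L
    }
  }
  out
}

tnt_state_symbol <- function(ch) {
  v <- suppressWarnings(as.integer(ch))
  if (!is.na(v)) return(v)
  v <- match(toupper(ch), LETTERS)
  if (!is.na(v)) return(v + 9L)
  stop("parse error: undeclared state symbol '", ch, "'")
}

tnt_cell_states <- function(cell) {
  if (cell %in% c("?", "-")) return(NA)
  if (substr(cell, 1L, 1L) %in% c("[", "{")) {
    inner <- substr(cell, 2L, nchar(cell) - 1L)
    syms <- strsplit(inner, "")[[1]]
    syms <- syms[nzchar(trimws(syms))]
    if (length(syms) == 0L) stop("parse error: empty polymorphic bracket")
    return(vapply(syms, tnt_state_symbol, 1L, USE.NAMES = FALSE))
  }
  tnt_state_symbol(cell)
}

#' Write a character matrix in TNT xread format
#' @param m a \code{\link{character_matrix}}
#' @param path output file
#' @return invisibly, the path
#' @export
write_tnt_matrix <- function(m, path) {
  sym <- function(s) if (s < 10L) as.character(s) else LETTERS[s - 9L]
  full <- bitwShiftL(1L, m$state_count) - 1L
  lines <- c("xread", paste(m$n_char, length(m$taxa)))
  for (i in seq_along(m$taxa)) {
    cells <- vapply(seq_len(m$n_char), function(j) {
      mk <- m$mask[i, j]
      if (mk == full[j]) return("?")
      st <- mask_to_states(mk)
      if (length(st) == 1L) sym(st) else paste0("[", paste(vapply(st, sym, ""), collapse = ""), "]")
    }, "")
    lines <- c(lines, paste(gsub("\\s", "_", m$taxa[i]), paste(cells, collapse = "")))
  }
  lines <- c(lines, ";")
  writeLines(lines, path)
  invisible(path)
}

#' Read a list of 1-based character indices (one or more per line)
#' @param path text file of integers; blank lines and \code{#} comments allowed
#' @return sorted integer vector
#' @export
read_character_indices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- unlist(strsplit(lines, "[,[:space:]]+"))
  toks <- toks[nzchar(toks)]
  idx <- suppressWarnings(as.integer(toks))
  if (anyNA(idx)) stop("non-integer entry in ", path)
  sort(unique(idx))
}

#' Read a tip-age table
#'
#' TSV sidecar with columns \code{taxon}, \code{mean} and optional
#' \code{min}, \code{max} (all ages in Mya, positive; \code{min <= mean <= max}).
#'
#' @param path TSV file
#' @return data.frame with columns taxon, mean, min, max
#' @export
read_tip_ages <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "mean") %in% names(d))) stop("tip age table needs columns 'taxon' and 'mean'")
  if (is.null(d$min)) d$min <- d$mean
  if (is.null(d$max)) d$max <- d$mean
  if (any(d$mean <= 0)) stop("tip ages must be positive")
  if (any(d$min > d$mean | d$mean > d$max)) stop("tip age ranges must satisfy min <= mean <= max")
  if (anyDuplicated(d$taxon)) stop("duplicate taxa in tip age table")
  d[, c("taxon", "mean", "min", "max")]
}

#' Serialize a tree to Newick
#'
#' Sampled ancestors are serialized by the zero-length-leaf convention: a
#' flagged fossil appears as a terminal with branch length 0 attached at its
#' host node. Node ages, when present as attribute \code{node_ages}, are
#' encoded through the branch lengths (duration = parent age - child age).
#'
#' @param tree an \code{ape::phylo} (possibly with \code{sampled_ancestor}
#'   and \code{node_ages} attributes)
#' @param with_lengths include branch lengths
#' @return a Newick string
#' @export
write_newick <- function(tree, with_lengths = TRUE) {
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("all leaves must be labelled")
  ages <- attr(tree, "node_ages")
  if (!is.null(ages)) {
    tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  }
  if (!with_lengths) tree$edge.length <- NULL
  ape::write.tree(tree)
}

#' Read a Newick tree
#'
#' The inverse of \code{\link{write_newick}}. If \code{tip_ages} (a named
#' vector, Mya) is given, node ages are reconstructed from the branch
#' lengths and attached as attribute \code{node_ages}; terminals with
#' zero-length subtending branches are flagged as sampled ancestors
#' (attribute \code{sampled_ancestor}, logical per tip).
#'
#' @param text Newick string (or use \code{file})
#' @param file optional path
#' @param tip_ages optional named numeric vector of tip ages (Mya)
#' @param sa_tol tolerance for the zero-length sampled-ancestor convention
#' @return an \code{ape::phylo}
#' @export
read_newick <- function(text = NULL, file = NULL, tip_ages = NULL, sa_tol = 1e-8) {
  tree <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  if (!is.null(tip_ages) && !is.null(tree$edge.length)) {
    n <- length(tree$tip.label)
    depth <- ape::node.depth.edgelength(tree)
    # age(x) = root_age - depth(x); root_age chosen so an anchor tip hits its age
    anchor <- match(names(tip_ages), tree$tip.label)
    ok <- which(!is.na(anchor))
    if (length(ok) == 0L) stop("tip_ages match no leaf labels")
    root_age <- unname(tip_ages[ok[1L]]) + depth[anchor[ok[1L]]]
    ages <- root_age - depth
    attr(tree, "node_ages") <- ages
    term_edge <- match(seq_len(n), tree$edge[, 2])
    sa <- tree$edge.length[term_edge] <= sa_tol
    attr(tree, "sampled_ancestor") <- sa
  }
  tree
}

#' Read a clade-definition registry (JSON)
#'
#' Schema: an array of objects \code{\{name, type: "node"|"branch",
#' internal: [taxon | \{node_of: [taxa]\}], external: [...], authorship\}}.
#'
#' @param path JSON file
#' @return list of \code{\link{phylo_definition}} objects
#' @export
read_definitions <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(d) {
    if (is.null(d$name) || is.null(d$type))
      stop("definition registry schema error: every entry needs 'name' and 'type'")
    parse_spec <- function(s) {
      if (is.character(s)) return(s)
      if (is.list(s) && !is.null(s$node_of)) return(node_of(unlist(s$node_of)))
      stop("schema error in definition '", d$name, "': bad specifier")
    }
    phylo_definition(
      name = d$name,
      kind = d$type,
      internal = lapply(d$internal, parse_spec),
      external = lapply(if (is.null(d$external)) list() else d$external, parse_spec),
      authorship = if (is.null(d$authorship)) "" else d$authorship
    )
  })
}

#' Read a specifier proxy map
#'
#' TSV with columns \code{specifier}, \code{otu}: maps specifier species
#' that are absent from the matrix OTUs onto the OTU label that stands for
#' them (an \code{otu} of \code{NONE} marks an explicitly unresolvable
#' specifier).
#'
#' @param path TSV file
#' @return named character vector (specifier -> OTU)
#' @export
read_proxy_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("specifier", "otu") %in% names(d))) stop("proxy map needs columns 'specifier' and 'otu'")
  stats::setNames(d$otu, d$specifier)
}
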