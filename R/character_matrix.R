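#' Discrete morphological character matrix
#'
#' The central data container: an OTU-by-character matrix of discrete state
#' sets. Cells are stored internally as integer bitmasks (bit \code{s} set
#' means state \code{s} is compatible with the observation), which makes
#' set-based (Fitch) parsimony bit-parallel across characters. A fully
#' ambiguous cell (\code{?} or \code{-} in TNT notation) carries all bits of
#' its character's state space.
#'
#' @param cells list of length \code{n_taxa}; each element a list of integer
#'   vectors (observed state sets, e.g. \code{c(0L, 1L)} for a polymorphic
#'   cell) or \code{NA} for full ambiguity.
#' @param taxa character vector of unique OTU labels.
#' @param weight per-character non-negative weights (recycled).
#' @param active per-character logical (recycled).
#' @return an object of class \code{character_matrix} with fields
#'   \code{taxa}, \code{mask} (n_taxa x n_char integer bitmask matrix),
#'   \code{n_char}, \code{state_count}, \code{weight}, \code{active}.
#' @export
character_matrix <- function(cells, taxa, weight = 1, active = TRUE) {
  if (anyDuplicated(taxa)) stop("taxon labels must be unique")
  n_taxa <- length(taxa)
  if (length(cells) != n_taxa) stop("cells must have one entry per taxon")
  n_char <- length(cells[[1L]])
  if (any(vapply(cells, length, 1L) != n_char))
    stop("ragged matrix: all taxa must score the same number of characters")

  max_state <- rep(-1L, n_char)
  for (i in seq_len(n_taxa)) {
    row <- cells[[i]]
    for (j in seq_len(n_char)) {
      st <- row[[j]]
      if (length(st) == 0L) stop("empty state set at taxon ", taxa[i], ", character ", j)
      if (length(st) == 1L && is.na(st)) next
      st <- as.integer(st)
      if (any(st < 0L)) stop("negative state at taxon ", taxa[i], ", character ", j)
      if (any(st > 30L)) stop("states above 30 not supported (bitmask encoding)")
      max_state[j] <- max(max_state[j], st)
    }
  }
  state_count <- pmax(max_state + 1L, 1L)

  mask <- matrix(0L, n_taxa, n_char, dimnames = list(taxa, NULL))
  full <- as.integer(bitwShiftL(1L, state_count) - 1L)
  for (i in seq_len(n_taxa)) {
    row <- cells[[i]]
    for (j in seq_len(n_char)) {
      st <- row[[j]]
      if (length(st) == 1L && is.na(st)) {
        mask[i, j] <- full[j]
      } else {
        m <- 0L
        for (s in as.integer(st)) m <- bitwOr(m, bitwShiftL(1L, s))
        mask[i, j] <- m
      }
    }
  }
  new_character_matrix(mask, taxa, state_count, weight, active)
}

new_character_matrix <- function(mask, taxa, state_count, weight = 1, active = TRUE) {
  n_char <- ncol(mask)
  structure(list(
    taxa = taxa,
    mask = mask,
    n_char = n_char,
    state_count = as.integer(state_count),
    weight = rep_len(as.numeric(weight), n_char),
    active = rep_len(as.logical(active), n_char)
  ), class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("character_matrix:", length(x$taxa), "taxa x", x$n_char, "characters\n")
  cat("  state counts:", paste(range(x$state_count), collapse = "-"),
      "| active:", sum(x$active), "\n")
  invisible(x)
}

#' Extract the state set of one cell
#' @param m a \code{character_matrix}
#' @param taxon taxon label or index
#' @param char 1-based character index
#' @return integer vector of states
#' @export
cell_states <- function(m, taxon, char) {
  i <- if (is.character(taxon)) match(taxon, m$taxa) else taxon
  mask_to_states(m$mask[i, char])
}

mask_to_states <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:30)) != 0L) - 1L
}

is_full_ambiguity <- function(m) {
  full <- matrix(rep(bitwShiftL(1L, m$state_count) - 1L, each = nrow(m$mask)),
                 nrow(m$mask), m$n_char)
  m$mask == full
}

#' Validate a character matrix for analysis
#' @param m a \code{character_matrix}
#' @param min_taxa minimum number of taxa required
#' @return invisibly \code{TRUE}; errors otherwise
#' @export
validate_matrix <- function(m, min_taxa = 4L) {
  stopifnot(inherits(m, "character_matrix"))
  if (length(m$taxa) < min_taxa) stop("need at least ", min_taxa, " taxa")
  if (!any(m$active)) stop("need at least one active character")
  if (any(m$weight < 0)) stop("character weights must be non-negative")
  invisible(TRUE)
}

#' Parsimony analysis settings
#'
#' Bundles the character-ordering assignment and the weighting criterion.
#' Ordered (additive) characters are scored with linear step costs
#' \code{|i - j|}; under implied weighting the search objective is the total
#' distortion \code{sum(h / (h + K))} of per-character homoplasy \code{h}.
#'
#' @param ordered 1-based indices of characters treated as additive.
#' @param weighting \code{"equal"} or \code{"implied"}.
#' @param K concavity constant (implied weighting only), positive.
#' @return object of class \code{parsimony_settings}
#' @export
parsimony_settings <- function(ordered = integer(0), weighting = c("equal", "implied"), K = 3) {
  weighting <- match.arg(weighting)
  ordered <- sort(unique(as.integer(ordered)))
  if (weighting == "implied" && K <= 0) stop("K must be positive")
  structure(list(ordered = ordered, weighting = weighting, K = K),
            class = "parsimony_settings")
}

is_ordered_char <- function(settings, n_char) {
  out <- logical(n_char)
  idx <- settings$ordered
  idx <- idx[idx >= 1L & idx <= n_char]
  out[idx] <- TRUE
  out
}

#' Restrict a matrix to a subset of taxa
#' @param m a \code{character_matrix}
#' @param keep taxon labels to keep
#' @return a \code{character_matrix} on the kept taxa (state counts preserved)
#' @export
subset_taxa <- function(m, keep) {
  idx <- match(keep, m$taxa)
  if (anyNA(idx)) stop("unknown taxa: ", paste(keep[is.na(idx)], collapse = ", "))
  new_character_matrix(m$mask[idx, , drop = FALSE], m$taxa[idx],
                       m$state_count, m$weight, m$active)
}

#' Resample characters with replacement (bootstrap pseudo-replicate)
#' @param m a \code{character_matrix}
#' @param idx character indices to take (defaults to a bootstrap resample of
#'   the active characters using the current RNG state)
#' @return a \code{character_matrix}
#' @export
resample_characters <- function(m, idx = NULL) {
  if (is.null(idx)) {
    act <- which(m$active)
    idx <- sample(act, length(act), replace = TRUE)
  }
  new_character_matrix(m$mask[, idx, drop = FALSE], m$taxa,
                       m$state_count[idx], m$weight[idx], m$active[idx])
}
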