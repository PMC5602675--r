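#' @name posterior
#' @title Posterior summaries: MCCT, consensus, SA histogram, ESS
NULL

#' Drop burn-in from a posterior sample
#' @param sample a \code{posterior_sample}
#' @param burnin fraction to discard (default: the run's configured value)
#' @return a \code{posterior_sample}
#' @export
discard_burnin <- function(sample, burnin = NULL) {
  if (is.null(burnin)) burnin <- sample$cfg$burnin_fraction
  n <- nrow(sample$params)
  keep <- seq.int(floor(burnin * n) + 1L, n)
  sample$params <- sample$params[keep, , drop = FALSE]
  sample$trees <- sample$trees[keep]
  sample
}

#' Posterior clade frequencies of a tree sample
#' @param trees list of \code{\link{dated_tree}}
#' @return data.frame: clade (";"-joined taxa), freq
#' @export
posterior_clade_freqs <- function(trees) {
  counts <- new.env(parent = emptyenv())
  for (dt in trees) {
    for (cl in unique(clade_table(dt))) {
      counts[[cl]] <- (if (is.null(counts[[cl]])) 0L else counts[[cl]]) + 1L
    }
  }
  keys <- ls(counts)
  data.frame(clade = keys,
             freq = vapply(keys, function(k) counts[[k]], 1L) / length(trees),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior probability of one clade
#' @param sample a \code{posterior_sample} (burn-in should be removed first)
#' @param clade character vector of taxa
#' @return proportion of sampled trees containing the clade
#' @export
clade_posterior_probability <- function(sample, clade) {
  key <- paste(sort(clade), collapse = ";")
  mean(vapply(sample$trees, function(dt) key %in% clade_table(dt), TRUE))
}

#' Maximum clade credibility tree
#'
#' The sampled tree maximizing the product of its clades' posterior
#' frequencies. Node ages are annotated with the mean and central 95%
#' interval of the clade's age across the samples containing it.
#'
#' @param sample a \code{posterior_sample} (apply
#'   \code{\link{discard_burnin}} first)
#' @return list: \code{tree} (the winning \code{dated_tree}),
#'   \code{phylo}, \code{score} (sum of log clade frequencies),
#'   \code{clade_ages} (data.frame: clade, freq, age_mean, age_lo, age_hi)
#' @export
mcct <- function(sample) {
  trees <- sample$trees
  if (length(trees) == 0L) stop("empty post-burn-in sample")
  fr <- posterior_clade_freqs(trees)
  freq_of <- stats::setNames(fr$freq, fr$clade)
  ages <- new.env(parent = emptyenv())
  for (dt in trees) {
    ct <- clade_table(dt)
    ag <- dt$age[-seq_len(dt$n_tip)]
    for (i in seq_along(ct)) ages[[ct[i]]] <- c(ages[[ct[i]]], ag[i])
  }
  scores <- vapply(trees, function(dt) sum(log(freq_of[unique(clade_table(dt))])), 1)
  best <- which.max(scores)
  dt <- trees[[best]]
  ct <- unique(clade_table(dt))
  clade_ages <- do.call(rbind, lapply(ct, function(k) {
    a <- ages[[k]]
    data.frame(clade = k, freq = freq_of[[k]], age_mean = mean(a),
               age_lo = unname(stats::quantile(a, 0.025)),
               age_hi = unname(stats::quantile(a, 0.975)))
  }))
  list(tree = dt, phylo = dated_to_phylo(dt), score = scores[best],
       clade_ages = clade_ages)
}

#' Half-compact (majority-rule) consensus of posterior topologies
#'
#' The 50%-majority-rule consensus of the post-burn-in sampled trees,
#' with clade frequencies annotated.
#'
#' @param sample a \code{posterior_sample}
#' @param cutoff retention threshold (default 0.5)
#' @return rooted \code{phylo} with frequency node labels
#' @export
half_compact_consensus <- function(sample, cutoff = 0.5) {
  trees <- sample$trees
  fr <- posterior_clade_freqs(trees)
  taxa <- sort(trees[[1L]]$labels)
  keep <- fr[fr$freq > cutoff, , drop = FALSE]
  cl <- strsplit(keep$clade, ";", fixed = TRUE)
  full <- vapply(cl, function(x) length(x) >= length(taxa), TRUE)
  tree_from_clades(cl[!full], taxa,
                   labels = formatC(keep$freq[!full], digits = 3, format = "f"))
}

#' Histogram of sampled-ancestor counts
#'
#' Per sampled tree, the number of fossils flagged as sampled ancestors;
#' returns the frequency table and the central 95% interval.
#'
#' @param sample a \code{posterior_sample}
#' @return list: \code{counts} (named table proportions), \code{interval}
#'   (length-2 integer vector), \code{mode}
#' @export
sampled_ancestor_histogram <- function(sample) {
  k <- vapply(sample$trees, count_sampled_ancestors, 1L)
  tab <- table(factor(k, levels = 0:max(max(k), 1L)))
  prop <- tab / sum(tab)
  iv <- unname(stats::quantile(k, c(0.025, 0.975), type = 1L))
  list(counts = prop, interval = as.integer(iv),
       mode = as.integer(names(prop)[which.max(prop)]))
}

#' Effective sample size of an MCMC trace
#'
#' Autocorrelation-time estimate using Geyer-style initial positive pair
#' sums: \code{ESS = N / tau} with \code{tau = 1 + 2 sum(rho_k)} truncated
#' at the first non-positive even-odd pair sum. A constant trace returns
#' the sample count with attribute \code{degenerate = TRUE}; negative
#' autocorrelation can yield ESS above N.
#'
#' @param x numeric trace (>= 10 values for a meaningful estimate)
#' @return ESS estimate (numeric)
#' @export
ess <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("trace too short")
  v <- stats::var(x)
  if (v == 0) return(structure(n, degenerate = TRUE))
  ac <- stats::acf(x, lag.max = min(n - 2L, 2000L), plot = FALSE)$acf[-1L]
  tau <- 1
  m <- 1L
  while (m + 1L <= length(ac)) {
    pair <- ac[m] + ac[m + 1L]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    m <- m + 2L
  }
  if (m == 1L && length(ac) >= 1L && ac[1L] < 0) tau <- max(1 + 2 * ac[1L], 1e-3)
  n / tau
}
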