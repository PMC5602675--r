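#' Mk substitution model settings
#'
#' The symmetric k-state Markov model for discrete morphology (equal
#' exchange rates, uniform stationary frequencies), with discrete-gamma
#' rate variation across characters and optional conditioning on characters
#' being variable (the ascertainment correction for matrices that exclude
#' constant characters).
#'
#' @param gamma_shape shape of the across-character gamma rate distribution
#' @param n_gamma number of discrete gamma categories (quantile midpoints)
#' @param condition_on_variable apply the variable-characters-only
#'   correction per character (using that character's state count)
#' @return an \code{mk_model}
#' @export
mk_model <- function(gamma_shape = 1, n_gamma = 4L, condition_on_variable = TRUE) {
  stopifnot(gamma_shape > 0, n_gamma >= 1L)
  structure(list(gamma_shape = gamma_shape, n_gamma = as.integer(n_gamma),
                 condition_on_variable = condition_on_variable), class = "mk_model")
}

gamma_category_rates <- function(shape, n) {
  if (n == 1L) return(1)
  r <- stats::qgamma((seq_len(n) - 0.5) / n, shape = shape, rate = shape)
  r / mean(r)
}

# k-state symmetric transition probabilities at branch "length" (expected
# substitutions) v: p_same and p_diff
mk_pmat <- function(k, v) {
  e <- exp(-k * v / (k - 1))
  p_diff <- (1 - e) / k
  p_same <- 1 / k + (k - 1) / k * e
  m <- matrix(p_diff, k, k)
  diag(m) <- p_same
  m
}

#' Mk (Lewis) log-likelihood on a dated tree
#'
#' Felsenstein pruning over the active characters, summed over gamma
#' categories with equal weights. Ambiguous cells contribute partial
#' likelihood 1 over their state set. With
#' \code{model$condition_on_variable}, each character's likelihood is
#' divided by the probability of being variable for its own state count:
#' \code{L_var = L / (1 - sum_s L_const(s))}.
#'
#' @param dt a \code{\link{dated_tree}} (zero-length sampled-ancestor
#'   attachments allowed)
#' @param m a \code{\link{character_matrix}}; taxa must cover the tips
#' @param model an \code{\link{mk_model}}
#' @param rates branch rates (expected substitutions per My): scalar or a
#'   vector indexed by child node (length \code{2n-1})
#' @return total log-likelihood (finite, or an error naming the offending
#'   character)
#' @export
mk_log_likelihood <- function(dt, m, model = mk_model(), rates = 1) {
  cols <- which(m$active)
  idx <- match(dt$labels, m$taxa)
  if (anyNA(idx)) stop("tip absent from matrix: ", dt$labels[which(is.na(idx))[1L]])
  durs <- branch_durations(dt)
  if (length(rates) == 1L) rates <- rep(rates, length(durs))
  v_branch <- durs * rates                 # expected substitutions per branch
  po <- dated_postorder(dt)
  ch <- children_of(dt)
  grates <- gamma_category_rates(model$gamma_shape, model$n_gamma)
  kvals <- pmax(m$state_count[cols], 2L)
  total <- 0
  for (k in sort(unique(kvals))) {
    cc <- cols[kvals == k]
    nc <- length(cc)
    tipmask <- m$mask[idx, cc, drop = FALSE]
    tip_part <- vector("list", dt$n_tip)
    for (v in seq_len(dt$n_tip)) {
      P <- matrix(0, k, nc)
      mk <- tipmask[v, ]
      for (s in seq_len(k)) P[s, bitwAnd(mk, bitwShiftL(1L, s - 1L)) != 0L] <- 1
      tip_part[[v]] <- P
    }
    lik_sum <- numeric(nc)                     # sum over gamma cats of L_char
    const_sum <- numeric(k)                    # same for each constant pattern
    for (g in grates) {
      lik_sum <- lik_sum + mk_prune(dt, po, ch, tip_part, k, v_branch * g)
      if (model$condition_on_variable) {
        const_sum <- const_sum + mk_prune_const(dt, po, ch, k, v_branch * g)
      }
    }
    lik_sum <- lik_sum / length(grates)
    const_sum <- const_sum / length(grates)
    if (model$condition_on_variable) {
      p_var <- 1 - sum(const_sum)
      if (p_var <= 0) stop("variable-character conditioning degenerate for k = ", k)
      lik_sum <- lik_sum / p_var
    }
    if (any(!is.finite(log(lik_sum))))
      stop("non-finite Mk likelihood at character ", cc[which(!is.finite(log(lik_sum)))[1L]])
    total <- total + sum(log(lik_sum))
  }
  total
}

# pruning for one gamma category (state count k); per-character likelihood.
# No per-node rescaling: per-character products stay within double range for
# the desk-scale trees this sampler targets (dozens of tips).
mk_prune <- function(dt, po, ch, tip_part, k, v_branch) {
  n <- dt$n_tip
  partial <- tip_part
  length(partial) <- length(dt$parent)
  for (v in po) {
    if (v > n) {
      kids <- ch[[v]]
      partial[[v]] <- (mk_pmat(k, v_branch[kids[1L]]) %*% partial[[kids[1L]]]) *
        (mk_pmat(k, v_branch[kids[2L]]) %*% partial[[kids[2L]]])
    }
  }
  .colMeans(partial[[dt$root]], k, ncol(partial[[dt$root]]))  # uniform root freqs
}

# likelihood of each all-tips-constant pattern (state s), one column per s
mk_prune_const <- function(dt, po, ch, k, v_branch) {
  n <- dt$n_tip
  partial <- vector("list", length(dt$parent))
  I <- diag(k)
  for (v in po) {
    if (v <= n) {
      partial[[v]] <- I                       # column s = indicator of state s
    } else {
      kids <- ch[[v]]
      partial[[v]] <- (mk_pmat(k, v_branch[kids[1L]]) %*% partial[[kids[1L]]]) *
        (mk_pmat(k, v_branch[kids[2L]]) %*% partial[[kids[2L]]])
    }
  }
  .colMeans(partial[[dt$root]], k, k)
}
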