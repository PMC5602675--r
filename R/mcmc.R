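#' @name tip_dating
#' @title Bayesian tip dating under Mk + FBDSA
#' @description
#' Metropolis-Hastings sampler over dated trees with sampled ancestors and
#' model parameters. The posterior combines the Mk likelihood conditioned
#' on variable characters (discrete-gamma rate variation across characters,
#' discretized lognormal relaxed clock across branches with \code{n-1}
#' categories for \code{n} branches), the constant-rate fossilized
#' birth-death sampled-ancestor tree prior conditional on the origin time
#' (\eqn{\rho = 0}), and the parameter priors. Moves: multiplier moves on
#' \eqn{\lambda, \mu, \psi}, the base clock rate, the clock scale and the
#' gamma shape; uniform node-age and origin slides; branch rate-category
#' reassignment; sampled-ancestor toggles (reversible jump); and dated SPR
#' for topology.
NULL

#' MCMC configuration for tip dating
#'
#' @param generations number of move attempts
#' @param sample_interval record every this many generations
#' @param burnin_fraction fraction of samples discarded by summaries
#' @param seed RNG seed
#' @param tree_prior \code{"fbdsa"} or \code{"reference"} (uniform relative
#'   node ages given the root age; used for prior-validation runs)
#' @param likelihood include the Mk likelihood (switch off to sample the
#'   prior)
#' @param fixed_topology disable topology and SA moves
#' @param fixed_ages disable node-age and origin moves
#' @param max_root_age upper bound of the uniform origin/root-age prior (Mya)
#' @param clock_rate_prior_mean,clock_scale_prior_mean,rate_prior_mean,
#'   alpha_prior_mean exponential prior means
#' @return an \code{mcmc_config}
#' @export
mcmc_config <- function(generations = 100000L, sample_interval = 500L,
                        burnin_fraction = 0.2, seed = 1L,
                        tree_prior = c("fbdsa", "reference"),
                        likelihood = TRUE, fixed_topology = FALSE,
                        fixed_ages = FALSE, max_root_age = 200,
                        rate_prior_mean = 1, clock_rate_prior_mean = 0.1,
                        clock_scale_prior_mean = 0.3, alpha_prior_mean = 1) {
  tree_prior <- match.arg(tree_prior)
  structure(as.list(environment()), class = "mcmc_config")
}

# lognormal relaxed-clock branch multipliers: quantile midpoints of
# LogNormal(-s^2/2, s) (mean 1), n-1 categories for n branches
clock_multipliers <- function(s, n_cat) {
  if (n_cat < 1L) n_cat <- 1L
  stats::qlnorm((seq_len(n_cat) - 0.5) / n_cat, meanlog = -s^2 / 2, sdlog = s)
}

tip_dating_state <- function(dt, cfg) {
  n_branch <- 2L * dt$n_tip - 2L
  list(dt = dt, lambda = 0.1, mu = 0.05, psi = 0.05,
       clock_rate = 0.05, clock_s = 0.3, alpha = 1,
       cat = rep(1L, length(dt$parent)),    # per-node (branch above); root unused
       n_cat = max(n_branch - 1L, 1L))
}

state_rates <- function(st) {
  mult <- clock_multipliers(st$clock_s, st$n_cat)
  r <- st$clock_rate * mult[pmin(st$cat, st$n_cat)]
  r[st$dt$root] <- st$clock_rate
  r
}

state_log_prior <- function(st, cfg, t0) {
  lp <- stats::dexp(st$lambda, 1 / cfg$rate_prior_mean, log = TRUE) +
    stats::dexp(st$mu, 1 / cfg$rate_prior_mean, log = TRUE) +
    stats::dexp(st$psi, 1 / cfg$rate_prior_mean, log = TRUE) +
    stats::dexp(st$clock_rate, 1 / cfg$clock_rate_prior_mean, log = TRUE) +
    stats::dexp(st$clock_s, 1 / cfg$clock_scale_prior_mean, log = TRUE) +
    stats::dexp(st$alpha, 1 / cfg$alpha_prior_mean, log = TRUE)
  if (cfg$tree_prior == "fbdsa") {
    if (st$dt$origin < st$dt$age[st$dt$root] || st$dt$origin > cfg$max_root_age) return(-Inf)
    lp <- lp - log(cfg$max_root_age - t0)   # uniform origin prior
  } else {
    ra <- st$dt$age[st$dt$root]
    if (ra > cfg$max_root_age) return(-Inf)
    n_int_free <- st$dt$n_tip - 2L          # non-root internal nodes
    lp <- lp - log(cfg$max_root_age - t0) - n_int_free * log(ra - t0)
  }
  lp
}

state_tree_prior <- function(st, cfg) {
  if (cfg$tree_prior == "fbdsa") {
    fbd_sa_log_prior(st$dt, fbd_params(st$lambda, st$mu, st$psi, st$dt$origin))
  } else 0
}

state_loglik <- function(st, m, model, cfg) {
  if (!cfg$likelihood) return(0)
  mod <- mk_model(st$alpha, model$n_gamma, model$condition_on_variable)
  mk_log_likelihood(st$dt, m, mod, rates = state_rates(st))
}

#' Run the tip-dating MCMC
#'
#' @param m a \code{\link{character_matrix}} of the fossil tips
#' @param tip_ages named numeric vector (Mya, positive: extant tips are
#'   rejected under \eqn{\rho = 0})
#' @param cfg an \code{\link{mcmc_config}}
#' @param model an \code{\link{mk_model}} (its gamma shape is the sampled
#'   parameter's initial value)
#' @param start_tree optional \code{\link{dated_tree}} start state
#' @return a \code{posterior_sample}: list(params data.frame, trees list of
#'   \code{dated_tree}, cfg, acceptance rates)
#' @export
tip_dating_mcmc <- function(m, tip_ages, cfg = mcmc_config(), model = mk_model(),
                            start_tree = NULL) {
  set.seed(cfg$seed)
  tip_ages <- tip_ages[m$taxa]
  if (anyNA(tip_ages)) stop("tip_ages must cover all matrix taxa")
  if (any(tip_ages <= 0)) stop("extant (age-0) tips are invalid under rho = 0")
  t0 <- max(tip_ages)                       # oldest tip bounds the root below
  dt <- if (is.null(start_tree)) init_dated_tree(m$taxa, tip_ages, cfg$max_root_age) else start_tree
  st <- tip_dating_state(dt, cfg)
  st$alpha <- model$gamma_shape
  cur_lik <- state_loglik(st, m, model, cfg)
  cur_tp <- state_tree_prior(st, cfg)
  cur_pr <- state_log_prior(st, cfg, t0)
  if (!is.finite(cur_lik + cur_tp + cur_pr))
    stop("non-finite posterior at initialization: loglik=", cur_lik,
         " treeprior=", cur_tp, " prior=", cur_pr)
  move_names <- c("lambda", "mu", "psi", "clock_rate", "clock_s", "alpha",
                  "node_age", "origin", "category", "sa_toggle", "spr")
  w <- c(1, 1, 1, 1, 1, 1, 4, 1, 2, 2, 3)
  if (cfg$fixed_topology) w[match(c("sa_toggle", "spr"), move_names)] <- 0
  if (cfg$fixed_ages) w[match(c("node_age", "origin"), move_names)] <- 0
  if (!cfg$likelihood) w[match(c("clock_rate", "clock_s", "alpha", "category"), move_names)] <-
    if (cfg$tree_prior == "fbdsa") 1 else 0
  acc <- att <- stats::setNames(numeric(length(move_names)), move_names)
  n_samp <- floor(cfg$generations / cfg$sample_interval)
  params <- matrix(NA_real_, n_samp, 11,
                   dimnames = list(NULL, c("gen", "lambda", "mu", "psi", "clock_rate",
                                           "clock_s", "alpha", "origin", "root_age",
                                           "loglik", "n_sa")))
  trees <- vector("list", n_samp)
  si <- 0L
  for (gen in seq_len(cfg$generations)) {
    mv <- sample(move_names, 1L, prob = w)
    att[mv] <- att[mv] + 1L
    prop <- propose_move(st, mv, cfg, t0)
    if (!is.null(prop)) {
      st2 <- prop$state
      lik2 <- if (prop$lik_changed) state_loglik(st2, m, model, cfg) else cur_lik
      tp2 <- if (prop$tree_changed || mv %in% c("lambda", "mu", "psi", "origin"))
        state_tree_prior(st2, cfg) else cur_tp
      pr2 <- state_log_prior(st2, cfg, t0)
      la <- (lik2 + tp2 + pr2) - (cur_lik + cur_tp + cur_pr) + prop$log_hastings
      if (is.finite(la) && log(stats::runif(1L)) < la) {
        st <- st2; cur_lik <- lik2; cur_tp <- tp2; cur_pr <- pr2
        acc[mv] <- acc[mv] + 1L
      }
    }
    if (gen %% cfg$sample_interval == 0L) {
      si <- si + 1L
      params[si, ] <- c(gen, st$lambda, st$mu, st$psi, st$clock_rate, st$clock_s,
                        st$alpha, st$dt$origin, st$dt$age[st$dt$root],
                        cur_lik, sum(st$dt$sa))
      trees[[si]] <- st$dt
    }
  }
  structure(list(params = as.data.frame(params[seq_len(si), , drop = FALSE]),
                 trees = trees[seq_len(si)], cfg = cfg,
                 acceptance = ifelse(att > 0, acc / att, NA)),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("posterior_sample:", nrow(x$params), "samples,",
      x$cfg$generations, "generations\n")
  invisible(x)
}

# sequential random start tree compatible with the tip ages
init_dated_tree <- function(taxa, tip_ages, max_age) {
  n <- length(taxa)
  ord <- order(tip_ages)                    # youngest first
  parent <- integer(2L * n - 1L)
  age <- numeric(2L * n - 1L)
  age[seq_len(n)] <- tip_ages
  cur_root <- ord[1L]
  cur_age <- tip_ages[ord[1L]]
  nexti <- n
  for (i in seq_len(n - 1L)) {
    tip <- ord[i + 1L]
    nexti <- nexti + 1L
    new_age <- max(cur_age, tip_ages[tip]) + stats::rexp(1L, 0.5) + 0.5
    parent[cur_root] <- nexti
    parent[tip] <- nexti
    age[nexti] <- new_age
    cur_root <- nexti
    cur_age <- new_age
  }
  origin <- min(cur_age + stats::rexp(1L, 0.2) + 1, max_age)
  dated_tree(parent, age, taxa, origin = max(origin, cur_age))
}

# ---- proposals ------------------------------------------------------------

scale_move <- function(x, delta = 0.7) {
  u <- stats::runif(1L, -delta, delta)
  list(value = x * exp(u), log_hastings = u)
}

propose_move <- function(st, mv, cfg, t0) {
  dt <- st$dt
  switch(mv,
    lambda = { p <- scale_move(st$lambda); st$lambda <- p$value
               list(state = st, log_hastings = p$log_hastings, lik_changed = FALSE, tree_changed = FALSE) },
    mu = { p <- scale_move(st$mu); st$mu <- p$value
           list(state = st, log_hastings = p$log_hastings, lik_changed = FALSE, tree_changed = FALSE) },
    psi = { p <- scale_move(st$psi); st$psi <- p$value
            list(state = st, log_hastings = p$log_hastings, lik_changed = FALSE, tree_changed = FALSE) },
    clock_rate = { p <- scale_move(st$clock_rate); st$clock_rate <- p$value
                   list(state = st, log_hastings = p$log_hastings, lik_changed = TRUE, tree_changed = FALSE) },
    clock_s = { p <- scale_move(st$clock_s, 0.4); st$clock_s <- p$value
                list(state = st, log_hastings = p$log_hastings, lik_changed = TRUE, tree_changed = FALSE) },
    alpha = { p <- scale_move(st$alpha, 0.5); st$alpha <- p$value
              list(state = st, log_hastings = p$log_hastings, lik_changed = TRUE, tree_changed = FALSE) },
    category = {
      v <- sample(setdiff(seq_along(dt$parent), dt$root), 1L)
      st$cat[v] <- sample.int(st$n_cat, 1L)
      list(state = st, log_hastings = 0, lik_changed = TRUE, tree_changed = FALSE)
    },
    origin = {
      ra <- dt$age[dt$root]
      if (cfg$tree_prior != "fbdsa") return(NULL)
      dt$origin <- stats::runif(1L, ra, cfg$max_root_age)
      st$dt <- dt
      list(state = st, log_hastings = 0, lik_changed = FALSE, tree_changed = TRUE)
    },
    node_age = propose_node_age(st, cfg, t0),
    sa_toggle = propose_sa_toggle(st, cfg),
    spr = propose_spr(st, cfg)
  )
}

propose_node_age <- function(st, cfg, t0) {
  dt <- st$dt
  n <- dt$n_tip
  ch <- children_of(dt)
  locked <- unique(dt$parent[which(dt$sa)])
  cand <- setdiff((n + 1L):(2L * n - 1L), locked)
  if (!length(cand)) return(NULL)
  v <- if (length(cand) == 1L) cand else sample(cand, 1L)
  lo <- max(dt$age[ch[[v]]])
  hi <- if (v == dt$root) {
    if (cfg$tree_prior == "fbdsa") dt$origin else cfg$max_root_age
  } else dt$age[dt$parent[v]]
  if (hi <= lo) return(NULL)
  dt$age[v] <- stats::runif(1L, lo, hi)
  if (v == dt$root && cfg$tree_prior != "fbdsa") dt$origin <- dt$age[v]
  st$dt <- dt
  list(state = st, log_hastings = 0, lik_changed = TRUE, tree_changed = TRUE)
}

propose_sa_toggle <- function(st, cfg) {
  dt <- st$dt
  n <- dt$n_tip
  ch <- children_of(dt)
  i <- sample.int(n, 1L)
  p <- dt$parent[i]
  if (p == 0L) return(NULL)
  sib <- setdiff(ch[[p]], i)
  gp_age <- if (dt$parent[p] == 0L) dt$origin else dt$age[dt$parent[p]]
  if (!dt$sa[i]) {
    # fossil tip -> sampled ancestor: parent age collapses onto the tip age
    if (dt$sa[sib] && sib <= n) return(NULL)      # sibling already locks p
    if (dt$age[sib] >= dt$age[i]) return(NULL)    # sibling subtree too old
    lo <- max(dt$age[i], dt$age[sib]); hi <- gp_age
    if (hi <= lo) return(NULL)
    dt$age[p] <- dt$age[i]
    dt$sa[i] <- TRUE
    st$dt <- dt
    # RJ: the parent-age dimension is removed; the reverse move draws it
    # uniformly, so the ratio carries 1/(hi - lo)
    list(state = st, log_hastings = -log(hi - lo), lik_changed = TRUE, tree_changed = TRUE)
  } else {
    # sampled ancestor -> terminal fossil: redraw the parent age
    lo <- max(dt$age[i], dt$age[sib]); hi <- gp_age
    if (hi <= lo) return(NULL)
    dt$age[p] <- stats::runif(1L, lo, hi)
    dt$sa[i] <- FALSE
    st$dt <- dt
    list(state = st, log_hastings = log(hi - lo), lik_changed = TRUE, tree_changed = TRUE)
  }
}

spr_feasible_targets <- function(dt, v, p, cfg) {
  # edges (a, b) able to receive the pruned node p (with child subtree at v):
  # window (max(age_v, age_b), age_a) non-empty; b outside v's subtree; b != p
  n <- dt$n_tip
  sub <- v
  repeat {
    grow <- which(dt$parent %in% sub & !(seq_along(dt$parent) %in% sub))
    if (!length(grow)) break
    sub <- c(sub, grow)
  }
  ok <- list()
  for (b in seq_along(dt$parent)) {
    if (b %in% sub || b == p) next
    a <- dt$parent[b]
    if (a == p) next
    hi <- if (a == 0L) {
      if (cfg$tree_prior == "fbdsa") dt$origin else cfg$max_root_age
    } else dt$age[a]
    lo <- max(dt$age[v], dt$age[b])
    if (hi > lo + 1e-12) ok[[length(ok) + 1L]] <- c(b = b, lo = lo, hi = hi)
  }
  ok
}

propose_spr <- function(st, cfg) {
  dt <- st$dt
  n <- dt$n_tip
  ch <- children_of(dt)
  # eligible pruned subtrees: node v, parent p not root-locked, v not SA tip,
  # sibling not an SA tip (p age locked)
  cand <- which(dt$parent != 0L)
  cand <- cand[dt$parent[cand] != dt$root]
  cand <- setdiff(cand, which(dt$sa))
  keep <- vapply(cand, function(v) {
    sib <- setdiff(ch[[dt$parent[v]]], v)
    !(sib <= n && dt$sa[sib])
  }, TRUE)
  cand <- cand[keep]
  if (!length(cand)) return(NULL)
  v <- if (length(cand) == 1L) cand else sample(cand, 1L)
  p <- dt$parent[v]
  g <- dt$parent[p]
  sib <- setdiff(ch[[p]], v)
  # forward feasibility BEFORE detaching (state for reverse bookkeeping)
  dt2 <- dt
  dt2$parent[sib] <- g
  dt2$parent[p] <- -1L                      # temporarily detached marker
  targets <- spr_feasible_targets_detached(dt2, v, p, cfg)
  if (!length(targets)) return(NULL)
  pick <- targets[[if (length(targets) == 1L) 1L else sample.int(length(targets), 1L)]]
  b <- pick[["b"]]; lo <- pick[["lo"]]; hi <- pick[["hi"]]
  a <- dt2$parent[b]
  new_age <- stats::runif(1L, lo, hi)
  dt2$parent[p] <- a                        # 0 if b was the root
  dt2$parent[b] <- p
  dt2$age[p] <- new_age
  if (a == 0L) {
    dt2$root <- p
    if (cfg$tree_prior != "fbdsa") dt2$origin <- new_age
    else if (dt2$origin < new_age) return(NULL)
  } else if (dt$root == p) {
    dt2$root <- dt$root                     # unchanged (p was not root by construction)
  }
  # reverse move: prune v (parent p) in the new state, reattach on edge
  # (g, sib) [or stem if g == 0]
  dt3 <- dt2
  dt3$parent[sib] <- g
  dt3$parent[p] <- -1L
  rev_targets <- spr_feasible_targets_detached(dt3, v, p, cfg)
  rev_hit <- Filter(function(tg) tg[["b"]] == sib, rev_targets)
  if (!length(rev_hit)) return(NULL)
  rlo <- rev_hit[[1L]][["lo"]]; rhi <- rev_hit[[1L]][["hi"]]
  lh <- (log(length(targets)) + log(hi - lo)) - (log(length(rev_targets)) + log(rhi - rlo))
  st$dt <- dt2
  list(state = st, log_hastings = lh, lik_changed = TRUE, tree_changed = TRUE)
}

spr_feasible_targets_detached <- function(dt, v, p, cfg) {
  # dt has parent[p] == -1 (detached); find receivable edges incl. root stem
  sub <- v
  repeat {
    grow <- which(dt$parent %in% sub & !(seq_along(dt$parent) %in% sub))
    if (!length(grow)) break
    sub <- c(sub, grow)
  }
  root_now <- which(dt$parent == 0L)
  ok <- list()
  for (b in seq_along(dt$parent)) {
    if (b %in% sub || b == p) next
    a <- dt$parent[b]
    if (a == -1L) next
    hi <- if (a == 0L) {
      if (cfg$tree_prior == "fbdsa") dt$origin else cfg$max_root_age
    } else dt$age[a]
    lo <- max(dt$age[v], dt$age[b])
    if (hi > lo + 1e-12) ok[[length(ok) + 1L]] <- c(b = b, lo = lo, hi = hi)
  }
  ok
}
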