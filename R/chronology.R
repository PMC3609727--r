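# Penalized-likelihood chronogram estimation under a fixed root calibration.
#
# The model follows rate-smoothing dating: each branch j carries an expected
# substitution count x_j = b_j * L (b_j in substitutions/site, L sites) and a
# rate r_j (substitutions/site/Myr). Given node ages (tips at 0, root fixed
# at the calibration age) with branch durations tau_j, the objective is
#
#   Psi = sum_j [ x_j * ln(r_j * L * tau_j) - r_j * L * tau_j ]  -  lambda * Phi
#
# (Poisson log-likelihood up to the x! constant) where the roughness penalty
#
#   Phi = sum_{j: parent(j) not root} (ln r_j - ln r_parent(j))^2
#       + Var_pop({ ln r_k : k a child edge of the root })
#
# penalizes ancestor-descendant rate changes; the root's children, having no
# parent rate, are penalized through the population variance of their (log)
# rates. The penalty acts on LOG rates, i.e. on relative rate changes. This
# keeps the objective invariant under a rescaling of the time axis (dividing
# all rates by s shifts every log rate equally), which makes dating at a
# 20 Myr root exactly the 20/25-rescaled dating at a 25 Myr root, and it
# matches the lognormal rate-evolution model the synthetic-data generator
# uses. A penalty on raw rate differences would instead be numerically
# negligible whenever rates are small (r ~ 1e-4/Myr gives Phi ~ 1e-8),
# leaving node ages effectively non-identifiable.
# Optimization is done on transformed variables: log rates, and internal node
# ages expressed as fractions of the parent age (logistic-transformed), which
# enforces the age ordering by construction.

#' Penalized-likelihood configuration
#'
#' @param smoothing Penalty weight lambda >= 0 (default 1). The smoothing
#'   value used by the original analysis is unstated, so 1 is the package
#'   default and is exposed everywhere.
#' @param seq_length Number of alignment sites L used to convert per-site
#'   branch lengths to substitution counts (>= 1).
#' @param min_duration Floor on branch durations in Myr; `NULL` (default)
#'   resolves to `1e-6 * root_age` at fit time, protecting the `ln(tau)` term
#'   against zero-length branches.
#' @param tol Convergence tolerance of the optimizer (relative).
#' @param max_iter Maximum optimizer iterations per restart.
#' @param n_restarts Number of deterministic restarts (>= 1); restart 1 is
#'   the clock initialization, later restarts are seeded perturbations of it.
#' @param seed Integer seed driving the restart perturbations.
#' @return An object of class `pl_config`.
#' @export
pl_config <- function(smoothing = 1, seq_length = 1000L, min_duration = NULL,
                      tol = 1e-12, max_iter = 2000L, n_restarts = 5L,
                      seed = 0L) {
  stopifnot(smoothing >= 0, seq_length >= 1,
            is.null(min_duration) || min_duration > 0,
            tol > 0, max_iter >= 1, n_restarts >= 1)
  structure(list(smoothing = smoothing, seq_length = as.integer(seq_length),
                 min_duration = min_duration, tol = tol,
                 max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "pl_config")
}

#' Secondary root calibration
#'
#' A fixed root age taken from a previously dated phylogeny, with the 95%
#' confidence interval of that external estimate (used for linear CI
#' propagation to clade ages).
#'
#' @param root_age Root age in Myr (> 0).
#' @param ci_low,ci_high 95% CI bounds of the calibration, `ci_low <=
#'   root_age <= ci_high`; default to `root_age` (degenerate interval).
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(root_age, ci_low = root_age, ci_high = root_age) {
  stopifnot(root_age > 0, ci_low <= root_age, root_age <= ci_high)
  structure(list(root_age = root_age, ci_low = ci_low, ci_high = ci_high),
            class = "calibration_spec")
}

# Edge/topology bookkeeping shared by the objective and the optimizer.
# Returns indices on the ape node numbering: tips 1..ntip, internals above.
.pl_structure <- function(tree) {
  ntip <- length(tree$tip.label)
  E <- tree$edge
  nnode <- tree$Nnode
  N <- ntip + nnode
  root <- tree_root(tree)
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  pre <- rev(po)
  parent_edge <- match(seq_len(N), E[, 2])            # edge whose child is v
  pe <- parent_edge[E[, 1]]                           # parent edge per edge
  free <- setdiff((ntip + 1L):N, root)                # internal, non-root
  fidx <- rep(NA_integer_, N)
  fidx[free] <- seq_along(free)
  list(ntip = ntip, nnode = nnode, N = N, root = root, E = E,
       nedge = nrow(E), po = po, pre = pre, pe = pe,
       root_child_edges = which(is.na(pe)), free = free, fidx = fidx)
}

#' Penalized log-likelihood of a dated tree
#'
#' Evaluates the rate-smoothing objective (Poisson branch log-likelihood
#' minus `smoothing` times the log-rate roughness penalty; the `ln(x!)`
#' constant is omitted) for given node ages and branch rates. A
#' deterministic pure function used by the optimizer and by oracle tests.
#' See the file header for the exact form; the penalty acts on log rates,
#' making the objective invariant under rescaling of the time axis.
#'
#' @param tree `phylo` with branch lengths in substitutions/site.
#' @param ages Numeric vector of node ages in Myr indexed by ape node number
#'   (length `ntip + nnode`); tips must be at age 0 and every parent strictly
#'   older than its child.
#' @param rates Numeric vector of per-edge rates (substitutions/site/Myr,
#'   > 0), in `tree$edge` row order.
#' @param cfg A [pl_config()]; `seq_length` and `smoothing` are used.
#' @return The penalized log-likelihood (scalar).
#' @export
pl_objective <- function(tree, ages, rates, cfg = pl_config()) {
  s <- .pl_structure(tree)
  if (length(ages) != s$N) stop("ages must have length ntip + nnode")
  if (length(rates) != s$nedge) stop("rates must have one entry per edge")
  if (any(rates <= 0)) stop("all rates must be > 0")
  if (any(abs(ages[seq_len(s$ntip)]) > 1e-9)) stop("tip ages must be 0")
  tau <- ages[s$E[, 1]] - ages[s$E[, 2]]
  if (any(tau <= 0)) stop("non-positive branch duration (parent must be older than child)")
  x <- tree$edge.length * cfg$seq_length
  mu <- rates * cfg$seq_length * tau
  ll <- sum(x[x > 0] * log(mu[x > 0])) - sum(mu)
  ll - cfg$smoothing * .pl_penalty(log(rates), s)
}

# Roughness on log rates (see header); lr = log rates per edge.
.pl_penalty <- function(lr, s) {
  nonroot <- which(!is.na(s$pe))
  pen <- sum((lr[nonroot] - lr[s$pe[nonroot]])^2)
  rc <- lr[s$root_child_edges]
  pen + mean((rc - mean(rc))^2)          # population variance of root children
}

# ages from the fraction parameterization: a[root] = R, a[c] = a[p] * f[c].
.pl_ages <- function(th_a, s, R, eps) {
  f <- rep(NA_real_, s$N)
  f[s$free] <- eps + (1 - 2 * eps) * plogis(th_a)
  a <- numeric(s$N)
  a[s$root] <- R
  for (e in s$pre) {
    ch <- s$E[e, 2]
    if (ch > s$ntip) a[ch] <- a[s$E[e, 1]] * f[ch]
  }
  list(ages = a, f = f)
}

# Negative objective and gradient on par = c(th_a[free], log_r[edges]).
.pl_make_funs <- function(tree, s, R, cfg) {
  L <- cfg$seq_length
  lam <- cfg$smoothing
  x <- tree$edge.length * L
  xpos <- x > 0
  md <- if (is.null(cfg$min_duration)) 1e-6 * R else cfg$min_duration
  eps <- min(md / R, 0.01)
  nfa <- length(s$free)
  unpack <- function(par) {
    th_a <- if (nfa) par[seq_len(nfa)] else numeric(0)
    list(th_a = th_a, lr = par[nfa + seq_len(s$nedge)])
  }
  fn <- function(par) {
    p <- unpack(par)
    af <- .pl_ages(p$th_a, s, R, eps)
    tau <- af$ages[s$E[, 1]] - af$ages[s$E[, 2]]
    r <- exp(p$lr)
    mu <- r * L * tau
    ll <- sum(x[xpos] * log(mu[xpos])) - sum(mu)
    -(ll - lam * .pl_penalty(p$lr, s))
  }
  gr <- function(par) {
    p <- unpack(par)
    af <- .pl_ages(p$th_a, s, R, eps)
    a <- af$ages
    tau <- a[s$E[, 1]] - a[s$E[, 2]]
    r <- exp(p$lr)
    mu <- r * L * tau
    # d logL / d log r = x - mu; penalty is quadratic in log rates directly
    gp <- numeric(s$nedge)
    nr <- which(!is.na(s$pe))
    d <- p$lr[nr] - p$lr[s$pe[nr]]
    for (k in seq_along(nr)) {
      gp[nr[k]] <- gp[nr[k]] + 2 * d[k]
      gp[s$pe[nr[k]]] <- gp[s$pe[nr[k]]] - 2 * d[k]
    }
    rc <- s$root_child_edges
    if (length(rc) > 1L)
      gp[rc] <- gp[rc] + (2 / length(rc)) * (p$lr[rc] - mean(p$lr[rc]))
    g_lr <- (x - mu) - lam * gp
    if (nfa) {
      g_tau <- ifelse(xpos, x / tau, 0) - r * L
      g_a <- numeric(s$N)
      for (e in seq_len(s$nedge)) {
        pnode <- s$E[e, 1]; cnode <- s$E[e, 2]
        g_a[pnode] <- g_a[pnode] + g_tau[e]
        g_a[cnode] <- g_a[cnode] - g_tau[e]
      }
      # accumulate S[v] = sum over free descendants m (incl. v) of g_a[m]*a[m]
      acc <- numeric(s$N)
      acc[s$free] <- g_a[s$free] * a[s$free]
      for (e in s$po) {
        ch <- s$E[e, 2]
        if (ch > s$ntip) acc[s$E[e, 1]] <- acc[s$E[e, 1]] + acc[ch]
      }
      sig <- plogis(p$th_a)
      fprime <- (1 - 2 * eps) * sig * (1 - sig)
      g_th <- acc[s$free] * fprime / af$f[s$free]
    } else g_th <- numeric(0)
    -c(g_th, g_lr)
  }
  list(fn = fn, gr = gr, eps = eps, x = x, unpack = unpack)
}

# Clock initialization: node ages proportional to mean root-to-tip depth,
# one common rate. This is the exact optimum for strictly clock-like trees.
.pl_init <- function(tree, s, R, funs) {
  sumd <- numeric(s$N)
  ntips <- numeric(s$N)
  ntips[seq_len(s$ntip)] <- 1
  for (e in s$po) {
    pnode <- s$E[e, 1]; cnode <- s$E[e, 2]
    sumd[pnode] <- sumd[pnode] + sumd[cnode] + tree$edge.length[e] * ntips[cnode]
    ntips[pnode] <- ntips[pnode] + ntips[cnode]
  }
  h <- sumd / ntips                      # mean substitutions to tips below
  a0 <- numeric(s$N)
  a0[s$root] <- R
  if (h[s$root] <= 0) h[s$root] <- 1     # all-zero tree: flat fallback
  for (e in s$pre) {
    ch <- s$E[e, 2]
    if (ch > s$ntip) a0[ch] <- R * h[ch] / h[s$root]
  }
  eps <- funs$eps
  th_a <- vapply(s$free, function(v) {
    pnode <- s$E[match(v, s$E[, 2]), 1]
    f <- if (a0[pnode] > 0) a0[v] / a0[pnode] else 0.5
    f <- min(max((f - eps) / (1 - 2 * eps), 1e-7), 1 - 1e-7)
    min(max(qlogis(f), -14), 14)
  }, numeric(1))
  tau0 <- pmax(a0[s$E[, 1]] - a0[s$E[, 2]], eps * R)
  r0 <- sum(tree$edge.length) / sum(tau0)
  if (!is.finite(r0) || r0 <= 0) r0 <- 1e-8
  c(th_a, rep(log(r0), s$nedge))
}

#' Estimate an ultrametric chronogram by penalized likelihood
#'
#' Maximizes [pl_objective()] subject to: root age fixed at the calibration
#' value, tip ages 0, parent strictly older than child, positive rates.
#' The search runs on transformed variables (log rates; node ages as
#' logistic fractions of the parent age) with deterministic seeded
#' multi-start L-BFGS-B; the best objective wins, ties broken by the
#' first-found solution.
#'
#' @param tree `phylo` with branch lengths in substitutions/site (>= 2 tips).
#' @param calib A [calibration_spec()] (or a single root age in Myr).
#' @param cfg A [pl_config()].
#' @return An object of class `chronogram`: list with `tree` (same topology,
#'   branch lengths in Myr), `ages` (node ages, Myr), `rates` (per-edge,
#'   substitutions/site/Myr), `root_age`, `calibration`, `objective`,
#'   `convergence` and a per-restart `trace`.
#' @export
estimate_chronogram <- function(tree, calib, cfg = pl_config()) {
  if (!inherits(calib, "calibration_spec")) calib <- calibration_spec(calib)
  if (length(tree$tip.label) < 2L) stop("dating requires a tree with >= 2 tips")
  R <- calib$root_age
  s <- .pl_structure(tree)
  funs <- .pl_make_funs(tree, s, R, cfg)
  par0 <- .pl_init(tree, s, R, funs)
  nfa <- length(s$free)
  lower <- c(rep(-16, nfa), rep(log(1e-10), s$nedge))
  upper <- c(rep(16, nfa), rep(log(1e4), s$nedge))
  runs <- vector("list", cfg$n_restarts)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  best <- NULL
  for (k in seq_len(cfg$n_restarts)) {
    park <- if (k == 1L) par0 else
      pmin(pmax(par0 + rnorm(length(par0), 0, 0.5), lower), upper)
    fit <- optim(park, funs$fn, funs$gr, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = cfg$max_iter, factr = 10,
                                pgtol = 1e-12))
    # polish: a second pass from the solution tightens near-converged runs
    fit2 <- optim(fit$par, funs$fn, funs$gr, method = "L-BFGS-B",
                  lower = lower, upper = upper,
                  control = list(maxit = cfg$max_iter, factr = 10,
                                 pgtol = 1e-12))
    if (fit2$value <= fit$value) fit <- fit2
    runs[[k]] <- list(objective = -fit$value, convergence = fit$convergence)
    tie_tol <- cfg$tol * (1 + abs(fit$value))
    if (is.null(best) || fit$value < best$value - tie_tol) best <- fit
  }
  if (all(vapply(runs, function(r) r$convergence, numeric(1)) != 0)) {
    cond <- errorCondition(
      paste0("penalized-likelihood optimization did not converge in any of ",
             cfg$n_restarts, " restarts (max_iter = ", cfg$max_iter, ")"),
      class = "pl_nonconvergence", best = best, trace = runs)
    stop(cond)
  }
  p <- funs$unpack(best$par)
  af <- .pl_ages(p$th_a, s, R, funs$eps)
  ages <- af$ages
  rates <- exp(p$lr)
  timetree <- tree
  timetree$edge.length <- ages[s$E[, 1]] - ages[s$E[, 2]]
  structure(list(tree = timetree, ages = ages, rates = rates, root_age = R,
                 calibration = calib, objective = -best$value,
                 smoothing = cfg$smoothing, seq_length = cfg$seq_length,
                 convergence = best$convergence, trace = runs),
            class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat("chronogram:", length(x$tree$tip.label), "tips, root age",
      format(x$root_age), "Myr")
  if (!is.na(x$objective))
    cat(", penalized logLik", format(x$objective, digits = 8))
  cat("\n")
  invisible(x)
}

#' Rescale a chronogram to a different root calibration
#'
#' Multiplies every node age (and branch duration) by
#' `new_root_age / root_age` and divides every rate by the same factor.
#' This is the exact optimum transfer for a single fixed root age: the
#' Poisson term is invariant under the rescaling, so re-optimizing at the
#' new root age is equivalent up to the (tiny) rescaling of the roughness
#' penalty.
#'
#' @param chrono A `chronogram`.
#' @param new_root_age New root age in Myr (> 0).
#' @return A rescaled `chronogram` (objective set to `NA`, since the
#'   penalized objective is defined at the fitted calibration).
#' @export
rescale_chronogram <- function(chrono, new_root_age) {
  stopifnot(inherits(chrono, "chronogram"), new_root_age > 0)
  f <- new_root_age / chrono$root_age
  chrono$ages <- chrono$ages * f
  chrono$tree$edge.length <- chrono$tree$edge.length * f
  chrono$rates <- chrono$rates / f
  chrono$root_age <- new_root_age
  chrono$objective <- NA_real_
  chrono
}

#' Propagate calibration uncertainty to a clade age
#'
#' Linear scaling of the point age by the calibration's relative CI bounds:
#' `low = age * ci_low / root_age`, `high = age * ci_high / root_age`.
#' Rounding is left to report time.
#'
#' @param age Clade age in Myr (>= 0).
#' @param calib A [calibration_spec()].
#' @return Named numeric vector `c(low, high)` in Myr.
#' @export
propagate_calibration_ci <- function(age, calib) {
  stopifnot(inherits(calib, "calibration_spec"), age >= 0)
  c(low = age * calib$ci_low / calib$root_age,
    high = age * calib$ci_high / calib$root_age)
}

#' Crown-group age of a clade
#'
#' Age of the most recent common ancestor of the clade's tips in a dated
#' tree. A single-tip clade has no crown group and returns 0 with a warning.
#'
#' @param chrono A `chronogram`.
#' @param clade A [clade_definition()] or character vector of tip labels.
#' @return Crown age in Myr.
#' @export
crown_age <- function(chrono, clade) {
  stopifnot(inherits(chrono, "chronogram"))
  tips <- if (inherits(clade, "clade_definition")) clade$tips else as.character(clade)
  unknown <- setdiff(tips, chrono$tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(tips) == 1L) {
    warning("single-tip clade has no crown group; returning age 0")
    return(0)
  }
  chrono$ages[ape::getMRCA(chrono$tree, tips)]
}
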