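# Independent oracles and small generators shared across the suite.
# These deliberately avoid the code paths they check.

# Brute-force MRCA: intersect root paths of all tips, take the node of that
# intersection farthest from the root. Uses only the edge matrix.
mrca_path_oracle <- function(tree, tips) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root_path <- function(v) {
    path <- v
    while (parent[v] != 0L) {
      v <- parent[v]
      path <- c(v, path)
    }
    path
  }
  idx <- match(tips, tree$tip.label)
  paths <- lapply(idx, root_path)
  common <- Reduce(intersect, paths)
  common[length(common)]              # paths are root-first; last = deepest
}

# Random clean (A/C/G/T only) alignment.
random_alignment <- function(n, L, seed) {
  set.seed(seed)
  dna_alignment(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)), paste0("s", seq_len(n)))
}

# Simulated non-clock phylogram plus its generating truth.
sim_dataset <- function(seed, n_tips = 12L, seq_length = 2000L,
                        rate_autocorr_sd = 0.1, crown_age = NULL) {
  cfg <- sim_config(birth_rate = 1,
                    target_n = if (is.null(crown_age)) n_tips else NULL,
                    crown_age = crown_age, seq_length = seq_length,
                    rate_autocorr_sd = rate_autocorr_sd, seed = seed)
  chrono <- simulate_tree(cfg)
  ph <- assign_rates(chrono, cfg)
  list(cfg = cfg, chrono = chrono, tree = ph$tree, rates = ph$rates)
}

# Grid-search oracle for the penalized-likelihood optimum on a rooted
# 3-taxon tree ((A:b2,B:b3):b1,C:b4). Profiles the single free node age
# over a fixed grid (step 1e-3 * root age); for each age the inner
# maximization over the four log rates runs coordinate ascent on a
# log-spaced grid, refined around the incumbent (the inner problem is
# strictly concave in log rates, so coordinate ascent finds its optimum).
# The objective is written out inline, independent of pl_objective().
pl_grid_oracle_3taxon <- function(b, L, R, lambda) {
  x <- b * L
  astep <- 1e-3 * R
  agrid <- seq(astep, R - astep, by = astep)
  loc <- function(j, v, lr, tau) {      # terms of Psi that involve lr[j] = v
    mu <- exp(v) * L * tau[j]
    ll <- (if (x[j] > 0) x[j] * v else 0) - mu
    pen <- switch(j,
                  (v - lr[2])^2 + (v - lr[3])^2 + (v - lr[4])^2 / 4,
                  (lr[1] - v)^2,
                  (lr[1] - v)^2,
                  (lr[1] - v)^2 / 4)
    ll - lambda * pen
  }
  full_psi <- function(lr, tau) {
    mu <- exp(lr) * L * tau
    sum(ifelse(x > 0, x * log(mu), 0)) - sum(mu) -
      lambda * ((lr[2] - lr[1])^2 + (lr[3] - lr[1])^2 + (lr[1] - lr[4])^2 / 4)
  }
  final_step <- 0.2 / 8^3
  solve_rates <- function(tau, lr) {
    step <- 0.2
    for (stage in 1:4) {
      repeat {
        changed <- FALSE
        for (j in 1:4) {
          v <- lr[j] + seq(-40, 40) * step
          k <- which.max(loc(j, v, lr, tau))
          if (v[k] != lr[j]) { lr[j] <- v[k]; changed <- TRUE }
        }
        if (!changed) break
      }
      step <- step / 8
    }
    lr
  }
  best <- list(psi = -Inf)
  lr <- log(pmax(x / (L * R / 2), 1e-10))   # warm start, carried across ages
  for (a in agrid) {
    tau <- c(R - a, a, a, R)
    lr <- solve_rates(tau, lr)
    psi <- full_psi(lr, tau)
    if (psi > best$psi)
      best <- list(psi = psi, age = a, log_rates = lr,
                   age_step = astep, rate_step = final_step)
  }
  best
}

# 3-taxon helper: tree text and the optimizer's view of it.
tree3 <- function(b) {
  ape::read.tree(text = sprintf("((A:%.10g,B:%.10g):%.10g,C:%.10g);",
                                b[2], b[3], b[1], b[4]))
}

# Map the optimizer's per-edge values into the oracle's fixed edge order
# (root->I, I->A, I->B, root->C) for a tree built by tree3().
edge_order_3taxon <- function(tree) {
  s <- radrate:::.pl_structure(tree)
  inner <- setdiff((s$ntip + 1):s$N, s$root)
  tip <- function(lbl) match(lbl, tree$tip.label)
  c(which(s$E[, 2] == inner),
    which(s$E[, 2] == tip("A")),
    which(s$E[, 2] == tip("B")),
    which(s$E[, 2] == tip("C")))
}
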