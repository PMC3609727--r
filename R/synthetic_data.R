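# Seeded generators for birth-death trees, autocorrelated branch rates and
# Jukes-Cantor alignments: ground truth for every pipeline stage.

#' Simulation configuration
#'
#' @param birth_rate Speciation rate per lineage per Myr (> death_rate).
#' @param death_rate Extinction rate per lineage per Myr (default 0: Yule).
#' @param crown_age Crown age in Myr to grow the tree to (variable tip
#'   count); exactly one of `crown_age` / `target_n` must be given.
#' @param target_n Number of extant tips to grow to (variable age).
#' @param rate_mean Mean substitution rate, substitutions/site/Myr. The
#'   default 0.005 is a realistic fast nuclear spacer (ITS-like) rate.
#' @param rate_autocorr_sd Standard deviation of the per-branch log-rate
#'   step (lognormal autocorrelated rates; 0 gives a strict clock).
#' @param seq_length Alignment length in sites.
#' @param seed Integer seed; all generators are deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(birth_rate = 1, death_rate = 0, crown_age = NULL,
                       target_n = NULL, rate_mean = 0.005,
                       rate_autocorr_sd = 0.1, seq_length = 1000L,
                       seed = 0L) {
  stopifnot(birth_rate > death_rate, death_rate >= 0, rate_mean > 0,
            rate_autocorr_sd >= 0, seq_length >= 1)
  if (is.null(crown_age) == is.null(target_n))
    stop("give exactly one of crown_age or target_n")
  if (!is.null(crown_age)) stopifnot(crown_age > 0)
  if (!is.null(target_n)) stopifnot(target_n >= 2)
  structure(list(birth_rate = birth_rate, death_rate = death_rate,
                 crown_age = crown_age, target_n = target_n,
                 rate_mean = rate_mean, rate_autocorr_sd = rate_autocorr_sd,
                 seq_length = as.integer(seq_length), seed = as.integer(seed)),
            class = "sim_config")
}

# One forward pass of the crown birth-death process (2 starting lineages).
# Returns NULL on total extinction (crown_age mode) / stall (target_n mode).
.bd_grow <- function(cfg) {
  b <- cfg$birth_rate; d <- cfg$death_rate
  alive <- data.frame(id = c(1L, 2L), parent = 0L, t0 = 0)
  next_id <- 3L
  t <- 0
  events <- list()
  repeat {
    n_alive <- nrow(alive)
    if (n_alive == 0L) return(NULL)
    if (!is.null(cfg$target_n) && n_alive == cfg$target_n) {
      t_end <- t + rexp(1, n_alive * (b + d))
      break
    }
    wait <- rexp(1, n_alive * (b + d))
    t <- t + wait
    if (!is.null(cfg$crown_age) && t >= cfg$crown_age) {
      t_end <- cfg$crown_age
      break
    }
    i <- sample.int(n_alive, 1L)
    if (runif(1) < b / (b + d)) {       # speciation: lineage i splits
      events[[length(events) + 1L]] <-
        list(id = alive$id[i], time = t, children = c(next_id, next_id + 1L))
      alive <- rbind(alive[-i, , drop = FALSE],
                     data.frame(id = c(next_id, next_id + 1L),
                                parent = alive$id[i], t0 = t))
      next_id <- next_id + 2L
    } else {                            # extinction: lineage i dies
      alive <- alive[-i, , drop = FALSE]
    }
  }
  if (nrow(alive) < 2L) return(NULL)    # need a crown group of >= 2 tips
  list(events = events, alive = alive, t_end = t_end)
}

# Assemble an ape phylo from the event log, pruning extinct lineages and
# collapsing pass-through nodes (splits with a single surviving side).
# Returns NULL unless both crown lineages (ids 1 and 2) have survivors.
.bd_to_phylo <- function(g) {
  split_time <- numeric(0)
  children <- list()
  parent_of <- character(0)
  for (ev in g$events) {
    id <- as.character(ev$id)
    split_time[id] <- ev$time
    children[[id]] <- as.character(ev$children)
    parent_of[as.character(ev$children)] <- id
  }
  # ids on root-paths of survivors
  keep <- character(0)
  for (id in as.character(g$alive$id)) {
    cur <- id
    while (!is.na(cur) && !(cur %in% keep)) {
      keep <- c(keep, cur)
      cur <- if (cur %in% names(parent_of)) parent_of[[cur]] else NA
    }
  }
  if (!all(c("1", "2") %in% keep)) return(NULL)   # crown conditioning
  surv_children <- lapply(children, function(ch) ch[ch %in% keep])
  did_split <- function(id) id %in% names(split_time)
  n_surv <- function(id) if (did_split(id)) length(surv_children[[id]]) else 0L
  # follow pass-through chains (single surviving side) down to a real node/tip
  resolve <- function(id) {
    while (n_surv(id) == 1L) id <- surv_children[[id]][1]
    id
  }
  tips <- keep[vapply(keep, n_surv, integer(1)) == 0L]
  real_internal <- keep[vapply(keep, n_surv, integer(1)) >= 2L]
  ntip <- length(tips)
  internal_ids <- c("root", real_internal)
  node_num <- setNames(seq_len(ntip), tips)
  node_num[internal_ids] <- ntip + seq_along(internal_ids)
  time_of <- setNames(c(rep(g$t_end, ntip), 0, unname(split_time[real_internal])),
                      c(tips, internal_ids))
  edges <- matrix(integer(0), ncol = 2)
  stack <- list(list(id = "root",
                     ch = vapply(c("1", "2"), resolve, character(1))))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (c_id in top$ch) {
      edges <- rbind(edges, c(node_num[[top$id]], node_num[[c_id]]))
      if (c_id %in% real_internal)
        stack[[length(stack) + 1L]] <-
          list(id = c_id, ch = vapply(surv_children[[c_id]], resolve, character(1)))
    }
  }
  elen <- time_of[match(edges[, 2], node_num)] - time_of[match(edges[, 1], node_num)]
  tr <- structure(list(edge = matrix(as.integer(edges), ncol = 2),
                       edge.length = unname(elen),
                       Nnode = length(internal_ids),
                       tip.label = paste0("t", seq_len(ntip))),
                  class = "phylo")
  ages <- setNames(g$t_end - unname(time_of[match(seq_len(ntip + length(internal_ids)),
                                                  node_num)]), NULL)
  list(tree = tr, ages = ages, crown_age = g$t_end)
}

#' Simulate a constant-rate birth-death (Yule) chronogram
#'
#' Grows a crown group (two starting lineages) forward in time, either to a
#' fixed `crown_age` (variable tip count) or until `target_n` extant
#' lineages exist (the stopping time is the next event time, so a 2-tip
#' target yields an exponentially distributed crown age with mean
#' `1/(2 birth_rate)` under pure birth). Conditioned on survival of at
#' least two crown lineages by resimulation (up to `max_retry`). Extinct
#' lineages are pruned.
#'
#' @param cfg A [sim_config()].
#' @param max_retry Resimulation cap when all lineages die (default 100).
#' @return A `chronogram` (branch lengths in Myr, true node ages, `rates`
#'   set to `NA`; `objective` `NA`).
#' @export
simulate_tree <- function(cfg, max_retry = 100L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  for (try in seq_len(max_retry)) {
    g <- .bd_grow(cfg)
    res <- if (is.null(g)) NULL else .bd_to_phylo(g)
    if (!is.null(res)) {
      tr <- res$tree
      .pl_structure(tr)                    # validates >= 2 tips, indices
      return(structure(list(tree = tr, ages = res$ages,
                            rates = rep(NA_real_, nrow(tr$edge)),
                            root_age = res$crown_age,
                            calibration = NULL,
                            objective = NA_real_,
                            smoothing = NA_real_, seq_length = NA_integer_,
                            convergence = NA_integer_, trace = NULL),
                       class = "chronogram"))
    }
  }
  stop("all lineages went extinct in ", max_retry, " attempts")
}

#' Assign autocorrelated lognormal rates and branch lengths
#'
#' Walks the tree from the root; each branch's rate is its parent branch's
#' rate times `exp(N(-sd^2/2, sd))` (root branches descend from
#' `rate_mean`), so the expected rate is preserved along paths
#' (mean-preserving lognormal steps). Branch length = rate x duration,
#' producing a non-clock phylogram in substitutions/site.
#'
#' @param chrono A `chronogram` (e.g. from [simulate_tree()]).
#' @param cfg A [sim_config()]; uses `rate_mean`, `rate_autocorr_sd`, `seed`.
#' @return A list: `tree` (phylogram, substitutions/site), `rates` (true
#'   per-edge rates, substitutions/site/Myr), `chronogram` (the input).
#' @export
assign_rates <- function(chrono, cfg) {
  stopifnot(inherits(chrono, "chronogram"), inherits(cfg, "sim_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed + 1L)
  s <- .pl_structure(chrono$tree)
  sdv <- cfg$rate_autocorr_sd
  rates <- numeric(s$nedge)
  for (e in s$pre) {
    parent_rate <- if (is.na(s$pe[e])) cfg$rate_mean else rates[s$pe[e]]
    step <- if (sdv > 0) exp(rnorm(1, -sdv^2 / 2, sdv)) else 1
    rates[e] <- parent_rate * step
  }
  phylogram <- chrono$tree
  phylogram$edge.length <- rates * chrono$tree$edge.length
  list(tree = phylogram, rates = rates, chronogram = chrono)
}

#' Simulate a Jukes-Cantor alignment along a phylogram
#'
#' The root sequence is uniform over A/C/G/T; sites evolve independently
#' down each branch of length `b` (substitutions/site) with change
#' probability `p = (3/4)(1 - exp(-4b/3))`, the changed base drawn
#' uniformly from the three alternatives.
#'
#' @param tree `phylo` with branch lengths in substitutions/site.
#' @param cfg A [sim_config()]; uses `seq_length`, `seed`.
#' @return A [dna_alignment()] of the tip sequences (labels = tip labels).
#' @export
simulate_sequences <- function(tree, cfg) {
  stopifnot(inherits(tree, "phylo"), inherits(cfg, "sim_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed + 2L)
  s <- .pl_structure(tree)
  L <- cfg$seq_length
  bases <- c("A", "C", "G", "T")
  seqs <- vector("list", s$N)
  seqs[[s$root]] <- sample(4L, L, replace = TRUE)
  for (e in s$pre) {
    b <- tree$edge.length[e]
    p <- 0.75 * (1 - exp(-4 * b / 3))
    parent_seq <- seqs[[s$E[e, 1]]]
    child <- parent_seq
    hit <- which(runif(L) < p)
    if (length(hit)) {
      # uniform among the three other bases
      shift <- sample.int(3L, length(hit), replace = TRUE)
      child[hit] <- ((parent_seq[hit] - 1L + shift) %% 4L) + 1L
    }
    seqs[[s$E[e, 2]]] <- child
  }
  tip_seqs <- vapply(seq_len(s$ntip), function(i)
    paste(bases[seqs[[i]]], collapse = ""), character(1))
  dna_alignment(tip_seqs, tree$tip.label)
}
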