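# shared fixtures and independent oracles, built in code at test time

# small dated tree with named tips and root.time
make_dated_tree <- function(newick = "((a:2,b:2):3,(c:4,d:4):1);",
                            root_time = 470) {
  tr <- ape::read.tree(text = newick)
  tr$root.time <- root_time
  tr
}

# random character matrix on given taxa
random_char_matrix <- function(taxa, n_char, k = 2L, seed = 1,
                               missing_frac = 0) {
  set.seed(seed)
  k <- rep_len(as.integer(k), n_char)
  st <- sapply(seq_len(n_char), function(j)
    sample.int(k[j], length(taxa), replace = TRUE) - 1L)
  st <- matrix(as.integer(st), length(taxa), n_char,
               dimnames = list(taxa, NULL))
  if (missing_frac > 0)
    st[matrix(runif(length(st)) < missing_frac, nrow(st))] <- NA_integer_
  character_matrix(st, k_per_char = k)
}

# drop tips from a dated tree while preserving node ages
prune_dated <- function(tree, keep) {
  ages <- node_ages(tree)
  tr2 <- ape::keep.tip(tree, keep)
  d <- ape::node.depth.edgelength(tr2)
  tr2$root.time <- ages[match(tr2$tip.label[1], tree$tip.label)] + d[1]
  tr2
}

# brute-force Mk likelihood: enumerate all internal-node state assignments
brute_force_loglik <- function(tree, cm, clock, rc) {
  ea <- stratoclock:::.tree_edges_aged(tree)
  tr <- ea$tree
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  nu0 <- branch_expected_change(ea$older, ea$younger, clock)
  st <- cm$states[tr$tip.label, , drop = FALSE]
  total <- 0
  for (ch in seq_len(ncol(st))) {
    k <- max(cm$k_per_char[ch], 2L)
    lik_classes <- numeric(length(rc$factors))
    for (cl in seq_along(rc$factors)) {
      nu <- nu0 * rc$factors[cl]
      internal <- (ntip + 1L):nnode
      grid <- do.call(expand.grid, rep(list(0:(k - 1)), length(internal)))
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        assign_int <- as.integer(grid[g, ])
        state_of <- function(v) {
          if (v <= ntip) st[v, ch] else assign_int[v - ntip]
        }
        pr <- 1 / k      # uniform root frequency
        ok <- TRUE
        for (e in seq_len(nrow(tr$edge))) {
          sp <- state_of(tr$edge[e, 1])
          sc <- state_of(tr$edge[e, 2])
          if (is.na(sc)) next          # missing tip: marginalized below
          P <- mk_transition_probability(nu[e], k)
          if (is.na(sp)) { ok <- FALSE; break }
          pr <- pr * P[sp + 1, sc + 1]
        }
        # missing tips: sum over their states = 1 (row sums), handled by 'next'
        if (ok) lik <- lik + pr
      }
      lik_classes[cl] <- lik
    }
    total <- total + log(sum(rc$weights * lik_classes))
  }
  total
}

# brute-force parsimony: minimize steps over all internal labelings
brute_force_parsimony <- function(tree, cm) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  st <- cm$states[tr$tip.label, , drop = FALSE]
  vapply(seq_len(ncol(st)), function(ch) {
    k <- max(max(st[, ch], na.rm = TRUE) + 1L, 2L)
    internal <- (ntip + 1L):nnode
    grid <- do.call(expand.grid, rep(list(0:(k - 1)), length(internal)))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      lab <- c(st[, ch], as.integer(grid[g, ]))
      steps <- 0
      for (e in seq_len(nrow(tr$edge))) {
        a <- lab[tr$edge[e, 1]]; b <- lab[tr$edge[e, 2]]
        if (is.na(a) || is.na(b)) next
        steps <- steps + (a != b)
      }
      # missing tips add no constraint only if internal labels free; with NA
      # tips skipped this underestimates nothing for the exhaustive min
      best <- min(best, steps)
    }
    as.integer(best)
  }, 0L)
}

# brute-force timer counts by per-taxon scan
brute_force_timers <- function(pres) {
  n <- ncol(pres)
  out <- data.frame(interval = seq_len(n), two_timer_older = 0L,
                    two_timer_younger = 0L, three_timer = 0L, part_timer = 0L)
  for (i in seq_len(n)) for (tx in seq_len(nrow(pres))) {
    if (i > 1 && pres[tx, i - 1] && pres[tx, i])
      out$two_timer_older[i] <- out$two_timer_older[i] + 1L
    if (i < n && pres[tx, i] && pres[tx, i + 1])
      out$two_timer_younger[i] <- out$two_timer_younger[i] + 1L
    if (i > 1 && i < n) {
      if (pres[tx, i - 1] && pres[tx, i] && pres[tx, i + 1])
        out$three_timer[i] <- out$three_timer[i] + 1L
      if (pres[tx, i - 1] && !pres[tx, i] && pres[tx, i + 1])
        out$part_timer[i] <- out$part_timer[i] + 1L
    }
  }
  out
}

# simulate branch durations from the cladogenesis branch model: a branch
# starts at an age drawn in proportion to the generating rate lambda(t)
# (branches are produced by cladogenesis itself) and ends at its defining
# divergence - the first sampled cladogenetic event, arriving at rate
# lambda(t) (1 - E2(t)) (E2 under doubled origination), drawn by thinning
# against the envelope lambda(t)
simulate_clado_branches <- function(n, lambda0, kappa, t0, rates, seed,
                                    start_window = c(452, 478.5),
                                    young_stop = 441) {
  set.seed(seed)
  m <- clado_rate_model(if (kappa > 0) "exponential_decay" else "constant",
                        lambda0, kappa, t0)
  E2 <- stratoclock:::.clado_unsampled(m, rates)
  starts <- numeric(0)
  while (length(starts) < n) {
    cand <- runif(2 * n, start_window[1], start_window[2])
    keep <- runif(2 * n) < exp(-kappa * (t0 - cand))
    starts <- c(starts, cand[keep])
  }
  starts <- starts[seq_len(n)]
  brs <- NULL
  for (a in starts) {
    t <- a
    repeat {
      env <- lambda0 * exp(-kappa * (t0 - t))
      if (env < 1e-7) { t <- NA; break }
      t <- t - rexp(1, env)
      if (t <= young_stop) { t <- NA; break }
      lam_t <- lambda0 * exp(-kappa * (t0 - t))
      if (runif(1) < lam_t * (1 - E2(t)) / env) break
    }
    if (!is.na(t) && a - t > 0.01) brs <- rbind(brs, c(a, t))
  }
  data.frame(older = brs[, 1], younger = brs[, 2])
}

# forward Monte-Carlo estimate of the FBD branch survival probability:
# P(no sample on the focal branch and no birth on it leaving any sampled
# descendant), with constant rates and the observation window closing at
# the branch's younger end. Independent of the package's E(t) solver.
mc_branch_survival <- function(older, younger, lambda, mu, psi, nrep,
                               seed = 1) {
  set.seed(seed)
  # simulate one side lineage forward from age t down to 'younger';
  # returns TRUE if it (or its descendants) is ever sampled
  side_sampled <- function(t) {
    stack <- t
    while (length(stack)) {
      tt <- stack[1]; stack <- stack[-1]
      repeat {
        rate <- lambda + mu + psi
        dt <- rexp(1, rate)
        tt <- tt - dt
        if (tt <= younger) break
        u <- runif(1) * rate
        if (u < psi) return(TRUE)
        if (u < psi + mu) break
        stack <- c(stack, tt)      # birth: push the new lineage
      }
    }
    FALSE
  }
  ok <- 0L
  for (r in seq_len(nrep)) {
    t <- older
    surv <- TRUE
    repeat {
      rate <- lambda + psi
      if (rate == 0) break
      dt <- rexp(1, rate)
      t <- t - dt
      if (t <= younger) break
      if (runif(1) * rate < psi) { surv <- FALSE; break }
      if (side_sampled(t)) { surv <- FALSE; break }
    }
    ok <- ok + surv
  }
  p <- ok / nrep
  list(p = p, se = sqrt(p * (1 - p) / nrep))
}
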