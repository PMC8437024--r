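# Forward simulation of the processes the analysis assumes: a
# birth-death-sampling tree with piecewise-constant rates, fossil
# occurrence tables with lognormal among-taxon sampling heterogeneity and
# bounded age uncertainty, candidate first-appearance sets, and Mk
# character matrices evolved under a strict or early-burst clock. Lets
# every stage of the pipeline be exercised without any database download.

#' Specify a synthetic data set
#'
#' Defaults emulate an Ordovician brachiopod-like radiation: a clade
#' originating at 480 Ma tracked to 440 Ma, species-level origination
#' 0.35, extinction 0.25 and sampling 0.15 per lineage-Myr on
#' Cambrian-Ordovician stage bins, lognormal sampling heterogeneity of
#' scale 1, and 65 mostly binary characters evolving under an early burst
#' (rates 3.25 times higher before 462 Ma) with among-character lognormal
#' scale 1.
#'
#' @param origin age (Ma) at which the single founder lineage starts.
#' @param ts a [timescale()] carrying the rate bins (its young edge closes
#'   the observation window).
#' @param lambda,mu,psi per-interval rates (recycled).
#' @param sampling_sdlog lognormal scale of among-taxon sampling rates.
#' @param clock a [clock_model()] for character change.
#' @param n_char number of characters.
#' @param p_three_state fraction of characters with three states (the rest
#'   are binary).
#' @param taxon_cap maximum standing diversity before the simulation is
#'   truncated.
#' @param age_uncertainty full width (Myr) of collection age bounds.
#' @param share_prob chance an occurrence is filed in a co-occurring
#'   taxon's collection.
#' @param missing_frac fraction of character cells masked as missing.
#' @param seed master seed.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(origin = 480, ts = ordovician_timescale(1),
                            lambda = 0.35, mu = 0.25, psi = 0.15,
                            sampling_sdlog = 1,
                            clock = clock_model("early_burst",
                                                alpha_early = 0.049,
                                                alpha_late = 0.015,
                                                tau = 462, sigma = 1),
                            n_char = 65L, p_three_state = 0.2,
                            taxon_cap = 400L, age_uncertainty = 1.5,
                            share_prob = 0.1, missing_frac = 0.05,
                            seed = 1L) {
  if (taxon_cap < 2) stop("taxon_cap must be >= 2")
  rates <- skyline_rates(ts$older, ts$younger, lambda, mu, psi)
  if (origin > ts$older[1] || origin <= ts$younger[nrow(ts)])
    stop("origin must lie inside the timescale window")
  structure(list(origin = origin, timescale = ts, rates = rates,
                 sampling_sdlog = sampling_sdlog, clock = clock,
                 n_char = as.integer(n_char), p_three_state = p_three_state,
                 taxon_cap = as.integer(taxon_cap),
                 age_uncertainty = age_uncertainty, share_prob = share_prob,
                 missing_frac = missing_frac, seed = as.integer(seed)),
            class = "simulation_spec")
}

# rate interval index at age t (old -> young ordering)
.rate_idx <- function(t, rates) {
  i <- findInterval(-t, -rates$older)
  min(max(i, 1L), nrow(rates))
}

#' Simulate a fossilized-birth-death tree
#'
#' Forward Gillespie simulation from a single lineage at `spec$origin` with
#' piecewise-constant birth, death and fossil-sampling rates; fossilization
#' events are Poisson(psi) per lineage. Rejection-resamples (with derived
#' seeds) until at least `min_sampled` lineages carry a fossil.
#'
#' @param spec a [simulation_spec()].
#' @param seed seed (defaults to `spec$seed`).
#' @param min_sampled minimum number of fossil-bearing lineages to accept.
#' @param max_attempts rejection-loop cap.
#' @return a list of class `fbd_sim`: `lineages` (id, parent, birth, death),
#'   `fossils` (list of ages per lineage), `sampled_ids`, `fa` (oldest
#'   fossil per sampled lineage), `tree` (dated reconstructed tree of
#'   sampled lineages, tips at first appearances), `complete_tree`, and
#'   `attempts`.
#' @export
simulate_fbd_tree <- function(spec, seed = spec$seed, min_sampled = 4L,
                              max_attempts = 50L) {
  rates <- spec$rates
  young_edge <- rates$younger[nrow(rates)]
  for (attempt in seq_len(max_attempts)) {
    set.seed((as.integer(seed) + (attempt - 1L) * 7919L) %% .Machine$integer.max)
    parent <- c(NA_integer_); birth <- c(spec$origin); death <- c(NA_real_)
    fossils <- list(numeric(0))
    active <- 1L
    t <- spec$origin
    truncated <- FALSE
    repeat {
      if (!length(active) || t <= young_edge + 1e-12) break
      iv <- .rate_idx(t, rates)
      lam <- rates$lambda[iv]; mu <- rates$mu[iv]; psi <- rates$psi[iv]
      rho <- lam + mu + psi
      boundary <- max(rates$younger[iv], young_edge)
      if (rho == 0 || length(active) == 0) { t <- boundary; next }
      dt <- stats::rexp(1, length(active) * rho)
      if (t - dt <= boundary) { t <- boundary; next }
      t <- t - dt
      l <- active[sample.int(length(active), 1L)]
      u <- stats::runif(1) * rho
      if (u < lam) {
        if (length(parent) >= spec$taxon_cap) {
          warning("taxon cap reached at ", round(t, 2), " Ma; truncating")
          truncated <- TRUE
          break
        }
        parent <- c(parent, l); birth <- c(birth, t); death <- c(death, NA_real_)
        fossils[[length(parent)]] <- numeric(0)
        active <- c(active, length(parent))
      } else if (u < lam + mu) {
        death[l] <- t
        active <- setdiff(active, l)
      } else {
        fossils[[l]] <- c(fossils[[l]], t)
      }
    }
    end_t <- if (truncated) t else young_edge
    death[is.na(death)] <- end_t
    sampled <- which(lengths(fossils) > 0)
    if (length(sampled) >= min_sampled) {
      lin <- data.frame(id = seq_along(parent), parent = parent,
                        birth = birth, death = death)
      fa <- vapply(fossils[sampled], max, 0)
      names(fa) <- paste0("t", sampled)
      out <- list(lineages = lin, fossils = fossils, sampled_ids = sampled,
                  fa = fa, attempts = attempt, origin = spec$origin,
                  truncated = truncated)
      # a newick tree needs at least two tips
      out$complete_tree <- if (nrow(lin) >= 2)
        .sim_tree_phylo(lin, spec$origin) else NULL
      out$tree <- if (length(sampled) >= 2)
        .sim_sampled_phylo(lin, spec$origin, sampled, fa) else NULL
      class(out) <- "fbd_sim"
      return(out)
    }
  }
  stop("rejection loop: no attempt of ", max_attempts, " yielded >= ",
       min_sampled, " sampled taxa (is psi too low or zero?)")
}

.fmt_bl <- function(x) format(max(x, 0), digits = 12, scientific = FALSE)

# complete tree: every lineage becomes a tip at its death time
.sim_tree_phylo <- function(lin, origin) {
  kids <- split(lin$id[-1], lin$parent[-1])
  rec <- function(i, from, kid_list) {
    if (!length(kid_list))
      return(paste0("t", i, ":", .fmt_bl(from - lin$death[i])))
    k1 <- kid_list[1]
    b <- lin$birth[k1]
    paste0("(", rec(i, b, kid_list[-1]), ",",
           rec(k1, b, .kids_of(kids, k1)), "):", .fmt_bl(from - b))
  }
  str <- rec(1L, origin, .kids_of(kids, 1L))
  tr <- ape::read.tree(text = paste0(str, ";"))
  tr$root.time <- origin - (tr$root.edge %||% 0)
  tr
}

# children of a lineage, oldest first (ids are assigned in birth order, so
# ascending id = descending birth age)
.kids_of <- function(kids, i) {
  k <- kids[[as.character(i)]]
  if (is.null(k)) integer(0) else sort(k)
}

# reconstructed tree of sampled lineages; tips at first-appearance ages
# (clamped to the youngest retained divergence: sampled-ancestor convention,
# emitted as a zero-length branch)
.sim_sampled_phylo <- function(lin, origin, sampled, fa) {
  n <- nrow(lin)
  has <- logical(n)
  has[sampled] <- TRUE
  for (i in rev(seq_len(n))) if (has[i] && !is.na(lin$parent[i]))
    has[lin$parent[i]] <- TRUE
  kids_all <- split(lin$id[-1], lin$parent[-1])
  kids_s <- lapply(kids_all, function(k) k[has[k]])
  is_sampled <- logical(n)
  is_sampled[sampled] <- TRUE
  fa_of <- rep(NA_real_, n)
  fa_of[sampled] <- fa
  rec <- function(i, from, kid_list) {
    # kid_list: sampled-descendant children of i not yet placed, oldest first
    if (!length(kid_list)) {
      a <- min(fa_of[i], from)
      return(paste0("t", i, ":", .fmt_bl(from - a)))
    }
    k1 <- kid_list[1]
    if (!is_sampled[i] && length(kid_list) == 1L)
      return(rec(k1, from, .skids_of(kids_s, k1)))      # pass-through node
    b <- lin$birth[k1]
    paste0("(", rec(i, b, kid_list[-1]), ",",
           rec(k1, b, .skids_of(kids_s, k1)), "):", .fmt_bl(from - b))
  }
  str <- rec(1L, origin, .skids_of(kids_s, 1L))
  tr <- ape::read.tree(text = paste0(str, ";"))
  tr$root.time <- origin - (tr$root.edge %||% 0)
  tr
}

.skids_of <- function(kids_s, i) {
  k <- kids_s[[as.character(i)]]
  if (is.null(k) || !length(k)) integer(0) else k
}

#' Simulate an occurrence table and FA candidate sets from a tree
#'
#' Each lineage's sampling rate is the skyline mean multiplied by a
#' lognormal(0, `sdlog`) draw; occurrence counts are Poisson in the
#' lineage's duration (zero-truncated for lineages required to be
#' sampled), ages uniform over the duration, and each occurrence is filed
#' in a collection with bounds `age +/- age_uncertainty/2` (or, with
#' probability `share_prob`, in a close-aged collection of another taxon,
#' creating shared first-appearance candidates). Species are grouped into
#' genera by a Markov rule giving a mean of two species per genus. A
#' taxon's FA candidates are all of its collections whose age bounds
#' overlap its oldest collection's bounds.
#'
#' @param sim a [simulate_fbd_tree()] result.
#' @param spec the [simulation_spec()] used.
#' @param seed seed.
#' @return list with `occurrences` (an [occurrence_table()]) and
#'   `fa_candidates` (an [fa_candidates()] for the sampled tree tips).
#' @export
simulate_occurrence_table <- function(sim, spec, seed = spec$seed) {
  set.seed(as.integer(seed))
  lin <- sim$lineages
  rates <- spec$rates
  n <- nrow(lin)
  # genus assignment: inherit parent's genus with prob 1/2
  genus <- integer(n)
  genus[1] <- 1L
  ng <- 1L
  for (i in seq_len(n)[-1]) {
    if (stats::runif(1) < 0.5) genus[i] <- genus[lin$parent[i]]
    else { ng <- ng + 1L; genus[i] <- ng }
  }
  u <- spec$age_uncertainty
  window_old <- rates$older[1]; window_young <- rates$younger[nrow(rates)]
  het <- stats::rlnorm(n, 0, spec$sampling_sdlog)
  rows <- list()
  coll_id <- 0L
  for (i in seq_len(n)) {
    dur <- lin$birth[i] - lin$death[i]
    if (dur <= 0) next
    psi_bar <- rates$psi[.rate_idx((lin$birth[i] + lin$death[i]) / 2, rates)]
    # start from the fossilization events realized in the tree simulation,
    # so first appearances stay consistent with the sampled tree's tip ages;
    # the heterogeneity multiplier thins (keeping the oldest find) or
    # augments each taxon's record
    ages <- sim$fossils[[i]]
    if (spec$sampling_sdlog > 0 && length(ages)) {
      if (het[i] < 1) {
        keep_ev <- stats::runif(length(ages)) < het[i]
        keep_ev[which.max(ages)] <- TRUE
        ages <- ages[keep_ev]
      } else if (het[i] > 1) {
        extra <- stats::rpois(1, psi_bar * (het[i] - 1) * dur)
        if (extra > 0)
          ages <- c(ages, stats::runif(extra, lin$death[i], lin$birth[i]))
      }
    }
    if (!length(ages)) next
    for (a in ages) {
      coll_id <- coll_id + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        species = paste0("t", i), genus = paste0("g", genus[i]),
        collection = sprintf("c%05d", coll_id),
        max_ma = min(a + u / 2, window_old),
        min_ma = max(a - u / 2, window_young),
        true_age = a)
    }
  }
  occ <- do.call(rbind, rows)
  # share some collections between close-aged occurrences of different taxa
  if (spec$share_prob > 0 && nrow(occ) > 1) {
    for (r in seq_len(nrow(occ))) {
      if (stats::runif(1) >= spec$share_prob) next
      close <- which(occ$species != occ$species[r] &
                       abs(occ$true_age - occ$true_age[r]) < u / 2)
      close <- close[close < r]
      if (length(close)) {
        d <- close[which.min(abs(occ$true_age[close] - occ$true_age[r]))]
        occ$collection[r] <- occ$collection[d]
        occ$max_ma[r] <- occ$max_ma[d]
        occ$min_ma[r] <- occ$min_ma[d]
      }
    }
  }
  table_out <- occurrence_table(occ$species, occ$genus, occ$collection,
                                occ$max_ma, occ$min_ma)
  # FA candidates for the sampled tips: collections overlapping the bounds
  # of the taxon's oldest collection
  fa_rows <- list()
  for (tx in paste0("t", sim$sampled_ids)) {
    mine <- occ[occ$species == tx, ]
    if (!nrow(mine)) next
    oldest <- mine[which.max(mine$max_ma), ]
    cand <- mine[mine$max_ma > oldest$min_ma & mine$min_ma < oldest$max_ma, ]
    cand <- cand[!duplicated(cand$collection), ]
    fa_rows[[tx]] <- data.frame(taxon = tx, collection = cand$collection,
                                max_ma = cand$max_ma, min_ma = cand$min_ma)
  }
  fc <- fa_candidates(do.call(rbind, fa_rows))
  list(occurrences = table_out, fa_candidates = fc, genus = genus,
       heterogeneity = het)
}

#' Simulate a character matrix on a dated tree
#'
#' Per character: a rate factor is drawn lognormal(0, `clock$sigma`); states
#' evolve by the Mk process along branches, with expected change from
#' [branch_expected_change()] scaled by the factor; tip states are emitted
#' and optionally masked missing at random.
#'
#' @param tree dated `phylo`.
#' @param clock a [clock_model()].
#' @param n_char number of characters.
#' @param k_states integer vector of state counts (recycled).
#' @param seed seed.
#' @param missing_frac fraction of cells masked missing.
#' @return a [character_matrix()].
#' @export
simulate_characters <- function(tree, clock, n_char, k_states = 2L,
                                seed = 1L, missing_frac = 0) {
  set.seed(as.integer(seed))
  k_states <- rep_len(as.integer(k_states), n_char)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  tr$root.time <- tree$root.time
  ages <- node_ages(tr)
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  root <- ntip + 1L
  factors <- stats::rlnorm(n_char, 0, clock$sigma %||% 0)
  st <- matrix(NA_integer_, nnode, n_char)
  st[root, ] <- vapply(k_states, function(k) sample.int(k, 1L) - 1L, 0L)
  nu0 <- branch_expected_change(ages[tr$edge[, 1]], ages[tr$edge[, 2]], clock)
  transitions <- integer(nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    for (ch in seq_len(n_char)) {
      k <- k_states[ch]
      P <- mk_transition_probability(nu0[e] * factors[ch], k)
      st[child, ch] <- sample.int(k, 1L, prob = P[st[par, ch] + 1L, ]) - 1L
    }
    transitions[e] <- sum(st[child, ] != st[par, ])
  }
  tips <- st[seq_len(ntip), , drop = FALSE]
  rownames(tips) <- tr$tip.label
  if (missing_frac > 0) {
    mask <- matrix(stats::runif(length(tips)) < missing_frac, nrow(tips))
    tips[mask] <- NA_integer_
  }
  out <- character_matrix(tips, k_per_char = k_states)
  # realized end-point state changes per branch (edge order of the
  # cladewise-reordered tree), for calibration checks
  attr(out, "branch_changes") <- data.frame(
    older = ages[tr$edge[, 1]], younger = ages[tr$edge[, 2]],
    changes = transitions)
  out
}

#' Write a self-consistent synthetic fixture bundle
#'
#' Simulates a tree, occurrence table, FA candidates and character matrix
#' from one spec and writes them (newick, CSV, NEXUS, YAML) to a
#' directory, together with an analysis configuration whose scan window is
#' placed just above the synthetic first appearances. Deterministic per
#' seed. Seeds are retried (reported in `meta.yml`) until the sampled
#' taxon count falls in `n_range`.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed).
#' @param n_range acceptable range of sampled taxon counts.
#' @param config optional [analysis_config()] template; scan bounds are
#'   adapted to the synthetic first appearances.
#' @return the directory path, invisibly; the simulated objects in
#'   attribute `"objects"`.
#' @export
make_fixture_bundle <- function(spec, dir, n_range = c(25L, 60L),
                                config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- spec$seed
  for (try in 1:200) {
    sim <- simulate_fbd_tree(spec, seed = seed + (try - 1L) * 101L)
    if (length(sim$sampled_ids) >= n_range[1] &&
        length(sim$sampled_ids) <= n_range[2]) break
    if (try == 200) stop("no seed yielded a sampled taxon count in range")
  }
  occ <- simulate_occurrence_table(sim, spec, seed = spec$seed + 1L)
  set.seed(spec$seed + 2L)
  k_states <- ifelse(stats::runif(spec$n_char) < spec$p_three_state, 3L, 2L)
  cm <- simulate_characters(sim$tree, spec$clock, spec$n_char,
                            k_states = k_states, seed = spec$seed + 3L,
                            missing_frac = spec$missing_frac)
  max_fa <- max(occ$fa_candidates$max_ma)
  cfg <- config %||% analysis_config()
  cfg$scan_min <- ceiling(max_fa) + 1
  cfg$scan_max <- min(spec$origin + 10, spec$rates$older[1])
  write_dated_tree(sim$tree, file.path(dir, "tree.nwk"))
  write_character_matrix(cm, file.path(dir, "characters.nex"))
  write_occurrences(occ$occurrences, file.path(dir, "occurrences.csv"))
  utils::write.csv(as.data.frame(occ$fa_candidates),
                   file.path(dir, "fa_candidates.csv"),
                   row.names = FALSE, quote = FALSE)
  write_timescale(spec$timescale, file.path(dir, "timescale.yml"))
  write_config(cfg, file.path(dir, "config.yml"))
  yaml::write_yaml(list(synthetic = TRUE, seed_used = seed + (try - 1L) * 101L,
                        attempts = try, n_sampled = length(sim$sampled_ids),
                        origin = spec$origin),
                   file.path(dir, "meta.yml"))
  out <- dir
  attr(out, "objects") <- list(sim = sim, occ = occ, cm = cm, config = cfg)
  invisible(out)
}
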