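# Assembling the posterior over basal divergence ages and clock models:
# beta(1,N) priors on uncertain first appearances, coordinate-ascent dating
# of internal nodes against lnL alpha + lnP FBD, a deterministic grid scan
# over basal ages, credible intervals, and Bayes factors.

#' First-appearance candidate sets
#'
#' One row per (taxon, candidate collection): the collections that might be
#' a taxon's oldest occurrence, with their age bounds. A collection id
#' appearing under several taxa is a shared collection: it receives a
#' single age draw per replicate.
#'
#' @param df data frame with columns `taxon`, `collection`, `max_ma`,
#'   `min_ma`.
#' @return a data frame of class `fa_candidates`.
#' @export
fa_candidates <- function(df) {
  need <- c("taxon", "collection", "max_ma", "min_ma")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fa_candidates needs column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$taxon <- as.character(df$taxon)
  df$collection <- as.character(df$collection)
  if (any(df$max_ma < df$min_ma))
    stop("candidate with max_ma < min_ma")
  # a shared collection must carry one set of bounds
  b <- unique(df[c("collection", "max_ma", "min_ma")])
  if (anyDuplicated(b$collection))
    stop("collection appearing with inconsistent age bounds")
  class(df) <- c("fa_candidates", "data.frame")
  df
}

#' Read FA candidates from CSV
#' @param path CSV with columns `taxon`, `collection`, `max_ma`, `min_ma`.
#' @return an [fa_candidates()] object.
#' @export
read_fa_candidates <- function(path) {
  fa_candidates(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Draw one first-appearance replicate
#'
#' Every candidate collection receives an age drawn uniformly within its
#' bounds (one draw per collection, so taxa linked through a shared
#' collection see the same age); each taxon's first appearance is then the
#' oldest drawn age among its candidates.
#'
#' @param fc an [fa_candidates()] object.
#' @param seed integer seed.
#' @return an object of class `fa_replicate`: `ages` (named by taxon),
#'   `fa_collection`, and the per-collection `collection_ages`.
#' @export
sample_fa_replicate <- function(fc, seed = 1L) {
  set.seed(as.integer(seed))
  coll <- unique(fc[c("collection", "max_ma", "min_ma")])
  coll <- coll[order(coll$collection), ]
  draw <- stats::runif(nrow(coll), coll$min_ma, coll$max_ma)
  names(draw) <- coll$collection
  taxa <- unique(fc$taxon)
  ages <- numeric(length(taxa))
  fa_coll <- character(length(taxa))
  for (i in seq_along(taxa)) {
    cand <- fc$collection[fc$taxon == taxa[i]]
    a <- draw[cand]
    j <- which.max(a)
    ages[i] <- a[j]
    fa_coll[i] <- cand[j]
  }
  names(ages) <- names(fa_coll) <- taxa
  structure(list(ages = ages, fa_collection = fa_coll,
                 collection_ages = draw, seed = as.integer(seed)),
            class = "fa_replicate")
}

#' beta(1, N) prior mass of the j-th oldest of N candidate collections
#'
#' Cutting a beta(1, N) distribution into N equal quantile bins, the j-th
#' bin from the old end carries mass `(1 - (j-1)/N)^N - (1 - j/N)^N`. With
#' N = 1 the mass is 1 (a uniform prior on the single candidate).
#'
#' @param j rank of the chosen candidate, oldest = 1.
#' @param N number of candidate collections.
#' @return prior mass in (0, 1].
#' @export
beta_rank_mass <- function(j, N) {
  if (any(j < 1 | j > N)) stop("rank j must lie in 1..N")
  (1 - (j - 1) / N)^N - (1 - j / N)^N
}

#' Log prior probability of a first-appearance replicate (lnP FAs)
#'
#' Per taxon, candidates are ranked oldest to youngest by their drawn ages;
#' the collection chosen as the first appearance at rank j of N contributes
#' the log of its [beta_rank_mass()]. Taxa with a single candidate
#' contribute 0.
#'
#' @param rep an [sample_fa_replicate()] result.
#' @param fc the [fa_candidates()] it was drawn from.
#' @return lnP FAs (<= 0).
#' @export
fa_log_prior <- function(rep, fc) {
  total <- 0
  for (tx in names(rep$ages)) {
    cand <- fc$collection[fc$taxon == tx]
    N <- length(cand)
    chosen <- rep$fa_collection[[tx]]
    if (!chosen %in% cand)
      stop("first appearance of '", tx, "' is not among its candidates")
    ord <- cand[order(-rep$collection_ages[cand])]
    j <- match(chosen, ord)
    total <- total + log(beta_rank_mass(j, N))
  }
  total
}

# golden-section maximization on [lo, hi]
.golden_max <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- f(c1); fd <- f(d1)
  while (b - a > tol) {
    if (fc >= fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- f(c1)
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- f(d1)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = f(x))
}

#' Date internal nodes conditional on a fixed basal age
#'
#' With tip ages fixed at the replicate's first appearances and the root at
#' `basal_age`, internal node ages are set to maximize
#' `lnL alpha + lnP FBD` (the likelihood alone when `use_fbd = FALSE`) by
#' coordinate ascent: nodes are cycled root-down, each optimized by
#' golden-section search inside its feasible window (parent age above,
#' oldest descendant below), to a fixed age tolerance. Deterministic given
#' its inputs.
#'
#' @param tree `phylo` topology whose tips match `names(fa_ages)`.
#' @param cm a [character_matrix()].
#' @param basal_age root age in Ma; must be older than every FA.
#' @param fa_ages named tip ages (Ma), e.g. `rep$ages`.
#' @param clock a [clock_model()].
#' @param rates a [skyline_rates()] (needed unless `use_fbd = FALSE`).
#' @param rc optional [quartile_rate_classes()].
#' @param use_fbd include the FBD branch prior in the objective?
#' @param E optional precomputed [unsampled_probability()].
#' @param tol age tolerance in Myr.
#' @param max_sweeps cap on coordinate-ascent sweeps.
#' @return a dated `phylo`, with the objective in attribute `"objective"`.
#' @export
date_internal_nodes <- function(tree, cm, basal_age, fa_ages, clock,
                                rates = NULL, rc = NULL, use_fbd = TRUE,
                                E = NULL, tol = 0.01, max_sweeps = 30L) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  if (!all(tree$tip.label %in% names(fa_ages)))
    stop("fa_ages missing for: ",
         paste(setdiff(tree$tip.label, names(fa_ages)), collapse = ", "))
  tip_ages <- fa_ages[tree$tip.label]
  if (basal_age <= max(tip_ages))
    stop("basal_age (", basal_age, ") must be older than every first appearance (",
         max(tip_ages), ")")
  if (use_fbd) {
    if (is.null(rates)) stop("rates required when use_fbd = TRUE")
    E <- E %||% unsampled_probability(rates)
  }
  rc <- rc %||% quartile_rate_classes(clock$sigma %||% 0)

  parent <- integer(nnode)
  children <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    parent[ch] <- p
    children[[p]] <- c(children[[p]], ch)
  }
  # oldest descendant tip age below each node (postorder accumulation)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  maxdesc <- c(tip_ages, rep(-Inf, tree$Nnode))
  for (e in seq_len(nrow(po)))
    maxdesc[po[e, 1]] <- max(maxdesc[po[e, 1]], maxdesc[po[e, 2]])

  ages <- c(tip_ages, rep(NA_real_, tree$Nnode))
  ages[root] <- basal_age
  pre <- unique(po[rev(seq_len(nrow(po))), 1])   # parents before children
  for (v in pre) if (v != root)
    ages[v] <- (ages[parent[v]] + maxdesc[v]) / 2

  objective <- function(a) {
    tr <- tree_from_ages(tree, a)
    ll <- as.numeric(matrix_log_likelihood(tr, cm, clock, rc))
    if (use_fbd) ll <- ll + as.numeric(tree_log_prior(tr, rates, E = E))
    ll
  }
  internal <- setdiff(pre, root)
  if (length(internal)) {
    for (sweep in seq_len(max_sweeps)) {
      delta <- 0
      for (v in internal) {
        lo <- max(ages[children[[v]]]); hi <- ages[parent[v]]
        if (hi - lo < tol) { ages[v] <- (lo + hi) / 2; next }
        res <- .golden_max(function(x) { ages[v] <<- x; objective(ages) },
                           lo, hi, tol = tol)
        delta <- max(delta, abs(ages[v] - res$x))
        ages[v] <- res$x
      }
      if (delta < tol) break
    }
  }
  out <- tree_from_ages(tree, ages)
  attr(out, "objective") <- objective(ages)
  out
}

#' Optimize clock rates on a fixed dated tree
#'
#' Golden-section search on the log rate scale: a single rate for the
#' strict clock, alternating searches over the early and late rates (with
#' the breakpoint fixed) for the early burst.
#'
#' @param tree dated `phylo`.
#' @param cm a [character_matrix()].
#' @param mode `"strict"` or `"early_burst"`.
#' @param tau breakpoint in Ma (early burst).
#' @param sigma among-character lognormal scale.
#' @param rc optional [quartile_rate_classes()].
#' @param bounds log-rate search bounds.
#' @param tol search tolerance on the log scale.
#' @return the fitted [clock_model()], with `"loglik"` attribute.
#' @export
fit_clock <- function(tree, cm, mode = c("strict", "early_burst"), tau = NULL,
                      sigma = 0, rc = NULL, bounds = c(log(1e-5), log(5)),
                      tol = 1e-4) {
  mode <- match.arg(mode)
  rc <- rc %||% quartile_rate_classes(sigma)
  if (mode == "strict") {
    opt <- .golden_max(function(la)
      as.numeric(matrix_log_likelihood(
        tree, cm, clock_model("strict", alpha = exp(la), sigma = sigma), rc)),
      bounds[1], bounds[2], tol = tol)
    ck <- clock_model("strict", alpha = exp(opt$x), sigma = sigma)
    attr(ck, "loglik") <- opt$value
    return(ck)
  }
  if (is.null(tau)) stop("early burst needs tau")
  strict0 <- fit_clock(tree, cm, "strict", sigma = sigma, rc = rc,
                       bounds = bounds, tol = tol)
  ae <- al <- strict0$alpha
  val <- attr(strict0, "loglik")
  for (round in 1:3) {
    oe <- .golden_max(function(la) as.numeric(matrix_log_likelihood(
      tree, cm, clock_model("early_burst", alpha_early = exp(la),
                            alpha_late = al, tau = tau, sigma = sigma), rc)),
      bounds[1], bounds[2], tol = tol)
    ae <- exp(oe$x)
    ol <- .golden_max(function(la) as.numeric(matrix_log_likelihood(
      tree, cm, clock_model("early_burst", alpha_early = ae,
                            alpha_late = exp(la), tau = tau, sigma = sigma), rc)),
      bounds[1], bounds[2], tol = tol)
    al <- exp(ol$x)
    val <- ol$value
  }
  ck <- clock_model("early_burst", alpha_early = ae, alpha_late = al,
                    tau = tau, sigma = sigma)
  attr(ck, "loglik") <- val
  ck
}

#' Assemble a model posterior from its components
#'
#' The log posterior of a divergence-time and rate model decomposes
#' additively as `lnP FAs + lnL alpha + lnP FBD`.
#'
#' @param model model label.
#' @param basal_age basal divergence age in Ma.
#' @param lnp_fa,lnl_alpha,lnp_fbd the three log components.
#' @param ci optional 95% credible interval `c(older, younger)`.
#' @return an object of class `model_posterior` with the summed
#'   `ln_posterior`.
#' @export
model_posterior <- function(model, basal_age, lnp_fa, lnl_alpha, lnp_fbd,
                            ci = NULL) {
  structure(list(model = model, basal_age = basal_age, ci = ci,
                 lnp_fa = lnp_fa, lnl_alpha = lnl_alpha, lnp_fbd = lnp_fbd,
                 ln_posterior = lnp_fa + lnl_alpha + lnp_fbd),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  ci <- if (is.null(x$ci)) "" else sprintf(" [%g, %g]", x$ci[1], x$ci[2])
  cat(sprintf("%s: basal divergence %g Ma%s\n", x$model, x$basal_age, ci))
  cat(sprintf("  lnP FAs %.2f + lnL alpha %.2f + lnP FBD %.2f = ln posterior %.2f\n",
              x$lnp_fa, x$lnl_alpha, x$lnp_fbd, x$ln_posterior))
  invisible(x)
}

#' @export
as.data.frame.model_posterior <- function(x, ...) {
  data.frame(model = x$model, basal_age = x$basal_age,
             ci_older = if (is.null(x$ci)) NA_real_ else x$ci[1],
             ci_younger = if (is.null(x$ci)) NA_real_ else x$ci[2],
             lnp_fa = x$lnp_fa, lnl_alpha = x$lnl_alpha,
             lnp_fbd = x$lnp_fbd, ln_posterior = x$ln_posterior)
}

#' Grid scan of the posterior over basal divergence ages
#'
#' For each model and each basal age on the grid, clock rates and internal
#' node ages are optimized (clock rates on the first replicate and then
#' shared; node ages re-optimized per replicate), and the per-age posterior
#' mass is the mean over FA replicates of
#' `exp(lnP FAs + lnL alpha + lnP FBD)` (the FBD term is omitted from the
#' first model). Grid ages not older than some replicate's oldest FA are
#' infeasible and carry no mass.
#'
#' Models: `"strict_fa"` (strict clock + FA priors), `"strict_fbd"` (strict
#' clock + FA priors + FBD branch priors), `"early_burst_fbd"` (early burst
#' + FA priors + FBD branch priors).
#'
#' @param tree `phylo` topology (tips = analysed taxa).
#' @param cm a [character_matrix()].
#' @param fc an [fa_candidates()] set.
#' @param rates a [skyline_rates()].
#' @param config an [analysis_config()].
#' @param models subset of the three model labels.
#' @return an object of class `posterior_scan`: `surfaces` (data frame of
#'   model, age, ln_posterior), `posteriors` (per-model
#'   [model_posterior()]), `trees` (best dated tree per model), `sigma`,
#'   and `clocks` (fitted clock per model at its best age).
#' @export
scan_posterior <- function(tree, cm, fc, rates, config,
                           models = c("strict_fa", "strict_fbd",
                                      "early_burst_fbd")) {
  models <- match.arg(models, several.ok = TRUE)
  grid <- seq(config$scan_min, config$scan_max, by = config$grid_step)
  if (!length(grid)) stop("empty basal-age grid")
  sigma <- config$sigma
  if (is.null(sigma)) {
    fit <- fit_rate_distribution(count_parsimony_steps(tree, cm))
    sigma <- fit$lognormal$sdlog
  }
  rc <- quartile_rate_classes(sigma, config$n_rate_classes)
  R <- config$replicates
  reps <- lapply(seq_len(R), function(r)
    sample_fa_replicate(fc, seed = config$seed + r))
  lnfa <- vapply(reps, fa_log_prior, fc = fc, FUN.VALUE = 0)
  E <- unsampled_probability(rates)

  surfaces <- NULL
  posteriors <- list()
  best_trees <- list()
  clocks <- list()
  for (model in models) {
    use_fbd <- model != "strict_fa"
    mode <- if (model == "early_burst_fbd") "early_burst" else "strict"
    lnp <- rep(-Inf, length(grid))
    comp <- vector("list", length(grid))
    for (gi in seq_along(grid)) {
      age <- grid[gi]
      if (age <= max(vapply(reps, function(r) max(r$ages), 0))) next
      # fit the clock on replicate 1, then share it
      clock <- clock_model("strict", alpha = 0.02, sigma = sigma)
      for (round in 1:2) {
        dated <- date_internal_nodes(tree, cm, age, reps[[1]]$ages, clock,
                                     rates, rc, use_fbd = use_fbd, E = E)
        clock <- fit_clock(dated, cm, mode, tau = config$tau, sigma = sigma,
                           rc = rc)
      }
      tot <- numeric(R)
      comps_r <- vector("list", R)
      for (r in seq_len(R)) {
        dated_r <- date_internal_nodes(tree, cm, age, reps[[r]]$ages, clock,
                                       rates, rc, use_fbd = use_fbd, E = E)
        lnl <- as.numeric(matrix_log_likelihood(dated_r, cm, clock, rc))
        lnfbd <- if (use_fbd)
          as.numeric(tree_log_prior(dated_r, rates, E = E)) else 0
        tot[r] <- lnfa[r] + lnl + lnfbd
        comps_r[[r]] <- list(lnp_fa = lnfa[r], lnl_alpha = lnl,
                             lnp_fbd = lnfbd, tree = dated_r, clock = clock)
      }
      lnp[gi] <- logmeanexp(tot)
      comp[[gi]] <- comps_r[[which.max(tot)]]
    }
    surf <- data.frame(model = model, age = grid, ln_posterior = lnp)
    surfaces <- rbind(surfaces, surf)
    feas <- is.finite(lnp)
    if (!any(feas)) stop("no feasible basal age on the grid for model ", model)
    best <- which(lnp == max(lnp[feas]))[1]
    ci <- credible_interval(surf[feas, ], 0.95)
    bc <- comp[[best]]
    posteriors[[model]] <- model_posterior(model, grid[best], bc$lnp_fa,
                                           bc$lnl_alpha, bc$lnp_fbd, ci = ci)
    best_trees[[model]] <- bc$tree
    clocks[[model]] <- bc$clock
  }
  structure(list(surfaces = surfaces, posteriors = posteriors,
                 trees = best_trees, clocks = clocks, sigma = sigma,
                 grid = grid, lnfa = lnfa),
            class = "posterior_scan")
}

#' Credible interval from a posterior surface
#'
#' The smallest set of grid ages holding at least `level` of the normalized
#' posterior mass, reported as `c(older, younger)`. Ties are broken by
#' including the higher-posterior point first, and among equal posteriors
#' the older age first.
#'
#' @param surface data frame with columns `age` and `ln_posterior` (one
#'   model).
#' @param level coverage level.
#' @return numeric `c(older, younger)` in Ma.
#' @export
credible_interval <- function(surface, level = 0.95) {
  age <- surface$age
  lnp <- surface$ln_posterior
  if (!any(is.finite(lnp))) stop("posterior surface is not normalizable")
  if (length(age) > 2 && diff(range(lnp)) < 1e-12) {
    warning("flat posterior surface; returning the full window")
    return(c(older = max(age), younger = min(age)))
  }
  w <- exp(lnp - max(lnp))
  p <- w / sum(w)
  ord <- order(-p, -age)
  cum <- cumsum(p[ord])
  m <- which(cum >= level - 1e-12)[1]
  sel <- ord[seq_len(m)]
  c(older = max(age[sel]), younger = min(age[sel]))
}

#' Bayes factor between two posterior surfaces
#'
#' The ratio of grid-summed posterior masses of model `a` to model `b`,
#' optionally restricted to a subset of grid ages (e.g. the ages favoured
#' by the weaker model, giving the conditional variant).
#'
#' @param a,b data frames with columns `age` and `ln_posterior` on the same
#'   grid.
#' @param at_ages optional ages to restrict the comparison to.
#' @return the Bayes factor (numeric).
#' @export
bayes_factor <- function(a, b, at_ages = NULL) {
  if (!setequal(a$age, b$age))
    stop("posterior surfaces are on non-overlapping grids")
  if (!is.null(at_ages)) {
    a <- a[a$age %in% at_ages, ]
    b <- b[b$age %in% at_ages, ]
    if (!nrow(a)) stop("no grid points at the requested ages")
  }
  exp(logsumexp(a$ln_posterior) - logsumexp(b$ln_posterior))
}
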