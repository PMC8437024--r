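# Mk-model likelihood of a discrete character matrix on a dated tree, under
# strict-clock or early-burst rates of change, with among-character rate
# variation handled by four equally weighted classes cut from a lognormal.

#' Construct a morphological clock model
#'
#' Rates are expected character changes per character per Myr. In
#' `early_burst` mode the rate equals `alpha_early` before the breakpoint
#' `tau` (Ma) and `alpha_late` after it; `strict` mode uses a single
#' `alpha`. `sigma` is the lognormal scale of among-character rate
#' variation (0 = all characters share the clock rate).
#'
#' @param mode `"strict"` or `"early_burst"`.
#' @param alpha strict-clock rate.
#' @param alpha_early,alpha_late early-burst rates before/after `tau`.
#' @param tau breakpoint age in Ma (early-burst only).
#' @param sigma among-character lognormal scale (>= 0).
#' @return an object of class `clock_model`.
#' @export
clock_model <- function(mode = c("strict", "early_burst"), alpha = NULL,
                        alpha_early = NULL, alpha_late = NULL, tau = NULL,
                        sigma = 0) {
  mode <- match.arg(mode)
  if (sigma < 0) stop("sigma must be >= 0")
  if (mode == "strict") {
    if (is.null(alpha) || alpha <= 0) stop("strict clock needs alpha > 0")
    alpha_early <- alpha_late <- alpha
  } else {
    if (is.null(alpha_early) || is.null(alpha_late) ||
        alpha_early <= 0 || alpha_late <= 0)
      stop("early burst needs alpha_early > 0 and alpha_late > 0")
    if (is.null(tau)) stop("early burst needs a breakpoint tau (Ma)")
    alpha <- alpha_late
  }
  structure(list(mode = mode, alpha = alpha, alpha_early = alpha_early,
                 alpha_late = alpha_late, tau = tau, sigma = sigma),
            class = "clock_model")
}

#' Mk transition probability matrix
#'
#' Lewis's Mk model with k symmetric states: after an expected `nu` changes
#' per character, the chance of observing the same state is
#' `1/k + (k-1)/k * exp(-k nu / (k-1))` and each different state is equally
#' probable.
#'
#' @param nu expected number of changes (>= 0).
#' @param k number of states (>= 2).
#' @return a k-by-k row-stochastic matrix.
#' @export
mk_transition_probability <- function(nu, k) {
  if (k < 2) stop("Mk model needs k >= 2 states")
  if (nu < 0) stop("nu must be >= 0")
  e <- exp(-k * nu / (k - 1))
  p_diff <- (1 - e) / k
  p_same <- 1 / k + (k - 1) / k * e
  P <- matrix(p_diff, k, k)
  diag(P) <- p_same
  P
}

#' Expected character change along a branch
#'
#' The time-integral of the clock rate over the branch's span. Under an
#' early burst the rate is a step function of age with the step at `tau`.
#'
#' @param older,younger branch endpoint ages in Ma (`older > younger`).
#' @param clock a [clock_model()].
#' @return expected changes per character (`nu`).
#' @export
branch_expected_change <- function(older, younger, clock) {
  if (any(older < younger - 1e-12)) stop("branch ages reversed (older < younger)")
  if (clock$mode == "strict") return(clock$alpha * (older - younger))
  tau <- clock$tau
  t_early <- pmax(0, older - pmax(tau, younger))
  t_late <- pmax(0, pmin(tau, older) - younger)
  clock$alpha_early * t_early + clock$alpha_late * t_late
}

#' Discretized lognormal rate classes
#'
#' Four multiplicative rate factors with equal 1/4 weights, taken at the
#' quartile midpoints (p = 0.125, 0.375, 0.625, 0.875) of a lognormal with
#' median 1 and log-scale `sigma`; the class median therefore equals the
#' nominal clock rate.
#'
#' @param sigma lognormal scale (>= 0).
#' @param n number of classes.
#' @return an object of class `rate_classes` with `factors` and `weights`.
#' @export
quartile_rate_classes <- function(sigma, n = 4L) {
  if (sigma < 0) stop("sigma must be >= 0")
  p <- (seq_len(n) - 0.5) / n
  structure(list(factors = exp(sigma * stats::qnorm(p)),
                 weights = rep(1 / n, n), sigma = sigma),
            class = "rate_classes")
}

# internal: postorder edge matrix plus per-edge (older, younger) ages
.tree_edges_aged <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ages <- node_ages(tree)
  list(tree = tree, ages = ages,
       older = ages[tree$edge[, 1]], younger = ages[tree$edge[, 2]])
}

#' Mk log-likelihood of a character matrix on a dated tree
#'
#' Felsenstein pruning with uniform root state frequencies, averaged over
#' the rate classes (each class scales every branch's expected change), with
#' missing and inapplicable cells marginalized over states. Optionally
#' conditions each character on being variable (ascertainment correction);
#' off by default.
#'
#' @param tree dated `phylo` containing all matrix taxa as tips.
#' @param cm a [character_matrix()].
#' @param clock a [clock_model()].
#' @param rc a [quartile_rate_classes()] object; defaults to classes built
#'   from `clock$sigma`.
#' @param ascertainment condition on characters being variable?
#' @return total log-likelihood (`lnL alpha`), with per-character values in
#'   attribute `"per_character"`.
#' @export
matrix_log_likelihood <- function(tree, cm, clock, rc = NULL,
                                  ascertainment = FALSE) {
  extra <- setdiff(cm$taxa, tree$tip.label)
  absent <- setdiff(tree$tip.label, cm$taxa)
  if (length(extra) || length(absent))
    stop("taxon mismatch between matrix and tree; only in matrix: [",
         paste(extra, collapse = ", "), "]; only on tree: [",
         paste(absent, collapse = ", "), "]")
  rc <- rc %||% quartile_rate_classes(clock$sigma %||% 0)
  ea <- .tree_edges_aged(tree)
  tr <- ea$tree
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  nu_base <- branch_expected_change(ea$older, ea$younger, clock)
  states <- cm$states[tr$tip.label, , drop = FALSE]
  k_use <- pmax(cm$k_per_char, 2L)

  per_char <- matrix(-Inf, length(rc$factors), ncol(states))
  for (ki in sort(unique(k_use))) {
    chars <- which(k_use == ki)
    st <- states[, chars, drop = FALSE]
    for (cl in seq_along(rc$factors)) {
      nu <- nu_base * rc$factors[cl]
      per_char[cl, chars] <- .prune_loglik(tr, st, ki, nu, ntip, nnode)
      if (ascertainment) {
        # subtract log P(variable) = log(1 - sum_s L(constant pattern s))
        p_inv <- .prune_invariant_prob(tr, ki, nu, ntip, nnode, nrow(st))
        per_char[cl, chars] <- per_char[cl, chars] - log1p(-p_inv)
      }
    }
  }
  logw <- log(rc$weights)
  char_ll <- apply(per_char + logw, 2, logsumexp)
  structure(sum(char_ll), per_character = char_ll)
}

# pruning over a block of characters sharing state count k; returns the
# per-character log-likelihood under one rate class
.prune_loglik <- function(tr, st, k, nu, ntip, nnode) {
  nchar_b <- ncol(st)
  partial <- vector("list", nnode)
  logscale <- numeric(nchar_b)
  # tip partials: one-hot, or all-ones for missing
  for (tip in seq_len(ntip)) {
    m <- matrix(0, k, nchar_b)
    s <- st[tip, ]
    obs <- !is.na(s)
    m[cbind(s[obs] + 1L, which(obs))] <- 1
    m[, !obs] <- 1
    partial[[tip]] <- m
  }
  edge <- tr$edge
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; child <- edge[e, 2]
    P <- mk_transition_probability(nu[e], k)
    up <- P %*% partial[[child]]
    if (is.null(partial[[par]])) partial[[par]] <- up
    else partial[[par]] <- partial[[par]] * up
  }
  root <- ntip + 1L
  pr <- partial[[root]]
  # rescale guard: values can underflow on deep trees; normalize once at root
  colmax <- apply(pr, 2, max)
  colmax[colmax == 0] <- 1
  lik <- colSums(pr / rep(colmax, each = k)) / k
  log(lik) + log(colmax)
}

# likelihood mass of the k constant patterns under one rate class
.prune_invariant_prob <- function(tr, k, nu, ntip, nnode, ntaxa) {
  st <- matrix(rep(0:(k - 1), each = ntaxa), ntaxa, k)
  rownames(st) <- tr$tip.label
  sum(exp(.prune_loglik(tr, st, k, nu, ntip, nnode)))
}

#' Minimum character change counts by Fitch parsimony
#'
#' Per-character minimum number of state changes on the fixed topology,
#' treating characters as unordered; missing and inapplicable cells impose
#' no constraint.
#'
#' @param tree a `phylo` (branch lengths ignored).
#' @param cm a [character_matrix()].
#' @return integer vector of step counts, one per character.
#' @export
count_parsimony_steps <- function(tree, cm) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  states <- cm$states[tr$tip.label, , drop = FALSE]
  nchar_m <- ncol(states)
  kmax <- max(pmax(cm$k_per_char, 1L))
  full <- bitwShiftL(1L, kmax) - 1L
  masks <- matrix(full, nnode, nchar_m)
  obs <- !is.na(states)
  masks[seq_len(ntip), ][obs] <- bitwShiftL(1L, states[obs])
  steps <- integer(nchar_m)
  edge <- tr$edge
  seen <- logical(nnode)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; child <- edge[e, 2]
    if (!seen[par]) {
      masks[par, ] <- masks[child, ]
      seen[par] <- TRUE
    } else {
      inter <- bitwAnd(masks[par, ], masks[child, ])
      empty <- inter == 0L
      steps <- steps + empty
      masks[par, ] <- ifelse(empty, bitwOr(masks[par, ], masks[child, ]), inter)
    }
  }
  steps
}

#' Fit lognormal and gamma rate distributions to parsimony change counts
#'
#' Treats per-character change counts as Poisson draws whose means follow a
#' lognormal or gamma distribution across characters, fits both by maximum
#' likelihood (the gamma mixture via its negative-binomial closed form, the
#' lognormal via Gauss-Hermite quadrature), and reports the log-likelihood
#' difference plus the expected number of invariant (zero-change)
#' characters under each fit.
#'
#' @param counts integer change counts, one per character (>= 10 characters).
#' @return a list with elements `lognormal`, `gamma`, `delta_loglik`
#'   (lognormal minus gamma) and `preferred`.
#' @export
fit_rate_distribution <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 10) stop("need at least 10 characters")
  if (all(counts == 0)) stop("all change counts are zero: no signal to fit")
  n <- length(counts)
  gh <- pracma::gaussHermite(20)
  wn <- gh$w / sqrt(pi)

  ln_nll <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    m <- exp(mu + sqrt(2) * s * gh$x)            # quadrature nodes for the mean
    ll <- vapply(counts, function(ci)
      log(sum(wn * stats::dpois(ci, m))), 0)
    -sum(ll)
  }
  mstart <- mean(log(counts + 0.5))
  sstart <- max(stats::sd(log(counts + 0.5)), 0.1)
  fit_ln <- stats::optim(c(mstart, log(sstart)), ln_nll, method = "Nelder-Mead",
                         control = list(maxit = 500))
  mu_ln <- fit_ln$par[1]; sd_ln <- exp(fit_ln$par[2])
  m_nodes <- exp(mu_ln + sqrt(2) * sd_ln * gh$x)
  inv_ln <- n * sum(wn * exp(-m_nodes))

  gm_nll <- function(par) {
    shape <- exp(par[1]); mean_m <- exp(par[2])
    -sum(stats::dnbinom(counts, size = shape, mu = mean_m, log = TRUE))
  }
  fit_gm <- stats::optim(c(0, log(mean(counts) + 1e-6)), gm_nll,
                         method = "Nelder-Mead", control = list(maxit = 500))
  shape <- exp(fit_gm$par[1]); mean_gm <- exp(fit_gm$par[2])
  inv_gm <- n * stats::dnbinom(0, size = shape, mu = mean_gm)

  delta <- -fit_ln$value - (-fit_gm$value)
  list(
    lognormal = list(meanlog = mu_ln, sdlog = sd_ln, loglik = -fit_ln$value,
                     expected_invariant = inv_ln),
    gamma = list(shape = shape, mean = mean_gm, loglik = -fit_gm$value,
                 expected_invariant = inv_gm),
    delta_loglik = delta,
    preferred = if (delta >= 0) "lognormal" else "gamma")
}
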