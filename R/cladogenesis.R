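# Reconstructed cladogenesis rates on the dated tree. Each branch's
# defining event is the single divergence that terminates it: the
# likelihood of a hypothesized origination rate given a branch is the
# Poisson probability of exactly one sampled cladogenetic event over the
# branch (with the chance of an event being sampled computed from the
# hypothesized origination - doubled, reflecting about two species per
# genus - and the empirical extinction and sampling rates) times the
# probability of zero sampled ancestors along the branch.

#' Construct a cladogenesis rate model
#'
#' Constant rate `lambda0`, or exponential decay
#' `lambda(t) = lambda0 * exp(-kappa * (t0 - t))` with `t0` the clade's
#' basal age; `kappa = 0` reduces the decay form to the constant one.
#'
#' @param form `"constant"` or `"exponential_decay"`.
#' @param lambda0 rate at the basal age, per lineage-Myr (> 0).
#' @param kappa decay constant per Myr (>= 0).
#' @param t0 basal age anchoring the decay clock (Ma).
#' @return an object of class `clado_rate_model`.
#' @export
clado_rate_model <- function(form = c("constant", "exponential_decay"),
                             lambda0, kappa = 0, t0 = NULL) {
  form <- match.arg(form)
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  if (kappa < 0) stop("kappa must be >= 0")
  if (form == "exponential_decay" && is.null(t0))
    stop("exponential decay needs a basal anchor age t0")
  structure(list(form = form, lambda0 = lambda0, kappa = kappa, t0 = t0),
            class = "clado_rate_model")
}

# hypothesized cladogenesis rate at age t (vectorized)
.clado_lambda_at <- function(t, model) {
  if (model$form == "constant" || model$kappa == 0)
    rep_len(model$lambda0, length(t))
  else model$lambda0 * exp(-model$kappa * (model$t0 - t))
}

# E(t) with origination = 2 * hypothesized lambda(t), extinction/sampling
# empirical; the decaying rate is discretized onto sub-Myr slices so the
# piecewise-constant solver applies
.clado_unsampled <- function(model, rates, step = 0.5) {
  cuts <- sort(unique(c(rates$older, rates$younger,
                        seq(rates$younger[nrow(rates)], rates$older[1], by = step))),
               decreasing = TRUE)
  older <- cuts[-length(cuts)]
  younger <- cuts[-1]
  mid <- (older + younger) / 2
  idx <- findInterval(-mid, -rates$older)
  idx[idx < 1] <- 1L; idx[idx > nrow(rates)] <- nrow(rates)
  fine <- skyline_rates(older, younger,
                        lambda = 2 * .clado_lambda_at(mid, model),
                        mu = rates$mu[idx], psi = rates$psi[idx])
  unsampled_probability(fine)
}

#' Log-likelihood of a cladogenesis rate model for one branch
#'
#' With `Lambda = integral over the branch of lambda(t) (1 - E(t)) dt`
#' (E computed with origination doubled) and `Psi = integral of psi(t) dt`,
#' the log-likelihood is `log(Lambda) - Lambda - Psi`: exactly one sampled
#' cladogenetic event and zero sampled ancestors.
#'
#' @param older,younger branch endpoint ages (Ma).
#' @param model a [clado_rate_model()].
#' @param rates empirical [skyline_rates()] (species-level).
#' @param E optional precomputed result of the internal doubled-origination
#'   solver, for reuse across branches of one model.
#' @return the branch log-likelihood.
#' @export
branch_clado_loglik <- function(older, younger, model, rates, E = NULL) {
  if (older < younger) stop("branch ages reversed (older < younger)")
  if (older == younger) return(-Inf)
  E <- E %||% .clado_unsampled(model, rates)
  seg <- .segments_in_window(older, younger, rates)
  Lam <- Psi <- 0
  for (s in seq_len(seg$n)) {
    i <- seg$idx[s]
    len <- seg$hi[s] - seg$lo[s]
    if (len <= 0) next
    Lam <- Lam + gl_integrate(function(t)
      .clado_lambda_at(t, model) * (1 - E(t)), seg$lo[s], seg$hi[s])
    Psi <- Psi + rates$psi[i] * len
  }
  if (Lam <= 0) return(-Inf)
  log(Lam) - Lam - Psi
}

#' Per-branch maximum-likelihood origination rates
#'
#' For every branch of the dated tree, the constant rate maximizing
#' [branch_clado_loglik()] for that branch alone, found by golden-section
#' search on the log-rate scale. Reported against the branch midpoint age,
#' for plotting rate-versus-time scatters.
#'
#' @param tree dated `phylo`.
#' @param rates empirical [skyline_rates()].
#' @param bounds log-rate search bounds.
#' @return data frame with `older`, `younger`, `midpoint`, `lambda_hat`,
#'   `loglik` per branch.
#' @export
per_branch_mle <- function(tree, rates, bounds = c(log(1e-4), log(20))) {
  ea <- .tree_edges_aged(tree)
  n <- length(ea$older)
  out <- data.frame(older = ea$older, younger = ea$younger,
                    midpoint = (ea$older + ea$younger) / 2,
                    lambda_hat = NA_real_, loglik = NA_real_)
  for (e in seq_len(n)) {
    if (ea$older[e] - ea$younger[e] <= 0) next
    opt <- .golden_max(function(ll) {
      m <- clado_rate_model("constant", lambda0 = exp(ll))
      branch_clado_loglik(ea$older[e], ea$younger[e], m, rates)
    }, bounds[1], bounds[2], tol = 1e-4)
    out$lambda_hat[e] <- exp(opt$x)
    out$loglik[e] <- opt$value
  }
  out
}

#' Fit a cladogenesis rate model to all branches of a dated tree
#'
#' Maximizes the sum of [branch_clado_loglik()] over the branches, over
#' `lambda0` (constant) or `(lambda0, kappa)` (exponential decay, `kappa`
#' bounded in [0, 2]/Myr, initialized from the constant fit).
#'
#' @param tree dated `phylo` with at least 2 branches, or a data frame of
#'   branches with columns `older` and `younger` (Ma).
#' @param rates empirical [skyline_rates()].
#' @param form `"constant"` or `"exponential_decay"`.
#' @param t0 basal anchor age; defaults to the root age (or oldest branch).
#' @return an object of class `clado_fit`: `model`, `loglik`,
#'   `convergence`.
#' @export
fit_clado_model <- function(tree, rates, form = c("constant", "exponential_decay"),
                            t0 = NULL) {
  form <- match.arg(form)
  if (inherits(tree, "phylo")) {
    ea <- .tree_edges_aged(tree)
    t0 <- t0 %||% tree$root.time
  } else {
    ea <- list(older = tree$older, younger = tree$younger)
    t0 <- t0 %||% max(ea$older)
  }
  keep <- ea$older - ea$younger > 1e-9
  if (sum(keep) < 2) stop("need at least 2 branches of positive duration")
  total_ll <- function(lambda0, kappa) {
    m <- clado_rate_model(if (kappa > 0) "exponential_decay" else "constant",
                          lambda0 = lambda0, kappa = kappa, t0 = t0)
    E <- .clado_unsampled(m, rates)
    sum(vapply(which(keep), function(e)
      branch_clado_loglik(ea$older[e], ea$younger[e], m, rates, E), 0))
  }
  const <- .golden_max(function(ll) total_ll(exp(ll), 0),
                       log(1e-4), log(20), tol = 1e-4)
  if (form == "constant") {
    return(structure(list(
      model = clado_rate_model("constant", lambda0 = exp(const$x), t0 = t0),
      loglik = const$value, convergence = 0L), class = "clado_fit"))
  }
  opt <- stats::optim(c(const$x, 0.01),
                      function(p) -total_ll(exp(p[1]), min(max(p[2], 0), 2)),
                      method = "L-BFGS-B",
                      lower = c(log(1e-4), 0), upper = c(log(20), 2))
  loglik <- -opt$value
  kappa <- opt$par[2]
  if (loglik < const$value) {      # nesting: decay can never fit worse
    loglik <- const$value
    kappa <- 0
    opt$par[1] <- const$x
  }
  structure(list(
    model = clado_rate_model("exponential_decay", lambda0 = exp(opt$par[1]),
                             kappa = kappa, t0 = t0),
    loglik = loglik, convergence = opt$convergence), class = "clado_fit")
}

#' Likelihood-ratio test of exponential decay against a constant rate
#'
#' Statistic `2 (lnL_decay - lnL_constant)`, compared to a chi-square with
#' one degree of freedom (one extra parameter, kappa).
#'
#' @param constant,exponential [fit_clado_model()] results (or any lists
#'   with a `loglik` element) for nested fits on identical branches.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
likelihood_ratio_test <- function(constant, exponential) {
  stat <- 2 * (exponential$loglik - constant$loglik)
  if (stat < -1e-6)
    stop("nesting violated: exponential log-likelihood below constant")
  stat <- max(stat, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}
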