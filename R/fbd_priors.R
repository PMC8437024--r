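# Fossilized-birth-death prior probabilities of branch durations under
# piecewise-constant origination (lambda), extinction (mu) and fossil
# sampling (psi) rates. All analysed tips are fossils, so there is no
# extant-sampling probability: the probability E(t) that a lineage alive at
# age t is never sampled (itself or via descendants) satisfies
#   dE/dt = mu - (lambda + mu + psi) E + lambda E^2,   t increasing into the past,
# with E = 1 at the young edge of the rate window.

#' Construct a piecewise-constant rate skyline
#'
#' @param older,younger interval bounds in Ma, ordered old to young and
#'   contiguous.
#' @param lambda,mu,psi origination, extinction and sampling rates per
#'   lineage-Myr (recycled if scalar).
#' @param ... further per-interval columns (e.g. a completeness diagnostic).
#' @return a data frame of class `skyline_rates`.
#' @export
skyline_rates <- function(older, younger, lambda, mu, psi, ...) {
  n <- length(older)
  df <- data.frame(older = as.numeric(older), younger = as.numeric(younger),
                   lambda = rep_len(as.numeric(lambda), n),
                   mu = rep_len(as.numeric(mu), n),
                   psi = rep_len(as.numeric(psi), n), ...)
  if (any(df$older <= df$younger))
    stop("interval bounds must satisfy older > younger")
  if (n > 1 && any(abs(df$older[-1] - df$younger[-n]) > 1e-9))
    stop("skyline intervals must be contiguous, ordered old to young")
  if (any(df$lambda < 0 | df$mu < 0 | df$psi < 0))
    stop("rates must be >= 0")
  class(df) <- c("skyline_rates", "data.frame")
  df
}

# closed-form E inside one constant-rate interval: s = time before the
# interval's young edge (s >= 0), with E(0) = e0
.e_const <- function(s, lambda, mu, psi, e0) {
  if (lambda > 0) {
    S <- lambda + mu + psi
    disc <- S * S - 4 * lambda * mu
    sq <- sqrt(max(disc, 0))
    x1 <- (S - sq) / (2 * lambda)
    x2 <- (S + sq) / (2 * lambda)
    if (sq < 1e-12) {                      # coincident roots
      x <- S / (2 * lambda)
      return(x + (e0 - x) / (1 - lambda * (e0 - x) * s))
    }
    if (abs(e0 - x2) < 1e-14) return(rep(e0, length(s)))
    K <- (e0 - x1) / (e0 - x2)
    g <- K * exp(-sq * s)
    (x1 - x2 * g) / (1 - g)
  } else {
    tot <- mu + psi
    if (tot == 0) return(rep(e0, length(s)))
    einf <- mu / tot
    einf + (e0 - einf) * exp(-tot * s)
  }
}

# closed-form antiderivative of E inside one constant-rate interval:
# integral of E(u) du from u = 0 to s (s measured from the interval's young
# edge), with E(0) = e0. Matches the Riccati solution used in .e_const.
.e_const_integral <- function(s, lambda, mu, psi, e0) {
  if (lambda > 0) {
    S <- lambda + mu + psi
    disc <- S * S - 4 * lambda * mu
    sq <- sqrt(max(disc, 0))
    if (sq < 1e-12)
      return(gl_integrate(function(u) .e_const(u, lambda, mu, psi, e0), 0, s))
    x1 <- (S - sq) / (2 * lambda)
    x2 <- (S + sq) / (2 * lambda)
    if (abs(e0 - x2) < 1e-14) return(e0 * s)
    K <- (e0 - x1) / (e0 - x2)
    x1 * s + (x1 - x2) / sq * log((1 - K * exp(-sq * s)) / (1 - K))
  } else {
    tot <- mu + psi
    if (tot == 0) return(e0 * s)
    einf <- mu / tot
    einf * s + (e0 - einf) * (1 - exp(-tot * s)) / tot
  }
}

#' Probability that a lineage leaves no sampled descendant
#'
#' Solves the FBD unsampled-lineage equation piecewise over a rate skyline,
#' using the constant-rate closed form inside each interval with continuity
#' at boundaries and E = 1 at the young edge of the window (no extant
#' sampling).
#'
#' @param rates a [skyline_rates()] covering the window of interest.
#' @return an object of class `unsampled_prob`: call it as a function of
#'   age (Ma) to evaluate E(t).
#' @export
unsampled_probability <- function(rates) {
  n <- nrow(rates)
  e0 <- numeric(n)           # E at the young edge of each interval
  e0[n] <- 1
  if (n > 1) for (i in rev(seq_len(n - 1))) {
    j <- i + 1L
    e0[i] <- .e_const(rates$older[j] - rates$younger[j],
                      rates$lambda[j], rates$mu[j], rates$psi[j], e0[j])
  }
  young_edge <- rates$younger[n]
  old_edge <- rates$older[1]
  f <- function(t) {
    t <- as.numeric(t)
    if (any(t < young_edge - 1e-9 | t > old_edge + 1e-9))
      stop("age outside the rate window [", young_edge, ", ", old_edge, "] Ma")
    t <- pmin(pmax(t, young_edge), old_edge)
    out <- numeric(length(t))
    # interval index: youngest interval whose older bound >= t
    idx <- findInterval(-t, -rates$older)
    idx[idx < 1] <- 1L
    idx[idx > n] <- n
    for (i in unique(idx)) {
      sel <- idx == i
      out[sel] <- .e_const(t[sel] - rates$younger[i], rates$lambda[i],
                           rates$mu[i], rates$psi[i], e0[i])
    }
    pmin(pmax(out, 0), 1)
  }
  structure(f, class = c("unsampled_prob", "function"),
            e_young = e0, rates = rates)
}

# split [younger, older] at skyline interval boundaries; returns plain
# vectors (this sits on the hot path of node-age optimization)
.segments_in_window <- function(older, younger, rates) {
  ro <- rates$older
  cuts <- sort(unique(c(younger, older, ro[ro > younger & ro < older])))
  lo <- cuts[-length(cuts)]
  hi <- cuts[-1]
  idx <- findInterval(-(lo + hi) / 2, -ro)
  idx[idx < 1L] <- 1L
  idx[idx > length(ro)] <- length(ro)
  list(lo = lo, hi = hi, idx = idx, n = length(lo))
}

#' FBD log prior probability of one branch duration
#'
#' The log-probability that a lineage persisting from `older` to `younger`
#' is never itself sampled over that span and produces no branching event
#' whose other descendant clade is ever sampled:
#' `-integral over the branch of [psi(t) + lambda(t) (1 - E(t))] dt`.
#'
#' @param older,younger branch endpoint ages in Ma.
#' @param rates a [skyline_rates()].
#' @param E optionally, a precomputed [unsampled_probability()] for `rates`.
#' @return log prior probability (<= 0).
#' @export
branch_log_prior <- function(older, younger, rates, E = NULL) {
  if (older < younger) stop("branch ages reversed (older < younger)")
  if (older == younger) return(0)
  if (younger < rates$younger[nrow(rates)] - 1e-9 ||
      older > rates$older[1] + 1e-9)
    stop("branch [", younger, ", ", older, "] outside the rate window")
  E <- E %||% unsampled_probability(rates)
  seg <- .segments_in_window(older, younger, rates)
  e_young <- attr(E, "e_young")
  lam_v <- rates$lambda; psi_v <- rates$psi; mu_v <- rates$mu
  yb <- rates$younger
  total <- 0
  for (s in seq_len(seg$n)) {
    i <- seg$idx[s]
    len <- seg$hi[s] - seg$lo[s]
    if (len <= 0) next
    lam <- lam_v[i]; psi <- psi_v[i]
    if (lam > 0) {
      int_e <- .e_const_integral(seg$hi[s] - yb[i], lam, mu_v[i], psi,
                                 e_young[i]) -
        .e_const_integral(seg$lo[s] - yb[i], lam, mu_v[i], psi, e_young[i])
      total <- total + psi * len + lam * (len - int_e)
    } else {
      total <- total + psi * len
    }
  }
  min(-total, 0)
}

#' FBD log prior of a dated tree (lnP FBD)
#'
#' Sum of [branch_log_prior()] over every branch, optionally including a
#' root stem running from `origin_age` down to the root.
#'
#' @param tree dated `phylo`.
#' @param rates a [skyline_rates()].
#' @param origin_age optional basal divergence age (Ma) older than the root,
#'   adding a stem branch.
#' @param E optional precomputed [unsampled_probability()].
#' @return total log prior (`lnP FBD`), with per-branch values in attribute
#'   `"per_branch"`.
#' @export
tree_log_prior <- function(tree, rates, origin_age = NULL, E = NULL) {
  E <- E %||% unsampled_probability(rates)
  ea <- .tree_edges_aged(tree)
  per_branch <- vapply(seq_along(ea$older), function(e)
    branch_log_prior(ea$older[e], ea$younger[e], rates, E), 0)
  total <- sum(per_branch)
  if (!is.null(origin_age)) {
    if (origin_age < tree$root.time - 1e-9)
      stop("origin_age is younger than the root")
    total <- total + branch_log_prior(origin_age, tree$root.time, rates, E)
  }
  structure(total, per_branch = per_branch)
}
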