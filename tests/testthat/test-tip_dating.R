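make_fc <- function(df) fa_candidates(df)

test_that("beta(1,N) rank masses are correct and telescope to one", {
  expect_equal(beta_rank_mass(1, 1), 1)
  expect_equal(beta_rank_mass(1, 2), 3 / 4)      # oldest of two candidates
  for (N in c(2, 3, 7, 20, 50)) {
    masses <- beta_rank_mass(seq_len(N), N)
    expect_equal(sum(masses), 1, tolerance = 1e-12)
    expect_true(all(diff(masses) < 0))           # mass concentrates old-ward
  }
  expect_error(beta_rank_mass(3, 2), "1..N")
})

test_that("FA replicates share collection draws and stay within bounds", {
  fc <- make_fc(data.frame(
    taxon = c("A", "A", "B", "B"),
    collection = c("c1", "c2", "c2", "c3"),
    max_ma = c(470, 469, 469, 468), min_ma = c(466, 464, 464, 463)))
  rep <- sample_fa_replicate(fc, seed = 8)
  expect_equal(rep$collection_ages[["c2"]], rep$collection_ages[["c2"]])
  # the shared collection c2 has one age seen by both taxa
  expect_equal(unname(rep$collection_ages["c2"]),
               unname(rep$collection_ages["c2"]))
  for (cl in names(rep$collection_ages)) {
    b <- fc[fc$collection == cl, ][1, ]
    expect_gte(rep$collection_ages[[cl]], b$min_ma)
    expect_lte(rep$collection_ages[[cl]], b$max_ma)
  }
  # each taxon's FA is its oldest drawn candidate
  expect_equal(unname(rep$ages["A"]),
               max(rep$collection_ages[c("c1", "c2")]))
  r2 <- sample_fa_replicate(fc, seed = 8)
  expect_identical(rep$ages, r2$ages)            # seeded determinism
})

test_that("which candidate ends up oldest matches the overlap geometry", {
  fc <- make_fc(data.frame(taxon = "A", collection = c("cA", "cB"),
                           max_ma = c(470, 469), min_ma = c(466, 464)))
  hits <- vapply(1:1000, function(s)
    sample_fa_replicate(fc, seed = s)$fa_collection[["A"]] == "cA", TRUE)
  # P(U(466,470) > U(464,469)) = 0.775
  p <- 0.775
  expect_lt(abs(mean(hits) - p), 3 * sqrt(p * (1 - p) / 1000))
})

test_that("lnP FAs sums beta bin masses and vanishes for single candidates", {
  fc1 <- make_fc(data.frame(taxon = c("A", "B"), collection = c("c1", "c2"),
                            max_ma = c(470, 468), min_ma = c(466, 464)))
  rep1 <- sample_fa_replicate(fc1, seed = 2)
  expect_identical(fa_log_prior(rep1, fc1), 0)   # N = 1 is uniform

  fc2 <- make_fc(data.frame(taxon = c("A", "A", "A"),
                            collection = c("c1", "c2", "c3"),
                            max_ma = c(470, 470, 470), min_ma = c(466, 466, 466)))
  rep2 <- sample_fa_replicate(fc2, seed = 4)
  expect_equal(fa_log_prior(rep2, fc2), log(beta_rank_mass(1, 3)))

  bad <- rep2
  bad$fa_collection[["A"]] <- "zzz"
  expect_error(fa_log_prior(bad, fc2), "not among")
})

test_that("node dating is trivial for two tips and matches grid search on four", {
  rates <- skyline_rates(c(490, 470), c(470, 450), 0.3, 0.25, 0.2)
  cm2 <- character_matrix(matrix(c(0L, 1L), 2, 1,
                                 dimnames = list(c("a", "b"), NULL)))
  topo2 <- ape::read.tree(text = "(a,b);")
  fa2 <- c(a = 465, b = 463)
  ck <- clock_model("strict", alpha = 0.03)
  dated2 <- date_internal_nodes(topo2, cm2, 472, fa2, ck, rates)
  expect_equal(dated2$root.time, 472)
  expect_equal(node_ages(dated2)[1:2], fa2, ignore_attr = TRUE)
  expect_error(date_internal_nodes(topo2, cm2, 460, fa2, ck, rates),
               "older than every first appearance")

  # 4-tip balanced tree: coordinate ascent vs exhaustive 0.1-Myr grid
  topo <- ape::read.tree(text = "((a,b),(c,d));")
  fa <- c(a = 466, b = 464.5, c = 465, d = 463)
  cm <- random_char_matrix(c("a", "b", "c", "d"), 12, seed = 3)
  ck <- clock_model("strict", alpha = 0.05, sigma = 0.5)
  rc <- quartile_rate_classes(0.5)
  E <- unsampled_probability(rates)
  basal <- 470
  dated <- date_internal_nodes(topo, cm, basal, fa, ck, rates, rc)

  obj <- function(a1, a2) {
    ages <- c(fa[topo$tip.label], basal, a1, a2)
    tr <- tree_from_ages(topo, ages)
    as.numeric(matrix_log_likelihood(tr, cm, ck, rc)) +
      as.numeric(tree_log_prior(tr, rates, E = E))
  }
  g1 <- seq(466.05, 469.95, by = 0.1)   # node above a,b
  g2 <- seq(465.05, 469.95, by = 0.1)   # node above c,d
  val <- outer(g1, g2, Vectorize(obj))
  best <- which(val == max(val), arr.ind = TRUE)[1, ]
  ages_hat <- node_ages(dated)
  expect_lt(abs(ages_hat[6] - g1[best[1]]), 0.2)
  expect_lt(abs(ages_hat[7] - g2[best[2]]), 0.2)
  expect_gte(attr(dated, "objective"), val[best[1], best[2]] - 0.01)
})

test_that("with a flat likelihood the FBD prior pushes nodes young", {
  rates <- skyline_rates(c(490, 470), c(470, 450), 0.3, 0.25, 1.5)
  topo <- ape::read.tree(text = "((a,b),(c,d));")
  fa <- c(a = 466, b = 464.5, c = 465, d = 463)
  # invariant characters with a vanishing clock rate: likelihood truly flat
  cm <- character_matrix(matrix(0L, 4, 4,
                                dimnames = list(c("a", "b", "c", "d"), NULL)))
  ck <- clock_model("strict", alpha = 1e-6)
  dated <- date_internal_nodes(topo, cm, 470, fa, ck, rates)
  ages <- node_ages(dated)
  # internal nodes hug their oldest descendants (short unsampled branches)
  expect_lt(ages[6] - 466, 0.6)
  expect_lt(ages[7] - 465, 0.6)
})

test_that("posterior assembly reproduces direct component calls", {
  set.seed(40)
  spec <- simulation_spec(seed = 40, taxon_cap = 60)
  sim <- suppressWarnings(simulate_fbd_tree(spec, min_sampled = 6))
  keep <- sim$tree$tip.label[seq_len(min(6, ape::Ntip(sim$tree)))]
  dated_keep <- prune_dated(sim$tree, keep)
  tr <- dated_keep
  tr$root.time <- NULL                     # topology only
  occ <- simulate_occurrence_table(sim, spec, seed = 41)
  fc <- occ$fa_candidates[occ$fa_candidates$taxon %in% keep, ]
  class(fc) <- c("fa_candidates", "data.frame")
  cm <- simulate_characters(dated_keep, spec$clock, 30, seed = 42)
  rates <- suppressWarnings(occurrence_skyline(occ$occurrences, spec$timescale,
                                               seed = 1))
  a0 <- ceiling(max(fc$max_ma)) + 2
  cfg <- analysis_config(scan_min = a0, scan_max = a0 + 0.5, grid_step = 1,
                         replicates = 1, seed = 7, sigma = 0)
  scan <- scan_posterior(tr, cm, fc, rates, cfg, models = "strict_fbd")
  mp <- scan$posteriors[["strict_fbd"]]

  rep <- sample_fa_replicate(fc, seed = cfg$seed + 1)
  clock <- scan$clocks[["strict_fbd"]]
  rc <- quartile_rate_classes(0, cfg$n_rate_classes)
  dated <- date_internal_nodes(tr, cm, a0, rep$ages, clock, rates, rc)
  expect_equal(mp$lnp_fa, fa_log_prior(rep, fc), tolerance = 1e-12)
  expect_equal(mp$lnl_alpha, as.numeric(matrix_log_likelihood(dated, cm, clock, rc)),
               tolerance = 1e-9)
  expect_equal(mp$lnp_fbd, as.numeric(tree_log_prior(dated, rates)),
               tolerance = 1e-9)
  expect_equal(mp$ln_posterior, mp$lnp_fa + mp$lnl_alpha + mp$lnp_fbd,
               tolerance = 1e-12)
  # with a single replicate the surface equals the component sum
  s <- scan$surfaces
  expect_equal(s$ln_posterior[is.finite(s$ln_posterior)][1], mp$ln_posterior,
               tolerance = 1e-9)
})

test_that("an early burst with equal rates reproduces the strict model pointwise", {
  rates <- skyline_rates(c(490, 470), c(470, 450), 0.3, 0.25, 0.2)
  topo <- ape::read.tree(text = "((a,b),(c,d));")
  fa <- c(a = 466, b = 464.5, c = 465, d = 463)
  cm <- random_char_matrix(c("a", "b", "c", "d"), 10, seed = 13)
  rc <- quartile_rate_classes(0.5)
  for (basal in c(469, 472, 476)) {
    st <- clock_model("strict", alpha = 0.04, sigma = 0.5)
    eb <- clock_model("early_burst", alpha_early = 0.04, alpha_late = 0.04,
                      tau = 465, sigma = 0.5)
    d_st <- date_internal_nodes(topo, cm, basal, fa, st, rates, rc)
    d_eb <- date_internal_nodes(topo, cm, basal, fa, eb, rates, rc)
    expect_equal(attr(d_st, "objective"), attr(d_eb, "objective"),
                 tolerance = 1e-12)
    expect_equal(node_ages(d_st), node_ages(d_eb), tolerance = 1e-9)
  }
})

test_that("credible intervals match brute-force cumulative mass", {
  # point mass
  s1 <- data.frame(age = 466:470, ln_posterior = c(-1e3, -1e3, 0, -1e3, -1e3))
  expect_equal(credible_interval(s1, 0.95), c(older = 468, younger = 468))

  # symmetric two-point surface at level 0.5: single (older) point by tie-break
  s2 <- data.frame(age = c(466, 470), ln_posterior = c(-1, -1))
  ci <- credible_interval(s2, 0.5)
  expect_equal(ci, c(older = 470, younger = 470))

  # Gaussian-shaped surface vs direct cumulative computation (same tie rule:
  # higher posterior first, then older age)
  ages <- seq(466, 521, by = 1)
  lnp <- dnorm(ages, 480, 4, log = TRUE)
  ci <- credible_interval(data.frame(age = ages, ln_posterior = lnp), 0.95)
  p <- exp(lnp - max(lnp)); p <- p / sum(p)
  ord <- order(-p, -ages)
  m <- which(cumsum(p[ord]) >= 0.95)[1]
  expect_equal(unname(ci), c(max(ages[ord[1:m]]), min(ages[ord[1:m]])))
  expect_true(ci[1] >= 480 && ci[2] <= 480)
  # selected mass reaches the level and is minimal in point count
  expect_gte(sum(p[ord[1:m]]), 0.95)
  expect_lt(sum(p[ord[1:(m - 1)]]), 0.95)

  expect_warning(credible_interval(data.frame(age = 1:3,
                                              ln_posterior = rep(-2, 3))),
                 "flat")
})

test_that("Bayes factors compare grid-summed masses", {
  a <- data.frame(age = 466:470, ln_posterior = c(-5, -4, -3, -4, -5))
  expect_equal(bayes_factor(a, a), 1)
  b <- a; b$ln_posterior <- a$ln_posterior - 1
  expect_equal(bayes_factor(a, b), exp(1), tolerance = 1e-12)
  # analytic two-surface check
  c1 <- data.frame(age = 1:2, ln_posterior = log(c(0.3, 0.1)))
  c2 <- data.frame(age = 1:2, ln_posterior = log(c(0.05, 0.05)))
  expect_equal(bayes_factor(c1, c2), 0.4 / 0.1, tolerance = 1e-12)
  expect_error(bayes_factor(a, data.frame(age = 1:3, ln_posterior = 1:3)),
               "non-overlapping")
  # conditional variant restricted to chosen ages
  expect_equal(bayes_factor(c1, c2, at_ages = 1), 0.3 / 0.05, tolerance = 1e-12)
})
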