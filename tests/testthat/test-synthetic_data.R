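test_that("perfect sampling makes the reconstructed tree match the complete tree", {
  ts <- timescale(paste0("b", 1:6), seq(480, 460, -4), seq(476, 456, -4))
  spec <- simulation_spec(origin = 479, ts = ts, lambda = 0.3, mu = 0,
                          psi = 15, sampling_sdlog = 0, taxon_cap = 60,
                          seed = 3)
  sim <- suppressWarnings(simulate_fbd_tree(spec))
  # with mu = 0 and near-certain sampling almost every lineage is a sampled
  # tip (a lineage born just before the window's end can still be missed)
  expect_gte(length(sim$sampled_ids) / nrow(sim$lineages), 0.95)
  expect_equal(ape::Ntip(sim$tree), length(sim$sampled_ids))
  expect_lte(ape::Ntip(sim$complete_tree) - ape::Ntip(sim$tree),
             0.05 * nrow(sim$lineages) + 1)
})

test_that("zero sampling reports the rejection loop", {
  ts <- timescale(paste0("b", 1:3), seq(480, 472, -4), seq(476, 468, -4))
  spec <- simulation_spec(origin = 479, ts = ts, lambda = 0.3, mu = 0.2,
                          psi = 0, seed = 1)
  expect_error(simulate_fbd_tree(spec, max_attempts = 5), "rejection loop")
})

test_that("sampled-taxon counts agree with the analytic clade-sampling expectation", {
  # P(>= 1 sampled | origin) = 1 - E(origin); check the rejection-free
  # fraction of attempts with any sampled lineage over many seeds
  ts <- timescale(paste0("b", 1:5), seq(470, 454, -4), seq(466, 450, -4))
  lam <- 0.25; mu <- 0.35; psi <- 0.12
  rates <- skyline_rates(ts$older, ts$younger, lam, mu, psi)
  p_expect <- 1 - unsampled_probability(rates)(469.9)
  spec <- simulation_spec(origin = 469.9, ts = ts, lambda = lam, mu = mu,
                          psi = psi, sampling_sdlog = 0, taxon_cap = 4000,
                          seed = 1)
  hits <- vapply(1:500, function(s) {
    sim <- tryCatch(suppressWarnings(
      simulate_fbd_tree(spec, seed = s, min_sampled = 1L, max_attempts = 1L)),
      error = function(e) NULL)
    !is.null(sim)
  }, TRUE)
  p_hat <- mean(hits)
  se <- sqrt(p_expect * (1 - p_expect) / 500)
  expect_lt(abs(p_hat - p_expect), 3 * se)
})

test_that("tip first appearances line up with the occurrence-derived candidates", {
  spec <- simulation_spec(seed = 9, taxon_cap = 120)
  sim <- suppressWarnings(simulate_fbd_tree(spec, min_sampled = 10))
  occ <- simulate_occurrence_table(sim, spec, seed = 10)
  fc <- occ$fa_candidates
  expect_true(all(sim$tree$tip.label %in% fc$taxon))
  # every candidate's bounds overlap the taxon's oldest collection's bounds
  for (tx in unique(fc$taxon)[1:5]) {
    cand <- fc[fc$taxon == tx, ]
    oldest <- cand[which.max(cand$max_ma), ]
    expect_true(all(cand$max_ma > oldest$min_ma & cand$min_ma < oldest$max_ma))
  }
  # occurrence table passes the reader validations via a round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ$occurrences, path)
  expect_equal(nrow(read_occurrences(path)), nrow(occ$occurrences))
})

test_that("sampling heterogeneity controls dispersion and FA candidate counts", {
  spec0 <- simulation_spec(seed = 23, sampling_sdlog = 0, taxon_cap = 150,
                           psi = 0.5)
  sim <- suppressWarnings(simulate_fbd_tree(spec0, min_sampled = 25))

  # scale = 0: homogeneous sampling; among taxa alive through a whole
  # interval (known from the simulation truth, so counts share one
  # exposure) the lognormal fit recovers scale ~ 0
  occ0 <- simulate_occurrence_table(sim, spec0, seed = 24)
  pm <- bin_collections(occ0$occurrences, spec0$timescale, seed = 1)
  ts0 <- spec0$timescale
  lin <- sim$lineages
  n_through <- vapply(seq_len(nrow(ts0)), function(i)
    sum(lin$birth >= ts0$older[i] & lin$death <= ts0$younger[i]), 0)
  rich <- which.max(n_through)
  through <- paste0("t", lin$id[lin$birth >= ts0$older[rich] &
                                  lin$death <= ts0$younger[rich]])
  cts <- pm$counts[intersect(through, rownames(pm$counts)), rich]
  fit <- suppressWarnings(fit_sampling_lognormal(cts[cts > 0],
                                                 ts0$older[rich] -
                                                   ts0$younger[rich]))
  expect_lt(fit$sdlog, 0.5)

  # widening age uncertainty never decreases any taxon's candidate count
  spec_narrow <- spec0; spec_narrow$age_uncertainty <- 0.4
  spec_wide <- spec0; spec_wide$age_uncertainty <- 4
  occ_n <- simulate_occurrence_table(sim, spec_narrow, seed = 30)
  occ_w <- simulate_occurrence_table(sim, spec_wide, seed = 30)
  n_n <- table(occ_n$fa_candidates$taxon)
  n_w <- table(occ_w$fa_candidates$taxon)
  shared <- intersect(names(n_n), names(n_w))
  expect_true(all(n_w[shared] >= n_n[shared]))
})

test_that("character simulation follows the Mk transition probabilities", {
  # alpha -> 0: all characters invariant
  tr <- make_dated_tree("((a:2,b:2):3,(c:4,d:4):1);", root_time = 470)
  cm0 <- simulate_characters(tr, clock_model("strict", alpha = 1e-9), 30,
                             seed = 2)
  expect_true(all(count_parsimony_steps(tr, cm0) == 0L))

  # two-tip tree: tip mismatch frequency matches P(different)
  tr2 <- make_dated_tree("(a:5,b:5);", root_time = 465)
  ck <- clock_model("strict", alpha = 0.04)   # nu = 0.2 per branch
  cm <- simulate_characters(tr2, ck, 1e4, k_states = 2L, seed = 3)
  mism <- mean(cm$states["a", ] != cm$states["b", ])
  # tips mismatch iff their independent nu = 0.2 paths from the (uniform)
  # root end in different states: 1 - sum_x P(r -> x)^2
  P <- mk_transition_probability(0.2, 2)
  p_mm <- 1 - sum(P[1, ]^2)
  se <- sqrt(p_mm * (1 - p_mm) / 1e4)
  expect_lt(abs(mism - p_mm), 3 * se)
})

test_that("an early burst leaves more change per Myr before the breakpoint", {
  ok <- 0L
  n_used <- 0L
  for (s in 1:50) {
    spec <- simulation_spec(seed = 1000 + s, taxon_cap = 100)
    sim <- suppressWarnings(simulate_fbd_tree(spec, min_sampled = 10))
    tr <- sim$tree
    cm <- simulate_characters(tr, spec$clock, 40, seed = 2000 + s)
    bc <- attr(cm, "branch_changes")
    tau <- spec$clock$tau
    pre <- bc$younger >= tau
    post <- bc$older <= tau
    t_pre <- sum(bc$older[pre] - bc$younger[pre])
    t_post <- sum(bc$older[post] - bc$younger[post])
    if (t_pre < 5 || t_post < 5) next   # need exposure on both sides
    n_used <- n_used + 1L
    rate_pre <- sum(bc$changes[pre]) / t_pre
    rate_post <- sum(bc$changes[post]) / t_post
    if (rate_pre > rate_post) ok <- ok + 1L
  }
  expect_gte(n_used, 25L)
  expect_gte(ok / n_used, 0.95)
})

test_that("data simulated with a burst favour the early-burst model in the scan", {
  pref <- logical(0)
  s <- 100
  while (length(pref) < 20 && s < 4000) {
    s <- s + 13
    ck <- clock_model("early_burst", alpha_early = 0.045, alpha_late = 0.015,
                      tau = 462, sigma = 0)
    spec <- simulation_spec(seed = s, taxon_cap = 120, clock = ck, psi = 0.4,
                            sampling_sdlog = 0.5)
    sim <- tryCatch(suppressWarnings(simulate_fbd_tree(spec, min_sampled = 10)),
                    error = function(e) NULL)
    if (is.null(sim)) next
    full <- sim$tree
    tip_ages <- node_ages(full)[seq_len(ape::Ntip(full))]
    lin <- sim$lineages[sim$sampled_ids, ]
    post_exp <- sum(pmax(0, pmin(lin$birth, 462) - lin$death))
    pre_exp <- sum(pmax(0, lin$birth - pmax(lin$death, 462)))
    if (post_exp < 20 || pre_exp < 15) next
    tips <- full$tip.label
    ord <- order(tip_ages)
    keep <- tips[unique(c(ord[1:4], ord[round(seq(1, length(ord),
                                                  length.out = 8))]))]
    keep <- keep[seq_len(min(10, length(keep)))]
    dtr <- prune_dated(full, keep)
    topo <- dtr; topo$root.time <- NULL
    occ <- simulate_occurrence_table(sim, spec, seed = s + 1)
    fc <- occ$fa_candidates[occ$fa_candidates$taxon %in% keep, ]
    class(fc) <- c("fa_candidates", "data.frame")
    cm <- simulate_characters(dtr, ck, 40, seed = s + 2)
    a0 <- ceiling(max(fc$max_ma)) + 1
    cfg <- analysis_config(scan_min = a0, scan_max = a0 + 3, grid_step = 3,
                           replicates = 1, seed = s, sigma = 0, tau = 462)
    scan <- tryCatch(scan_posterior(topo, cm, fc, spec$rates, cfg,
                                    models = c("strict_fbd",
                                               "early_burst_fbd")),
                     error = function(e) NULL)
    if (is.null(scan)) next
    pref <- c(pref, scan$posteriors[["early_burst_fbd"]]$ln_posterior >
                scan$posteriors[["strict_fbd"]]$ln_posterior)
  }
  expect_equal(length(pref), 20L)
  expect_gte(mean(pref), 0.9)
})

test_that("fixture bundles are deterministic, self-consistent and readable", {
  spec <- simulation_spec(seed = 61, taxon_cap = 150, n_char = 30)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressWarnings(make_fixture_bundle(spec, d1, n_range = c(10, 60)))
  suppressWarnings(make_fixture_bundle(spec, d2, n_range = c(10, 60)))
  files <- c("tree.nwk", "characters.nex", "occurrences.csv",
             "fa_candidates.csv", "timescale.yml", "config.yml", "meta.yml")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # everything re-reads cleanly and consistently
  tr <- read_dated_tree(file.path(d1, "tree.nwk"))
  cm <- read_character_matrix(file.path(d1, "characters.nex"))
  occ <- read_occurrences(file.path(d1, "occurrences.csv"))
  fc <- read_fa_candidates(file.path(d1, "fa_candidates.csv"))
  ts <- read_timescale(file.path(d1, "timescale.yml"))
  cfg <- read_config(file.path(d1, "config.yml"))
  expect_setequal(cm$taxa, tr$tip.label)
  expect_true(all(tr$tip.label %in% fc$taxon))
  expect_true(all(occ$max_ma <= ts$older[1]))
  expect_gt(cfg$scan_min, max(fc$max_ma))
})
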