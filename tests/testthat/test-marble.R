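test_that("transition probabilities are a normalized Boltzmann softmax", {
  # flat landscape: uniform over N + 1 options
  flat <- landscape_from_T(rep(0, 8))
  p <- transition_probabilities(flat, 3, beta = 1)
  expect_equal(p, rep(1 / 4, 4))

  # two-option case: one neighbor lower by 1 at beta = 1 -> e / (e + 1)
  l1 <- landscape_from_T(c(1, 0))
  p1 <- transition_probabilities(l1, 0, beta = 1)
  expect_equal(p1[1], exp(1) / (exp(1) + 1), tolerance = 1e-12)

  # worked three-option case from state 1 of T = (0, 1, 1, -2)
  l2 <- landscape_from_T(c(0, 1, 1, -2))
  p2 <- transition_probabilities(l2, 1, beta = 1)
  expect_equal(p2[2], exp(3) / (exp(3) + exp(1) + 1), tolerance = 1e-12)

  # normalization on random landscapes and betas
  set.seed(2)
  for (rep_i in 1:10) {
    l <- landscape_from_T(stats::rnorm(16))
    s <- sample(0:15, 1)
    b <- stats::runif(1, 0, 4)
    expect_equal(sum(transition_probabilities(l, s, b)), 1, tolerance = 1e-12)
  }
})

test_that("frozen genes get zero probability and the rest renormalize", {
  land <- landscape_from_T(c(0, 1, 1, -2), genes = c("A", "B"))
  p <- transition_probabilities(land, 1, beta = 1, frozen = "A")
  expect_identical(p[1], 0)
  expect_equal(sum(p), 1)
  # renormalized softmax, not inflated stay probability
  p_free <- transition_probabilities(land, 1, beta = 1)
  expect_equal(p[2] / p[3], p_free[2] / p_free[3], tolerance = 1e-12)
  expect_error(transition_probabilities(land, 1, 1, frozen = "Z"), "unknown frozen")
})

test_that("step selection takes the smallest index whose cumulative exceeds r", {
  probs <- c(0.2, 0, 0.5, 0.3)
  expect_identical(step_choice(probs, r = 0), 1L)
  expect_identical(step_choice(probs, r = 0.1999), 1L)
  expect_identical(step_choice(probs, r = 0.2), 3L)   # skips zero-probability move
  expect_identical(step_choice(probs, r = 1 - 1e-12), 4L)
})

test_that("empirical move frequencies match the analytic two-option probability", {
  l1 <- landscape_from_T(c(1, 0))
  p_move <- exp(1) / (exp(1) + 1)
  probs <- transition_probabilities(l1, 0, beta = 1)
  cum <- cumsum(probs)
  set.seed(606)
  r <- stats::runif(1e5)
  mu <- colSums(outer(cum, r, `<=`)) + 1L
  phat <- mean(mu == 1L)
  se <- sqrt(p_move * (1 - p_move) / 1e5)
  expect_lt(abs(phat - p_move), 3 * se)
})

test_that("large beta walks descend greedily and stay at strict minima", {
  land <- landscape_from_T(c(0, 1, 1, -2))
  cfg <- marble_config(beta = 50, n_marbles = 1, seed = 1)
  set.seed(10)
  for (i in 1:5) {
    out <- run_marble(land, 1, cfg)
    expect_identical(out$final, 3L)
    expect_false(out$censored)
  }
  # started at an isolated strict minimum, it stays
  set.seed(11)
  out <- run_marble(land, 3, marble_config(beta = 20, n_marbles = 1, seed = 1))
  expect_identical(out$final, 3L)
})

test_that("ensembles are reproducible, row-stochastic and pool degenerate states", {
  land <- landscape_from_T(c(0, 1, 1, -2))
  at <- find_attractors(land)
  cfg <- marble_config(beta = 1.5, n_marbles = 300, n_replicates = 3, seed = 77)
  t1 <- simulate_ensemble(land, at, cfg)
  t2 <- simulate_ensemble(land, at, cfg)
  expect_identical(t1$replicates, t2$replicates)
  expect_equal(unname(rowSums(t1$mean)), rep(1, 4))
  expect_true(all(apply(t1$replicates, 3, rowSums) - 1 < 1e-12))

  # initial state inside an attractor with large beta stays there
  tcold <- simulate_ensemble(land, at, marble_config(beta = 30, n_marbles = 100,
                                                     n_replicates = 2, seed = 5),
                             initial_states = 3)
  expect_equal(unname(tcold$mean[1, "A1"]), 1)

  # degenerate plateau: both member states pool into one column
  dl <- landscape_from_T(c(0, 0, -1, -1), genes = c("A", "B"))
  dat <- find_attractors(dl)
  expect_true(dat[[1]]$degenerate)
  td <- simulate_ensemble(dl, dat, marble_config(beta = 8, n_marbles = 200,
                                                 n_replicates = 2, seed = 3,
                                                 max_steps = 400))
  expect_identical(colnames(td$mean), c("A1", "Other"))
  expect_gt(td$mean[3, "A1"], 0.99)
})

test_that("uphill escape probability decreases with beta", {
  land <- landscape_from_T(c(0, 1, 1, -2))
  # probability of the strict-descent move from state 1 grows with beta
  p_desc <- vapply(c(0.5, 1, 2, 4), function(b) {
    transition_probabilities(land, 1, b)[2]
  }, 0)
  expect_true(all(diff(p_desc) > 0))
})

test_that("long unstopped two-state walks satisfy detailed balance", {
  beta <- 0.8
  land <- landscape_from_T(c(0, 1))
  probs0 <- transition_probabilities(land, 0, beta)
  probs1 <- transition_probabilities(land, 1, beta)
  set.seed(44)
  s <- 0L
  visits <- c(0L, 0L)
  for (i in 1:20000) {
    p <- if (s == 0L) probs0[1] else probs1[1]
    if (stats::runif(1) < p) s <- 1L - s
    visits[s + 1L] <- visits[s + 1L] + 1L
  }
  ratio <- visits[2] / visits[1]
  expect_equal(ratio, exp(-beta), tolerance = 0.12)
})

test_that("frozen genes never differ between start and final state", {
  fx <- fixture("toy")
  res <- search_configurations(fx$grn, operator_preset("bar"), fx$constraints,
                               mode = "exhaustive")
  cfg <- parse_configuration(res$valid[[1]], ops = operator_preset("bar"))
  land <- compute_landscape(fx$grn, cfg, operator_preset("bar"))
  at <- find_attractors(land)
  mc <- marble_config(beta = 0.5, n_marbles = 50, n_replicates = 1, seed = 13,
                      frozen_genes = "A")
  abit <- 1L
  for (start in c(0L, 9L, 22L, 31L)) {
    tab <- simulate_ensemble(land, at, mc, initial_states = start)
    # rebuild final states by rerunning the identical substream
    set.seed(as.integer((13 * 1009 + start * 131 + 1) %% 2147483647))
    fin <- enscape:::.walk_batch(enscape:::.cdf_matrix(land, 0.5, "A"), land$n,
                                 start, 50, 3, 150)
    fin <- fin[!is.na(fin)]
    expect_true(all(bitwAnd(fin, abit) == bitwAnd(start, abit)))
  }
})

test_that("reprogramming matrices are row-stochastic with identity cold limit", {
  land <- landscape_from_T(c(0, 1, 1, -2))
  at <- find_attractors(land)
  cold <- reprogramming_matrix(land, at, marble_config(beta = 40, n_marbles = 60,
                                                       n_replicates = 2, seed = 21))
  expect_equal(unname(rowSums(cold$mean)), rep(1, 2))
  expect_equal(unname(diag(cold$mean[, 1:2])), rep(1, 2))
  warm <- reprogramming_matrix(land, at, marble_config(beta = 0.7, n_marbles = 200,
                                                       n_replicates = 2, seed = 22))
  expect_equal(unname(rowSums(warm$mean)), rep(1, 2))
  expect_gt(warm$mean[2, 1], 0)   # escapes from the weak attractor occur
})

test_that("media transfer freezes media bits and projects initial states", {
  g <- grn(c("M", "X"),
           data.frame(source = "M", target = "X", sign = 1L), media = "M")
  land <- compute_landscape(g, list(M = NULL, X = tree_leaf("M")))
  at <- find_attractors(land)
  res <- media_transfer(land, "M", at,
                        marble_config(beta = 5, n_marbles = 100,
                                      n_replicates = 1, seed = 2))
  expect_length(res, 2)   # one sub-landscape per medium assignment
  expect_identical(res[[1]]$medium, c(M = 0L))
  for (r in res) expect_equal(unname(rowSums(r$table)), rep(1, length(at)))
})

test_that("basin strength summaries order states by dominating probability", {
  land <- landscape_from_T(c(0, 1, 1, -2))
  at <- find_attractors(land)
  tab <- simulate_ensemble(land, at, marble_config(beta = 1, n_marbles = 200,
                                                   n_replicates = 2, seed = 12))
  sm <- basin_strength_summary(tab)
  expect_identical(sum(sm$segments), 4L)
  expect_identical(nrow(sm$mean), 4L)
  # within each segment the dominating probability is non-decreasing
  start <- 0L
  for (lab in names(sm$segments)) {
    k <- sm$segments[[lab]]
    if (k == 0) next
    rows <- (start + 1):(start + k)
    domp <- sm$mean[rows, lab]
    expect_true(all(diff(domp) >= -1e-12))
    start <- start + k
  }
})

test_that("probability tables serialize with one row per state and replicate", {
  land <- landscape_from_T(c(0, 1, 1, -2))
  at <- find_attractors(land)
  tab <- simulate_ensemble(land, at, marble_config(beta = 1, n_marbles = 50,
                                                   n_replicates = 2, seed = 31))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probability_table(tab, land, path)
  df <- utils::read.delim(path, colClasses = c(bits = "character"))
  expect_identical(nrow(df), 8L)
  expect_true(all(c("state_index", "bits", "A1", "A2", "Other", "n", "replicate")
                  %in% names(df)))
})
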