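# Gibbs sampler: full conditionals, likelihood, sweeps, chains

test_that("the prior ICAR full conditional follows the neighbour formula", {
  g <- path_graph(c("A", "B", "C"))
  fc <- icar_full_conditional("B", c(1, NA, 3), g, sigma2_S = 2)
  expect_equal(fc$mean, 2)
  expect_equal(fc$variance, 1)

  # all-zero neighbours give mean zero
  fc0 <- icar_full_conditional(1, c(0, 0, 0), g, 5)
  expect_equal(fc0$mean, 0)
  expect_equal(fc0$variance, 5)

  # 4-cycle, ward 1 neighbours 2 and 4: mean (2 + 4) / 2 = 3
  g4 <- cycle_graph(4)
  fc4 <- icar_full_conditional(1, c(1, 2, 3, 4), g4, 2)
  expect_equal(fc4$mean, 3)
  expect_equal(fc4$variance, 1)

  g_iso <- ward_graph(c("A", "B", "Z"), cbind("A", "B"))
  expect_error(icar_full_conditional("Z", c(0, 0, 0), g_iso, 1),
               "isolated")
})

test_that("log-likelihood matches a brute-force density-sum oracle", {
  # single observation at the mode of a variance-1/(2pi) normal: density 1
  g <- ward_graph("A")
  d <- manual_dataset(y = 0.7, X = matrix(0, 1, 0), graph = g,
                      ward_index = 1L,
                      spec = custom_spec(FALSE, FALSE, FALSE))
  expect_equal(log_likelihood(list(alpha = 0.7, sigma2_e = 1 / (2 * pi)), d),
               0)

  # additivity over iid observations
  d2 <- manual_dataset(y = c(0.7, 0.7), X = matrix(0, 2, 0), graph = g,
                       ward_index = c(1L, 1L),
                       spec = custom_spec(FALSE, FALSE, FALSE))
  expect_equal(log_likelihood(list(alpha = 0.2, sigma2_e = 2), d2),
               2 * log_likelihood(list(alpha = 0.2, sigma2_e = 2), d))

  # random state and data of size 20 against an independent density sum
  set.seed(6)
  g3 <- path_graph()
  y <- rnorm(20)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
  widx <- sample.int(3, 20, replace = TRUE)
  d3 <- manual_dataset(y, X, g3, widx, custom_spec(TRUE, TRUE, TRUE))
  st <- list(alpha = 0.3, beta = c(0.5, -1.2), R = c(0.1, -0.2, 0.05),
             S = c(-0.3, 0.1, 0.2), sigma2_e = 1.7)
  mu <- 0.3 + X %*% c(0.5, -1.2) + st$R[widx] + st$S[widx]
  oracle <- sum(-0.5 * log(2 * pi * 1.7) - (y - mu)^2 / (2 * 1.7))
  expect_equal(log_likelihood(st, d3), oracle, tolerance = 1e-10)
  expect_error(log_likelihood(list(alpha = 0, sigma2_e = 0), d3),
               "positive")
})

test_that("a sweep only touches the blocks the model spec includes", {
  g <- make_lattice_graph(2, 3)
  sim <- simulate_dataset(g, simulation_params(seed = 2))
  d3 <- build_dataset(sim$records, g, model_spec("model3"))
  st <- list(alpha = 4, beta = rep(0, 8), sigma2_e = 2)
  set.seed(1)
  out <- gibbs_sweep(st, d3)
  expect_named(out, c("alpha", "beta", "sigma2_e"))
  expect_null(out$R)
  expect_null(out$S)
})

test_that("intercept-only sweeps reproduce the conjugate normal posterior", {
  # sigma_e^2 fixed at 1, near-flat prior: alpha | y ~ N(ybar, 1/n)
  g <- ward_graph("A")
  set.seed(8)
  y <- rnorm(40, 2, 1)
  d <- manual_dataset(y, matrix(0, 40, 0), g, rep(1L, 40),
                      custom_spec(FALSE, FALSE, FALSE))
  pri <- prior_spec(fixed_effect_sd = 1e6)
  st <- list(alpha = 0, sigma2_e = 1)
  draws <- numeric(4000)
  set.seed(9)
  for (t in seq_along(draws)) {
    st <- gibbs_sweep(st, d, pri, fix_sigma2_e = 1)
    draws[t] <- st$alpha
  }
  n <- length(y)
  se_mean <- (1 / sqrt(n)) / sqrt(length(draws))
  expect_equal(mean(draws), mean(y), tolerance = 4 * se_mean)
  expect_equal(stats::var(draws), 1 / n, tolerance = 0.08)
})

test_that("spatial effects sum to zero after every sweep", {
  g <- make_lattice_graph(3, 3)
  sim <- simulate_dataset(g, simulation_params(seed = 14))
  d <- build_dataset(sim$records, g, model_spec("model6"))
  st <- list(alpha = 4, beta = rep(0, 8), R = rep(0, 9), S = rep(0, 9),
             sigma2_e = 2, sigma2_R = 0.5, sigma2_S = 0.5)
  set.seed(10)
  for (t in 1:30) {
    st <- gibbs_sweep(st, d)
    expect_lt(abs(sum(st$S)), 1e-10)
  }
})

test_that("retention arithmetic and the seed contract hold", {
  g <- make_lattice_graph(2, 3)
  sim <- simulate_dataset(g, simulation_params(seed = 4))
  d <- build_dataset(sim$records, g, model_spec("model2"))
  fit <- run_chain(d, n_iter = 1000, burn_in = 500, thin = 5,
                   n_chains = 2, seed = 17)
  expect_equal(nrow(fit$chains[[1]]), 100L)
  expect_equal(nrow(fit$chains[[2]]), 100L)

  fit2 <- run_chain(d, n_iter = 1000, burn_in = 500, thin = 5,
                    n_chains = 2, seed = 17)
  expect_identical(fit$chains, fit2$chains)
  fit3 <- run_chain(d, n_iter = 1000, burn_in = 500, thin = 5,
                    n_chains = 2, seed = 18)
  expect_false(identical(fit$chains, fit3$chains))

  expect_error(run_chain(d, n_iter = 100, burn_in = 100), "n_iter")
})

test_that("single fits recover generating parameters within posterior
           uncertainty", {
  g <- make_lattice_graph(4, 8)
  p <- simulation_params(seed = 23)
  sim <- simulate_dataset(g, p)
  d <- build_dataset(sim$records, g, model_spec("model2"))
  fit <- run_chain(d, n_iter = 4000, burn_in = 1000, n_chains = 2,
                   seed = 29)
  s <- summarize_posterior(fit, c("age", "sigma2_e"))
  # truth beta_age = 0.052 within the 95% interval (wide at n ~ 300)
  expect_gt(0.052, s$lower[1] - 1e-9)
  expect_lt(0.052, s$upper[1] + 1e-9)
  expect_gt(1.9^2, s$lower[2])
  expect_lt(1.9^2, s$upper[2])
})

test_that("with no data the sampler reproduces the uniform SD prior", {
  # prior recovery: zero observations, so the marginal of each SD must be
  # its Uniform(0, upper) prior
  g <- path_graph()
  d <- manual_dataset(numeric(0), matrix(0, 0, 0), g, integer(0),
                      custom_spec(FALSE, TRUE, FALSE, label = "model1"))
  pri <- prior_spec(uniform_upper = 10)
  fit <- run_chain(d, priors = pri, n_iter = 60000, burn_in = 5000,
                   thin = 5, n_chains = 1, seed = 41)
  sdr <- sqrt(as.matrix(fit)[, "sigma2_R"])
  emp <- stats::ecdf(sdr)(seq(1, 9, by = 1))
  expect_equal(emp, seq(0.1, 0.9, by = 0.1), tolerance = 0.06)
})

test_that("the spatial variance update uses ICAR rank K - c", {
  # two disconnected edges: K = 4, c = 2, rank 2. With zero observations
  # the Gibbs chain must return the Uniform(0, upper) prior for sigma_S;
  # an update using rank K instead would visibly skew the marginal.
  g <- ward_graph(c("A", "B", "C", "D"), rbind(c("A", "B"), c("C", "D")))
  d <- manual_dataset(numeric(0), matrix(0, 0, 0), g, integer(0),
                      custom_spec(FALSE, FALSE, TRUE, label = "model4"))
  pri <- prior_spec(uniform_upper = 10)
  fit <- run_chain(d, priors = pri, n_iter = 60000, burn_in = 5000,
                   thin = 5, n_chains = 1, seed = 43)
  draws <- as.matrix(fit)
  sds <- sqrt(draws[, "sigma2_S"])
  emp <- stats::ecdf(sds)(seq(1, 9, by = 1))
  expect_equal(emp, seq(0.1, 0.9, by = 0.1), tolerance = 0.06)
  # and each component's S still sums to zero
  s_cols <- grep("^S\\[", colnames(draws))
  expect_lt(max(abs(draws[, s_cols[1]] + draws[, s_cols[2]])), 1e-10)
  expect_lt(max(abs(draws[, s_cols[3]] + draws[, s_cols[4]])), 1e-10)
})

test_that("permuting individuals within a ward leaves summaries unchanged", {
  g <- make_lattice_graph(2, 3)
  sim <- simulate_dataset(g, simulation_params(seed = 19))
  rec <- sim$records
  set.seed(55)
  perm <- unlist(tapply(seq_len(nrow(rec)), rec$ward_id, sample))
  rec2 <- rec[perm, ]
  d1 <- build_dataset(rec, g, model_spec("model2"))
  d2 <- build_dataset(rec2, g, model_spec("model2"))
  f1 <- run_chain(d1, n_iter = 6000, burn_in = 2000, n_chains = 1, seed = 5)
  f2 <- run_chain(d2, n_iter = 6000, burn_in = 2000, n_chains = 1, seed = 5)
  s1 <- summarize_posterior(f1, c("alpha", "age", "sigma2_e"))
  s2 <- summarize_posterior(f2, c("alpha", "age", "sigma2_e"))
  expect_equal(s1$median, s2$median, tolerance = 0.05)
})

test_that("posterior sigma_R median rises monotonically with generator
           sigma_R", {
  g <- make_lattice_graph(4, 8)
  meds <- vapply(c(0.3, 0.9, 1.8), function(sr) {
    sim <- simulate_dataset(g, simulation_params(
      seed = 61, sigma_R = sr, mean_cases_per_ward = 20))
    d <- build_dataset(sim$records, g, model_spec("model2"))
    fit <- run_chain(d, n_iter = 3000, burn_in = 1000, n_chains = 1,
                     seed = 62)
    stats::median(as.matrix(fit)[, "sigma2_R"])
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("isolated wards are an error under spatial specs unless allowed", {
  g_iso <- ward_graph(c("A", "B", "C", "Z"),
                      rbind(c("A", "B"), c("B", "C")))
  rec <- toy_records()
  rec$ward_id <- c("A", "B", "Z")
  d <- build_dataset(rec, g_iso, model_spec("model4"))
  expect_error(run_chain(d, n_iter = 20, burn_in = 10), "isolated")
  expect_warning(
    fit <- run_chain(d, n_iter = 200, burn_in = 100, n_chains = 1,
                     seed = 1, allow_islands = TRUE),
    "pinned")
  expect_equal(unname(as.matrix(fit)[, "S[Z]"]),
               rep(0, nrow(as.matrix(fit))))
})

test_that("samples persist to columnar text with a chain column", {
  g <- make_lattice_graph(2, 2)
  sim <- simulate_dataset(g, simulation_params(seed = 3))
  d <- build_dataset(sim$records, g, model_spec("model1"))
  fit <- run_chain(d, n_iter = 200, burn_in = 100, n_chains = 2, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_samples(fit, f)
  tab <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(tab), 200L)
  expect_equal(sort(unique(tab$chain)), c(1L, 2L))
  expect_true(all(c("alpha", "sigma2_e", "sigma2_R", "deviance",
                    "R[w01]") %in% names(tab)))
})
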