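#' Prior specification for the Gibbs sampler
#'
#' Minimally informative defaults: Normal(0, sd 100) on the intercept and
#' every regression coefficient, and a Uniform(0, 100) prior on each
#' standard deviation component. The WinBUGS-era Gamma(0.001, 0.001) prior
#' on precisions is selectable for sensitivity analysis; the uniform-on-SD
#' default avoids that prior's known pile-up near zero variance, exactly
#' the regime a near-null area-level signal occupies.
#'
#' @param fixed_effect_sd prior SD for the intercept and coefficients.
#' @param variance_prior `"uniform_sd"` or `"gamma_precision"`.
#' @param uniform_upper upper bound of the uniform prior on SDs.
#' @param gamma_shape,gamma_rate gamma-precision hyperparameters.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(fixed_effect_sd = 100,
                       variance_prior = c("uniform_sd", "gamma_precision"),
                       uniform_upper = 100,
                       gamma_shape = 0.001, gamma_rate = 0.001) {
  variance_prior <- match.arg(variance_prior)
  stopifnot(fixed_effect_sd > 0, uniform_upper > 0,
            gamma_shape > 0, gamma_rate > 0)
  structure(list(fixed_effect_sd = fixed_effect_sd,
                 variance_prior = variance_prior,
                 uniform_upper = uniform_upper,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate),
            class = "prior_spec")
}

#' Prior ICAR full conditional for one ward
#'
#' The conditional distribution of a spatial effect given its neighbours,
#' before any likelihood contribution:
#' \eqn{S_i \mid S_{j \ne i} \sim N(\bar S_i, \sigma_S^2 / \nu_i)} with
#' \eqn{\bar S_i} the mean of the adjacent wards' effects and \eqn{\nu_i}
#' the neighbour count.
#'
#' @param i ward index (1-based) or ward label.
#' @param S numeric spatial-effect vector over all wards.
#' @param graph a [ward_graph()].
#' @param sigma2_S conditional variance \eqn{\sigma_S^2}.
#' @return List with `mean` and `variance`.
#' @export
icar_full_conditional <- function(i, S, graph, sigma2_S) {
  if (is.character(i)) i <- match(i, graph$wards)
  stopifnot(!is.na(i), i >= 1, i <= n_wards(graph), sigma2_S >= 0)
  nu <- graph$degrees[i]
  if (nu == 0L)
    stop("ward ", graph$wards[i], " has no neighbours; the ICAR ",
         "conditional is undefined for isolated wards")
  list(mean = mean(S[graph$neighbours[[i]]]), variance = sigma2_S / nu)
}

#' Conditional Gaussian log-likelihood of a model state
#'
#' \eqn{\sum_{ij} \log N(T_{ij} \mid \mu_{ij}, \sigma_e^2)} with
#' \eqn{\mu_{ij} = \alpha + x_{ij}'\beta + R_i + S_i} (absent blocks
#' contribute nothing). The deviance used by DIC is \eqn{-2} times this
#' value.
#'
#' @param state list with `alpha`, `sigma2_e` and optionally `beta`, `R`,
#'   `S` (a [gibbs_sweep()] state).
#' @param data a [build_dataset()] result.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(state, data) {
  if (is.null(state$sigma2_e) || state$sigma2_e <= 0)
    stop("state$sigma2_e must be positive")
  mu <- rep(state$alpha, length(data$response))
  if (!is.null(state$beta) && ncol(data$covariates) > 0L)
    mu <- mu + drop(data$covariates %*% state$beta)
  if (!is.null(state$R)) mu <- mu + state$R[data$ward_index]
  if (!is.null(state$S)) mu <- mu + state$S[data$ward_index]
  sum(stats::dnorm(data$response, mu, sqrt(state$sigma2_e), log = TRUE))
}

param_names <- function(data) {
  spec <- data$spec
  wards <- data$graph$wards
  c("alpha",
    if (spec$include_covariates) colnames(data$covariates),
    if (spec$include_unstructured) paste0("R[", wards, "]"),
    if (spec$include_spatial) paste0("S[", wards, "]"),
    "sigma2_e",
    if (spec$include_unstructured) "sigma2_R",
    if (spec$include_spatial) "sigma2_S")
}

pack_state <- function(state, data) {
  spec <- data$spec
  c(state$alpha,
    if (spec$include_covariates) state$beta,
    if (spec$include_unstructured) state$R,
    if (spec$include_spatial) state$S,
    state$sigma2_e,
    if (spec$include_unstructured) state$sigma2_R,
    if (spec$include_spatial) state$sigma2_S)
}

unpack_state <- function(v, data) {
  spec <- data$spec
  K <- n_wards(data$graph)
  p <- ncol(data$covariates)
  pos <- 1L
  take <- function(k) {
    out <- v[pos:(pos + k - 1L)]
    pos <<- pos + k
    out
  }
  st <- list(alpha = take(1L))
  if (spec$include_covariates)
    st$beta <- stats::setNames(take(p), colnames(data$covariates))
  if (spec$include_unstructured)
    st$R <- stats::setNames(take(K), data$graph$wards)
  if (spec$include_spatial)
    st$S <- stats::setNames(take(K), data$graph$wards)
  st$sigma2_e <- take(1L)
  if (spec$include_unstructured) st$sigma2_R <- take(1L)
  if (spec$include_spatial) st$sigma2_S <- take(1L)
  st
}

check_spatial_graph <- function(data, allow_islands) {
  if (!data$spec$include_spatial) return(invisible())
  isolated <- data$graph$degrees == 0L
  if (any(isolated)) {
    if (!allow_islands)
      stop("spatial model on a graph with isolated ward(s): ",
           paste(data$graph$wards[isolated], collapse = ", "),
           " (set allow_islands = TRUE to pin their S at zero)")
    warning("isolated ward(s) ",
            paste(data$graph$wards[isolated], collapse = ", "),
            " have their spatial effect pinned at zero")
  }
  invisible()
}

run_gibbs_cpp <- function(data, priors, init, n_iter, burn_in, thin,
                          fix_sigma2_e) {
  car_gibbs_cpp(
    y = data$response, X = data$covariates,
    ward = as.integer(data$ward_index - 1L),
    nbrs = lapply(data$graph$neighbours, function(v) as.integer(v - 1L)),
    comp = as.integer(graph_components(data$graph) - 1L),
    use_R = data$spec$include_unstructured,
    use_S = data$spec$include_spatial,
    beta_prior_sd = priors$fixed_effect_sd,
    var_prior_type = if (priors$variance_prior == "uniform_sd") 0L else 1L,
    unif_upper = priors$uniform_upper,
    g_shape = priors$gamma_shape, g_rate = priors$gamma_rate,
    fixed_sigma2_e = if (is.null(fix_sigma2_e)) NaN else fix_sigma2_e,
    init = pack_state(init, data),
    n_iter = n_iter, burn_in = burn_in, thin = thin)
}

#' One full Gibbs scan
#'
#' Runs a single sweep of the sampler from a given state: the joint
#' conjugate update of (alpha, beta), every \eqn{R_i}, a sequential scan
#' of every \eqn{S_i} (posterior precision \eqn{\nu_i/\sigma_S^2 +
#' n_i/\sigma_e^2}, mean the precision-weighted blend of the ICAR
#' conditional mean and the ward residual mean) followed by per-component
#' sum-to-zero recentring absorbed into the intercept, then the three
#' variance components. Randomness comes from R's RNG stream; set a seed
#' for reproducibility.
#'
#' @param state list with `alpha`, `sigma2_e`, and the blocks the model
#'   spec requires (`beta`, `R` + `sigma2_R`, `S` + `sigma2_S`).
#' @param data a [build_dataset()] result (carries the spec and graph).
#' @param priors a [prior_spec()].
#' @param fix_sigma2_e optional known residual variance (not updated).
#' @param allow_islands permit isolated wards under spatial specs.
#' @return The updated state list.
#' @export
gibbs_sweep <- function(state, data, priors = prior_spec(),
                        fix_sigma2_e = NULL, allow_islands = FALSE) {
  check_spatial_graph(data, allow_islands)
  draws <- run_gibbs_cpp(data, priors, state, n_iter = 1L, burn_in = 0L,
                         thin = 1L, fix_sigma2_e = fix_sigma2_e)
  unpack_state(draws[1L, -ncol(draws)], data)
}

initial_state <- function(data, chain) {
  spec <- data$spec
  K <- n_wards(data$graph)
  n <- length(data$response)
  W <- if (n > 0L) cbind(1, data$covariates) else
    matrix(0, 0L, ncol(data$covariates) + 1L)
  if (n > ncol(W)) {
    fit <- stats::lm.fit(W, data$response)
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    s2 <- sum(fit$residuals^2) / max(n - ncol(W), 1L)
  } else {
    coefs <- rep(0, ncol(W))
    s2 <- 1
  }
  # overdispersed starts: chain c jitters the least-squares coefficients by
  # (c-1) x 0.1 residual SDs; variances cycle through (0.5, 1, 2) x estimate
  mult <- c(0.5, 1, 2)[(chain - 1L) %% 3L + 1L]
  coefs <- coefs + (chain - 1L) * 0.1 * sqrt(s2) * stats::rnorm(length(coefs))
  st <- list(alpha = coefs[1L])
  if (spec$include_covariates) st$beta <- coefs[-1L]
  if (spec$include_unstructured) st$R <- 0.01 * stats::rnorm(K)
  if (spec$include_spatial) st$S <- 0.01 * stats::rnorm(K)
  st$sigma2_e <- s2 * mult
  re_var <- max(0.1 * s2, 1e-3) * mult
  if (spec$include_unstructured) st$sigma2_R <- re_var
  if (spec$include_spatial) st$sigma2_S <- re_var
  st
}

#' Run the Gibbs sampler
#'
#' Fits the model defined by `data$spec` with the bespoke conjugate Gibbs
#' sampler. Chains start overdispersed around the least-squares fit; the
#' per-iteration deviance (\eqn{-2\times} the conditional log-likelihood
#' given all effects) is stored alongside the parameters. Identical seed
#' and configuration give identical output.
#'
#' @param data a [build_dataset()] result.
#' @param priors a [prior_spec()].
#' @param n_iter total sweeps per chain.
#' @param burn_in sweeps discarded from the front of each chain.
#' @param thin keep every `thin`-th retained sweep.
#' @param n_chains number of independent chains.
#' @param seed root seed; per-chain seeds are derived from it.
#' @param fix_sigma2_e optional known residual variance (held fixed).
#' @param allow_islands permit isolated wards under spatial specs (their
#'   spatial effect is pinned at zero, with a warning).
#' @return An object of class `car_samples`: per-chain draw matrices (one
#'   column per parameter plus `deviance`), the spec, priors and run
#'   metadata.
#' @export
run_chain <- function(data, priors = prior_spec(),
                      n_iter = 30000, burn_in = 10000, thin = 1,
                      n_chains = 2, seed = 1, fix_sigma2_e = NULL,
                      allow_islands = FALSE) {
  stopifnot(inherits(data, "dup_dataset"), n_iter > burn_in, burn_in >= 0,
            thin >= 1, n_chains >= 1)
  check_spatial_graph(data, allow_islands)
  set.seed(seed)
  chain_seeds <- sample.int(2147483646L, n_chains)
  nms <- c(param_names(data), "deviance")
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    init <- initial_state(data, ch)
    if (!is.null(fix_sigma2_e)) init$sigma2_e <- fix_sigma2_e
    draws <- run_gibbs_cpp(data, priors, init, n_iter = n_iter,
                           burn_in = burn_in, thin = thin,
                           fix_sigma2_e = fix_sigma2_e)
    colnames(draws) <- nms
    chains[[ch]] <- draws
  }
  structure(list(chains = chains, parameters = nms,
                 spec = data$spec, priors = priors,
                 wards = data$graph$wards,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 n_chains = n_chains, seed = seed,
                 chain_seeds = chain_seeds,
                 fix_sigma2_e = fix_sigma2_e),
            class = "car_samples")
}

#' @export
print.car_samples <- function(x, ...) {
  cat("car_samples: ", x$spec$label, ", ", x$n_chains, " chain(s) x ",
      nrow(x$chains[[1L]]), " retained draws (burn-in ", x$burn_in,
      ", thin ", x$thin, ")\n", sep = "")
  invisible(x)
}

#' Pooled draw matrix
#' @param x a `car_samples` object.
#' @param ... unused.
#' @return Matrix of all chains' retained draws stacked, one column per
#'   parameter (plus `deviance`).
#' @export
as.matrix.car_samples <- function(x, ...) do.call(rbind, x$chains)

#' Persist posterior samples as delimited text
#'
#' One retained iteration per row, one parameter per column, with a
#' leading `chain` column: the columnar format external tools read.
#'
#' @param samples a `car_samples` object.
#' @param path output file.
#' @param sep field separator.
#' @export
write_samples <- function(samples, path, sep = ",") {
  tabs <- lapply(seq_along(samples$chains), function(ch)
    cbind(chain = ch, as.data.frame(samples$chains[[ch]])))
  utils::write.table(do.call(rbind, tabs), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
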