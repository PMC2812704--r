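#' Parameters of the synthetic-data generator
#'
#' Defaults are calibrated to the Southeast London first-episode psychosis
#' catchment the package emulates: intercept 4.2 log-days (median DUP near
#' 69.5 days), the model-2 covariate coefficients (per-year age effect
#' 0.052, male-vs-female contrast 0.24, six ethnicity contrasts against
#' white British), residual SD 1.9, small ward-level SDs (unstructured
#' 0.11, spatial conditional 0.19), and a mean of 314/32 = 9.8125 cases
#' per ward so a 32-ward map yields about 314 cases. Ages are uniform over
#' the 16-64-year eligibility window and sex is a fair coin. The ethnicity
#' mix is not reported for the source sample; the default is a plausible
#' inner-London first-episode mix, configurable.
#'
#' @param alpha intercept on the log-day scale.
#' @param beta numeric length-8 coefficient vector in the fixed covariate
#'   order (age, sexMale, six ethnicity dummies).
#' @param sigma_e residual SD of log-DUP.
#' @param sigma_R SD of the unstructured ward effects.
#' @param sigma_S conditional SD of the ICAR spatial effects.
#' @param mean_cases_per_ward expected cases per ward (> 1 guarantees no
#'   empty wards under the shifted-Poisson count model).
#' @param age_range min/max age in years.
#' @param ethnicity_probs length-7 probabilities over the ethnicity
#'   categories, summing to 1.
#' @param diagnosis_probs length-2 probabilities (nonaffective, affective);
#'   set to `NULL` to omit the diagnosis column.
#' @param seed integer seed governing all generator randomness.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(alpha = 4.2,
                              beta = c(0.052, 0.24, -0.13, 0.20, -0.74,
                                       -1.2, -0.86, -0.40),
                              sigma_e = 1.9, sigma_R = 0.11, sigma_S = 0.19,
                              mean_cases_per_ward = 9.8125,
                              age_range = c(16, 64),
                              ethnicity_probs = c(0.30, 0.10, 0.25, 0.20,
                                                  0.03, 0.07, 0.05),
                              diagnosis_probs = c(0.7, 0.3),
                              seed = 1L) {
  stopifnot(length(beta) == 8L, sigma_e >= 0, sigma_R >= 0, sigma_S >= 0,
            mean_cases_per_ward > 0, length(age_range) == 2L,
            age_range[1L] <= age_range[2L],
            length(ethnicity_probs) == 7L, all(ethnicity_probs >= 0))
  if (abs(sum(ethnicity_probs) - 1) > 1e-8)
    stop("ethnicity_probs must sum to 1")
  if (!is.null(diagnosis_probs)) {
    stopifnot(length(diagnosis_probs) == 2L, all(diagnosis_probs >= 0))
    if (abs(sum(diagnosis_probs) - 1) > 1e-8)
      stop("diagnosis_probs must sum to 1")
  }
  structure(list(alpha = alpha, beta = stats::setNames(beta, covariate_names),
                 sigma_e = sigma_e, sigma_R = sigma_R, sigma_S = sigma_S,
                 mean_cases_per_ward = mean_cases_per_ward,
                 age_range = age_range,
                 ethnicity_probs = stats::setNames(ethnicity_probs,
                                                   ethnicity_levels),
                 diagnosis_probs = diagnosis_probs,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Rook-contiguity lattice ward map
#'
#' A rows x cols grid of wards with 4-neighbour (rook) adjacency: the
#' stand-in for an urban contiguity map. The 4 x 8 lattice gives the
#' 32-ward setting the generator defaults target.
#'
#' @param rows,cols positive lattice dimensions.
#' @return A connected [ward_graph()] with wards labelled `w01`, `w02`,
#'   ... in row-major order.
#' @export
make_lattice_graph <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  K <- rows * cols
  id <- function(r, c) (r - 1L) * cols + c
  wards <- sprintf("w%02d", seq_len(K))
  el <- NULL
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) el <- rbind(el, c(id(r, c), id(r, c + 1L)))
    if (r < rows) el <- rbind(el, c(id(r, c), id(r + 1L, c)))
  }
  if (!is.null(el)) el <- cbind(wards[el[, 1L]], wards[el[, 2L]])
  ward_graph(wards, el)
}

#' Draw from the intrinsic CAR (ICAR) distribution
#'
#' Samples spatial effect vectors with covariance \eqn{\sigma_S^2 L^{+}}
#' (the Moore-Penrose pseudo-inverse of the graph Laplacian), i.e. the
#' proper sum-to-zero-constrained subspace representation of the improper
#' ICAR prior. Each connected component of the graph sums to zero by
#' construction; isolated wards are an error unless `allow_islands`
#' pins their effect at zero.
#'
#' @param graph a [ward_graph()].
#' @param sigma_S conditional SD; `0` returns exact zeros.
#' @param n number of independent draws.
#' @param allow_islands permit degree-zero wards (their effect is 0).
#' @return A K x n matrix of draws (a vector when `n = 1`).
#' @export
sample_icar <- function(graph, sigma_S, n = 1, allow_islands = FALSE) {
  stopifnot(sigma_S >= 0, n >= 1)
  K <- n_wards(graph)
  if (any(graph$degrees == 0L) && !allow_islands)
    stop("graph has isolated ward(s): ",
         paste(graph$wards[graph$degrees == 0L], collapse = ", "),
         " (set allow_islands = TRUE to pin their effect at zero)")
  if (sigma_S == 0 || K == 1L) {
    out <- matrix(0, K, n, dimnames = list(graph$wards, NULL))
    return(if (n == 1L) out[, 1L] else out)
  }
  ee <- eigen(laplacian_matrix(graph), symmetric = TRUE)
  tol <- K * .Machine$double.eps * max(ee$values)
  pos <- ee$values > max(tol, 1e-12)
  Z <- matrix(stats::rnorm(sum(pos) * n), sum(pos), n)
  out <- sigma_S * (ee$vectors[, pos, drop = FALSE] %*%
                      (Z / sqrt(ee$values[pos])))
  dimnames(out) <- list(graph$wards, NULL)
  if (n == 1L) out[, 1L] else out
}

#' Simulate a synthetic case dataset from the full generative model
#'
#' Generates individual-level records from the most general model form:
#' per-ward case counts \eqn{n_i \sim 1 + }Poisson(mean - 1) (no ward is
#' empty), covariates drawn independently, ward effects
#' \eqn{R_i \sim N(0, \sigma_R^2)} and \eqn{S} from the constrained ICAR,
#' then \eqn{T_{ij} = \alpha + x_{ij}'\beta + R_i + S_i + e_{ij}} with
#' \eqn{e_{ij} \sim N(0, \sigma_e^2)} and DUP = \eqn{\exp(T_{ij})} days.
#' One root seed is split into separate streams for ward effects,
#' counts/covariates and residual noise, so each component is
#' independently reproducible.
#'
#' @param graph a [ward_graph()].
#' @param params a [simulation_params()].
#' @return List with `records` (data frame in the format
#'   [read_individuals()] reads) and `truth` (every generating parameter
#'   and effect vector, plus per-ward counts).
#' @export
simulate_dataset <- function(graph, params = simulation_params()) {
  stopifnot(inherits(graph, "ward_graph"),
            inherits(params, "simulation_params"))
  K <- n_wards(graph)
  set.seed(params$seed)
  streams <- sample.int(2147483646L, 3L)

  set.seed(streams[1L])                              # ward effects
  R <- stats::rnorm(K, 0, params$sigma_R)
  S <- sample_icar(graph, params$sigma_S)

  set.seed(streams[2L])                              # counts + covariates
  n_i <- 1L + stats::rpois(K, max(params$mean_cases_per_ward - 1, 0))
  n <- sum(n_i)
  ward_id <- rep(graph$wards, n_i)
  age <- stats::runif(n, params$age_range[1L], params$age_range[2L])
  sex <- sample(sex_levels, n, replace = TRUE)
  eth <- sample(ethnicity_levels, n, replace = TRUE,
                prob = params$ethnicity_probs)
  diagnosis <- if (!is.null(params$diagnosis_probs))
    sample(diagnosis_levels, n, replace = TRUE,
           prob = params$diagnosis_probs)

  X <- matrix(0, n, 8L, dimnames = list(NULL, covariate_names))
  X[, "age"] <- age
  X[, "sexMale"] <- as.numeric(sex == "male")
  ek <- match(eth, ethnicity_levels)
  for (k in 2:7) X[ek == k, k + 1L] <- 1
  widx <- rep(seq_len(K), n_i)
  mu <- params$alpha + drop(X %*% params$beta) + R[widx] + S[widx]

  set.seed(streams[3L])                              # residual noise
  Tij <- mu + stats::rnorm(n, 0, params$sigma_e)

  records <- data.frame(ward_id = ward_id, dup_days = exp(Tij),
                        age = age, sex = sex, ethnicity = eth,
                        stringsAsFactors = FALSE)
  if (!is.null(diagnosis)) records$diagnosis <- diagnosis
  truth <- list(alpha = params$alpha, beta = params$beta,
                R = stats::setNames(R, graph$wards),
                S = stats::setNames(S, graph$wards),
                sigma_e = params$sigma_e, sigma_R = params$sigma_R,
                sigma_S = params$sigma_S,
                n_per_ward = stats::setNames(n_i, graph$wards),
                seed = params$seed)
  list(records = records, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Writes `records.csv` (the format [read_individuals()] reads),
#' `adjacency.txt` (edge-list dialect) and `truth.txt` (key = value lines,
#' vectors comma-separated) into `dir`.
#'
#' @param sim result of [simulate_dataset()].
#' @param graph the [ward_graph()] the data were simulated on.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("records.csv", "adjacency.txt", "truth.txt"))
  write_individuals(sim$records, paths[1L])
  write_adjacency(graph, paths[2L], format = "edge_list")
  tr <- sim$truth
  lines <- vapply(names(tr), function(k)
    paste0(k, " = ", paste(format(tr[[k]], digits = 15, trim = TRUE),
                           collapse = ",")), character(1))
  writeLines(lines, paths[3L])
  invisible(paths)
}
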