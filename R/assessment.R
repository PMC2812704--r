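#' Deviance Information Criterion
#'
#' \eqn{\bar D} is the mean stored deviance over all retained draws,
#' \eqn{p_D = \bar D - D(\bar\theta)} the effective number of parameters,
#' and DIC \eqn{= \bar D + p_D}. The plug-in deviance \eqn{D(\bar\theta)}
#' is evaluated at the posterior means of the focus parameters — the
#' intercept, coefficients, ward effects and residual variance — so the
#' random effects are "in focus" and a near-null hierarchical model costs
#' only the few effective degrees of freedom its shrunken effects use.
#'
#' @param samples a `car_samples` object (see [run_chain()]).
#' @param data the [build_dataset()] result the samples were fitted to.
#' @return List with `dic`, `p_d` and `d_bar`.
#' @export
compute_dic <- function(samples, data) {
  draws <- as.matrix(samples)
  if (nrow(draws) == 0L) stop("empty sample set")
  d_bar <- mean(draws[, "deviance"])
  means <- colMeans(draws[, setdiff(colnames(draws), "deviance"),
                          drop = FALSE])
  state <- unpack_state(means, data)
  d_hat <- -2 * log_likelihood(state, data)
  p_d <- d_bar - d_hat
  list(dic = d_bar + p_d, p_d = p_d, d_bar = d_bar)
}

#' Posterior medians and 95\% credible intervals
#'
#' Equal-tailed 2.5\%/50\%/97.5\% quantiles per parameter, pooled across
#' chains (the reporting convention of the WinBUGS era: point estimate =
#' median, interval = central 95\%).
#'
#' @param samples a `car_samples` object.
#' @param parameters optional character vector restricting the summary.
#' @return Data frame with columns `parameter`, `median`, `lower`,
#'   `upper`.
#' @export
summarize_posterior <- function(samples, parameters = NULL) {
  draws <- as.matrix(samples)
  if (nrow(draws) == 0L) stop("empty sample set")
  if (is.null(parameters)) parameters <- colnames(draws)
  missing <- setdiff(parameters, colnames(draws))
  if (length(missing))
    stop("unknown parameter(s): ", paste(missing, collapse = ", "))
  qs <- t(apply(draws[, parameters, drop = FALSE], 2L, stats::quantile,
                probs = c(0.5, 0.025, 0.975), names = FALSE))
  data.frame(parameter = parameters, median = qs[, 1L],
             lower = qs[, 2L], upper = qs[, 3L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proportion of variance attributable to area-level random effects
#'
#' Per retained draw, the area-level variance is \eqn{\sigma_R^2} (when
#' the unstructured block is present) plus the empirical variance of the
#' current spatial-effect vector (the standard resolution of the ICAR
#' scale being conditional, not marginal); the proportion is
#' \eqn{100\, v_{area} / (v_{area} + \sigma_e^2)}. The default summarises
#' the per-draw ratios by their median and central 95\% interval, which
#' propagates the (often large) uncertainty in small variance components;
#' `method = "point"` instead evaluates one ratio at the posterior
#' medians.
#'
#' @param samples a `car_samples` object.
#' @param method `"per_iteration"` (default) or `"point"`.
#' @return List with `median`, `lower`, `upper` (percent) and
#'   `applicable`; for a model with no area-level block (model 3) the
#'   values are `NA` and `applicable` is `FALSE`, mirroring a reported
#'   "NA" cell.
#' @export
variance_partition <- function(samples,
                               method = c("per_iteration", "point")) {
  method <- match.arg(method)
  spec <- samples$spec
  if (!spec$include_unstructured && !spec$include_spatial)
    return(list(median = NA_real_, lower = NA_real_, upper = NA_real_,
                applicable = FALSE))
  draws <- as.matrix(samples)
  s_cols <- grep("^S\\[", colnames(draws))
  pop_var <- function(m) {
    if (!length(s_cols)) return(0)
    v <- m[, s_cols, drop = FALSE]
    rowMeans((v - rowMeans(v))^2)
  }
  if (method == "per_iteration") {
    v_area <- (if (spec$include_unstructured) draws[, "sigma2_R"] else 0) +
      pop_var(draws)
    prop <- 100 * v_area / (v_area + draws[, "sigma2_e"])
    qs <- stats::quantile(prop, c(0.5, 0.025, 0.975), names = FALSE)
    list(median = qs[1L], lower = qs[2L], upper = qs[3L],
         applicable = TRUE)
  } else {
    med <- apply(draws, 2L, stats::median)
    v_area <- (if (spec$include_unstructured) med[["sigma2_R"]] else 0) +
      (if (length(s_cols)) {
        s <- med[s_cols]
        mean((s - mean(s))^2)
      } else 0)
    list(median = 100 * v_area / (v_area + med[["sigma2_e"]]),
         lower = NA_real_, upper = NA_real_, applicable = TRUE)
  }
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half; R-hat compares between- and within-half
#' variances. Values near 1 indicate mixing; a warning is raised when any
#' parameter exceeds 1.05. Constant parameters report R-hat 1.
#'
#' @param samples a `car_samples` object with at least two chains.
#' @return Named numeric vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(samples) {
  if (samples$n_chains < 2L)
    stop("R-hat needs n_chains >= 2; rerun with more chains")
  halves <- list()
  for (ch in samples$chains) {
    L <- floor(nrow(ch) / 2L)
    halves <- c(halves, list(ch[seq_len(L), , drop = FALSE],
                             ch[L + seq_len(L), , drop = FALSE]))
  }
  m <- length(halves)
  L <- nrow(halves[[1L]])
  rhat <- vapply(colnames(halves[[1L]]), function(par) {
    mus <- vapply(halves, function(h) mean(h[, par]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, par]), numeric(1))
    W <- mean(vars)
    if (!is.finite(W) || W <= 0) return(1)
    B <- L * stats::var(mus)
    sqrt(((L - 1) / L * W + B / L) / W)
  }, numeric(1))
  if (any(rhat > 1.05, na.rm = TRUE))
    warning("possible non-convergence: R-hat > 1.05 for ",
            paste(names(rhat)[rhat > 1.05], collapse = ", "))
  rhat
}

#' Full model report
#'
#' Assembles the per-model reporting unit: DIC decomposition, parameter
#' summaries (medians and 95\% credible intervals), the area-level
#' variance proportion and, with two or more chains, R-hat diagnostics.
#'
#' @param samples a `car_samples` object.
#' @param data the [build_dataset()] result the samples were fitted to.
#' @return An object of class `model_report`.
#' @export
model_report <- function(samples, data) {
  dic <- compute_dic(samples, data)
  rhat <- if (samples$n_chains >= 2L) {
    withCallingHandlers(gelman_rubin(samples),
                        warning = function(w) invokeRestart("muffleWarning"))
  }
  structure(list(
    label = samples$spec$label,
    spec = samples$spec,
    dic = dic$dic, p_d = dic$p_d, d_bar = dic$d_bar,
    parameter_summaries = summarize_posterior(samples),
    variance_proportion = variance_partition(samples),
    r_hat = rhat,
    convergence_flag = !is.null(rhat) && any(rhat > 1.05, na.rm = TRUE)
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("model_report for ", x$label, " (",
      model_descriptions[[x$label]], ")\n", sep = "")
  cat(sprintf("  DIC %.2f  (Dbar %.2f, pD %.2f)\n", x$dic, x$d_bar, x$p_d))
  vp <- x$variance_proportion
  if (vp$applicable)
    cat(sprintf("  area-level variance: %.2f%% (%.2g, %.2g)\n",
                vp$median, vp$lower, vp$upper))
  else cat("  area-level variance: not applicable\n")
  if (x$convergence_flag) cat("  WARNING: R-hat > 1.05 for some parameters\n")
  invisible(x)
}

fmt_ci <- function(med, lo, hi) {
  f <- function(v) sub("\\.$", "", formatC(v, digits = 2, format = "fg",
                                           flag = "#"))
  sprintf("%s (%s, %s)", f(med), f(lo), f(hi))
}

row_from_summary <- function(report, parameter, transform = identity) {
  s <- report$parameter_summaries
  hit <- s$parameter == parameter
  if (!any(hit)) return(NA_character_)
  fmt_ci(transform(s$median[hit]), transform(s$lower[hit]),
         transform(s$upper[hit]))
}

#' Table-layout comparison of model reports
#'
#' Formats a set of model reports into the study's reporting layout: one
#' column per model, rows for DIC, the three SD components, the
#' area-level variance percentage and the eight covariate contrasts, with
#' `NA` wherever a model omits the block. Variance-component rows are
#' reported on the SD scale (square roots of the sampled variances).
#'
#' @param reports list of `model_report` objects (typically the six-model
#'   ladder).
#' @return Data frame with a `quantity` column and one column per model.
#' @export
format_report_table <- function(reports) {
  cols <- lapply(reports, function(rep) {
    vp <- rep$variance_proportion
    c(DIC = sprintf("%.2f", rep$dic),
      pD = sprintf("%.2f", rep$p_d),
      sigma_e = row_from_summary(rep, "sigma2_e", sqrt),
      sigma_R = row_from_summary(rep, "sigma2_R", sqrt),
      sigma_S = row_from_summary(rep, "sigma2_S", sqrt),
      `Area-level variance (%)` = if (vp$applicable)
        fmt_ci(vp$median, vp$lower, vp$upper) else NA_character_,
      `Age (years)` = row_from_summary(rep, "age"),
      `Sex (men vs. women)` = row_from_summary(rep, "sexMale"),
      `White other` = row_from_summary(rep, "ethOtherWhite"),
      `Black Caribbean` = row_from_summary(rep, "ethBlackCaribbean"),
      `Black African` = row_from_summary(rep, "ethBlackAfrican"),
      Asian = row_from_summary(rep, "ethAsian"),
      `Mixed ethnicities` = row_from_summary(rep, "ethMixed"),
      `Other ethnicities` = row_from_summary(rep, "ethOther"))
  })
  out <- data.frame(quantity = names(cols[[1L]]),
                    stringsAsFactors = FALSE)
  labels <- vapply(reports, function(r) r$label, character(1))
  for (j in seq_along(cols)) out[[labels[j]]] <- unname(cols[[j]])
  out
}

#' Write a report table as delimited text
#' @param reports list of `model_report` objects.
#' @param path output file.
#' @param sep field separator.
#' @export
write_report_table <- function(reports, path, sep = ",") {
  utils::write.table(format_report_table(reports), path, sep = sep,
                     row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}
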