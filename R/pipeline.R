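#' Fit the six-model ladder
#'
#' Builds the dataset appropriate to each model form, fits all six models
#' with seed-derived random streams, and returns the reports together
#' with a comparison table ranked by DIC with the minimum flagged. When
#' `out_dir` is given, the comparison table, the formatted report table,
#' per-model parameter summaries and a deterministic JSON run manifest
#' (configuration, derived seeds, package and R versions, convergence
#' flags) are written there; a convergence warning is recorded, never
#' fatal.
#'
#' @param records validated record data frame.
#' @param graph a [ward_graph()].
#' @param priors a [prior_spec()].
#' @param n_iter,burn_in,thin,n_chains sampler settings (see
#'   [run_chain()]).
#' @param seed root seed; each model gets a derived stream.
#' @param drop_empty_wards,center_age passed to [build_dataset()].
#' @param allow_islands passed to [run_chain()].
#' @param out_dir optional output directory.
#' @param keep_samples if `FALSE`, drop the raw draws from the return
#'   value (reports only) to save memory in replicate runs.
#' @return List with `reports` (six `model_report`s), `comparison` (six
#'   rows: model, description, d_bar, p_d, dic, rank, best), and
#'   `samples` (six `car_samples`, unless dropped).
#' @export
run_six_models <- function(records, graph, priors = prior_spec(),
                           n_iter = 30000, burn_in = 10000, thin = 1,
                           n_chains = 2, seed = 1,
                           drop_empty_wards = FALSE, center_age = FALSE,
                           allow_islands = FALSE, out_dir = NULL,
                           keep_samples = TRUE) {
  set.seed(seed)
  model_seeds <- sample.int(2147483646L, 6L)
  specs <- six_model_specs()
  reports <- vector("list", 6L)
  samples <- vector("list", 6L)
  names(reports) <- names(samples) <- names(specs)
  for (m in seq_len(6L)) {
    data <- build_dataset(records, graph, specs[[m]],
                          drop_empty_wards = drop_empty_wards,
                          center_age = center_age)
    fit <- run_chain(data, priors = priors, n_iter = n_iter,
                     burn_in = burn_in, thin = thin, n_chains = n_chains,
                     seed = model_seeds[m], allow_islands = allow_islands)
    reports[[m]] <- model_report(fit, data)
    if (keep_samples) samples[[m]] <- fit
  }
  dics <- vapply(reports, function(r) r$dic, numeric(1))
  comparison <- data.frame(
    model = names(specs),
    description = unname(model_descriptions[names(specs)]),
    d_bar = vapply(reports, function(r) r$d_bar, numeric(1)),
    p_d = vapply(reports, function(r) r$p_d, numeric(1)),
    dic = dics,
    rank = rank(dics, ties.method = "first"),
    best = seq_along(dics) == which.min(dics),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(reports = reports, comparison = comparison,
              samples = if (keep_samples) samples)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(comparison, file.path(out_dir, "comparison.csv"),
                       sep = ",", row.names = FALSE, quote = TRUE)
    write_report_table(reports, file.path(out_dir, "report_table.csv"))
    for (m in names(reports))
      utils::write.table(reports[[m]]$parameter_summaries,
                         file.path(out_dir, paste0(m, "_summary.csv")),
                         sep = ",", row.names = FALSE, quote = TRUE)
    manifest <- list(
      package = "dupcar",
      package_version = as.character(utils::packageVersion("dupcar")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed, model_seeds = model_seeds,
      sampler = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                     n_chains = n_chains),
      priors = unclass(priors),
      drop_empty_wards = drop_empty_wards, center_age = center_age,
      n_records = nrow(records), n_wards = n_wards(graph),
      convergence_warnings = names(which(vapply(
        reports, function(r) isTRUE(r$convergence_flag), logical(1)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Rerun the ladder within diagnostic subgroups
#'
#' Splits the records by diagnosis class (non-affective F20-29 versus
#' affective F30-33), re-derives the per-ward counts, and reruns the full
#' six-model ladder within each class. Classes with no records are
#' skipped with a message; wards emptied by the filtering follow the
#' `drop_empty_wards` policy.
#'
#' @param records record data frame carrying a `diagnosis` column.
#' @param graph a [ward_graph()].
#' @param seed root seed; each class gets a derived stream.
#' @param ... passed on to [run_six_models()].
#' @return Named list of [run_six_models()] results, one per non-empty
#'   class.
#' @export
run_subgroups <- function(records, graph, seed = 1, ...) {
  if (!"diagnosis" %in% names(records))
    stop("records carry no diagnosis column")
  set.seed(seed)
  class_seeds <- stats::setNames(sample.int(2147483646L, 2L),
                                 diagnosis_levels)
  out <- list()
  for (cls in diagnosis_levels) {
    sub <- records[!is.na(records$diagnosis) & records$diagnosis == cls, ,
                   drop = FALSE]
    if (nrow(sub) == 0L) {
      message("subgroup \"", cls, "\" has no records; skipped")
      next
    }
    out[[cls]] <- run_six_models(sub, graph, seed = class_seeds[[cls]], ...)
  }
  out
}

#' Per-ward unstructured random-effect summaries
#'
#' The box-plot table of ward effects: posterior median and 95\% credible
#' interval of each \eqn{R_i}, with a flag marking wards whose interval
#' excludes zero. Rows are ordered by ward label.
#'
#' @param samples a `car_samples` object from a model with unstructured
#'   effects.
#' @return Data frame with columns `ward`, `median`, `lower`, `upper`,
#'   `excludes_zero`.
#' @export
export_ward_effects <- function(samples) {
  if (!samples$spec$include_unstructured)
    stop("model ", samples$spec$label, " has no unstructured ward effects")
  pars <- paste0("R[", samples$wards, "]")
  s <- summarize_posterior(samples, pars)
  out <- data.frame(ward = samples$wards, median = s$median,
                    lower = s$lower, upper = s$upper,
                    excludes_zero = s$lower > 0 | s$upper < 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$ward), , drop = FALSE]
}

#' Per-ward five-number summaries of log-DUP
#'
#' The figure-data export of the raw ward-level distributions: for each
#' ward, the case count and the minimum, quartiles and maximum of log-DUP.
#' Rows are ordered by ward label.
#'
#' @param records record data frame.
#' @return Data frame with columns `ward`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
export_ward_distributions <- function(records) {
  y <- log_transform(records)
  wards <- sort(unique(records$ward_id))
  rows <- lapply(wards, function(w) {
    v <- y[records$ward_id == w]
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(ward = w, n = length(v), min = q[1L], q1 = q[2L],
               median = q[3L], q3 = q[4L], max = q[5L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate-mode ladder runs over simulated datasets
#'
#' Simulates `n_replicates` datasets from one generator configuration and
#' runs the six-model ladder on each: the machinery behind
#' model-selection-recovery checks (which model wins the DIC race when
#' the truth has, or lacks, area-level variance).
#'
#' @param graph a [ward_graph()].
#' @param params a [simulation_params()]; its seed field is overridden by
#'   per-replicate derived seeds.
#' @param n_replicates number of simulated datasets.
#' @param seed root seed.
#' @param ... sampler settings passed to [run_six_models()].
#' @return Data frame with one row per replicate: the six DICs, the
#'   winning model label, and each model's posterior-median area-level
#'   variance proportion (`vp_model1` .. `vp_model6`, NA for the model
#'   with no area-level block).
#' @export
replicate_ladder <- function(graph, params = simulation_params(),
                             n_replicates = 20, seed = 1, ...) {
  set.seed(seed)
  rep_seeds <- sample.int(1073741824L, 2L * n_replicates)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    params$seed <- rep_seeds[2L * r - 1L]
    sim <- simulate_dataset(graph, params)
    run <- run_six_models(sim$records, graph, seed = rep_seeds[2L * r],
                          keep_samples = FALSE, ...)
    dics <- stats::setNames(run$comparison$dic, run$comparison$model)
    winner <- run$comparison$model[run$comparison$best]
    vps <- vapply(run$reports, function(rep) {
      vp <- rep$variance_proportion
      if (vp$applicable) vp$median else NA_real_
    }, numeric(1))
    names(vps) <- paste0("vp_", names(run$reports))
    rows[[r]] <- data.frame(replicate = r, t(dics), winner = winner,
                            t(vps), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
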