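#' Specify one of the six model forms
#'
#' The model ladder for the regression surface \eqn{\mu_{ij}}:
#' \describe{
#'   \item{model1}{unstructured ward effects \eqn{R_i} only (empty model)}
#'   \item{model2}{model 1 + age, sex and ethnicity covariates}
#'   \item{model3}{covariates only, no ward effects (single-level model)}
#'   \item{model4}{spatially structured ward effects \eqn{S_i} only}
#'   \item{model5}{model 4 + covariates}
#'   \item{model6}{covariates + both \eqn{R_i} and \eqn{S_i}}
#' }
#'
#' @param label `"model1"` .. `"model6"`, or an integer 1-6.
#' @return An object of class `model_spec` with logical fields
#'   `include_covariates`, `include_unstructured`, `include_spatial`.
#' @export
model_spec <- function(label) {
  if (is.numeric(label)) label <- paste0("model", as.integer(label))
  label <- match.arg(label, paste0("model", 1:6))
  m <- as.integer(substring(label, 6L))
  structure(list(
    label = label,
    include_covariates = m %in% c(2L, 3L, 5L, 6L),
    include_unstructured = m %in% c(1L, 2L, 6L),
    include_spatial = m %in% c(4L, 5L, 6L)
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(x$label, ": covariates=", x$include_covariates,
      ", unstructured R=", x$include_unstructured,
      ", spatial S=", x$include_spatial, "\n", sep = "")
  invisible(x)
}

#' All six model specifications
#' @return Named list of the six [model_spec()] objects.
#' @export
six_model_specs <- function() {
  stats::setNames(lapply(1:6, model_spec), paste0("model", 1:6))
}

model_descriptions <- c(
  model1 = "unstructured random effects",
  model2 = "model 1 + age, sex and ethnicity",
  model3 = "age, sex and ethnicity only (single-level model)",
  model4 = "spatially structured random effects",
  model5 = "model 4 + age, sex and ethnicity",
  model6 = "model 5 + unstructured random effects")

covariate_names <- c("age", "sexMale", "ethOtherWhite", "ethBlackCaribbean",
                     "ethBlackAfrican", "ethAsian", "ethMixed", "ethOther")

#' Build the modelling dataset
#'
#' Assembles the response \eqn{T_{ij}} (log-DUP), the ward index of each
#' individual, the fixed-effect design matrix and the per-ward case counts
#' \eqn{n_i}. Ethnicity enters as six 0/1 dummies with white British as the
#' omitted baseline; the covariate column order is fixed as
#' (age, sexMale, otherWhite, blackCaribbean, blackAfrican, Asian, mixed,
#' other) so fitted reports line up across models.
#'
#' @param records validated record data frame (see [read_individuals()]).
#' @param graph a [ward_graph()] covering every ward that appears in
#'   `records`.
#' @param spec a [model_spec()]; models without covariates get a
#'   zero-column design matrix.
#' @param drop_empty_wards if `TRUE`, wards with no cases are removed from
#'   the graph before fitting (the source study's handling of its one
#'   empty ward); by default empty wards are retained and still carry
#'   spatially smoothed effects.
#' @param center_age subtract the mean age (sampler conditioning aid);
#'   off by default so coefficients stay on the per-year scale.
#' @return An object of class `dup_dataset` with elements `response`,
#'   `ward_index` (1-based into `graph$wards`), `covariates`,
#'   `n_per_ward`, `graph`, `spec`, and `diagnosis` when available.
#' @export
build_dataset <- function(records, graph, spec = model_spec("model6"),
                          drop_empty_wards = FALSE, center_age = FALSE) {
  stopifnot(inherits(graph, "ward_graph"), inherits(spec, "model_spec"))
  unknown <- setdiff(unique(records$ward_id), graph$wards)
  if (length(unknown))
    stop("record ward(s) not in graph: ", paste(unknown, collapse = ", "))
  if (drop_empty_wards) {
    occupied <- graph$wards[graph$wards %in% records$ward_id]
    if (length(occupied) < n_wards(graph))
      graph <- subgraph(graph, occupied)
  }
  response <- log_transform(records)
  ward_index <- match(records$ward_id, graph$wards)
  n <- length(response)
  if (spec$include_covariates) {
    age <- as.numeric(records$age)
    if (center_age) age <- age - mean(age)
    X <- matrix(0, n, 8L, dimnames = list(NULL, covariate_names))
    X[, "age"] <- age
    X[, "sexMale"] <- as.numeric(records$sex == "male")
    eth <- match(records$ethnicity, ethnicity_levels)
    for (k in 2:7) X[eth == k, k + 1L] <- 1
  } else {
    X <- matrix(0, n, 0L)
  }
  structure(list(
    response = response,
    ward_index = ward_index,
    covariates = X,
    n_per_ward = stats::setNames(tabulate(ward_index, n_wards(graph)),
                                 graph$wards),
    graph = graph,
    spec = spec,
    diagnosis = if ("diagnosis" %in% names(records)) records$diagnosis
  ), class = "dup_dataset")
}

#' @export
print.dup_dataset <- function(x, ...) {
  cat("dup_dataset:", length(x$response), "cases across",
      n_wards(x$graph), "wards (", x$spec$label, ")\n")
  cat("cases per ward: median", stats::median(x$n_per_ward),
      "range", paste(range(x$n_per_ward), collapse = "-"), "\n")
  invisible(x)
}
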