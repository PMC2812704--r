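# Shared fixtures, all built in code.

path_graph <- function(labels = c("A", "B", "C")) {
  ward_graph(labels, cbind(labels[-length(labels)], labels[-1]))
}

cycle_graph <- function(K = 4) {
  labels <- LETTERS[seq_len(K)]
  ward_graph(labels, rbind(cbind(labels[-K], labels[-1]),
                           c(labels[K], labels[1])))
}

# minimal well-formed record set over two wards
toy_records <- function() {
  data.frame(
    ward_id = c("A", "A", "B"),
    dup_days = c(1, 69.5, exp(1)),
    age = c(30, 25, 40),
    sex = c("male", "female", "female"),
    ethnicity = c("white British", "black African", "Asian"),
    stringsAsFactors = FALSE)
}

# an ad hoc model_spec outside the six-model ladder (tests only)
custom_spec <- function(covariates, unstructured, spatial,
                        label = "custom") {
  structure(list(label = label, include_covariates = covariates,
                 include_unstructured = unstructured,
                 include_spatial = spatial), class = "model_spec")
}

# dataset assembled directly from components, bypassing build_dataset,
# for conjugate-oracle tests with arbitrary design matrices
manual_dataset <- function(y, X, graph, ward_index, spec) {
  structure(list(response = y, ward_index = ward_index,
                 covariates = X,
                 n_per_ward = stats::setNames(
                   tabulate(ward_index, n_wards(graph)), graph$wards),
                 graph = graph, spec = spec),
            class = "dup_dataset")
}

# Moore-Penrose pseudo-inverse of a connected graph's Laplacian via the
# bordered-system identity (L + J/K)^{-1} = L+ + J/K: a solve()-based
# oracle independent of the eigen-decomposition route the sampler uses.
laplacian_pinv_oracle <- function(graph) {
  K <- n_wards(graph)
  solve(laplacian_matrix(graph) + 1 / K) - 1 / K
}
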