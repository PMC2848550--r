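#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.eqtl_calls <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.eqtl_calls <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_tested = sum(!is.na(x$p_nominal)),
         n_significant = sum(x$significant),
         tail = x$tail[1],
         n_permutations = x$n_permutations[1])
}

#' @exportS3Method generics::tidy
tidy.qq_curves <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.qq_curves <- function(x, ...) {
  tibble(n_sets = attr(x, "n_sets"),
         n_snps_per_set = attr(x, "n_snps_per_set"),
         n_above_ci = sum(x$observed > x$ci_upper),
         max_observed = max(x$observed))
}
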