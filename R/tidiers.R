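#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns the per-term / per-axis table of a fit as a tibble;
#' `glance()` returns a one-row model summary.
#'
#' @param x a fitted object from this package.
#' @param ... unused.
#' @name ecoassembly-tidiers
NULL

#' @rdname ecoassembly-tidiers
#' @exportS3Method generics::tidy
tidy.eco_permanova <- function(x, ...) x$table

#' @rdname ecoassembly-tidiers
#' @exportS3Method generics::glance
glance.eco_permanova <- function(x, ...) {
  terms <- x$table[!x$table$term %in% c("Residual", "Total"), ]
  tibble(n_terms = nrow(terms),
         r_squared_model = sum(terms$r_squared),
         n_perm = x$n_perm)
}

#' @rdname ecoassembly-tidiers
#' @exportS3Method generics::tidy
tidy.eco_pcoa <- function(x, ...) {
  tibble(axis = paste0("Axis", seq_along(x$eigenvalues)),
         eigenvalue = x$eigenvalues,
         proportion = x$proportion)
}

#' @rdname ecoassembly-tidiers
#' @exportS3Method generics::glance
glance.eco_pcoa <- function(x, ...) {
  tibble(n_axes = length(x$eigenvalues),
         cailliez_constant = x$cailliez_constant,
         n_negative_eigenvalues = length(x$negative_eigenvalues))
}

#' @rdname ecoassembly-tidiers
#' @exportS3Method generics::tidy
tidy.eco_dbrda <- function(x, ...) {
  dplyr::left_join(x$eigenvalues, x$axis_tests, by = "axis")
}

#' @rdname ecoassembly-tidiers
#' @exportS3Method generics::glance
glance.eco_dbrda <- function(x, ...) {
  tibble(kind = x$kind, r_squared = x$r_squared,
         adj_r_squared = x$adj_r_squared,
         pseudo_f = x$overall_test$pseudo_f,
         p_value = x$overall_test$p_value,
         n = x$n, n_predictors = x$m)
}

#' @rdname ecoassembly-tidiers
#' @exportS3Method generics::tidy
tidy.eco_varpart <- function(x, ...) x$fractions

#' @rdname ecoassembly-tidiers
#' @exportS3Method generics::glance
glance.eco_varpart <- function(x, ...) {
  tibble(total_adj_r2 = x$total_adj_r2, residual = x$residual)
}

#' @rdname ecoassembly-tidiers
#' @exportS3Method generics::tidy
tidy.eco_vif <- function(x, ...) x$vif

#' @rdname ecoassembly-tidiers
#' @exportS3Method generics::tidy
tidy.eco_dispersion <- function(x, ...) x$distances

#' @rdname ecoassembly-tidiers
#' @exportS3Method generics::glance
glance.eco_dispersion <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_value,
         degenerate = x$degenerate)
}
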