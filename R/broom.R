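# broom-style tidiers for the fitted-object classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy pcm_pca
#' @export
tidy.pcm_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained_variance),
    explained_variance = x$explained_variance,
    cumulative = cumsum(x$explained_variance)
  )
}

#' @method glance pcm_pca
#' @export
glance.pcm_pca <- function(x, ...) {
  tibble::tibble(
    n_components = ncol(x$loadings),
    total_explained = sum(x$explained_variance)
  )
}

#' @method tidy pcm_pls
#' @export
tidy.pcm_pls <- function(x, n_components = NULL, ...) {
  B <- pls_coefficients(x, n_components)
  out <- tibble::as_tibble(B, rownames = "term")
  tidyr::pivot_longer(out, -"term", names_to = "response",
                      values_to = "estimate")
}

#' @method glance pcm_pls
#' @export
glance.pcm_pls <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_predictors = nrow(x$W),
                 n_responses = nrow(x$Q))
}

#' @method tidy pcm_plsda
#' @export
tidy.pcm_plsda <- function(x, ...) x$q2_per_class

#' @method glance pcm_plsda
#' @export
glance.pcm_plsda <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_components = x$n_components,
                 q2_overall = x$q2_overall)
}

#' @method tidy pcm_cv
#' @export
tidy.pcm_cv <- function(x, ...) x$predictions

#' @method glance pcm_cv
#' @export
glance.pcm_cv <- function(x, ...) {
  out <- tibble::tibble(
    method = x$method, mode = x$mode, n_pairs = nrow(x$predictions),
    p2 = x$p2, auc = x$auc
  )
  names(out)[names(out) == "p2"] <- tolower(x$metric)
  out
}

#' @method tidy pcm_roc
#' @export
tidy.pcm_roc <- function(x, ...) x$points

#' @method glance pcm_roc
#' @export
glance.pcm_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_active = x$n_active,
                 n_inactive = x$n_inactive)
}

#' @method tidy pcm_size_sweep
#' @export
tidy.pcm_size_sweep <- function(x, ...) x$results

#' @method glance pcm_size_sweep
#' @export
glance.pcm_size_sweep <- function(x, ...) x$summary

#' @method tidy pcm_error_hist
#' @export
tidy.pcm_error_hist <- function(x, ...) x$cumulative
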