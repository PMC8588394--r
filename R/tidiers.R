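#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pl_ranking <- function(x, ...) x$ranking

#' @export
glance.pl_ranking <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$ranking),
                 top_model = x$ranking$model[1],
                 top_p_best = x$ranking$p_best[1])
}

#' @export
tidy.mcs_result <- function(x, ...) x$p_values

#' @export
glance.mcs_result <- function(x, ...) {
  tibble::tibble(alpha = x$alpha,
                 n_models = nrow(x$p_values),
                 n_survivors = length(x$survivors))
}

#' @export
tidy.spa_result <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.glybench_fit <- function(x, ...) x$history

#' @export
glance.glybench_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(spec_id = x$spec_id, horizon = x$horizon,
                 epochs = nrow(x$history),
                 val_loss = last$val_loss, val_mae = last$val_mae)
}

#' @export
tidy.glybench_cv <- function(x, ...) x$metrics

#' @export
glance.glybench_cv <- function(x, ...) {
  tibble::tibble(n_folds = length(unique(x$metrics$fold)),
                 n_patients = length(unique(x$metrics$patient_id)),
                 mean_rmse = mean(x$losses$loss))
}
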