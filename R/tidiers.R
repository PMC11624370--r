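#' Tidy a REML fit into a long component table
#'
#' @param x a `reml_fit`.
#' @param ... unused.
#' @return Tibble with `component`, `trait_1`, `trait_2`, `estimate` and,
#'   when the average-information matrix is available, `std_error`.
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, ...) {
  k <- length(x$traits)
  ij <- vech_index(k)
  out <- purrr::map_dfr(c("HTD", "G", "P", "R"), function(nm) {
    m <- x$components[[nm]]
    tibble::tibble(
      component = nm,
      trait_1 = x$traits[ij[, 1]],
      trait_2 = x$traits[ij[, 2]],
      estimate = m[ij]
    )
  })
  if (!is.null(x$se)) out$std_error <- unname(x$se)
  out
}

#' One-row summary of a REML fit
#'
#' @param x a `reml_fit`.
#' @param ... unused.
#' @return Tibble with the restricted log-likelihood, iteration count,
#'   convergence flag, record count and per-trait heritabilities.
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  h2 <- heritability(x$components)
  dplyr::bind_cols(
    tibble::tibble(logL = x$logL, iterations = x$iterations,
                   converged = x$converged, n_records = x$n_records),
    tibble::as_tibble(as.list(stats::setNames(h2, paste0("h2_", x$traits))))
  )
}

#' @method tidy covariance_components
#' @export
tidy.covariance_components <- function(x, ...) {
  k <- length(x$traits)
  ij <- vech_index(k)
  purrr::map_dfr(c("HTD", "G", "P", "R"), function(nm) {
    tibble::tibble(component = nm,
                   trait_1 = x$traits[ij[, 1]],
                   trait_2 = x$traits[ij[, 2]],
                   value = x[[nm]][ij])
  })
}

#' @method glance brnn_fit
#' @export
glance.brnn_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta,
                 effective_parameters = x$gamma, n_parameters = x$npar,
                 epochs = x$epochs)
}

#' Tidy mixed-model solutions into long per-animal breeding values
#'
#' @param x an `mme_solution`.
#' @param effect which solution block to tidy.
#' @param ... unused.
#' @return Long tibble: level key, `trait`, `value`.
#' @method tidy mme_solution
#' @export
tidy.mme_solution <- function(x, effect = c("ebv", "htd", "pe", "fixed"),
                              ...) {
  effect <- match.arg(effect)
  tbl <- x[[effect]]
  key <- names(tbl)[1]
  tidyr::pivot_longer(tbl, -dplyr::all_of(key), names_to = "trait",
                      values_to = "value")
}

#' Iteration trace of a REML fit
#'
#' @param object a `reml_fit`.
#' @param ... unused.
#' @return A ggplot of restricted log-likelihood against iteration,
#'   colored by step type.
#' @method autoplot reml_fit
#' @export
autoplot.reml_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$logL)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(color = .data$step), size = 2) +
    ggplot2::labs(x = "iteration", y = "restricted log-likelihood",
                  color = "step") +
    ggplot2::theme_minimal()
}

#' Bar chart of methane by RBV class
#'
#' @param object a `mef_class_summary` from [rbv_class_summary()].
#' @param ... unused.
#' @return A ggplot with predicted and recorded methane means and SE
#'   error bars per RBV class.
#' @method autoplot mef_class_summary
#' @export
autoplot.mef_class_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::all_of(c("mean_predicted", "mean_recorded")),
    names_to = "kind", values_to = "mean"
  ) |>
    dplyr::mutate(
      se = ifelse(.data$kind == "mean_predicted",
                  object$se_predicted[match(.data$class, object$class)],
                  object$se_recorded[match(.data$class, object$class)]),
      kind = ifelse(.data$kind == "mean_predicted", "predicted CH4",
                    "recorded CH4")
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$mean,
                                     fill = .data$kind)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = "RBV class for methane efficiency",
                  y = "CH4 (g/d)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Distribution of RBVs in a methane-efficiency evaluation
#'
#' @param object a `mef_evaluation` from [mef_evaluation()].
#' @param ... unused.
#' @return A ggplot histogram of RBVs with the class boundaries marked.
#' @method autoplot mef_evaluation
#' @export
autoplot.mef_evaluation <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rbv)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue",
                            color = "white") +
    ggplot2::geom_vline(xintercept = c(95, 105), linetype = "dashed") +
    ggplot2::labs(x = "RBV for methane efficiency", y = "animals") +
    ggplot2::theme_minimal()
}
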