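## ggplot2 methods for the package's result types.

#' Plot a fraction vector
#'
#' A bar chart of the fractions over their state labels.
#'
#' @param object A [fraction_vector()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fraction_vector
#' @export
autoplot.fraction_vector <- function(object, ...) {
  spec <- fv_spec(object)
  d <- tibble(state = factor(object$state, levels = object$state),
              value = object$value)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$state, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "state", y = "fraction",
                  title = sprintf("%s fractions of %s", fv_interp(object),
                                  spec$metabolite_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a labeling solution
#'
#' Mass isotopomer distributions of every solved EMU, one facet per EMU.
#'
#' @param object A `labeling_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot labeling_solution
#' @export
autoplot.labeling_solution <- function(object, ...) {
  d <- tidy(object)
  d$shift <- factor(d$shift, levels = unique(d$shift[order(nchar(d$shift), d$shift)]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$shift, y = .data$fraction,
                                  fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~emu, scales = "free_x") +
    ggplot2::labs(x = "mass shift", y = "fraction") +
    ggplot2::theme_minimal()
}

#' Plot a mass tensor
#'
#' For two-element tensors, a heat map of the per-element shift
#' probabilities; one-element tensors fall back to a bar chart.
#'
#' @param object A `mass_tensor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mass_tensor
#' @export
autoplot.mass_tensor <- function(object, ...) {
  d <- tidy(object)
  axes <- setdiff(names(d), "fraction")
  if (length(axes) >= 2) {
    ggplot2::ggplot(d, ggplot2::aes(x = factor(.data[[axes[1]]]),
                                    y = factor(.data[[axes[2]]]),
                                    fill = .data$fraction)) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = axes[1], y = axes[2]) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = factor(.data[[axes[1]]]),
                                    y = .data$fraction)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "mass shift", y = "fraction") +
      ggplot2::theme_minimal()
  }
}
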