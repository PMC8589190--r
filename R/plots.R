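# ggplot2 displays: kernel contact sheets, aggregated spectra, training
# histories, and efficiency curves.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   facet_wrap scale_fill_gradient2 scale_fill_viridis_c labs theme_minimal
#'   theme element_blank coord_equal geom_errorbar
#' @export
ggplot2::autoplot

kernel_raster_df <- function(bank) {
  k <- kernel_side(bank)
  purrr::map_dfr(seq_len(length(bank)), function(i) {
    tibble::tibble(
      kernel = i,
      family = bank$info$family[i],
      row = rep(seq_len(k), times = k),
      col = rep(seq_len(k), each = k),
      value = as.numeric(bank$kernels[, , i])
    )
  })
}

#' Contact sheet of a kernel bank
#'
#' @param object A `kernel_bank`.
#' @param ncol Facet columns (default 8).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kernel_bank
#' @export
autoplot.kernel_bank <- function(object, ncol = 8, ...) {
  df <- kernel_raster_df(object)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "#313695", mid = "white", high = "#a50026") +
    facet_wrap(~kernel, ncol = ncol) +
    coord_equal() +
    theme_minimal() +
    theme(axis.text = element_blank(), axis.title = element_blank(),
          panel.grid = element_blank(), strip.text = element_blank()) +
    labs(title = object$name, fill = NULL)
}

#' Aggregated power spectrum display
#'
#' @param bank A `kernel_bank`.
#' @param pad_to DFT padding (default 64).
#' @return A ggplot object (centered spectrum, log10 power).
#' @export
plot_power_spectrum <- function(bank, pad_to = 64) {
  sp <- aggregate_power_spectrum(bank, pad_to)
  df <- tibble::tibble(
    fy = rep(seq_len(pad_to), times = pad_to),
    fx = rep(seq_len(pad_to), each = pad_to),
    power = as.numeric(sp)
  )
  ggplot(df, aes(x = .data$fx, y = .data$fy, fill = log10(.data$power + 1e-12))) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    theme_minimal() +
    labs(title = paste("Aggregated power spectrum:", bank$name),
         x = NULL, y = NULL, fill = "log10 power")
}

#' Training history curve
#'
#' @param object A trained `rf_net`.
#' @param ... Unused.
#' @return A ggplot of validation Pearson by epoch.
#' @method autoplot rf_net
#' @export
autoplot.rf_net <- function(object, ...) {
  if (is.null(object$history)) stop_invalid("net has no training history")
  ggplot(object$history, aes(x = .data$epoch, y = .data$val_pearson)) +
    geom_line() +
    geom_point(data = object$history[object$history$epoch == object$epochs_to_stop, ],
               color = "red", size = 2) +
    theme_minimal() +
    labs(x = "epoch", y = "validation Pearson r",
         title = sprintf("%s training (stopped at epoch %d)",
                         object$config$variant, object$epochs_to_stop))
}

#' Data-efficiency curve
#'
#' @param object An `efficiency_curve` from [data_efficiency_experiment()].
#' @param ... Unused.
#' @return A ggplot of mean test performance by training fraction.
#' @method autoplot efficiency_curve
#' @export
autoplot.efficiency_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$fraction, y = .data$mean_performance)) +
    geom_line() +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean_performance - .data$sd_performance,
                      ymax = .data$mean_performance + .data$sd_performance),
                  width = 0.02) +
    theme_minimal() +
    labs(x = "training fraction", y = "mean test Pearson r",
         title = "Data efficiency")
}

#' Pursuit model stage kernels
#'
#' @param object A `pursuit_model`.
#' @param ... Unused.
#' @return A ggplot contact sheet of stage kernels, ordered by
#'   contribution.
#' @method autoplot pursuit_model
#' @export
autoplot.pursuit_model <- function(object, ...) {
  if (length(object$stages) == 0) stop_invalid("empty pursuit model")
  k <- nrow(object$stages[[1]]$kernel)
  df <- purrr::map_dfr(seq_along(object$stages), function(i) {
    tibble::tibble(
      stage = sprintf("stage %d (I=%.3f)", i, object$stages[[i]]$contribution),
      row = rep(seq_len(k), times = k),
      col = rep(seq_len(k), each = k),
      value = as.numeric(object$stages[[i]]$kernel)
    )
  })
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "#313695", mid = "white", high = "#a50026") +
    facet_wrap(~stage) +
    coord_equal() +
    theme_minimal() +
    theme(axis.text = element_blank(), axis.title = element_blank(),
          panel.grid = element_blank()) +
    labs(title = sprintf("%s stages", object$mode), fill = NULL)
}

#' @importFrom rlang .data
NULL
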