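# broom-style tidiers and ggplot2 methods for the fitted objects and maps.

#' @importFrom rlang .data
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained end-to-end model's history
#'
#' @param x a `qdcnn_fit`.
#' @param ... unused.
#' @return tibble with one row per (epoch, loss series).
#' @export
tidy.qdcnn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epoch = rep(h$epoch, 2),
    series = rep(c("train", "validation"), each = nrow(h)),
    loss = c(h$train_loss, h$val_loss))
}

#' @rdname tidy.qdcnn_fit
#' @export
glance.qdcnn_fit <- function(x, ...) {
  tibble::tibble(method = x$method, epochs = nrow(x$history),
                 best_epoch = x$best_epoch, best_val_loss = x$best_val,
                 n_recon_params = n_parameters(x$weights$frec),
                 n_map_params = if (is.null(x$weights$fmap)) NA_integer_
                 else n_parameters(x$weights$fmap))
}

#' @rdname tidy.qdcnn_fit
#' @export
tidy.fmap_fit <- function(x, ...) x$history

#' @rdname tidy.qdcnn_fit
#' @export
glance.fmap_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 final_loss = x$history$loss[nrow(x$history)],
                 n_params = n_parameters(x$weights))
}

# Generics re-exported so tidy()/glance() work without loading broom.
#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")

map_to_df <- function(m, value_name = "value") {
  d <- dim(m)
  tibble::tibble(row = rep(seq_len(d[1]), times = d[2]),
                 col = rep(seq_len(d[2]), each = d[1]),
                 value = as.vector(m))
}

#' Plot parameter maps
#'
#' Raster panels of the T2 map (ms) and the |S0| map.
#'
#' @param object a `parameter_maps`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.parameter_maps <- function(object, ...) {
  df_t2 <- map_to_df(object$t2); df_t2$map <- "T2 [ms]"
  df_s0 <- map_to_df(s0_magnitude(object)); df_s0$map <- "|S0|"
  df <- rbind(df_t2, df_s0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~map, scales = "free") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}

#' Plot a sampling mask set
#'
#' Phase-encode line patterns per echo (white = sampled).
#'
#' @param object a `sampling_mask_set`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sampling_mask_set <- function(object, ...) {
  d <- dim(object$masks)
  lines <- do.call(rbind, lapply(seq_len(d[3]), function(i) {
    tibble::tibble(echo = i, line = seq_len(d[1]),
                   sampled = object$masks[, 1, i] > 0)
  }))
  ggplot2::ggplot(lines, ggplot2::aes(x = .data$echo, y = .data$line,
                                      fill = .data$sampled)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "black", `TRUE` = "white")) +
    ggplot2::labs(x = "echo", y = "phase-encode line", fill = "sampled")
}

#' Plot training curves
#'
#' @param object a `qdcnn_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.qdcnn_fit <- function(object, ...) {
  df <- tidy.qdcnn_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "total loss", color = NULL)
}
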