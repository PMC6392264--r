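#' Validation-accuracy learning curves
#'
#' One panel per task x architecture, curves colored by featurization and
#' faceted by training condition, mirroring the usual accuracy-over-epochs
#' view of the three input resolutions.
#'
#' @param runs List of `ci_run` records.
#' @return A ggplot object.
#' @export
plot_histories <- function(runs) {
  df <- do.call(rbind, lapply(runs, function(r) {
    h <- r$history
    data.frame(task = r$task, arch = r$arch, res = r$res,
               condition = r$condition, seed = r$seed, epoch = h$epoch,
               val_accuracy = h$val_accuracy, stringsAsFactors = FALSE)
  }))
  df$panel <- paste(df$task, df$arch, df$condition, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$val_accuracy,
                                   color = .data$res,
                                   group = interaction(.data$res, .data$seed))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = "epoch", y = "validation accuracy",
                  color = "resolution") +
    ggplot2::theme_minimal()
}

#' Three-resolution spectrogram panel
#'
#' High-, medium-, and low-resolution featurizations of one waveform,
#' stacked for visual comparison of the channel-interaction blur.
#'
#' @param waveform Numeric sample vector.
#' @param config A [feat_config()].
#' @return A ggplot object.
#' @export
plot_spectrogram_panel <- function(waveform, config = feat_config()) {
  panels <- lapply(c("high", "med", "low"), function(res) {
    s <- featurize(waveform, res, config)
    v <- s$values
    data.frame(resolution = res,
               time = rep(s$frame_times_s, each = nrow(v)),
               channel = rep(seq_len(nrow(v)), ncol(v)),
               amplitude = as.vector(v))
  })
  df <- do.call(rbind, panels)
  df$resolution <- factor(df$resolution, levels = c("high", "med", "low"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$channel,
                                   fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~resolution, ncol = 1) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "channel") +
    ggplot2::theme_minimal()
}
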