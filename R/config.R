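#' Default pipeline configuration
#'
#' The full configuration tree consumed by [run_all()]: synthetic-corpus
#' sizes, featurization front end, training recipe, experiment seeds and
#' architectures, and statistical-testing settings. Desk-scale defaults:
#' 2,000 gender utterances, 1,500 word utterances, perceptron only, five
#' seeds.
#'
#' @return Nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 0L,
    out_dir = "cisim_results",
    tasks = list(
      gender = list(n_utterances = 2000L, male_fraction = 0.7),
      words = list(n_utterances = 1500L, n_classes = 30L)),
    featurization = list(window_ms = 50, hop_ms = 10, fmin_hz = 200,
                         fmax_hz = 7000, n_channels_high = 32L,
                         n_channels_med = 16L, log_amplitude = FALSE),
    training = list(lr_per = 0.01, lr_cnn = 0.1, batch_size = 32L,
                    patience = 10L, max_epochs = 200L, monitor = "loss"),
    experiment = list(seeds = 0:4, arches = "per", family_size = 18L),
    stats = list(art_R = 100000L, alpha = 0.05),
    plots = TRUE)
}

merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ",
         paste(paste(c(path, unknown[1]), collapse = "$"), collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) {
        stop("config field '", paste(c(path, nm), collapse = "$"),
             "' must be a mapping")
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

validate_run_config <- function(config) {
  if (!config$training$monitor %in% c("loss", "accuracy")) {
    stop("config field 'training$monitor' must be \"loss\" or \"accuracy\"")
  }
  bad <- setdiff(config$experiment$arches, c("per", "cnn"))
  if (length(bad)) {
    stop("config field 'experiment$arches' has invalid value(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- setdiff(names(config$tasks), c("gender", "words"))
  if (length(bad)) {
    stop("config field 'tasks' has unknown task(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(config$tasks) == 0L) stop("config field 'tasks' is empty")
  if (config$stats$alpha <= 0 || config$stats$alpha >= 1) {
    stop("config field 'stats$alpha' must lie in (0, 1)")
  }
  config
}

#' Load a pipeline configuration from YAML
#'
#' Missing fields are filled with [default_run_config()] values; unknown
#' fields are rejected with a message naming the field. An empty file yields
#' all defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  validate_run_config(merge_config(default_run_config(), user))
}

#' Save a configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
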