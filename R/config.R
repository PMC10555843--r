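# Run configuration: a nested structure with simulate / model / train /
# denoise sections, every field defaulted by the corresponding
# constructor, unknown keys rejected, lossless YAML round-trips.

section_builders <- function() {
  list(simulate = simulation_config, model = support_config,
       train = train_config)
}

build_section <- function(name, builder, values) {
  defaults <- formals(builder)
  unknown <- setdiff(names(values), names(defaults))
  if (length(unknown))
    stop("unknown key", if (length(unknown) > 1) "s", " in section '",
         name, "': ", paste(unknown, collapse = ", "))
  values <- values[!vapply(values, function(v)
    length(v) == 1 && is.na(v), logical(1))]
  do.call(builder, values)
}

#' Assemble a full run configuration
#'
#' @param simulate,model,train Named lists overriding the defaults of
#'   [simulation_config()], [support_config()] and [train_config()].
#' @param denoise Named list with optional `tile`, `margin`,
#'   `batch_frames`.
#' @param seed Optional master seed propagated to the simulate and train
#'   sections.
#' @return A `run_config` list with fully defaulted sections.
#' @export
run_config <- function(simulate = list(), model = list(), train = list(),
                       denoise = list(), seed = NULL) {
  if (!is.null(seed)) {
    simulate$seed <- as.integer(seed)
    train$seed <- as.integer(seed)
  }
  builders <- section_builders()
  out <- list(
    simulate = build_section("simulate", builders$simulate, simulate),
    model = build_section("model", builders$model, model),
    train = build_section("train", builders$train, train))
  dn <- list(tile = NULL, margin = NULL, batch_frames = 16L)
  denoise <- denoise[!vapply(denoise, function(v)
    length(v) == 1 && is.na(v), logical(1))]
  unknown <- setdiff(names(denoise), names(dn))
  if (length(unknown))
    stop("unknown key", if (length(unknown) > 1) "s",
         " in section 'denoise': ", paste(unknown, collapse = ", "))
  out$denoise <- utils::modifyList(dn, denoise)
  structure(out, class = "run_config")
}

#' Load / save a run configuration as YAML
#'
#' An empty file yields the full default configuration; unknown keys are
#' rejected with the offending key named.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c("simulate", "model", "train", "denoise",
                                   "seed"))
  if (length(unknown))
    stop("unknown top-level key", if (length(unknown) > 1) "s", ": ",
         paste(unknown, collapse = ", "))
  run_config(simulate = raw$simulate %||% list(),
             model = raw$model %||% list(),
             train = raw$train %||% list(),
             denoise = raw$denoise %||% list(),
             seed = raw$seed)
}

#' @rdname load_run_config
#' @param config A `run_config`.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ser <- lapply(unclass(config), function(sec) {
    sec <- unclass(sec)
    lapply(sec, function(v) if (is.null(v)) NA else v)
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
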