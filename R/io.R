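# Persistence: banks and fitted models serialize to JSON with
# full-precision doubles, plus a content hash so a reloaded object can be
# verified against the artifact that produced it.

content_hash <- function(x) {
  # dependency-free polynomial rolling hash (mod a Mersenne prime) over the
  # full-precision decimal representation
  s <- paste(format(x, digits = 17), collapse = ",")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Save or load a kernel bank
#'
#' Banks round-trip through JSON with full-precision doubles: kernel values
#' are bit-identical after a save/load cycle and the stored content hash is
#' verified on load.
#'
#' @param bank A `kernel_bank`.
#' @param path File path (conventionally `.json`).
#' @return `save_bank` returns `path` invisibly; `load_bank` returns the
#'   `kernel_bank`.
#' @export
save_bank <- function(bank, path) {
  if (!inherits(bank, "kernel_bank")) stop_invalid("not a kernel_bank")
  obj <- list(
    type = "kernel_bank", version = "1",
    name = bank$name, normalized = bank$normalized,
    side = kernel_side(bank), n = length(bank),
    kernels = as.numeric(bank$kernels),
    info = bank$info,
    hash = content_hash(as.numeric(bank$kernels))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname save_bank
#' @export
load_bank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(errorCondition(
                      paste0("corrupt bank container at ", path, ": ",
                             conditionMessage(e)),
                      class = c("rfpursuit_corrupt_container", "error")))
                  })
  if (!identical(obj$type, "kernel_bank")) {
    stop(errorCondition(paste0("not a kernel bank file: ", path),
                        class = c("rfpursuit_type_mismatch", "error")))
  }
  vals <- as.numeric(obj$kernels)
  if (length(vals) != obj$side * obj$side * obj$n ||
      !identical(content_hash(vals), obj$hash)) {
    stop(errorCondition(paste0("corrupt bank container at ", path),
                        class = c("rfpursuit_corrupt_container", "error")))
  }
  info <- tibble::as_tibble(obj$info)
  info$scale_index <- as.integer(info$scale_index)
  info$rotation_index <- as.integer(info$rotation_index)
  info$orientation_deg <- as.numeric(info$orientation_deg)
  bank <- kernel_bank(array(vals, dim = c(obj$side, obj$side, obj$n)),
                      info, name = obj$name, normalized = FALSE)
  bank$normalized <- obj$normalized
  bank
}

#' Save or load a fitted model
#'
#' Handles both `pursuit_model` and `rf_net` objects. Reloaded models
#' reproduce the original predictions (same weights, same architecture);
#' loading a file of the wrong model type raises a typed error.
#'
#' @param model A `pursuit_model` or trained `rf_net`.
#' @param path File path.
#' @param type Expected type for `load_model` (`"any"`, `"pursuit_model"`,
#'   or `"rf_net"`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "pursuit_model")) {
    obj <- list(
      type = "pursuit_model", version = "1",
      mode = model$mode, image_side = model$image_side,
      kernel_side = model$kernel_side,
      dictionary_name = model$dictionary_name,
      stages = lapply(model$stages, function(st) list(
        kernel = as.numeric(st$kernel), side = nrow(st$kernel),
        a = st$link$a, b = st$link$b, c = st$link$c,
        contribution = st$contribution,
        dict_index = if (is.null(st$dict_index) || is.na(st$dict_index)) NULL
                     else st$dict_index
      ))
    )
  } else if (inherits(model, "rf_net")) {
    cfg <- model$config
    obj <- list(
      type = "rf_net", version = "1",
      variant = cfg$variant, n_kernels = cfg$n_kernels,
      kernel_size = cfg$kernel_size, input_side = cfg$input_side,
      pool_window = cfg$pool_window, pool_stride = cfg$pool_stride,
      seed = cfg$seed,
      W = as.numeric(model$W), conv_bias = model$conv_bias,
      fc_w = as.numeric(model$fc_w), fc_b = model$fc_b,
      epochs_to_stop = model$epochs_to_stop,
      front_end = if (is.null(cfg$front_end)) NULL else list(
        name = cfg$front_end$name, normalized = cfg$front_end$normalized,
        side = kernel_side(cfg$front_end), n = length(cfg$front_end),
        kernels = as.numeric(cfg$front_end$kernels),
        info = cfg$front_end$info
      ),
      history = model$history,
      hash = content_hash(c(as.numeric(model$W), as.numeric(model$fc_w)))
    )
  } else {
    stop_invalid("model must be a pursuit_model or rf_net")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, type = c("any", "pursuit_model", "rf_net")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(errorCondition(
                      paste0("corrupt model container at ", path),
                      class = c("rfpursuit_corrupt_container", "error")))
                  })
  if (type != "any" && !identical(obj$type, type)) {
    stop(errorCondition(
      sprintf("expected a %s but %s contains a %s", type, path, obj$type),
      class = c("rfpursuit_type_mismatch", "error")))
  }
  if (identical(obj$type, "pursuit_model")) {
    stages <- obj$stages
    if (is.data.frame(stages)) stages <- split(stages, seq_len(nrow(stages)))
    structure(list(
      mode = obj$mode,
      stages = unname(lapply(stages, function(st) {
        st <- as.list(st)
        side <- as.integer(st$side)
        list(kernel = matrix(as.numeric(unlist(st$kernel)), side, side),
             link = structure(list(a = as.numeric(st$a), b = as.numeric(st$b),
                                   c = as.numeric(st$c)),
                              class = "quadratic_link"),
             contribution = as.numeric(st$contribution),
             dict_index = if (is.null(st$dict_index) ||
                              is.null(st$dict_index[[1]])) NA_integer_
                          else as.integer(st$dict_index[[1]]),
             z = NULL)
      })),
      image_side = obj$image_side, kernel_side = obj$kernel_side,
      dictionary_name = obj$dictionary_name
    ), class = "pursuit_model")
  } else if (identical(obj$type, "rf_net")) {
    fe <- NULL
    if (!is.null(obj$front_end)) {
      fe <- kernel_bank(array(as.numeric(obj$front_end$kernels),
                              dim = c(obj$front_end$side, obj$front_end$side,
                                      obj$front_end$n)),
                        tibble::as_tibble(obj$front_end$info),
                        name = obj$front_end$name, normalized = FALSE)
      fe$normalized <- obj$front_end$normalized
    }
    cfg <- net_config(obj$variant, front_end = fe,
                      n_kernels = obj$n_kernels, kernel_size = obj$kernel_size,
                      input_side = obj$input_side,
                      pool_window = obj$pool_window,
                      pool_stride = obj$pool_stride, seed = obj$seed)
    net <- build_network(cfg)
    net$W <- matrix(as.numeric(obj$W), obj$kernel_size^2, cfg$n_kernels)
    if (length(obj$conv_bias)) net$conv_bias <- as.numeric(obj$conv_bias)
    net$fc_w <- matrix(as.numeric(obj$fc_w), ncol = 1)
    net$fc_b <- obj$fc_b
    net$epochs_to_stop <- obj$epochs_to_stop
    if (!is.null(obj$history)) net$history <- tibble::as_tibble(obj$history)
    if (!identical(content_hash(c(as.numeric(net$W), as.numeric(net$fc_w))),
                   obj$hash)) {
      stop(errorCondition(paste0("corrupt model container at ", path),
                          class = c("rfpursuit_corrupt_container", "error")))
    }
    net
  } else {
    stop(errorCondition(paste0("unrecognized model type in ", path),
                        class = c("rfpursuit_type_mismatch", "error")))
  }
}
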