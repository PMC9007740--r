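#' Describe one convolutional layer
#'
#' @param kernel_size,stride positive integers.
#' @return object of class `layer_spec`.
#' @export
layer_spec <- function(kernel_size, stride = 1L) {
  stopifnot(is_count(kernel_size), kernel_size >= 1,
            is_count(stride), stride >= 1)
  structure(list(kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride)),
            class = "layer_spec")
}

#' Maximum receptive field of a convolutional stack
#'
#' Closed form: `RF = 1 + sum_i (K_i - 1) * prod_j S_j`. With
#' `convention = "inclusive"` (the default) the stride product runs over
#' `j = 1..i`, i.e. it includes layer i's own stride; the textbook formula
#' uses `j = 1..i-1` and is available as `convention = "standard"`. The two
#' agree whenever all strides are 1.
#'
#' @param layers list of [layer_spec()] (or 2-column matrix of
#'   kernel/stride), encoder layers in order.
#' @param convention `"inclusive"` or `"standard"` stride-product bound.
#' @return integer receptive field in input pixels.
#' @examples
#' compute_receptive_field(list(layer_spec(3), layer_spec(3)))  # 5
#' @export
compute_receptive_field <- function(layers, convention = c("inclusive",
                                                           "standard")) {
  convention <- match.arg(convention)
  if (is.matrix(layers)) {
    layers <- lapply(seq_len(nrow(layers)),
                     function(i) layer_spec(layers[i, 1], layers[i, 2]))
  }
  if (!length(layers)) stop("need at least one layer")
  stopifnot(all(vapply(layers, inherits, logical(1), "layer_spec")))
  k <- vapply(layers, `[[`, integer(1), "kernel_size")
  s <- vapply(layers, `[[`, integer(1), "stride")
  sprod <- cumprod(s)
  prods <- switch(convention,
                  inclusive = sprod,
                  standard = c(1, sprod[-length(sprod)]))
  as.integer(1 + sum((k - 1) * prods))
}

# ---- configuration schema ---------------------------------------------------

config_schema <- function() {
  list(
    encoding = list(
      sigma_base = list(default = 1.0, check = function(x)
        is.numeric(x) && x > 0),
      paf_sigma = list(default = 5.0, check = function(x)
        is.numeric(x) && x > 0),
      output_stride = list(default = 1L, check = function(x)
        x %in% c(1, 2, 4, 8)),
      class_radius = list(default = 5.0, check = function(x)
        is.numeric(x) && x > 0)),
    inference = list(
      peak_threshold = list(default = 0.2, check = function(x)
        is.numeric(x) && x >= 0 && x <= 1),
      refine = list(default = TRUE, check = is.logical),
      patch_size = list(default = 5L, check = function(x)
        is_count(x) && x >= 1 && x %% 2 == 1)),
    grouping = list(
      min_connection_score = list(default = 0.05, check = function(x)
        is.numeric(x) && x >= -1 && x <= 1),
      n_line_samples = list(default = 10L, check = function(x)
        is_count(x) && x >= 2),
      allow_singletons = list(default = FALSE, check = is.logical),
      max_instances = list(default = NULL, check = function(x)
        is.null(x) || (is_count(x) && x >= 1))),
    tracking = list(
      window_size = list(default = 5L, check = function(x)
        is_count(x) && x >= 1),
      cost_threshold = list(default = NULL, check = function(x)
        is.null(x) || (is.numeric(x) && x > 0)),
      flow_levels = list(default = 3L, check = function(x)
        is_count(x) && x >= 1),
      flow_window = list(default = 15L, check = function(x)
        is_count(x) && x >= 3 && x %% 2 == 1),
      flow_iterations = list(default = 10L, check = function(x)
        is_count(x) && x >= 1)),
    provenance = list(
      version = list(default = "multipose-0.1", check = is.character),
      seed = list(default = NULL, check = function(x)
        is.null(x) || is_count(x))))
}

#' Build a run configuration
#'
#' Returns the full parameter set controlling encoding, inference, grouping
#' and tracking, with every block present and every key at its default
#' unless overridden. Unknown keys and out-of-range values are rejected with
#' the offending key named, so configuration files fail loudly instead of
#' silently drifting.
#'
#' @param ... named blocks (e.g. `encoding = list(sigma_base = 1.5)`)
#'   overriding defaults.
#' @return object of class `run_config` (a named list of blocks).
#' @export
run_config <- function(...) {
  overrides <- list(...)
  schema <- config_schema()
  unknown_block <- setdiff(names(overrides), names(schema))
  if (length(unknown_block)) {
    stop("unknown configuration block(s): ",
         paste(unknown_block, collapse = ", "))
  }
  cfg <- list()
  for (block in names(schema)) {
    spec <- schema[[block]]
    vals <- lapply(spec, `[[`, "default")
    ov <- overrides[[block]]
    if (!is.null(ov)) {
      bad <- setdiff(names(ov), names(spec))
      if (length(bad)) {
        stop(sprintf("unknown key '%s' in block '%s'", bad[1], block))
      }
      for (key in names(ov)) {
        v <- ov[[key]]
        if (!isTRUE(spec[[key]]$check(v))) {
          stop(sprintf("invalid value for %s$%s", block, key))
        }
        vals[key] <- list(v)  # [[<- would delete the element when v is NULL
      }
    }
    cfg[[block]] <- vals
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (block in names(x)) {
    cat(" ", block, ":", paste(names(x[[block]]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Save a run configuration as JSON
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load and validate a run configuration from JSON
#'
#' Missing blocks and keys are filled with defaults (and therefore explicit
#' on the next save); unknown keys, type mismatches and out-of-range values
#' raise an error naming the offending key.
#'
#' @param path path to a JSON configuration file.
#' @return a [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  # restore integer-ish values parsed as doubles
  raw <- lapply(raw, function(block) {
    lapply(block, function(v) {
      if (is.numeric(v) && length(v) == 1L && is.finite(v) &&
          v == as.integer(v)) as.integer(v) else v
    })
  })
  do.call(run_config, raw)
}
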