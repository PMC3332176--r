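# Layered run configuration: documented defaults, overridden by a flat
# dotted-key text file, overridden by CLI flags. The resolved configuration
# is written beside every output directory for provenance.

.config_defaults <- list(
  method = "wfcm",
  wavelet.family = "db4",
  wavelet.levels = 1L,
  wavelet.mode = "approximation",
  wavelet.boundary = "symmetric",
  wavelet.magnitude_sqrt = FALSE,
  cluster.C = 3L,
  cluster.fuzziness = 2,
  cluster.tol = 1e-5,
  cluster.max_iter = 300L,
  cluster.seed = 0L,
  preselect.rulebase_path = "",
  preselect.sets_distance_path = "",
  preselect.sets_size_path = "",
  preselect.sets_cluster_path = "",
  srm.Q = 256L,
  srm.predicate = "canonical",
  lesion.polarity = "dark",
  threshold = 0.5,
  seed = 0L
)

coerce_like <- function(value, template, key) {
  if (is.logical(template)) {
    v <- toupper(as.character(value))
    if (!v %in% c("TRUE", "FALSE", "T", "F", "1", "0"))
      stop("config key '", key, "' must be logical, got '", value, "'",
           call. = FALSE)
    return(v %in% c("TRUE", "T", "1"))
  }
  if (is.integer(template)) {
    v <- suppressWarnings(as.integer(value))
    if (is.na(v)) stop("config key '", key, "' must be an integer, got '",
                       value, "'", call. = FALSE)
    return(v)
  }
  if (is.numeric(template)) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) stop("config key '", key, "' must be numeric, got '",
                       value, "'", call. = FALSE)
    return(v)
  }
  as.character(value)
}

#' Default run configuration
#'
#' @return Named list of all configuration keys with their defaults.
#' @export
default_config <- function() .config_defaults

#' Load and resolve a run configuration
#'
#' Precedence: CLI `overrides` beat the `path` file, which beats the
#' defaults. The file format is one `key = value` pair per line with dotted
#' keys (e.g. `wavelet.family = db4`); blank lines and `#` comments are
#' ignored. Unknown keys raise an error naming the closest known key.
#'
#' @param path Optional configuration file.
#' @param overrides Named list (or character vector) of key-value overrides.
#' @return Resolved configuration list (class `run_config`).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- .config_defaults
  apply_kv <- function(cfg, key, value, origin) {
    if (!key %in% names(cfg)) {
      near <- agrep(key, names(cfg), max.distance = 0.3, value = TRUE)
      stop("unknown config key '", key, "' (", origin, ")",
           if (length(near)) paste0("; did you mean '", near[1L], "'?"),
           call. = FALSE)
    }
    cfg[[key]] <- coerce_like(value, .config_defaults[[key]], key)
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L)
        stop("config line must be 'key = value': '", ln, "'", call. = FALSE)
      cfg <- apply_kv(cfg, trimws(kv[1L]), trimws(kv[2L]), path)
    }
  }
  if (length(overrides)) {
    for (key in names(overrides))
      cfg <- apply_kv(cfg, key, overrides[[key]], "command line")
  }
  validate_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

validate_config <- function(cfg) {
  methods <- c("wfcm", "wkmeans", "wcpsfcm", "fcm", "kmeans", "cpsfcm", "srm")
  if (!cfg$method %in% methods)
    stop("method must be one of ", paste(methods, collapse = ", "),
         call. = FALSE)
  if (!cfg$wavelet.mode %in% c("approximation", "magnitude"))
    stop("wavelet.mode must be 'approximation' or 'magnitude'", call. = FALSE)
  if (!cfg$wavelet.boundary %in% c("symmetric", "periodic"))
    stop("wavelet.boundary must be 'symmetric' or 'periodic'", call. = FALSE)
  if (cfg$wavelet.levels < 1L) stop("wavelet.levels must be >= 1", call. = FALSE)
  if (cfg$cluster.C < 1L) stop("cluster.C must be >= 1", call. = FALSE)
  if (cfg$cluster.fuzziness <= 1) stop("cluster.fuzziness must be > 1",
                                       call. = FALSE)
  if (cfg$srm.Q < 1L) stop("srm.Q must be >= 1", call. = FALSE)
  if (!cfg$srm.predicate %in% c("canonical", "as_printed"))
    stop("srm.predicate must be 'canonical' or 'as_printed'", call. = FALSE)
  if (!cfg$lesion.polarity %in% c("dark", "light"))
    stop("lesion.polarity must be 'dark' or 'light'", call. = FALSE)
  if (cfg$threshold < 0 || cfg$threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

write_config <- function(cfg, path) {
  fmt <- vapply(names(cfg), function(k)
    paste0(k, " = ", format(cfg[[k]], scientific = FALSE)), character(1L))
  writeLines(fmt, path)
  invisible(path)
}

config_rulebase <- function(cfg) {
  args <- list()
  if (nzchar(cfg$preselect.sets_distance_path))
    args$distance_sets <- read_fuzzy_sets(cfg$preselect.sets_distance_path)
  if (nzchar(cfg$preselect.sets_size_path))
    args$size_sets <- read_fuzzy_sets(cfg$preselect.sets_size_path)
  if (nzchar(cfg$preselect.sets_cluster_path))
    args$cluster_sets <- read_fuzzy_sets(cfg$preselect.sets_cluster_path)
  if (nzchar(cfg$preselect.rulebase_path))
    args$rules <- read_rules(cfg$preselect.rulebase_path)
  do.call(default_rulebase, args)
}
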