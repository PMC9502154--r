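#' @importFrom rlang abort warn
NULL

# All package conditions share the "cellframe_error" class so callers can
# catch everything with one handler; the specific class encodes the rule
# that was violated.
cf_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(paste0("cellframe_", class), "cellframe_error"), ...)
}

err_identifier <- function(msg) cf_abort("identifier_error", msg)
err_shape <- function(msg) cf_abort("shape_error", msg)
err_duplication <- function(msg) cf_abort("duplication_error", msg)
err_reserved <- function(msg) cf_abort("reserved_column_error", msg)
err_collision <- function(msg) cf_abort("name_collision_error", msg)
err_name <- function(msg) cf_abort("name_error", msg)
err_readonly <- function(msg) cf_abort("readonly_column_error", msg)
err_index <- function(msg) cf_abort("index_error", msg)
err_sample_size <- function(msg) cf_abort("sample_size_error", msg)
err_join_key <- function(msg) cf_abort("join_key_error", msg)
err_aggregation <- function(msg) cf_abort("aggregation_error", msg)
err_pattern <- function(msg) cf_abort("pattern_error", msg)
err_feature <- function(msg, missing = character()) {
  cf_abort("feature_not_found_error", msg, missing_features = missing)
}
err_group_key <- function(msg) cf_abort("group_key_error", msg)
err_empty_input <- function(msg) cf_abort("empty_input_error", msg)
err_polygon <- function(msg) cf_abort("polygon_error", msg)
err_format <- function(msg) cf_abort("format_error", msg)
err_file_exists <- function(msg) cf_abort("file_exists_error", msg)
err_param <- function(msg) cf_abort("param_error", msg)

# Structured demotion warning: emitted once per verb call when a result is
# returned as a plain tibble instead of a container-backed view.
warn_demotion <- function(verb, rule) {
  rlang::warn(
    sprintf("`%s()` returned a plain tibble: %s", verb, rule),
    class = "cellframe_demotion",
    verb = verb, rule = rule
  )
}

warn_cellframe <- function(msg, class = "cellframe_warning", ...) {
  rlang::warn(msg, class = class, ...)
}
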