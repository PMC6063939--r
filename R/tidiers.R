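#' Tidy and glance methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns the per-unit table of a result
#' (per fold-by-threshold cells for a `cv_prs`, per fold-by-channel
#' statistics for a `channel_eval`), `glance()` the one-row (or one row per
#' channel) summary.
#'
#' @param x a `cv_prs` or `channel_eval` object.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL
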