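# Internal argument checks. All user-facing errors carry the offending
# argument name so CLI/config errors can point at a field.

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("sonodrop_input_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("sonodrop_config_error", "error")))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x <= 0)) {
    stop_input("`", name, "` must be a positive number, got ",
               paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x < 0)) {
    stop_input("`", name, "` must be a non-negative number, got ",
               paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_flow_index <- function(n, name = "n") {
  if (!is.numeric(n) || anyNA(n) || any(n <= 0) || any(n > 1)) {
    stop_input("`", name, "` (power-law flow index) must satisfy 0 < n <= 1, got ",
               paste(format(n), collapse = ", "))
  }
  invisible(n)
}
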