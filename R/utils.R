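# Internal argument checks shared across modules.

stop_invalid <- function(...) {
  stop(structure(
    class = c("mitobell_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_input <- function(...) {
  stop(structure(
    class = c("mitobell_invalid_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (integer && x != round(x))
    stop_invalid(name, " must be a whole number")
  if (strict_lower && x <= lower)
    stop_invalid(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_invalid(name, " must be >= ", lower)
  if (strict_upper && x >= upper)
    stop_invalid(name, " must be < ", upper)
  if (!strict_upper && x > upper)
    stop_invalid(name, " must be <= ", upper)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
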