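# Internal numeric and validation helpers.

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
#' @noRd
stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# scalar checks used across constructors
check_prob <- function(x, name, open_lower = TRUE, open_upper = TRUE) {
  lo <- if (open_lower) x > 0 else x >= 0
  hi <- if (open_upper) x < 1 else x <= 1
  if (length(x) != 1L || !is.finite(x) || !lo || !hi)
    stop_param("'%s' must be a single value in %s0,1%s (got %s)",
               name, if (open_lower) "(" else "[",
               if (open_upper) ")" else "]", format(x))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop_param("'%s' must be an integer >= %d (got %s)", name, min, format(x))
  invisible(as.integer(x))
}

# two-sided normal p from z, log-safe for large |z|
z_to_p <- function(z) 2 * stats::pnorm(abs(z), lower.tail = FALSE)

# upper-tail probit of a p-value (gene Z convention)
p_to_z <- function(p) stats::qnorm(p, lower.tail = FALSE)
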