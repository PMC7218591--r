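# Shared internals: error conditions and integer percentage rounding.

# Validation failures are signalled as classed conditions so callers (and
# the CLI, which maps them to exit code 2) can distinguish bad input from
# programming errors.
ddx_error <- function(message, class = "ddx_validation_error") {
  structure(
    class = c(class, "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
}

#' Round probability shares to integer percentages summing to 100
#'
#' Largest-remainder (Hamilton) apportionment: each share gets the floor of
#' `100 * share`, and the remaining points go to the entries with the
#' largest fractional remainders, earlier (higher-ranked) entries winning
#' remainder ties. This is the rounding convention behind every percentage
#' surety emitted by the engine, the vignette generator, and the simulated
#' raters, guaranteeing the sum-to-100 invariant of a differential.
#'
#' @param shares non-negative numeric vector; rescaled to sum to 1.
#' @param total integer total to apportion (default 100).
#' @return integer vector of the same length summing exactly to `total`.
#' @examples
#' surety_percentages(c(0.335, 0.333, 0.332))  # 34 33 33
#' @export
surety_percentages <- function(shares, total = 100L) {
  if (length(shares) == 0) stop(ddx_error("empty share vector"))
  if (any(is.na(shares) | shares < 0)) stop(ddx_error("shares must be non-negative"))
  s <- sum(shares)
  if (s <= 0) stop(ddx_error("shares sum to zero"))
  x <- shares / s * total
  base <- floor(x)
  need <- as.integer(round(total - sum(base)))
  if (need > 0) {
    rem <- x - base
    take <- order(-rem, seq_along(x))[seq_len(need)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Deterministic C-locale ordering helper (ties in posteriors etc. must not
# depend on the session locale).
.radix_order <- function(...) order(..., method = "radix")

.stop_if <- function(cond, msg) if (isTRUE(cond)) stop(ddx_error(msg))
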