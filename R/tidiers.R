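# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a unitary-brightness calibration
#'
#' @param x A `unitary_brightness` object.
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate`, `std.error`.
#' @export
tidy.unitary_brightness <- function(x, ...) {
  tibble(term = "I1", estimate = x$I1, std.error = x$uncertainty)
}

#' @rdname tidy.unitary_brightness
#' @export
glance.unitary_brightness <- function(x, ...) {
  tibble(I1 = x$I1, std.error = x$uncertainty, method = x$method,
         n_traces = x$n_traces, n_steps = x$n_steps, channel = x$channel)
}

#' Tidy a constrained-intercept diffusion fit
#'
#' @param x A `diffusion_fit` object.
#' @param ... Unused.
#' @return Tibble with the fitted slope and the derived diffusion
#'   coefficient.
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble(term = c("slope", "D"),
         estimate = c(x$slope, x$D))
}

#' @rdname tidy.diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(D = x$D, sigma_um = x$sigma_um, intercept = 4 * x$sigma_um^2,
         n_lags = x$n_lags, clipped = x$clipped,
         residual_rms = x$residual_rms)
}

#' Tidy a set overlap
#'
#' @param x A `set_overlap` object.
#' @param ... Unused.
#' @return Tibble with one row per identifier and its membership class.
#' @export
tidy.set_overlap <- function(x, ...) {
  bind_rows(
    tibble(id = x$intersection, membership = "both"),
    tibble(id = x$only_a, membership = "only_a"),
    tibble(id = x$only_b, membership = "only_b")
  )
}

#' @rdname tidy.set_overlap
#' @export
glance.set_overlap <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, n_intersection = x$n_intersection,
         n_only_a = length(x$only_a), n_only_b = length(x$only_b))
}
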