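# broom-style tidiers for the comparison result objects.

#' Tidy a metallome-quota correlation
#'
#' @param x A `metallome_cor` object from [correlate_metallome()].
#' @param ... Unused.
#' @return The per-metal (quota, abundance) pairs used in the fit, with an
#'   `included` flag covering the excluded metals too.
#' @exportS3Method generics::tidy
tidy.metallome_cor <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$pairs, included = TRUE, reason = NA_character_),
    dplyr::mutate(x$excluded, included = FALSE)
  ) |>
    dplyr::arrange(dplyr::desc(.data$included), .data$metal)
}

#' @rdname tidy.metallome_cor
#' @return `glance()`: a one-row tibble with `r.squared`, `n.metals`,
#'   `n.excluded` and the correlation space.
#' @exportS3Method generics::glance
glance.metallome_cor <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    n.metals = x$n_points,
    n.excluded = nrow(x$excluded),
    space = if (x$log10) "log10" else "linear"
  )
}

#' Tidy a differential-expression result
#'
#' @param x A `metallome_de` tibble from [differential_expression()].
#' @param ... Unused.
#' @return A plain tibble (metals list-column collapsed to a
#'   comma-separated string).
#' @exportS3Method generics::tidy
tidy.metallome_de <- function(x, ...) {
  out <- tibble::as_tibble(x)
  if ("metals" %in% names(out)) {
    out$metals <- purrr::map_chr(out$metals, paste, collapse = ",")
  }
  out
}

#' @rdname tidy.metallome_de
#' @return `glance()`: one row with the numbers of tested, significant,
#'   up- and down-regulated proteins and the significance level.
#' @exportS3Method generics::glance
glance.metallome_de <- function(x, ...) {
  tested <- !is.na(x$p)
  tibble::tibble(
    n.proteins = nrow(x),
    n.tested = sum(tested),
    n.significant = sum(x$significant, na.rm = TRUE),
    n.up = sum(x$significant & x$log2fc > 0, na.rm = TRUE),
    n.down = sum(x$significant & x$log2fc < 0, na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}
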