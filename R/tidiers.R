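# broom-style tidy()/glance() methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an embedding into long form
#'
#' @param x A `pt_embedding`.
#' @param ... Unused.
#' @return A tibble `cell`, `component`, `value`.
#' @export
tidy.pt_embedding <- function(x, ...) {
  as_tibble(x$coords, rownames = "cell") |>
    pivot_longer(-"cell", names_to = "component", values_to = "value")
}

#' One-row summary of an embedding
#'
#' @param x A `pt_embedding`.
#' @param ... Unused.
#' @return A tibble with `method`, `n_cells`, `n_components`,
#'   `first_component`, `last_component`.
#' @export
glance.pt_embedding <- function(x, ...) {
  tibble(method = x$method, n_cells = nrow(x$coords),
         n_components = ncol(x$coords),
         first_component = min(x$components),
         last_component = max(x$components))
}

#' Tidy a TSS profile into long form
#'
#' @param x A `tss_profile`.
#' @param ... Unused.
#' @return A tibble `gene_id`, `position`, `count`.
#' @export
tidy.tss_profile <- function(x, ...) {
  as_tibble(x$matrix, rownames = "gene_id") |>
    pivot_longer(-"gene_id", names_to = "position", values_to = "count") |>
    mutate(position = as.integer(.data$position))
}

#' One-row summary of a TSS profile
#'
#' @param x A `tss_profile`.
#' @param ... Unused.
#' @return A tibble with `n_genes`, `n_positions`, `step`, `total`,
#'   `peak_position`.
#' @export
glance.tss_profile <- function(x, ...) {
  tibble(n_genes = nrow(x$matrix), n_positions = length(x$position),
         step = x$position[2] - x$position[1],
         total = sum(x$matrix),
         peak_position = x$position[which.max(x$mean)])
}
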