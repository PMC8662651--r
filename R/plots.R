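#' @import ggplot2
NULL

#' Heatmap of a cluster similarity matrix
#'
#' Rows are source clusters (whose members are scored), columns target
#' clusters (whose constraints score them); the diagonal sits at or above
#' the classification cut-off, and the sub/supercluster asymmetry shows as
#' bright off-diagonal cells in one triangle only.
#'
#' @param object A `kc_similarity`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kc_similarity
#' @export
autoplot.kc_similarity <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$target, y = .data$source,
                 fill = .data$similarity)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    scale_y_discrete(limits = rev) +
    labs(x = "target cluster (constraints)",
         y = "source cluster (members)", fill = "mean fit score") +
    theme_minimal()
}

#' Presence/absence plot of a conservation matrix
#'
#' @param object A `kc_conservation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kc_conservation
#' @export
autoplot.kc_conservation <- function(object, ...) {
  df <- as_tibble(object)
  df$taxon_name <- factor(df$taxon_name, levels = unique(df$taxon_name))
  ggplot(df, aes(x = .data$cluster_id, y = .data$taxon_name,
                 fill = .data$detected)) +
    geom_tile(colour = "grey70") +
    scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    labs(x = "cluster", y = "taxon",
         fill = sprintf("detected (cutoff %.2f)", attr(object, "cutoff"))) +
    theme_minimal()
}

#' Divergence profile of comparative logo data
#'
#' Bar height is the per-column relative entropy (nats) of foreground vs
#' background residue composition; the most divergent columns are the
#' cluster's strongest constraints.
#'
#' @param object A `kc_logo`.
#' @param top_n Label the `top_n` most foreground-frequent residues per
#'   column. Default 1.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kc_logo
#' @export
autoplot.kc_logo <- function(object, top_n = 1, ...) {
  top <- object$freq %>%
    group_by(.data$column) %>%
    arrange(desc(.data$fg_freq), .by_group = TRUE) %>%
    slice(seq_len(top_n)) %>%
    summarise(label = paste(.data$residue, collapse = ""),
              .groups = "drop")
  df <- left_join(object$divergence, top, by = "column")
  ggplot(df, aes(x = factor(.data$column), y = .data$divergence)) +
    geom_col(fill = "steelblue") +
    geom_text(aes(label = .data$label), vjust = -0.3, size = 3) +
    labs(x = "alignment column", y = "divergence (nats)") +
    theme_minimal()
}

#' Median DE-loop lengths per family
#'
#' Bar chart of the per-family median alphaD-alphaE loop length, capped at
#' `display_cap` for display, coloured by longDE/shortDE clade.
#'
#' @param object A `kc_loops` table (ideally after [label_clades()]).
#' @param display_cap Display truncation. Default 30.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kc_loops
#' @export
autoplot.kc_loops <- function(object, display_cap = 30, ...) {
  df <- loop_display(object, display_cap)
  df$shown <- pmin(df$median_length, display_cap)
  ggplot(df, aes(x = stats::reorder(.data$family, .data$shown),
                 y = .data$shown, fill = .data$clade)) +
    geom_col() +
    geom_text(aes(label = .data$median_display), vjust = -0.3, size = 3) +
    labs(x = "family",
         y = sprintf("median loop length (capped at %d)", display_cap),
         fill = "clade") +
    theme_minimal()
}
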