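#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one participant's CD4 / viral-load course with visit codes
#'
#' The conventional longitudinal phenotyping display: CD4 count (dashed line)
#' and smoothed CD4 (solid), a horizontal nadir reference, log10 viral load on
#' a secondary axis, and one glyph per visit giving its phenotype code, so a
#' reviewer can see at a glance where the suppressed response window lies.
#'
#' @param visits Classified visit tibble (from [classify_visits()] or
#'   [phenotype_cohort()]).
#' @param participant Participant id to plot.
#' @param nadir Optional nadir CD4 reference line (cells/mm3).
#' @return A ggplot object.
#' @export
plot_participant <- function(visits, participant, nadir = NULL) {
  v <- visits[visits$participant_id == participant, ]
  assert_that(nrow(v) > 0, "no visits for that participant")
  vl_scale <- max(v$cd4, na.rm = TRUE) / max(log10(pmax(v$vl, 1)), 1, na.rm = TRUE)
  p <- ggplot2::ggplot(v, ggplot2::aes(x = .data$visit_index)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cd4), linetype = "dashed",
                       color = "steelblue", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cd4, shape = .data$on_cart),
                        color = "steelblue", na.rm = TRUE) +
    ggplot2::labs(x = "Study visit (semiannual)", y = "CD4 count (cells/mm3)",
                  title = participant, shape = "on cART") +
    ggplot2::theme_minimal()
  if ("smoothed_cd4" %in% names(v)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_cd4),
                                color = "steelblue", na.rm = TRUE)
  }
  if ("code" %in% names(v)) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(y = -0.05 * max(.data$cd4, na.rm = TRUE),
                   label = code_glyph(.data$code)),
      size = 3, na.rm = TRUE
    )
  }
  if (!is.null(nadir)) {
    p <- p + ggplot2::geom_hline(yintercept = nadir, color = "darkgreen")
  }
  if (any(!is.na(v$vl))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = log10(pmax(.data$vl, 1)) * vl_scale),
                                linetype = "dotdash", color = "grey30",
                                na.rm = TRUE) +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(~ . / vl_scale, name = "log10 HIV RNA")
      )
  }
  p
}

code_glyph <- function(code) {
  dplyr::case_match(code,
    "NOT_DETERMINED" ~ "U",
    "OFF_ART_VIREMIC_STABLE" ~ "-",
    "OFF_ART_VIREMIC_DECLINING" ~ "l",
    "SHORT_OFF_ART_VIREMIC_DECLINING" ~ "s",
    "FIRST_CART" ~ "H*",
    "REINITIATED_CART" ~ "H+",
    "CART_VIREMIC" ~ "Hv",
    "CART_SUPPRESSED" ~ "H",
    "CART_SUPPRESSED_MINIMAL_GAIN" ~ "h",
    .default = "?"
  )
}

#' Volcano-style overview of a burden scan
#'
#' @param object A [run_burden_scan()] result.
#' @param ... Unused.
#' @return A ggplot of -log10 permutation/asymptotic p per gene and test.
#' @method autoplot burden_scan
#' @export
autoplot.burden_scan <- function(object, ...) {
  df <- object$results |>
    dplyr::filter(.data$adjusted == object$adjusted) |>
    dplyr::mutate(p = dplyr::coalesce(.data$p_perm, .data$p_asym))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = -log10(.data$p),
                                   color = .data$test)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = -log10(object$threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "-log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
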