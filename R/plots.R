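#' ENc-GC3 plot coordinates
#'
#' Joins per-gene ENc values and GC profiles into the coordinate table of
#' the ENc-GC3 diagnostic plot, adding the value of Wright's expected curve
#' at each gene's GC3. Genes lying on or near the curve are compatible with
#' codon usage bias driven purely by third-position composition; genes far
#' below it indicate additional (e.g. translational-selection) bias.
#'
#' The abscissa is the silent-site GC3 (`gc3s`, Wright's `s`) when the GC
#' table carries it, falling back to plain `gc3` otherwise.
#'
#' @param enc_tbl A tibble from [enc()] (`gene_id`, `enc`).
#' @param gc_tbl A tibble from [gc_content()] (`gene_id`, `gc3s` and/or
#'   `gc3`).
#' @return A tibble with columns `gene_id`, `gc3`, `enc`, `expected`.
#' @export
enc_gc3_data <- function(enc_tbl, gc_tbl) {
  xcol <- if ("gc3s" %in% names(gc_tbl)) "gc3s" else "gc3"
  gc_tbl <- dplyr::rename(gc_tbl[, c("gene_id", xcol)], gc3 = !!xcol)
  out <- dplyr::inner_join(
    dplyr::select(enc_tbl, "gene_id", "enc"),
    gc_tbl,
    by = "gene_id"
  )
  if (nrow(out) == 0L) {
    stop("no genes shared between the ENc and GC tables", call. = FALSE)
  }
  out |>
    dplyr::mutate(expected = expected_enc(.data$gc3)) |>
    dplyr::select("gene_id", "gc3", "enc", "expected")
}

#' ENc-GC3 diagnostic plot
#'
#' Scatterplot of per-gene ENc against GC3 with Wright's expected curve
#' (codon usage bias from GC3 alone) overlaid as a solid red line.
#'
#' @inheritParams enc_gc3_data
#' @param file Optional output path (`.png` or `.svg`); written at 300 dpi.
#' @return A ggplot object; its `data` is the coordinate table from
#'   [enc_gc3_data()].
#' @export
plot_enc_gc3 <- function(enc_tbl, gc_tbl, file = NULL) {
  dat <- enc_gc3_data(enc_tbl, gc_tbl)
  curve <- tibble::tibble(gc3 = seq(0, 1, length.out = 201))
  curve$enc <- expected_enc(curve$gc3)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$gc3, y = .data$enc)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "red", linewidth = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(20, 61)) +
    ggplot2::labs(x = "GC3", y = "ENc",
                  title = "ENc vs GC3",
                  subtitle = "red: expected ENc under GC3-only bias") +
    ggplot2::theme_minimal()
  save_plot(p, file)
  p
}

#' PR2 plot coordinates
#'
#' Drops genes whose AT- or GC-bias is undefined (no fourfold third-position
#' A/T or G/C counts) and reports how many were excluded.
#'
#' @param pr2_tbl A tibble from [pr2_coordinates()].
#' @return A tibble of the defined points (`gene_id`, `gc_bias`, `at_bias`)
#'   with attribute `n_excluded`.
#' @export
pr2_data <- function(pr2_tbl) {
  ok <- !is.na(pr2_tbl$at_bias) & !is.na(pr2_tbl$gc_bias)
  if (!any(ok)) {
    stop("all points undefined: no gene has defined PR2 biases", call. = FALSE)
  }
  out <- dplyr::select(pr2_tbl[ok, ], "gene_id", "gc_bias", "at_bias")
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Parity-rule-2 diagnostic plot
#'
#' Per-gene AT-bias (`A3/(A3+T3)`, ordinate) against GC-bias (`G3/(G3+C3)`,
#' abscissa) over the fourfold-degenerate codon families, with solid red
#' reference lines at 0.5: the centre is where A = T and G = C, i.e. no net
#' strand bias between mutation and selection pressures.
#'
#' @inheritParams pr2_data
#' @param file Optional output path (`.png` or `.svg`); written at 300 dpi.
#' @return A ggplot object whose `data` is the table from [pr2_data()];
#'   excluded genes are counted in the caption.
#' @export
plot_pr2 <- function(pr2_tbl, file = NULL) {
  dat <- pr2_data(pr2_tbl)
  n_exc <- attr(dat, "n_excluded")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$gc_bias,
                                         y = .data$at_bias)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0.5, colour = "red") +
    ggplot2::geom_hline(yintercept = 0.5, colour = "red") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "GC bias  G3/(G3+C3)", y = "AT bias  A3/(A3+T3)",
      title = "PR2 plot (fourfold-degenerate sites)",
      caption = if (n_exc > 0) {
        sprintf("%d gene(s) with undefined bias omitted", n_exc)
      }
    ) +
    ggplot2::theme_minimal()
  save_plot(p, file)
  p
}

save_plot <- function(p, file) {
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 5, dpi = 300)
  }
  invisible(NULL)
}
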