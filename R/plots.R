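# Base-graphics figures for the standard summaries. Each function draws on
# the current device, or writes SVG/PNG when `file` is given (format chosen
# by extension).

open_device <- function(file, width, height) {
  if (is.null(file)) return(FALSE)
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         svg = grDevices::svg(file, width = width, height = height),
         png = grDevices::png(file, width = width * 96, height = height * 96,
                              res = 96),
         stop("unsupported figure format: .", ext, " (use .svg or .png)"))
  TRUE
}

#' Plot a merged-complement SBS spectrum
#'
#' @param spectrum a `spectrum_summary` from [sbs_spectrum()], or a named
#'   list of them (grouped bars).
#' @param file optional `.svg`/`.png` output path.
#' @param main plot title.
#' @export
plot_spectrum <- function(spectrum, file = NULL, main = "SBS spectrum") {
  if (inherits(spectrum, "spectrum_summary"))
    spectrum <- list(all = spectrum)
  mat <- vapply(spectrum, function(s) s$counts / max(1L, sum(s$counts)),
                numeric(length(SBS_CLASSES)))
  dev <- open_device(file, 7, 4.5)
  if (dev) on.exit(grDevices::dev.off())
  labels <- c("G:C→A:T", "A:T→G:C", "G:C→T:A",
              "G:C→C:G", "A:T→T:A", "A:T→C:G")
  graphics::barplot(t(mat), beside = TRUE, names.arg = labels,
                    col = grDevices::hcl.colors(ncol(mat), "Dark 3"),
                    ylab = "proportion of SBS", main = main,
                    legend.text = colnames(mat), las = 2)
  invisible(file)
}

#' Box plot of per-sample values by group with compact letters
#'
#' Boxes use the 1.5 x IQR whisker convention; letters above the boxes come
#' from a [anova_with_cld()] comparison (computed here when not supplied).
#'
#' @param values numeric per-sample values (e.g. mutation frequencies).
#' @param group group labels.
#' @param comparison optional precomputed `group_comparison`.
#' @param file optional `.svg`/`.png` output path.
#' @param ylab,main axis label and title.
#' @export
plot_group_boxes <- function(values, group, comparison = NULL, file = NULL,
                             ylab = "mutation frequency (per bp)",
                             main = "") {
  group <- as.character(group)
  if (is.null(comparison)) comparison <- anova_with_cld(values, group)
  groups <- comparison$groups
  dev <- open_device(file, 6.5, 4.5)
  if (dev) on.exit(grDevices::dev.off())
  b <- graphics::boxplot(split(values, factor(group, levels = groups)),
                         range = 1.5, ylab = ylab, main = main,
                         col = "grey90",
                         ylim = range(values) + c(0, 0.12 * diff(range(values))))
  graphics::text(seq_along(groups),
                 b$stats[5, ] + 0.06 * diff(range(values)),
                 unname(comparison$letters[groups]))
  invisible(file)
}
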