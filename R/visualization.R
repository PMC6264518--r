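# Figures: triangular pair-matrix risk heatmaps and per-reference
# homology profiles. Both renderers are thin ggplot2 layers over
# data-export hooks (heatmap_data, profile_data) that return exactly the
# values drawn, so tests and downstream scripts work on data, not pixels.

#' Heatmap rendering options
#'
#' @param color_anchors Named numeric-to-color mapping at the A-RISC
#'   anchor values 1.0, 0.75, 0.50, 0.25, 0.0. The default runs red
#'   (high risk) through orange, yellow and yellow-green to dark green
#'   (low risk), anchored at the four category boundaries with linear
#'   interpolation between anchors.
#' @param layout `"lower-triangle"` (default) or `"full"`.
#' @param label_rotation Axis-label rotation in degrees.
#' @return A list of class `heatmap_options`.
#' @export
heatmap_options <- function(color_anchors = c(
                              "1" = "#d73027", "0.75" = "#fc8d59",
                              "0.5" = "#fee08b", "0.25" = "#a6d96a",
                              "0" = "#1a9850"),
                            layout = c("lower-triangle", "full"),
                            label_rotation = 90) {
  layout <- match.arg(layout)
  vals <- as.numeric(names(color_anchors))
  if (any(is.na(vals)) || is.unsorted(rev(vals), strictly = TRUE)) {
    stop("color anchor values must be strictly descending", call. = FALSE)
  }
  structure(list(color_anchors = color_anchors, layout = layout,
                 label_rotation = label_rotation),
            class = "heatmap_options")
}

#' Profile rendering options
#'
#' @param panels Subset of `c("identity", "similarity", "arisc")`.
#' @param thresholds Guide-line positions on the A-RISC scale; drawn at
#'   100x on the percent panels. Default 0.75 / 0.50 / 0.25, the category
#'   boundaries.
#' @param sort `"descending"` (by plotted A-RISC, alphabetical tie-break)
#'   or `"input-order"`.
#' @param highlight_groups Optional named character vector mapping
#'   sequence id to a group label (e.g. plant vs animal origin), used to
#'   color points.
#' @return A list of class `profile_options`.
#' @export
profile_options <- function(panels = c("identity", "similarity", "arisc"),
                            thresholds = c(0.75, 0.50, 0.25),
                            sort = c("descending", "input-order"),
                            highlight_groups = NULL) {
  panels <- match.arg(panels, several.ok = TRUE)
  sort <- match.arg(sort)
  structure(list(panels = panels, thresholds = thresholds, sort = sort,
                 highlight_groups = highlight_groups),
            class = "profile_options")
}

#' Interpolate A-RISC values to risk colors
#'
#' Linear interpolation in RGB between the option anchors. Monotone by
#' construction: a larger A-RISC never maps to a greener color under the
#' default anchors.
#'
#' @param arisc Numeric vector in \[0, 1\].
#' @param options A `heatmap_options`.
#' @return Character vector of hex colors.
#' @export
arisc_color <- function(arisc, options = heatmap_options()) {
  anchors <- options$color_anchors
  vals <- as.numeric(names(anchors))   # descending
  ramp <- grDevices::colorRamp(rev(unname(anchors)))
  # rescale through the anchor breakpoints so each band interpolates
  # linearly between its own two anchor colors
  pos <- stats::approx(x = rev(vals), y = seq(0, 1, length.out = length(vals)),
                       xout = pmin(pmax(arisc, min(vals)), max(vals)))$y
  rgb <- ramp(pos)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' Data behind a pair-matrix heatmap
#'
#' @param matrix A `family_matrix`.
#' @param options A `heatmap_options`.
#' @return Data frame with one row per drawn cell: `id1`, `id2` (factors
#'   in matrix order), `arisc`, `category`, `is_diagonal`, `fill`.
#' @export
heatmap_data <- function(matrix, options = heatmap_options()) {
  stopifnot(inherits(matrix, "family_matrix"))
  ids <- matrix$ids
  n <- length(ids)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  if (options$layout == "lower-triangle") idx <- idx[idx$i >= idx$j, ]
  df <- data.frame(
    id1 = factor(ids[idx$i], levels = ids),
    id2 = factor(ids[idx$j], levels = ids),
    arisc = matrix$arisc[cbind(idx$i, idx$j)],
    category = matrix$category[cbind(idx$i, idx$j)],
    is_diagonal = idx$i == idx$j,
    stringsAsFactors = FALSE
  )
  df$fill <- arisc_color(df$arisc, options)
  rownames(df) <- NULL
  df
}

#' Render a triangular pair-matrix risk heatmap
#'
#' One colored cell per sequence pair; red means a high risk of IgE
#' cross-reactivity, dark green a low risk, intermediate colors a medium
#' risk. Diagonal self-comparison cells are drawn in the high-risk color
#' but de-emphasized (reduced alpha): identity with oneself is not a
#' cross-reactivity claim.
#'
#' @param matrix A `family_matrix` with >= 2 sequences.
#' @param path Output image path; format from the extension
#'   (pdf/png/svg).
#' @param options A `heatmap_options`.
#' @param export_data If TRUE, also write the plotted grid as TSV next to
#'   the image (same name, `.tsv`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly. The plotted values are exactly
#'   `heatmap_data(matrix, options)`.
#' @export
render_pair_heatmap <- function(matrix, path,
                                options = heatmap_options(),
                                export_data = FALSE,
                                width = 7, height = 6) {
  df <- heatmap_data(matrix, options)
  df$alpha <- ifelse(df$is_diagonal, 0.35, 1)
  # continuous fill with legend keys at the four category mid-points, so
  # the legend reads as the risk tiers while cells stay interpolated
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$id1, y = .data$id2)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$arisc,
                                    alpha = .data$alpha),
                       color = "white", linewidth = 0.3) +
    ggplot2::scale_alpha_identity() +
    ggplot2::scale_fill_gradientn(
      colors = rev(unname(options$color_anchors)),
      values = rev(as.numeric(names(options$color_anchors))),
      limits = c(0, 1),
      breaks = c(0.875, 0.625, 0.375, 0.125),
      labels = ARISC_CATEGORIES,
      guide = ggplot2::guide_legend(title = "cross-reactivity risk",
                                    reverse = FALSE),
      name = "cross-reactivity risk"
    ) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$id2))) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "A-RISC index for sequence pairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = options$label_rotation, hjust = 1, vjust = 0.5))
  save_plot(p, path, width, height)
  if (export_data) {
    utils::write.table(
      df[, c("id1", "id2", "arisc", "category", "is_diagonal")],
      paste0(tools::file_path_sans_ext(path), ".tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Data behind a reference homology profile
#'
#' @param matrix A `family_matrix`.
#' @param reference_id Id of the reference sequence; must be in the
#'   matrix.
#' @param options A `profile_options`.
#' @return Data frame with one row per other family member: `member`,
#'   `identity`, `similarity`, `arisc`, optional `group`, ordered per
#'   `options$sort`.
#' @export
profile_data <- function(matrix, reference_id,
                         options = profile_options()) {
  stopifnot(inherits(matrix, "family_matrix"))
  if (!(reference_id %in% matrix$ids)) {
    stop("reference id not found in matrix: '", reference_id, "'",
         call. = FALSE)
  }
  others <- setdiff(matrix$ids, reference_id)
  df <- data.frame(
    member = others,
    identity = matrix$identity[reference_id, others],
    similarity = matrix$similarity[reference_id, others],
    arisc = matrix$arisc[reference_id, others],
    stringsAsFactors = FALSE
  )
  if (!is.null(options$highlight_groups)) {
    df$group <- unname(options$highlight_groups[df$member])
  }
  if (options$sort == "descending") {
    df <- df[order(-df$arisc, df$member), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Render a per-reference homology profile
#'
#' One panel per requested quantity (identity and similarity in percent,
#' A-RISC as a fraction), every other family member plotted against the
#' chosen reference, with dashed guide lines at the 75/50/25 percent
#' (0.75/0.50/0.25) thresholds in red, gray and dark green.
#'
#' @param matrix A `family_matrix`.
#' @param reference_id Reference sequence id.
#' @param path Output image path (pdf/png/svg by extension).
#' @param options A `profile_options`.
#' @param export_data If TRUE, write the plotted series as TSV alongside.
#' @param width,height Device size in inches.
#' @return `path`, invisibly. The plotted series are exactly
#'   `profile_data(matrix, reference_id, options)`.
#' @export
render_reference_profile <- function(matrix, reference_id, path,
                                     options = profile_options(),
                                     export_data = FALSE,
                                     width = 8, height = 5) {
  df <- profile_data(matrix, reference_id, options)
  long <- do.call(rbind, lapply(options$panels, function(panel) {
    data.frame(
      member = df$member,
      panel = panel,
      value = if (panel == "arisc") df[[panel]] else 100 * df[[panel]],
      group = if (!is.null(df$group)) df$group else "member",
      stringsAsFactors = FALSE
    )
  }))
  long$member <- factor(long$member, levels = df$member)
  long$panel <- factor(long$panel, levels = options$panels)
  guides_df <- do.call(rbind, lapply(options$panels, function(panel) {
    data.frame(panel = panel,
               y = if (panel == "arisc") options$thresholds
                   else 100 * options$thresholds,
               col = c("#d73027", "gray50", "#1a9850")[
                 seq_along(options$thresholds)])
  }))
  guides_df$panel <- factor(guides_df$panel, levels = options$panels)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$member,
                                          y = .data$value)) +
    ggplot2::geom_hline(data = guides_df,
                        ggplot2::aes(yintercept = .data$y),
                        color = guides_df$col, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 2) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, color = NULL,
                  title = paste("Homology to", reference_id)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, hjust = 1, vjust = 0.5),
      legend.position = if (is.null(options$highlight_groups)) "none"
                        else "bottom")
  save_plot(p, path, width, height)
  if (export_data) {
    utils::write.table(df, paste0(tools::file_path_sans_ext(path), ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

save_plot <- function(p, path, width, height) {
  ext <- tolower(tools::file_ext(path))
  if (!(ext %in% c("pdf", "png", "svg"))) {
    stop("unsupported image format '.", ext, "' (use pdf, png or svg)",
         call. = FALSE)
  }
  dev <- switch(ext,
    pdf = function(f, w, h) grDevices::pdf(f, width = w, height = h),
    png = function(f, w, h) grDevices::png(f, width = w, height = h,
                                           units = "in", res = 150,
                                           type = "cairo"),
    svg = function(f, w, h) grDevices::svg(f, width = w, height = h)
  )
  ok <- tryCatch({ dev(path, width, height); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("cannot open graphics device for ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
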