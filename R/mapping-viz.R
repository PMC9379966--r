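#' Winsorized diverging colour coordinates for map values
#'
#' Reproduces the map-colouring rule used for national aetiology maps: the
#' highest `ceiling(q*n)` values are assigned the brightest red (+1) and
#' the lowest `ceiling(q*n)` the brightest blue (-1); the remaining values
#' are clamped to the winsorization cuts and mapped linearly around the
#' mean of all values, so colour salience encodes distance from the map
#' mean. The coordinate is then discretized into `n_bins` equal ranges on
#' `[-1, 1]`. Assignment depends only on ranks and the two cuts, so it is
#' invariant to row order.
#'
#' @param values finite numeric vector (at least 25 values for the default
#'   `q` so that 4% covers at least one value).
#' @param q winsorized tail fraction (default 0.04).
#' @param n_bins number of equal colour ranges (default 256).
#' @return data frame with `value`, `color` in `[-1, 1]`, `bin` in
#'   `1..n_bins`; the scale parameters (`center`, `low_cut`, `high_cut`,
#'   `n_bins`) are attached as attribute `"scale"`.
#' @export
#' @examples
#' cv <- winsorized_color_values(1:100)
#' sum(cv$color == 1)  # exactly ceiling(0.04 * 100) = 4
winsorized_color_values <- function(values, q = 0.04, n_bins = 256L) {
  v <- as.numeric(values)
  if (any(!is.finite(v))) stopf("values must be finite")
  n <- length(v)
  if (n < 2L) stopf("need at least 2 values")
  if (!is.finite(q) || q <= 0 || q >= 0.5) stopf("q must be in (0, 0.5)")
  if (n_bins < 2L) stopf("n_bins must be >= 2")
  k <- ceiling(q * n)
  if (2L * k > n) stopf("winsorized tails (%d each) exceed n = %d", k, n)
  center <- mean(v)
  if (all(v == v[1L])) {
    out <- data.frame(value = v, color = rep(0, n),
                      bin = rep(as.integer(ceiling(n_bins / 2)), n))
    attr(out, "scale") <- list(center = center, low_cut = v[1L],
                               high_cut = v[1L], n_bins = as.integer(n_bins))
    return(out)
  }
  ord <- order(v)
  lo_idx <- ord[seq_len(k)]              # brightest blue
  hi_idx <- ord[seq.int(n - k + 1L, n)]  # brightest red
  low_cut <- v[ord[k]]                   # largest of the bottom tail
  high_cut <- v[ord[n - k + 1L]]         # smallest of the top tail
  half <- max(high_cut - center, center - low_cut)
  u <- clamp((clamp(v, low_cut, high_cut) - center) / half, -1, 1)
  u[lo_idx] <- -1
  u[hi_idx] <- 1
  bin <- as.integer(clamp(ceiling((u + 1) / 2 * n_bins), 1L, n_bins))
  out <- data.frame(value = v, color = u, bin = bin)
  attr(out, "scale") <- list(center = center, low_cut = low_cut,
                             high_cut = high_cut, n_bins = as.integer(n_bins))
  out
}

# exactly n_bars equal-width bars spanning the data range
.hist_data <- function(values, n_bars) {
  rng <- range(values)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bars + 1L)
  graphics::hist(values, breaks = breaks, plot = FALSE)
}

# blue -> white -> red diverging palette, white at the map mean
.diverging_palette <- function(n_bins) {
  grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(n_bins)
}

.map_components <- c("a2_raw", "c2_or_d2_raw", "e2_raw",
                     "a2_std", "c2_or_d2_std", "e2_std",
                     "total_variance", "weighted_mean")

.component_column <- function(component) {
  if (!component %in% .map_components)
    stopf("unknown component '%s'; valid components: %s", component,
          paste(.map_components, collapse = ", "))
  if (component == "weighted_mean") "weighted_mean_trait" else component
}

#' Render a point map and matching histogram for one mapped component
#'
#' Writes `<component>_map.png` (points coloured by
#' [winsorized_color_values()], optionally over a boundary outline) and
#' `<component>_hist.png` (the distribution of the estimates, bars coloured
#' on the same scale) into `out_dir`. Non-converged rows are excluded
#' before the colour cuts are computed. Output is deterministic for
#' identical inputs.
#'
#' @param space_result a [run_space()] result (or any data frame with the
#'   component column plus `x`, `y`, `converged`).
#' @param component one of `a2_raw`, `c2_or_d2_raw`, `e2_raw`, `a2_std`,
#'   `c2_or_d2_std`, `e2_std`, `total_variance`, `weighted_mean`.
#' @param boundary_geometry optional data frame (or list of them) with
#'   columns `x`, `y` traced as an outline.
#' @param out_dir output directory (created if needed).
#' @param q,n_bins colour-scale parameters.
#' @param hist_bins number of histogram bars (default 30).
#' @param width,height image size in pixels.
#' @return invisibly, the paths of the two files written.
#' @export
render_map <- function(space_result, component, boundary_geometry = NULL,
                       out_dir = ".", q = 0.04, n_bins = 256L,
                       hist_bins = 30L, width = 900L, height = 900L) {
  col_name <- .component_column(component)
  .assert_cols(space_result, c("x", "y", col_name), "space result")
  keep <- if ("converged" %in% names(space_result))
    space_result$converged & is.finite(space_result[[col_name]])
  else is.finite(space_result[[col_name]])
  dat <- space_result[keep, , drop = FALSE]
  if (nrow(dat) < 1L) stopf("no converged rows to map")
  cv <- winsorized_color_values(dat[[col_name]], q = q, n_bins = n_bins)
  pal <- .diverging_palette(n_bins)
  cols <- pal[cv$bin]
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  map_path <- file.path(out_dir, paste0(component, "_map.png"))
  hist_path <- file.path(out_dir, paste0(component, "_hist.png"))

  grDevices::png(map_path, width = width, height = height)
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::plot(dat$x, dat$y, type = "n", asp = 1,
                 xlab = "x", ylab = "y", main = component)
  if (!is.null(boundary_geometry)) {
    polys <- if (is.data.frame(boundary_geometry)) list(boundary_geometry)
             else boundary_geometry
    for (pg in polys)
      graphics::polygon(pg$x, pg$y, border = "grey60", col = NA)
  }
  graphics::points(dat$x, dat$y, pch = 16, cex = 0.9, col = cols)
  grDevices::dev.off()

  h <- .hist_data(cv$value, hist_bins)
  sc <- attr(cv, "scale")
  half <- max(sc$high_cut - sc$center, sc$center - sc$low_cut, 1e-300)
  u_mid <- clamp((clamp(h$mids, sc$low_cut, sc$high_cut) - sc$center) / half, -1, 1)
  mid_bins <- as.integer(clamp(ceiling((u_mid + 1) / 2 * n_bins), 1L, n_bins))
  grDevices::png(hist_path, width = width, height = round(height * 0.6))
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::plot(h, col = pal[mid_bins], border = "white",
                 main = paste(component, "distribution"),
                 xlab = component, ylab = "count")
  grDevices::dev.off()
  invisible(c(map = map_path, hist = hist_path))
}

#' Export the colour table for a mapped component
#'
#' CSV with one row per mapped location: `target_id`, `value`, colour
#' coordinate in `[-1, 1]`, bin index and hex colour — the hand-off format
#' for interactive viewers.
#'
#' @inheritParams render_map
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
export_color_table <- function(space_result, component, path,
                               q = 0.04, n_bins = 256L) {
  col_name <- .component_column(component)
  keep <- if ("converged" %in% names(space_result))
    space_result$converged & is.finite(space_result[[col_name]])
  else is.finite(space_result[[col_name]])
  dat <- space_result[keep, , drop = FALSE]
  cv <- winsorized_color_values(dat[[col_name]], q = q, n_bins = n_bins)
  pal <- .diverging_palette(n_bins)
  out <- data.frame(target_id = dat$target_id, value = cv$value,
                    color = cv$color, bin = cv$bin, hex = pal[cv$bin],
                    stringsAsFactors = FALSE)
  .write_formatted_csv(out, path, num_cols = c("value", "color"))
  invisible(path)
}
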