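# Visual encoding and frame export. Node radius encodes concentration, edge
# thickness encodes |reaction velocity|, both scaled linearly between
# configurable floor/ceiling so empty species stay visible; in single-run
# mode everything is drawn white on black, with a comparison supplied the
# white/red/blue difference colors are used. Frames are rasterized into an
# in-memory RGB array and written with png::writePNG, which makes PNG export
# byte-deterministic; 3D and sphere layouts are projected orthographically
# (z dropped).

#' Visual-encoding configuration
#'
#' @param r_min,r_max Node radius floor/ceiling, pixels.
#' @param w_min,w_max Edge width floor/ceiling, pixels.
#' @param normalization `"per_entity"` or `"global"` scaling of radii/widths.
#' @param log_scale Use `log1p` scaling of encoded values (for wide dynamic
#'   ranges).
#' @param canvas `c(width, height)` in pixels.
#' @param alpha Node disc opacity in `[0, 1]`.
#' @param frames Number of animation frames exported by [cmd_compare()].
#' @return A list of class `"encoding_config"`.
#' @export
encoding_config <- function(r_min = 4, r_max = 40, w_min = 1, w_max = 10,
                            normalization = c("per_entity", "global"),
                            log_scale = FALSE, canvas = c(1200, 900),
                            alpha = 0.5, frames = 20) {
  stopifnot(r_min < r_max, w_min < w_max, r_min >= 0, w_min >= 0,
            alpha >= 0, alpha <= 1, length(canvas) == 2L, all(canvas >= 16))
  structure(list(r_min = r_min, r_max = r_max, w_min = w_min, w_max = w_max,
                 normalization = match.arg(normalization),
                 log_scale = isTRUE(log_scale),
                 canvas = as.integer(canvas), alpha = alpha,
                 frames = as.integer(frames)),
            class = "encoding_config")
}

# linear (or log1p) map of value v with per-entity ceiling Cmax onto [lo, hi]
encode_scale <- function(v, Cmax, lo, hi, log_scale) {
  if (log_scale) { v <- log1p(v); Cmax <- log1p(Cmax) }
  frac <- ifelse(Cmax > 0, v / Cmax, 0)
  lo + (hi - lo) * pmin(pmax(frac, 0), 1)
}

#' Encode one time point as a visual frame
#'
#' Node radius is `r_min + (r_max - r_min) * c(s,t) / C(s)` with `C(s)` the
#' per-entity (or global) maximum concentration over the run (`C(s) = 0`
#' gives `r_min`); edge width is the analogous map of |velocity|. Colors are
#' white in single-run mode; with a comparison supplied they follow the
#' white/red/blue encoding of [compare_trajectories()].
#'
#' @param traj A trajectory.
#' @param t A grid time (minutes); off-grid times snap to the nearest grid
#'   point with a warning.
#' @param cfg An [encoding_config()].
#' @param cmp Optional comparison aligned with `traj`.
#' @return An object of class `"visual_frame"`: `time`, `node_radius`,
#'   `node_color` (n x 3, 0-255), `edge_width`, `edge_color`.
#' @export
encode_frame <- function(traj, t, cfg = encoding_config(), cmp = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(cfg, "encoding_config"))
  j <- which.min(abs(traj$time - t))
  if (abs(traj$time[j] - t) > 1e-9 * max(traj$time[length(traj$time)], 1))
    warning("time ", t, " min is off the grid; using nearest grid point ",
            traj$time[j], " min")
  Cs <- apply(traj$conc, 1, max)
  Vs <- apply(abs(traj$vel), 1, max)
  if (cfg$normalization == "global") {
    Cs[] <- max(Cs, 0); Vs[] <- max(Vs, 0)
  }
  radius <- encode_scale(traj$conc[, j], Cs, cfg$r_min, cfg$r_max,
                         cfg$log_scale)
  width <- encode_scale(abs(traj$vel[, j]), Vs, cfg$w_min, cfg$w_max,
                        cfg$log_scale)
  nsp <- nrow(traj$conc); nrx <- nrow(traj$vel)
  if (is.null(cmp)) {
    node_color <- matrix(255, nsp, 3)
    edge_color <- matrix(255, max(nrx, 0), 3)
  } else {
    stopifnot(inherits(cmp, "regime_comparison"))
    node_color <- diff_color(cmp$node_hue[, j], cmp$node_intensity[, j])
    edge_color <- diff_color(cmp$edge_hue[, j], cmp$edge_intensity[, j])
  }
  rownames(node_color) <- rownames(traj$conc)
  if (nrx) rownames(edge_color) <- rownames(traj$vel)
  structure(list(time = traj$time[j],
                 node_radius = radius, node_color = node_color,
                 edge_width = width, edge_color = edge_color),
            class = "visual_frame")
}

#' @export
print.visual_frame <- function(x, ...) {
  cat(sprintf("<visual_frame> t=%g min: %d nodes (radius %.3g-%.3g px), %d edges\n",
              x$time, length(x$node_radius), min(x$node_radius),
              max(x$node_radius), length(x$edge_width)))
  invisible(x)
}

# ---- software rasterizer -----------------------------------------------------

blend_mask <- function(img, mask_rows, mask_cols, col, alpha) {
  for (ch in 1:3) {
    idx <- cbind(mask_rows, mask_cols, ch)
    img[idx] <- (1 - alpha) * img[idx] + alpha * col[ch]
  }
  img
}

draw_disc <- function(img, cx, cy, r, col, alpha) {
  H <- dim(img)[1]; W <- dim(img)[2]
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(img)
  m <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
  hit <- which(m, arr.ind = TRUE)
  if (!nrow(hit)) return(img)
  blend_mask(img, ys[hit[, 1]] - 0L, xs[hit[, 2]], col, alpha)
}

draw_segment <- function(img, x0, y0, x1, y1, w, col, alpha = 1) {
  H <- dim(img)[1]; W <- dim(img)[2]
  hw <- max(w / 2, 0.5)
  xs <- max(1L, floor(min(x0, x1) - hw)):min(W, ceiling(max(x0, x1) + hw))
  ys <- max(1L, floor(min(y0, y1) - hw)):min(H, ceiling(max(y0, y1) + hw))
  if (!length(xs) || !length(ys)) return(img)
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  tt <- if (len2 < 1e-12) rep(0, length(px)) else
    pmin(pmax(((px - x0) * vx + (py - y0) * vy) / len2, 0), 1)
  d2 <- (px - (x0 + tt * vx))^2 + (py - (y0 + tt * vy))^2
  hit <- d2 <= hw^2
  if (!any(hit)) return(img)
  blend_mask(img, py[hit], px[hit], col, alpha)
}

# map layout coordinates (z dropped for 3D/sphere) to pixel coordinates
layout_to_pixels <- function(layout, canvas, margin = 60) {
  allpos <- rbind(layout$positions, layout$reaction_positions)
  xy <- allpos[, 1:2, drop = FALSE]
  rngx <- range(xy[, 1]); rngy <- range(xy[, 2])
  spanx <- max(rngx[2] - rngx[1], 1e-9)
  spany <- max(rngy[2] - rngy[1], 1e-9)
  sc <- min((canvas[1] - 2 * margin) / spanx, (canvas[2] - 2 * margin) / spany)
  px <- margin + (xy[, 1] - rngx[1]) * sc +
    (canvas[1] - 2 * margin - spanx * sc) / 2
  py <- margin + (rngy[2] - xy[, 2]) * sc +
    (canvas[2] - 2 * margin - spany * sc) / 2
  out <- cbind(x = px, y = py)
  rownames(out) <- rownames(allpos)
  out
}

rasterize_frame <- function(frame, layout, net, cfg) {
  W <- cfg$canvas[1]; H <- cfg$canvas[2]
  img <- array(0, dim = c(H, W, 3))
  pix <- layout_to_pixels(layout, cfg$canvas)
  geo <- edge_geometry(layout, net)
  for (i in seq_len(NROW(geo))) {
    a <- pix[geo$species[i], ]
    b <- pix[paste0("rxn:", geo$reaction[i]), ]
    col <- frame$edge_color[geo$reaction[i], ] / 255
    w <- frame$edge_width[[geo$reaction[i]]]
    img <- draw_segment(img, a[1], a[2], b[1], b[2], w, col)
  }
  for (s in names(frame$node_radius)) {
    p <- pix[s, ]
    img <- draw_disc(img, p[1], p[2], frame$node_radius[[s]],
                     frame$node_color[s, ] / 255, cfg$alpha)
  }
  img
}

#' Export visual frames as an image sequence
#'
#' One raster file per frame, zero-padded numeric names, fixed canvas; 3D
#' and sphere layouts are orthographically projected. PNG output is
#' byte-deterministic for identical inputs.
#'
#' @param frames List of [encode_frame()] results, in time order.
#' @param layout The layout to draw on.
#' @param net The network (for edge geometry).
#' @param out_dir Output directory (created if absent).
#' @param format `"png"` or `"jpeg"`.
#' @param cfg The [encoding_config()] (canvas size, opacity).
#' @return Character vector of written file paths.
#' @export
export_frames <- function(frames, layout, net, out_dir, format = c("png", "jpeg"),
                          cfg = encoding_config()) {
  format <- match.arg(format)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    img <- rasterize_frame(frames[[i]], layout, net, cfg)
    p <- file.path(out_dir, sprintf("frame_%04d.%s", i,
                                    if (format == "png") "png" else "jpg"))
    if (format == "png") {
      png::writePNG(img, p)
    } else {
      grDevices::jpeg(p, width = cfg$canvas[1], height = cfg$canvas[2],
                      quality = 95)
      graphics::par(mar = c(0, 0, 0, 0))
      graphics::plot.new()
      graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
      grDevices::dev.off()
    }
    paths[i] <- p
  }
  paths
}

#' Plot one species' time course for one or two trajectories
#'
#' Line plot saved as PNG: control in black, experiment in red — the inset
#' style used to summarize a readout such as integrated AKT signaling.
#'
#' @param trajs A trajectory or list of 1-2 trajectories (control first).
#' @param species_id Species id.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_timeseries_plot <- function(trajs, species_id, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L, length(trajs) <= 2L)
  for (tr in trajs)
    if (!species_id %in% rownames(tr$conc))
      stop("unknown species '", species_id, "'", call. = FALSE)
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  ylim <- range(vapply(trajs, function(tr) range(tr$conc[species_id, ]),
                       numeric(2)))
  graphics::plot(trajs[[1]]$time, trajs[[1]]$conc[species_id, ], type = "l",
                 col = "black", lwd = 2, xlab = "time (min)",
                 ylab = paste0(species_id, " (nM)"), ylim = ylim,
                 main = species_id)
  if (length(trajs) == 2L)
    graphics::lines(trajs[[2]]$time, trajs[[2]]$conc[species_id, ],
                    col = "red", lwd = 2)
  graphics::legend("topright",
                   legend = vapply(trajs, `[[`, "", "regime_label"),
                   col = c("black", "red")[seq_along(trajs)], lwd = 2,
                   bty = "n")
  invisible(path)
}
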