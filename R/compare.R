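# Control-vs-Experiment differencing with the white/red/blue encoding:
# white where the regimes agree, red where the Experiment value is higher,
# blue where lower, intensity proportional to the difference. The
# proportionality scale is per-entity by default (max |value| across both
# regimes), which keeps low-abundance species visible; a global scale is
# available.

#' Compare two trajectories entity-by-entity over time
#'
#' Computes signed differences `experiment - control` for every species and
#' reaction at every grid point, plus the tri-color encoding: hue `high`
#' (red) where the difference is positive, `low` (blue) where negative,
#' `neutral` (white) where zero; intensity = |diff| / M(e) in `[0, 1]`,
#' where M(e) is the per-entity (or global) maximum |value| across both
#' regimes and all times (M(e) = 0 gives intensity 0).
#'
#' @param control,experiment Trajectories from [simulate_network()] on the
#'   same network and identical time grids.
#' @param normalization `"per_entity"` (default) or `"global"`.
#' @return An object of class `"regime_comparison"` with `node_diff`, `edge_diff`
#'   (signed matrices), `node_hue`, `edge_hue` (character matrices with
#'   values `"neutral"/"high"/"low"`), `node_intensity`, `edge_intensity`
#'   (in `[0,1]`), the shared `time` grid and the normalization constants.
#' @export
compare_trajectories <- function(control, experiment,
                                 normalization = c("per_entity", "global")) {
  stopifnot(inherits(control, "trajectory"), inherits(experiment, "trajectory"))
  normalization <- match.arg(normalization)
  if (length(control$time) != length(experiment$time) ||
      max(abs(control$time - experiment$time)) > 1e-12 * max(control$time, 1))
    stop("time grids differ; resample before comparing", call. = FALSE)
  if (!identical(rownames(control$conc), rownames(experiment$conc)) ||
      !identical(rownames(control$vel), rownames(experiment$vel)))
    stop("species/reaction sets differ between trajectories", call. = FALSE)

  enc <- function(ctl, exp) {
    d <- exp - ctl
    M <- pmax(apply(abs(ctl), 1, max), apply(abs(exp), 1, max))
    if (normalization == "global") M[] <- max(M, 0)
    scale <- ifelse(M > 0, M, Inf)           # M = 0 -> intensity 0
    intensity <- abs(d) / scale
    intensity <- pmin(intensity, 1)
    hue <- matrix("neutral", nrow(d), ncol(d), dimnames = dimnames(d))
    hue[d > 0] <- "high"
    hue[d < 0] <- "low"
    list(diff = d, hue = hue, intensity = intensity, M = M)
  }
  nodes <- enc(control$conc, experiment$conc)
  edges <- enc(control$vel, experiment$vel)
  structure(list(time = control$time,
                 node_diff = nodes$diff, edge_diff = edges$diff,
                 node_hue = nodes$hue, edge_hue = edges$hue,
                 node_intensity = nodes$intensity,
                 edge_intensity = edges$intensity,
                 node_scale = nodes$M, edge_scale = edges$M,
                 normalization = normalization,
                 control_label = control$regime_label,
                 experiment_label = experiment$regime_label),
            class = "regime_comparison")
}

#' @export
print.regime_comparison <- function(x, ...) {
  cat("<comparison> '", x$experiment_label, "' vs control '",
      x$control_label, "': ", nrow(x$node_diff), " species, ",
      nrow(x$edge_diff), " reactions, ", length(x$time),
      " time points (normalization: ", x$normalization, ")\n", sep = "")
  d <- x$node_diff[, length(x$time)]
  if (length(d)) {
    i <- which.max(abs(d))
    cat(sprintf("  largest final node difference: %s (%+.4g nM)\n",
                names(d)[i], d[i]))
  }
  invisible(x)
}

#' Rank entities by difference magnitude at one time point
#'
#' Headless stand-in for visually spotting the most-changed regions of the
#' network: returns the top-k species and reactions by |experiment -
#' control| at the requested time, descending, ties broken by entity id;
#' entities with zero difference are excluded.
#'
#' @param cmp A [compare_trajectories()] result.
#' @param time Time in minutes; snapped to the nearest grid point (with a
#'   warning if off-grid).
#' @param k Maximum number of entities to return.
#' @return A data frame with columns `entity`, `type` (`species`/`reaction`)
#'   and `diff`.
#' @export
diff_summary <- function(cmp, time, k = 10) {
  stopifnot(inherits(cmp, "regime_comparison"))
  j <- which.min(abs(cmp$time - time))
  if (abs(cmp$time[j] - time) > 1e-9 * max(cmp$time[length(cmp$time)], 1))
    warning("time ", time, " min is off the grid; using nearest grid point ",
            cmp$time[j], " min")
  d <- c(cmp$node_diff[, j], cmp$edge_diff[, j])
  type <- c(rep("species", nrow(cmp$node_diff)),
            rep("reaction", nrow(cmp$edge_diff)))
  keep <- d != 0
  d <- d[keep]; type <- type[keep]
  ord <- order(-abs(d), names(d))
  ord <- utils::head(ord, k)
  data.frame(entity = names(d)[ord], type = type[ord], diff = unname(d[ord]),
             stringsAsFactors = FALSE)
}

#' Convert hue/intensity encodings to RGB colors
#'
#' Neutral maps to white; `high` interpolates linearly white -> pure red and
#' `low` white -> pure blue as intensity goes 0 -> 1.
#'
#' @param hue Character vector/matrix with values `neutral`, `high`, `low`.
#' @param intensity Numeric in `[0,1]`, same shape.
#' @return A matrix with columns r, g, b in `[0, 255]` (one row per element,
#'   in column-major order for matrix input).
#' @export
diff_color <- function(hue, intensity) {
  hue <- as.vector(hue); intensity <- pmin(pmax(as.vector(intensity), 0), 1)
  r <- rep(255, length(hue)); g <- r; b <- r
  hi <- hue == "high"; lo <- hue == "low"
  g[hi] <- 255 * (1 - intensity[hi]); b[hi] <- g[hi]
  r[lo] <- 255 * (1 - intensity[lo]); g[lo] <- r[lo]
  cbind(r = r, g = g, b = b)
}

#' Export a comparison as CSV matrices plus a JSON sidecar
#'
#' Writes `<prefix>_node_diff.csv` and `<prefix>_edge_diff.csv` (wide tables
#' as in [write_trajectory()]) and `<prefix>_meta.json` recording the
#' normalization mode and per-entity scales M(e).
#'
#' @param cmp A comparison.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_comparison <- function(cmp, prefix) {
  stopifnot(inherits(cmp, "regime_comparison"))
  wide <- function(m) {
    df <- data.frame(time_min = cmp$time)
    for (i in seq_len(nrow(m))) df[[rownames(m)[i]]] <- m[i, ]
    df
  }
  pn <- paste0(prefix, "_node_diff.csv")
  pe <- paste0(prefix, "_edge_diff.csv")
  pm <- paste0(prefix, "_meta.json")
  utils::write.csv(wide(cmp$node_diff), pn, row.names = FALSE, quote = FALSE)
  utils::write.csv(wide(cmp$edge_diff), pe, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(normalization = cmp$normalization,
         control_label = cmp$control_label,
         experiment_label = cmp$experiment_label,
         node_scale = as.list(cmp$node_scale),
         edge_scale = as.list(cmp$edge_scale)),
    pm, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(pn, pe, pm))
}
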