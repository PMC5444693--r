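# Force-directed (Fruchterman-Reingold) placement of the bipartite
# species-reaction graph: each reaction is a small auxiliary node joined to
# its reactants, products and modifiers, so a multi-substrate reaction has a
# single well-defined drawable location carrying its velocity. Modes: free
# plane (planar2d), free 3D, or constrained to a sphere surface
# (re-projection after every iteration).

#' Compute a force-directed layout for a network
#'
#' Fruchterman-Reingold iteration: spring attraction along graph edges,
#' pairwise repulsion between all nodes, displacement capped by a
#' temperature cooled linearly to zero. Optimal edge length is
#' `k = C * sqrt(area / n)` with unit area and `C = 1`. Initial positions
#' are seeded uniform draws in the unit box (projected onto the sphere in
#' sphere mode), so the result is deterministic for a fixed
#' `(seed, iterations, mode)`. Disconnected networks are laid out per
#' component and the components offset side by side (with a warning); in
#' sphere mode all components share the sphere and only the warning is
#' raised.
#'
#' @param net A [reaction_network()].
#' @param mode `"planar2d"`, `"free3d"` or `"sphere"`.
#' @param seed Integer RNG seed for the initial placement.
#' @param iterations Number of iterations (>= 1); default 500.
#' @param sphere_radius Sphere radius (sphere mode), default 1.
#' @return An object of class `"network_layout"` with `positions` (species
#'   by coordinates matrix), `reaction_positions`, `mode`, `seed`,
#'   `iterations` and `sphere_radius`.
#' @export
compute_layout <- function(net, mode = c("planar2d", "free3d", "sphere"),
                           seed = 1L, iterations = 500L, sphere_radius = 1) {
  validate_network(net)
  mode <- match.arg(mode)
  stopifnot(iterations >= 1, sphere_radius > 0)
  d <- if (mode == "planar2d") 2L else 3L
  sids <- net$species$id
  rids <- reaction_ids(net)
  nodes <- c(sids, if (length(rids)) paste0("rxn:", rids))
  n <- length(nodes)

  # bipartite incidence edges, as node indices
  ei <- integer(); ej <- integer()
  for (jj in seq_along(net$reactions)) {
    rx <- net$reactions[[jj]]
    rnode <- length(sids) + jj
    for (s in unique(c(names(rx$reactants), names(rx$products), rx$modifiers))) {
      ei <- c(ei, match(s, sids)); ej <- c(ej, rnode)
    }
  }

  pos <- with_seed(seed, matrix(stats::runif(n * d, -0.5, 0.5), n, d))
  rownames(pos) <- nodes
  if (mode == "sphere") pos <- project_sphere(pos, sphere_radius)

  if (n == 1L) {
    pos[1, ] <- if (mode == "sphere") c(0, 0, sphere_radius) else rep(0, d)
  } else if (length(ei) == 0L) {
    # no edges at all: keep seeded positions (pure repulsion has no scale)
    comp <- seq_len(n)
    if (n > 1) warning("network graph is disconnected (", n, " components)")
  } else {
    g <- igraph::graph_from_edgelist(cbind(ei, ej), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    ncomp <- max(comp)
    if (ncomp > 1L)
      warning("network graph is disconnected (", ncomp,
              " components); components are laid out separately")
    if (mode == "sphere" || ncomp == 1L) {
      pos <- fr_iterate(pos, ei, ej, iterations, mode, sphere_radius)
    } else {
      shift <- 0
      for (cc in seq_len(ncomp)) {
        idx <- which(comp == cc)
        sub <- pos[idx, , drop = FALSE]
        emask <- comp[ei] == cc
        sei <- match(ei[emask], idx); sej <- match(ej[emask], idx)
        if (length(idx) > 1L)
          sub <- fr_iterate(sub, sei, sej, iterations, mode, sphere_radius)
        sub[, 1] <- sub[, 1] - min(sub[, 1]) + shift
        shift <- max(sub[, 1]) + 0.5
        pos[idx, ] <- sub
      }
    }
  }

  structure(list(positions = pos[seq_along(sids), , drop = FALSE],
                 reaction_positions =
                   pos[setdiff(seq_len(n), seq_along(sids)), , drop = FALSE],
                 mode = mode, seed = as.integer(seed),
                 iterations = as.integer(iterations),
                 sphere_radius = if (mode == "sphere") sphere_radius else NA_real_),
            class = "network_layout")
}

# run a block with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

project_sphere <- function(pos, radius) {
  nrm <- sqrt(rowSums(pos^2))
  nrm[nrm < 1e-12] <- 1e-12
  pos * (radius / nrm)
}

fr_iterate <- function(pos, ei, ej, iterations, mode, sphere_radius) {
  n <- nrow(pos); d <- ncol(pos)
  k <- sqrt(1 / n)
  t0 <- 0.1
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, d)
    # pairwise repulsion: force k^2 / dist along the separation vector
    D2 <- matrix(0, n, n)
    for (dd in seq_len(d)) D2 <- D2 + outer(pos[, dd], pos[, dd], "-")^2
    D2 <- pmax(D2, 1e-8)
    diag(D2) <- Inf
    for (dd in seq_len(d)) {
      DX <- outer(pos[, dd], pos[, dd], "-")
      disp[, dd] <- rowSums(DX * (k^2 / D2))
    }
    # spring attraction along edges: force dist^2 / k
    delta <- pos[ei, , drop = FALSE] - pos[ej, , drop = FALSE]
    dist <- pmax(sqrt(rowSums(delta^2)), 1e-8)
    pull <- delta * (dist / k)
    for (dd in seq_len(d)) {
      disp[, dd] <- disp[, dd] - tapply_add(pull[, dd], ei, n)
      disp[, dd] <- disp[, dd] + tapply_add(pull[, dd], ej, n)
    }
    temp <- t0 * (1 - (it - 1) / iterations)
    dn <- pmax(sqrt(rowSums(disp^2)), 1e-12)
    pos <- pos + disp * (pmin(dn, temp) / dn)
    if (mode == "sphere") pos <- project_sphere(pos, sphere_radius)
  }
  pos
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.network_layout <- function(x, ...) {
  cat("<network_layout> mode ", x$mode, ", ", nrow(x$positions),
      " species + ", nrow(x$reaction_positions), " reaction nodes, seed ",
      x$seed, ", ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Drawable segments for every reaction
#'
#' Each reaction contributes one segment from each participant species
#' (reactant, product or modifier) to its auxiliary reaction node.
#'
#' @param layout A [compute_layout()] result covering all species of `net`.
#' @param net The network.
#' @return A data frame with columns `reaction`, `species`, `role`
#'   (`reactant`/`product`/`modifier`) and endpoint coordinates
#'   `x0, y0, z0` (species end) and `x1, y1, z1` (reaction-node end);
#'   `z` is 0 in planar mode.
#' @export
edge_geometry <- function(layout, net) {
  stopifnot(inherits(layout, "network_layout"))
  missing_sp <- setdiff(net$species$id, rownames(layout$positions))
  if (length(missing_sp))
    stop("layout lacks positions for species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  co <- function(m, id) {
    p <- m[id, ]
    if (length(p) == 2L) c(p, 0) else p
  }
  rows <- list()
  for (jj in seq_along(net$reactions)) {
    rx <- net$reactions[[jj]]
    rpos <- co(layout$reaction_positions, paste0("rxn:", rx$id))
    part <- rbind(
      if (length(rx$reactants))
        data.frame(species = names(rx$reactants), role = "reactant"),
      if (length(rx$products))
        data.frame(species = names(rx$products), role = "product"),
      if (length(rx$modifiers))
        data.frame(species = rx$modifiers, role = "modifier"))
    for (i in seq_len(NROW(part))) {
      spos <- co(layout$positions, part$species[i])
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = rx$id, species = part$species[i], role = part$role[i],
        x0 = spos[1], y0 = spos[2], z0 = spos[3],
        x1 = rpos[1], y1 = rpos[2], z1 = rpos[3],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(reaction = character(), species = character(),
                      role = character(), x0 = numeric(), y0 = numeric(),
                      z0 = numeric(), x1 = numeric(), y1 = numeric(),
                      z1 = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write a layout to JSON
#' @param layout A `network_layout`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "network_layout"))
  tolist <- function(m) {
    out <- lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
    names(out) <- rownames(m)
    out
  }
  jsonlite::write_json(
    list(mode = layout$mode, seed = layout$seed,
         iterations = layout$iterations,
         sphere_radius = layout$sphere_radius,
         positions = tolist(layout$positions),
         reaction_positions = tolist(layout$reaction_positions)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a layout written by [write_layout()]
#' @param path JSON path.
#' @return A `network_layout`.
#' @export
read_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tomat <- function(l) {
    if (!length(l)) return(matrix(numeric(), 0, 0))
    m <- do.call(rbind, l)
    rownames(m) <- names(l)
    m
  }
  structure(list(positions = tomat(j$positions),
                 reaction_positions = tomat(j$reaction_positions),
                 mode = j$mode, seed = as.integer(j$seed),
                 iterations = as.integer(j$iterations),
                 sphere_radius = if (is.null(j$sphere_radius)) NA_real_
                                 else as.numeric(j$sphere_radius)),
            class = "network_layout")
}
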