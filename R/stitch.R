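# First-cycle stitching: adjacency graph over overlapping tiles, pairwise
# phase-correlation alignment of overlap strips, permutation-test E_NCC
# threshold plus translation limit to reject spurious alignments, global
# positions by per-component minimum spanning tree, and an affine model of
# systematic stage error used to reconcile disconnected pieces.

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Build the tile adjacency graph from recorded stage positions
#'
#' Tiles are connected when their recorded footprints (position + tile
#' extent) overlap by at least one pixel in both axes. Non-rectangular and
#' disconnected layouts are supported; an empty edge set is legal.
#'
#' @param ts a [tileset()].
#' @return data frame with columns `i`, `j` (tile indices, `i < j`) and the
#'   overlap extent `oy_um`, `ox_um` in micrometres.
#' @export
build_adjacency <- function(ts) {
  n <- n_tiles(ts)
  ext <- tile_shape(ts) * ts$pixel_size
  pos <- ts$positions
  psz <- ts$pixel_size
  res <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      oy <- min(pos[i, 1], pos[j, 1]) + ext[1] - max(pos[i, 1], pos[j, 1])
      ox <- min(pos[i, 2], pos[j, 2]) + ext[2] - max(pos[i, 2], pos[j, 2])
      if (oy >= psz && ox >= psz)
        res[[length(res) + 1L]] <- c(i, j, oy, ox)
    }
  }
  if (length(res) == 0L)
    return(data.frame(i = integer(0L), j = integer(0L),
                      oy_um = numeric(0L), ox_um = numeric(0L)))
  m <- do.call(rbind, res)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
             oy_um = m[, 3], ox_um = m[, 4])
}

# The most frequent overlap shape (rows, cols in px) among graph edges:
# the geometry used for permutation-test null crops.
modal_overlap_px <- function(ts, graph) {
  if (nrow(graph) == 0L) return(pmin(tile_shape(ts), 32L))
  shp <- cbind(pmax(2L, round(graph$oy_um / ts$pixel_size)),
               pmax(2L, round(graph$ox_um / ts$pixel_size)))
  key <- paste(shp[, 1], shp[, 2])
  mode_key <- names(sort(table(key), decreasing = TRUE))[1L]
  as.integer(strsplit(mode_key, " ")[[1L]])
}

#' Permutation-test threshold on the alignment error
#'
#' Estimates the E_NCC value separating informative alignments from chance
#' by aligning randomly selected pairs of non-adjacent tiles. Each null pair
#' is cropped to a strip of the modal true-overlap shape, whitened and
#' phase-correlated; the threshold is `-log` of the `percentile`-th
#' percentile of the null NCC values, so about `1 - percentile/100` of null
#' alignments score below it (an unadjusted one-sided empirical P-value
#' cutoff).
#'
#' @param ts a [tileset()].
#' @param graph adjacency graph from [build_adjacency()]; computed when
#'   missing.
#' @param n_pairs number of null pairs (default 1000); sampled with
#'   replacement.
#' @param percentile percentile of the null NCC distribution (default 99).
#' @param seed RNG seed for pair sampling (default 1).
#' @param upsample sub-pixel factor passed to [phase_correlate()].
#' @return list with `threshold` (E_NCC cutoff; `+Inf` when fewer than two
#'   non-adjacent tiles exist) and `null_sample` (the null NCC values).
#' @export
permutation_threshold <- function(ts, graph = NULL, n_pairs = 1000L,
                                  percentile = 99, seed = 1L,
                                  upsample = 10L) {
  if (is.null(graph)) graph <- build_adjacency(ts)
  n <- n_tiles(ts)
  adj <- new.env(parent = emptyenv())
  if (nrow(graph) > 0L)
    for (k in seq_len(nrow(graph)))
      assign(paste(graph$i[k], graph$j[k]), TRUE, envir = adj)
  is_adj <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    !is.null(adj[[paste(a, b)]])
  }
  # is any non-adjacent pair available?
  n_adj_max <- nrow(graph)
  if (n < 2L || n * (n - 1L) / 2L <= n_adj_max) {
    warning("fewer than 2 non-adjacent tiles; threshold set to +Inf")
    return(list(threshold = Inf, null_sample = numeric(0L)))
  }
  strip <- modal_overlap_px(ts, graph)
  strip <- pmin(strip, tile_shape(ts))
  strip <- pmax(strip, 8L)
  nccs <- with_seed(seed, {
    out <- numeric(n_pairs)
    for (k in seq_len(n_pairs)) {
      repeat {
        ij <- sample.int(n, 2L)
        if (!is_adj(ij[1], ij[2])) break
      }
      a <- whiten(get_tile(ts, ij[1])[seq_len(strip[1]), seq_len(strip[2]),
                                      drop = FALSE])
      b <- whiten(get_tile(ts, ij[2])[seq_len(strip[1]), seq_len(strip[2]),
                                      drop = FALSE])
      out[k] <- phase_correlate(a, b, upsample)$ncc
    }
    out
  })
  q <- stats::quantile(nccs, percentile / 100, na.rm = TRUE, names = FALSE)
  if (is.na(q)) return(list(threshold = Inf, null_sample = nccs))
  list(threshold = -log(min(max(q, .ncc_floor), 1)), null_sample = nccs)
}

# Crop two tiles to their mutual overlap (recorded frame), padded by
# `pad_um` on every side and clipped to tile bounds. Returns equally shaped
# crops plus the integer pixel anchors (0-based) of each crop within its
# tile, from which the corrected relative offset is reconstructed exactly.
edge_crops <- function(tile_i, pos_i, tile_j, pos_j, pixel_size, pad_um) {
  ext <- dim(tile_i) * pixel_size
  # both crops cover the SAME recorded-frame rectangle: the mutual overlap
  # padded by pad_um but never extending past either footprint
  lo <- pmax(pmax(pos_i, pos_j) - pad_um, pos_i, pos_j)
  hi <- pmin(pmin(pos_i + ext, pos_j + ext) + pad_um, pos_i + ext,
             pos_j + ext)
  a_i <- pmax(0L, round((lo - pos_i) / pixel_size))
  a_j <- pmax(0L, round((lo - pos_j) / pixel_size))
  len <- pmin(pmin(dim(tile_i) - a_i, dim(tile_j) - a_j),
              round((hi - lo) / pixel_size))
  if (any(len < 8L)) return(NULL)
  list(
    crop_i = tile_i[(a_i[1] + 1L):(a_i[1] + len[1]),
                    (a_i[2] + 1L):(a_i[2] + len[2]), drop = FALSE],
    crop_j = tile_j[(a_j[1] + 1L):(a_j[1] + len[1]),
                    (a_j[2] + 1L):(a_j[2] + len[2]), drop = FALSE],
    a_i = a_i, a_j = a_j)
}

crop_at <- function(tile, a, len) {
  tile[(a[1] + 1L):(a[1] + len[1]), (a[2] + 1L):(a[2] + len[2]),
       drop = FALSE]
}

# Align one tile pair given positions in a common frame. Returns the
# corrected offset (pos_j - pos_i, micrometres) implied by the measured
# shift, plus the E_NCC. With crops anchored at integer pixels a_i/a_j and
# measured in-crop shift s, the content offset is (a_i - a_j - s) px.
#
# Two-pass refinement: the first pass measures the offset on crops placed
# from the given positions, whose windows necessarily contain a border of
# non-shared content (the very positioning error being measured) that
# biases the sub-pixel peak. The second pass re-crops both tiles to the
# mutually overlapping region implied by the first-pass offset, so the
# windows cover identical content and only the sub-pixel residual remains.
align_pair <- function(tile_i, pos_i, tile_j, pos_j, pixel_size, pad_um,
                       upsample = 10L) {
  cr <- edge_crops(tile_i, pos_i, tile_j, pos_j, pixel_size, pad_um)
  if (is.null(cr)) return(NULL)
  pc <- phase_correlate(whiten(cr$crop_i), whiten(cr$crop_j), upsample)
  o <- cr$a_i - cr$a_j - pc$shift  # content offset estimate, px
  result <- list(offset_um = o * pixel_size, error = pc$error, ncc = pc$ncc)
  if (is.finite(pc$error)) {
    oi <- round(o)
    len <- pmin(dim(tile_i), dim(tile_j)) - abs(oi)
    if (all(len >= 8L)) {
      b_j <- pmax(0L, -oi)
      b_i <- b_j + oi
      p2 <- phase_correlate(whiten(crop_at(tile_i, b_i, len)),
                            whiten(crop_at(tile_j, b_j, len)), upsample)
      if (is.finite(p2$error)) {
        result <- list(offset_um = (oi - p2$shift) * pixel_size,
                       error = p2$error, ncc = p2$ncc)
      }
    }
  }
  result$shift_px <- result$offset_um / pixel_size -
    (pos_j - pos_i) / pixel_size
  result
}

#' Align all adjacency-graph edges and filter spurious ones
#'
#' For each edge, both tiles are cropped to their recorded mutual overlap
#' padded by `max_shift`, whitened and phase-correlated. An edge is accepted
#' when its E_NCC is at or below the permutation threshold **and** the
#' Euclidean magnitude of the positional correction is at most `max_shift`
#' micrometres; rejected edges are removed from the graph before spanning
#' trees are built. Overlaps too small to align (under 8 px in an axis) are
#' rejected with a warning.
#'
#' @param ts a [tileset()].
#' @param graph adjacency graph from [build_adjacency()].
#' @param threshold E_NCC cutoff from [permutation_threshold()].
#' @param max_shift translation limit in micrometres (default 15).
#' @param upsample sub-pixel factor.
#' @return data frame of edge alignments: `i`, `j`, corrected relative
#'   offset `dy_um`, `dx_um`, correction `shift_y_px`, `shift_x_px`,
#'   `error`, `accepted`.
#' @export
align_edges <- function(ts, graph, threshold, max_shift = 15,
                        upsample = 10L) {
  n <- nrow(graph)
  out <- data.frame(i = graph$i, j = graph$j,
                    dy_um = NA_real_, dx_um = NA_real_,
                    shift_y_px = NA_real_, shift_x_px = NA_real_,
                    error = Inf, accepted = FALSE)
  small <- 0L
  for (k in seq_len(n)) {
    i <- graph$i[k]; j <- graph$j[k]
    al <- align_pair(get_tile(ts, i), ts$positions[i, ],
                     get_tile(ts, j), ts$positions[j, ],
                     ts$pixel_size, pad_um = max_shift, upsample = upsample)
    if (is.null(al)) { small <- small + 1L; next }
    out$dy_um[k] <- al$offset_um[1]
    out$dx_um[k] <- al$offset_um[2]
    out$shift_y_px[k] <- al$shift_px[1]
    out$shift_x_px[k] <- al$shift_px[2]
    out$error[k] <- al$error
    shift_mag_um <- sqrt(sum((al$shift_px * ts$pixel_size)^2))
    out$accepted[k] <- is.finite(al$error) && al$error <= threshold &&
      shift_mag_um <= max_shift
  }
  if (small > 0L)
    warning(small, " edge(s) had overlap regions under 8 px and were rejected")
  out
}

## ---- spanning forest ------------------------------------------------------

# Union-find with path compression.
uf_new <- function(n) seq_len(n)
uf_find <- function(p, x) {
  while (p[x] != x) x <- p[x]
  x
}

# Kruskal minimum spanning forest with a documented, stable tie-break:
# edges are taken in increasing (weight, i, j) order, so ties in E_NCC are
# broken by canonical edge index order.
kruskal_forest <- function(n, edges) {
  if (nrow(edges) == 0L)
    return(integer(0L))
  ord <- order(edges$weight, edges$i, edges$j)
  parent <- uf_new(n)
  keep <- integer(0L)
  for (k in ord) {
    ri <- uf_find(parent, edges$i[k])
    rj <- uf_find(parent, edges$j[k])
    if (ri != rj) {
      parent[ri] <- rj
      keep <- c(keep, k)
    }
  }
  sort(keep)
}

# Connected components over an edge list; returns a component label per node.
components_of <- function(n, ei, ej) {
  parent <- uf_new(n)
  for (k in seq_along(ei)) {
    ri <- uf_find(parent, ei[k]); rj <- uf_find(parent, ej[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), function(x) uf_find(parent, x), integer(1L))
  match(roots, unique(roots))
}

#' Solve global tile positions from accepted edge alignments
#'
#' Within each connected component of the accepted-alignment graph, a
#' minimum spanning tree on the E_NCC weights selects one unambiguous
#' alignment path to every tile; corrected positions are obtained by walking
#' the tree from the root (the tile whose recorded position is nearest the
#' component centroid) and summing the pairwise offsets. An affine stage
#' model is then fitted on the largest component
#' (corrected ~ recorded, [fit_affine()]) and used to place isolated tiles
#' and to reposition secondary components, preserving their internal
#' geometry.
#'
#' @param ts a [tileset()].
#' @param alignments edge table from [align_edges()] (only accepted rows are
#'   used).
#' @param threshold,null_sample carried into the result for reporting.
#' @return an object of class `stitch_result`: `positions` (n x 2,
#'   micrometres), `forest` (per-component root + tree edge indices),
#'   `component` (label per tile), `affine` (`list(A, b, model)`),
#'   `alignments`, `threshold`, `null_sample`.
#' @export
solve_positions <- function(ts, alignments, threshold = NA_real_,
                            null_sample = numeric(0L)) {
  n <- n_tiles(ts)
  acc <- alignments[alignments$accepted, , drop = FALSE]
  comp <- components_of(n, acc$i, acc$j)
  pos <- ts$positions
  corrected <- pos  # isolated tiles keep recorded positions pending affine
  forest <- list()
  tree_rows <- integer(0L)
  in_tree_component <- integer(0L)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) < 2L) next
    sub <- acc[acc$i %in% members, , drop = FALSE]
    edges <- data.frame(i = match(sub$i, members), j = match(sub$j, members),
                        weight = sub$error)
    keep <- kruskal_forest(length(members), edges)
    sub <- sub[keep, , drop = FALSE]
    cen <- colMeans(pos[members, , drop = FALSE])
    root_local <- which.min(colSums((t(pos[members, , drop = FALSE]) - cen)^2))
    root <- members[root_local]
    # walk the tree from the root, adding up pairwise offsets
    nbr <- lapply(members, function(x) integer(0L))
    names(nbr) <- as.character(members)
    for (r in seq_len(nrow(sub))) {
      nbr[[as.character(sub$i[r])]] <- c(nbr[[as.character(sub$i[r])]], r)
      nbr[[as.character(sub$j[r])]] <- c(nbr[[as.character(sub$j[r])]], r)
    }
    corrected[root, ] <- pos[root, ]
    visited <- root
    queue <- root
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      for (r in nbr[[as.character(u)]]) {
        v <- if (sub$i[r] == u) sub$j[r] else sub$i[r]
        if (v %in% visited) next
        off <- c(sub$dy_um[r], sub$dx_um[r])
        if (sub$j[r] == u) off <- -off  # stored as pos_j - pos_i
        corrected[v, ] <- corrected[u, ] + off
        visited <- c(visited, v)
        queue <- c(queue, v)
      }
    }
    forest[[length(forest) + 1L]] <- list(
      root = root, tiles = members,
      edges = sub[, c("i", "j", "error")])
  }
  comp_sizes <- tabulate(comp)
  main <- which.max(comp_sizes)
  fitted <- which(comp == main)
  affine <- fit_affine(pos, corrected, fitted)
  if (length(fitted) < n) {
    pred <- predict_affine(affine, pos)
    for (cid in setdiff(unique(comp), main)) {
      members <- which(comp == cid)
      if (length(members) == 1L) {
        corrected[members, ] <- pred[members, , drop = FALSE]
      } else {
        t_off <- colMeans(pred[members, , drop = FALSE] -
                          corrected[members, , drop = FALSE])
        corrected[members, ] <- sweep(corrected[members, , drop = FALSE],
                                      2L, -t_off)
      }
    }
  }
  structure(list(positions = corrected, forest = forest, component = comp,
                 affine = affine, alignments = alignments,
                 threshold = threshold, null_sample = null_sample),
            class = "stitch_result")
}

#' @export
print.stitch_result <- function(x, ...) {
  cat(sprintf(
    "stitch_result: %d tiles, %d accepted / %d aligned edges, %d component tree(s), E_NCC threshold %.4f\n",
    nrow(x$positions), sum(x$alignments$accepted), nrow(x$alignments),
    length(x$forest), x$threshold))
  invisible(x)
}

#' Fit the affine stage-error model
#'
#' Least-squares regression of corrected tile positions on recorded
#' positions, `corrected ~ A recorded + b`, capturing systematic stage
#' errors such as miscalibrated pixel size or camera rotation. With fewer
#' than three non-collinear fitted tiles the model degrades to
#' translation-only (mean offset, with a warning); with none, to identity.
#' A linear-part determinant outside (0.9, 1.1) triggers a warning.
#'
#' @param recorded,corrected n x 2 position matrices (y, x micrometres).
#' @param fitted_mask indices (or logical mask) of tiles to fit on.
#' @return list with `A` (2x2), `b` (length 2), `model` one of
#'   `"affine"`, `"translation"`, `"identity"`.
#' @export
fit_affine <- function(recorded, corrected, fitted_mask = NULL) {
  if (is.null(fitted_mask)) fitted_mask <- seq_len(nrow(recorded))
  r <- recorded[fitted_mask, , drop = FALSE]
  cpos <- corrected[fitted_mask, , drop = FALSE]
  m <- nrow(r)
  if (m < 1L)
    return(list(A = diag(2L), b = c(0, 0), model = "identity"))
  collinear <- m < 3L || qr(cbind(1, r))$rank < 3L
  if (collinear) {
    warning("fewer than 3 non-collinear tiles; translation-only stage model")
    return(list(A = diag(2L), b = colMeans(cpos - r), model = "translation"))
  }
  X <- cbind(1, r)
  fit <- stats::lm.fit(X, cpos)
  cf <- fit$coefficients
  A <- unname(t(cf[2:3, , drop = FALSE]))  # rows: output; cols: input (y, x)
  b <- as.numeric(cf[1L, ])
  dt <- det(A)
  if (!is.finite(dt) || dt <= 0.9 || dt >= 1.1)
    warning(sprintf("stage model determinant %.4f outside (0.9, 1.1)", dt))
  list(A = A, b = b, model = "affine")
}

#' Apply an affine stage model to positions
#' @param affine model from [fit_affine()].
#' @param positions n x 2 matrix (y, x micrometres).
#' @return n x 2 matrix of transformed positions.
#' @export
predict_affine <- function(affine, positions) {
  t(affine$A %*% t(positions)) + rep(affine$b, each = nrow(positions))
}

#' Stitch the first cycle end to end
#'
#' Convenience wrapper running [build_adjacency()],
#' [permutation_threshold()], [align_edges()] and [solve_positions()].
#'
#' @param ts a [tileset()].
#' @param max_shift translation limit, micrometres (default 15).
#' @param n_pairs,percentile,seed permutation-test parameters.
#' @param upsample sub-pixel factor (default 10).
#' @return a `stitch_result` (see [solve_positions()]).
#' @export
stitch <- function(ts, max_shift = 15, n_pairs = 1000L, percentile = 99,
                   seed = 1L, upsample = 10L) {
  graph <- build_adjacency(ts)
  pt <- permutation_threshold(ts, graph, n_pairs = n_pairs,
                              percentile = percentile, seed = seed,
                              upsample = upsample)
  al <- align_edges(ts, graph, pt$threshold, max_shift = max_shift,
                    upsample = upsample)
  solve_positions(ts, al, threshold = pt$threshold,
                  null_sample = pt$null_sample)
}

#' Stitching report as a plain list (JSON-ready)
#'
#' The data behind threshold/shift diagnostics: permutation threshold and
#' null summary, per-edge shifts, errors and accepted flags, component
#' count, and the affine stage-model coefficients.
#'
#' @param sr a `stitch_result`.
#' @return a list serializable with `jsonlite::write_json()`.
#' @export
stitch_report <- function(sr) {
  list(
    threshold = sr$threshold,
    null_sample_summary = as.list(stats::setNames(
      stats::quantile(sr$null_sample, c(0.5, 0.9, 0.99), na.rm = TRUE,
                      names = FALSE),
      c("p50", "p90", "p99"))),
    n_components = length(unique(sr$component)),
    affine = list(A = sr$affine$A, b = sr$affine$b, model = sr$affine$model),
    edges = sr$alignments)
}
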