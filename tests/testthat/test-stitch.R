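# Adjacency graph, permutation threshold, edge filtering, spanning-forest
# position solving and the affine stage model.

test_that("adjacency edges follow footprint overlap, including corners", {
  ts <- noise_tileset(2, 2, tile = 100, overlap = 0.1)
  g <- build_adjacency(ts)
  # 2 horizontal + 2 vertical + 2 diagonal (10x10 px corner overlaps)
  expect_equal(nrow(g), 6L)
  far <- tileset(list(matrix(0.5, 32, 32), matrix(0.5, 32, 32)),
                 rbind(c(0, 0), c(0, 1000)), pixel_size = 1)
  expect_equal(nrow(build_adjacency(far)), 0L)
  strip <- noise_tileset(1, 3, tile = 100, overlap = 0.1)
  expect_equal(nrow(build_adjacency(strip)), 2L)
})

test_that("the permutation threshold is deterministic under a seed", {
  ts <- noise_tileset(4, 4, tile = 60, seed = 2)
  a <- permutation_threshold(ts, n_pairs = 50, seed = 9)
  b <- permutation_threshold(ts, n_pairs = 50, seed = 9)
  expect_identical(a$threshold, b$threshold)
  expect_identical(a$null_sample, b$null_sample)
  c <- permutation_threshold(ts, n_pairs = 50, seed = 10)
  expect_false(identical(a$null_sample, c$null_sample))
})

test_that("degenerate tilesets give an infinite or near-zero threshold", {
  two <- tileset(list(matrix(runif(64^2), 64, 64), matrix(runif(64^2), 64, 64)),
                 rbind(c(0, 0), c(0, 60)), pixel_size = 1)
  expect_warning(pt <- permutation_threshold(two, n_pairs = 10),
                 "non-adjacent")
  expect_identical(pt$threshold, Inf)
  # identical tiles: null NCC ~ 1, threshold ~ 0
  set.seed(4)
  img <- matrix(runif(60 * 60), 60, 60)
  dup <- tileset(replicate(16, img, simplify = FALSE),
                 grid_positions(4, 4, c(60, 60), 1, 0.1), pixel_size = 1)
  pt2 <- permutation_threshold(dup, n_pairs = 50, seed = 1)
  expect_lt(pt2$threshold, 1e-6)
})

test_that("edge alignment recovers injected jitter and rejects junk", {
  f <- fixture_acq()
  ts <- f$sa$tilesets[[1L]]
  g <- build_adjacency(ts)
  pt <- permutation_threshold(ts, g, n_pairs = 200, seed = 5)
  al <- align_edges(ts, g, pt$threshold, max_shift = 15)
  tp <- truth_positions(f$sa, 1)
  acc <- al[al$accepted, ]
  expect_gt(nrow(acc), 25)
  true_off <- tp[acc$j, ] - tp[acc$i, ]
  err_px <- cbind(acc$dy_um - true_off[, 1], acc$dx_um - true_off[, 2]) /
    ts$pixel_size
  # accepted edges recover the injected jitter: sub-0.2 px in the typical
  # case, within half a pixel for 90% (sparse near-threshold overlaps are
  # intrinsically noisier)
  per_edge <- apply(abs(err_px), 1, max)
  expect_lte(stats::median(per_edge), 0.2)
  expect_lte(stats::quantile(per_edge, 0.9, names = FALSE), 0.5)
  # translation limit: same edges, max_shift 0.5 um rejects jittered pairs
  al0 <- align_edges(ts, g, pt$threshold, max_shift = 0.5)
  expect_lt(sum(al0$accepted), sum(al$accepted))
})

test_that("blank overlaps score as uninformative and are rejected", {
  blank <- tileset(list(matrix(0, 64, 64), matrix(0, 64, 64)),
                   rbind(c(0, 0), c(0, 56)), pixel_size = 1)
  g <- build_adjacency(blank)
  al <- align_edges(blank, g, threshold = 10, max_shift = 15)
  expect_equal(nrow(al), 1L)
  expect_false(al$accepted[1L])
  expect_identical(al$error[1L], Inf)
})

test_that("the spanning forest is the minimum one (4-cycle drops the worst edge)", {
  # 4 tiles in a square, alignments forming a cycle with known weights
  ts <- noise_tileset(2, 2, tile = 50, overlap = 0.2, seed = 3)
  al <- data.frame(i = c(1L, 2L, 3L, 1L), j = c(2L, 4L, 4L, 3L),
                   dy_um = 0, dx_um = 0, shift_y_px = 0, shift_x_px = 0,
                   error = c(0.1, 0.2, 0.3, 0.4), accepted = TRUE)
  al$dy_um <- c(0, 40, 0, 40); al$dx_um <- c(40, 0, 40, 0)
  sr <- solve_positions(ts, al)
  tree <- sr$forest[[1L]]$edges
  expect_equal(nrow(tree), 3L)
  expect_false(any(tree$error == 0.4))  # da edge dropped
  # a tree-shaped accepted set is kept verbatim
  al2 <- al[1:3, ]
  sr2 <- solve_positions(ts, al2)
  expect_equal(sort(sr2$forest[[1L]]$edges$error), c(0.1, 0.2, 0.3))
})

test_that("corrected positions match generator truth on a dense grid", {
  f <- fixture_acq()
  sr <- fixture_stitch()
  tp <- truth_positions(f$sa, 1)
  err <- sr$positions - tp
  err <- sweep(err, 2L, colMeans(err))  # global translation is unobservable
  err_px <- err / f$sa$tilesets[[1L]]$pixel_size
  expect_lt(stats::median(sqrt(rowSums(err_px^2))), 0.3)
  expect_lt(max(abs(err_px)), 1)
})

test_that("non-tree accepted edges do not influence positions", {
  f <- fixture_acq()
  sr <- fixture_stitch()
  al <- sr$alignments
  tree_keys <- unlist(lapply(sr$forest, function(fr)
    paste(fr$edges$i, fr$edges$j)))
  acc_idx <- which(al$accepted)
  non_tree <- acc_idx[!(paste(al$i[acc_idx], al$j[acc_idx]) %in% tree_keys)]
  expect_gt(length(non_tree), 0L)
  al2 <- al[-non_tree[1L], ]
  sr2 <- solve_positions(f$sa$tilesets[[1L]], al2)
  expect_equal(sr2$positions, sr$positions)
})

test_that("tile order permutation leaves corrected positions unchanged", {
  f <- fixture_acq()
  ts <- f$sa$tilesets[[1L]]
  set.seed(6)
  perm <- sample(n_tiles(ts))
  ts_p <- tileset(ts$tiles[perm], ts$positions[perm, ], ts$pixel_size)
  g <- build_adjacency(ts)
  g_p <- build_adjacency(ts_p)
  pt <- permutation_threshold(ts, g, n_pairs = 100, seed = 5)
  al <- align_edges(ts, g, pt$threshold)
  al_p <- align_edges(ts_p, g_p, pt$threshold)
  sr <- solve_positions(ts, al)
  sr_p <- solve_positions(ts_p, al_p)
  expect_equal(sr_p$positions[order(perm), ], sr$positions, tolerance = 1e-9)
})

test_that("affine regression matches closed-form least squares", {
  rec <- cbind(runif(24, 0, 4000), runif(24, 0, 3000))
  expect_equal(fit_affine(rec, rec)$A, diag(2))
  expect_equal(fit_affine(rec, rec)$b, c(0, 0))
  th <- 0.2 * pi / 180
  A <- 1.01 * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  cor_pos <- t(A %*% t(rec)) + rep(c(5, -3), each = 24)
  fit <- fit_affine(rec, cor_pos)
  expect_equal(fit$A, A, tolerance = 1e-10)
  expect_equal(fit$b, c(5, -3), tolerance = 1e-8)
  # one outlier among 24 consistent tiles: scale still within 0.5%
  cor_out <- cor_pos
  cor_out[7, ] <- cor_out[7, ] + c(40, -25)
  fit_o <- fit_affine(rec, cor_out)
  expect_lt(abs(fit_o$A[1, 1] / A[1, 1] - 1), 0.005)
  expect_lt(abs(fit_o$A[2, 2] / A[2, 2] - 1), 0.005)
})

test_that("degenerate affine fits fall back to translation and identity", {
  rec <- rbind(c(0, 0), c(0, 100))  # collinear
  cor_pos <- rec + rep(c(3, 4), each = 2)
  expect_warning(fit <- fit_affine(rec, cor_pos), "translation-only")
  expect_equal(fit$model, "translation")
  expect_equal(fit$b, c(3, 4))
  expect_equal(fit_affine(rec, rec, integer(0))$model, "identity")
})

test_that("the fitted stage model recovers the injected systematic scale", {
  f <- fixture_acq()
  sr <- fixture_stitch()
  # 4x4 grid, 1.5 px jitter: the fit is jitter-limited
  expect_equal(sr$affine$A, f$acq$A, tolerance = 0.02)
})
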