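test_that("candidate edges enumerate default-to-other pairs", {
  p <- tiny_parc()
  tpos <- candidate_edges(p, "dmn_to_taskpos")
  expect_equal(nrow(tpos), 6L)   # 2 default x 3 task-positive
  all_scope <- candidate_edges(p, "dmn_to_all")
  expect_equal(nrow(all_scope), 8L)  # 2 x (3 + 1 other)
  expect_true(all(tpos$roi_i < tpos$roi_j))
  expect_true(all(tpos$net_i == "Default" |
                    tpos$net_j == "Default"))
  # scope nesting
  key <- function(e) paste(e$roi_i, e$roi_j)
  expect_true(all(key(tpos) %in% key(all_scope)))

  no_dmn <- parcellation(c("DorsalAttn", "Visual"))
  expect_error(candidate_edges(no_dmn), "no Default")
})

# reference matrices with a hand-chosen mean on one edge
controlled_refs <- function(parc, z_values, edge = c(1, 3),
                            background_z = -0.1) {
  n <- n_rois(parc)
  lapply(z_values, function(zv) {
    m <- matrix(background_z, n, n)
    m[edge[1], edge[2]] <- m[edge[2], edge[1]] <- zv
    diag(m) <- NA
    m
  })
}

test_that("threshold rule applies the tanh-converted mean", {
  p <- tiny_parc()
  # mean z = -0.4 -> r = tanh(-0.4) ~ -0.3799
  refs <- controlled_refs(p, c(-0.5, -0.3))
  expect_equal(tanh(-0.4), -0.38, tolerance = 1e-3)
  for (cut in c(-0.35, -0.375)) {
    m <- build_mask(refs, p, rule = "threshold", r_cut = cut)
    expect_equal(nrow(m), 1L)
    expect_equal(c(m$roi_i, m$roi_j), c(1, 3))
    expect_equal(m$ref_mean_r, tanh(-0.4))
  }
  # a stricter cut below the converted mean drops the edge entirely
  expect_error(build_mask(refs, p, rule = "threshold", r_cut = -0.39),
               "no edge survives")
})

test_that("density rule keeps the ceiling of the most negative edges", {
  p <- tiny_parc()
  refs <- controlled_refs(p, c(-0.5, -0.3))
  m <- build_mask(refs, p, rule = "density", fraction = 0.05)
  expect_equal(nrow(m), 1L)  # ceiling(0.05 * 6) = 1, the most negative
  expect_equal(c(m$roi_i, m$roi_j), c(1, 3))
  m3 <- build_mask(refs, p, rule = "density", fraction = 0.5)
  expect_equal(nrow(m3), 3L)  # ceiling(3)
})

test_that("all-positive references cannot form a mask", {
  p <- tiny_parc()
  refs <- controlled_refs(p, c(0.3, 0.5), background_z = 0.2)
  expect_error(build_mask(refs, p, rule = "threshold", r_cut = -0.35),
               "no edge survives")
  expect_error(build_mask(refs[1], p), "at least 2")
})

test_that("threshold masks nest monotonically on synthetic references", {
  parc <- toy_parcellation()
  refs <- reference_mats(parc, n_scans = 12L, seed = 77L)
  key <- function(m) paste(m$roi_i, m$roi_j)
  masks <- lapply(c(-0.3, -0.35, -0.375), function(cut) {
    build_mask(refs, parc, rule = "threshold", r_cut = cut)
  })
  expect_true(all(key(masks[[3]]) %in% key(masks[[2]])))
  expect_true(all(key(masks[[2]]) %in% key(masks[[1]])))
  # definitional audit: every retained reference mean below its cut
  for (i in seq_along(masks)) {
    expect_true(all(masks[[i]]$ref_mean_r < c(-0.3, -0.35, -0.375)[i]))
  }
  # task-positive-scope mask nests in the all-scope mask
  m_all <- build_mask(refs, parc, scope = "dmn_to_all",
                      rule = "threshold", r_cut = -0.35)
  expect_true(all(key(masks[[2]]) %in% key(m_all)))
})

test_that("averaging space z vs r is configurable and close", {
  parc <- toy_parcellation()
  refs <- reference_mats(parc, n_scans = 8L, seed = 78L)
  mz <- build_mask(refs, parc, rule = "density", fraction = 0.2,
                   average = "z")
  mr <- build_mask(refs, parc, rule = "density", fraction = 0.2,
                   average = "r")
  expect_equal(nrow(mz), nrow(mr))
  expect_equal(mz$ref_mean_r, mr$ref_mean_r, tolerance = 0.05)
})

test_that("region importance satisfies the handshake lemma", {
  single <- data.frame(roi_i = 2, roi_j = 5)
  ri <- region_importance(single, n_rois = 6)
  expect_equal(ri$n_edges, c(0, 1, 0, 0, 1, 0))

  star <- data.frame(roi_i = c(1, 1, 1), roi_j = c(2, 3, 4))
  ri2 <- region_importance(star)
  expect_equal(ri2$n_edges[1], 3)
  expect_equal(sum(ri2$n_edges), 2 * nrow(star))

  set.seed(5)
  pairs <- t(combn(10, 2))[sample(45, 12), ]
  rnd <- data.frame(roi_i = pairs[, 1], roi_j = pairs[, 2])
  expect_equal(sum(region_importance(rnd, 10)$n_edges), 24)
})

test_that("averaged metric equals the brute-force edge mean", {
  edges <- data.frame(roi_i = c(1, 2), roi_j = c(3, 4))
  m <- matrix(0, 4, 4)
  m[1, 3] <- m[3, 1] <- -0.3
  m[2, 4] <- m[4, 2] <- -0.5
  expect_equal(average_negative_connectivity(m, edges), -0.4)
  expect_equal(average_negative_connectivity(matrix(0, 4, 4), edges), 0)

  set.seed(6)
  for (i in 1:10) {
    z <- matrix(rnorm(36), 6, 6)
    z <- (z + t(z)) / 2
    pairs <- t(combn(6, 2))[sample(15, 5), ]
    mask <- data.frame(roi_i = pairs[, 1], roi_j = pairs[, 2])
    brute <- mean(vapply(seq_len(5), function(k)
      z[mask$roi_i[k], mask$roi_j[k]], numeric(1)))
    expect_equal(average_negative_connectivity(z, mask), brute)
  }
})

test_that("undefined masked edges are reported by name", {
  edges <- data.frame(roi_i = 1, roi_j = 3)
  m <- matrix(NA_real_, 4, 4)
  expect_error(average_negative_connectivity(m, edges), "\\(1,3\\)")
})

test_that("mask TSV round-trips", {
  parc <- toy_parcellation()
  refs <- reference_mats(parc, n_scans = 8L, seed = 79L)
  m <- build_mask(refs, parc, rule = "density", fraction = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mask(m, path)
  back <- read_mask(path)
  expect_equal(back$roi_i, m$roi_i)
  expect_equal(back$ref_mean_r, m$ref_mean_r, tolerance = 1e-12)
})
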