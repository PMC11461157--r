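# synthetic scenario-shaped design table
synthetic_design <- function(n, seed = 7) {
  set.seed(seed)
  data.frame(cost = sample(seq(25, 500, 25), n, TRUE),
             aa_sens = sample(seq(0.1, 0.5, 0.1), n, TRUE),
             interval = sample(1:3, n, TRUE),
             model = sample(c("m1", "m2", "m3"), n, TRUE),
             crc_sens = sample(c(0.74, 0.83, 0.92), n, TRUE))
}

full_design <- function() {
  g <- expand.grid(cost = seq(25, 500, 25), aa_sens = seq(0.1, 0.5, 0.1),
                   interval = 1:3, crc_sens = c(0.74, 0.83, 0.92),
                   KEEP.OUT.ATTRS = FALSE)
  g
}

test_that("a label perfectly separable on cost makes cost rank first in 5/5 seeds", {
  tab <- synthetic_design(600)
  tab$cost_effective <- tab$cost < 100
  for (s in 1:5) {
    r <- rank_importance(tab, ntree = 150, seed = s)
    expect_equal(r$variable[1], "cost")
    # dominant share: more than half of total importance
    expect_gt(r$importance[1], sum(r$importance) / 2)
    expect_equal(r$rank, seq_len(nrow(r)))
    expect_true(all(r$importance >= 0))
    expect_true(all(diff(r$importance) <= 0))
  }
})

test_that("a single-class label raises an explicit degenerate-label error", {
  tab <- synthetic_design(100)
  tab$cost_effective <- TRUE
  expect_error(rank_importance(tab), "single class")
})

test_that("forest predictions recover a separable rule", {
  tab <- synthetic_design(400)
  tab$label <- tab$cost < 200 & tab$aa_sens >= 0.3
  fit <- attr(rank_importance(tab, label = "label", ntree = 100, seed = 2),
              "forest")
  pred <- predict(fit, tab[1:5])
  expect_gt(mean((pred == "TRUE") == tab$label), 0.95)
})

test_that("no variable dominates under a null label (equal-cardinality design)", {
  set.seed(7)
  n <- 1500
  tab <- data.frame(v1 = sample(5, n, TRUE), v2 = sample(5, n, TRUE),
                    v3 = sample(5, n, TRUE), v4 = sample(5, n, TRUE),
                    v5 = sample(5, n, TRUE),
                    label = sample(c(TRUE, FALSE), n, TRUE))
  imp <- rowMeans(vapply(1:5, function(s) {
    r <- rank_importance(tab, label = "label", predictors = paste0("v", 1:5),
                         ntree = 100, seed = s)
    r$importance[match(paste0("v", 1:5), r$variable)]
  }, numeric(5)))
  expect_true(all(imp < 2 * mean(imp)))
})

test_that("LOESS surface reproduces an exactly linear NMB within 1%", {
  g <- full_design()
  g$nmb <- 15000 - 20 * g$cost + 8000 * g$aa_sens
  expect_warning(
    surf <- fit_nmb_surface(g, grid_n = 1000, conditioning = list(crc_sens = 0.92)),
    "integer lattice")
  truth <- 15000 - 20 * surf$grid$cost + 8000 * surf$grid$aa_sens
  expect_lt(max(abs(surf$grid$nmb_smooth - truth) / abs(truth)), 0.01)
})

test_that("constant tables give constant surfaces; empty conditioning errors", {
  g <- full_design()
  g$nmb <- 5000
  surf <- suppressWarnings(
    fit_nmb_surface(g, grid_n = 300, conditioning = list(crc_sens = 0.92)))
  expect_equal(unique(round(surf$grid$nmb_smooth, 6)), 5000)
  expect_error(fit_nmb_surface(g, conditioning = list(crc_sens = 0.99)),
               "leaves no scenarios")
})

test_that("surface averages NMB across model replicates", {
  g <- full_design()
  g1 <- g; g1$model <- "m1"; g1$nmb <- 1000
  g2 <- g; g2$model <- "m2"; g2$nmb <- 3000
  surf <- suppressWarnings(
    fit_nmb_surface(rbind(g1, g2), grid_n = 300,
                    conditioning = list(crc_sens = 0.92)))
  expect_equal(unique(round(surf$grid$nmb_smooth, 6)), 2000)
})

test_that("contours of a planar surface are the expected iso-lines", {
  g <- full_design()
  g$nmb <- g$cost   # plane z = cost
  surf <- suppressWarnings(
    fit_nmb_surface(g, grid_n = 2700, conditioning = list(crc_sens = 0.92)))
  cs <- extract_contours(surf, levels = 250)
  for (panel in cs) {
    expect_gte(length(panel), 1L)
    for (pl in panel) expect_true(all(abs(pl$x - 250) < 1e-6))
  }
  # level above the maximum yields no polylines
  cs2 <- extract_contours(surf, levels = 1e6)
  expect_true(all(vapply(cs2, length, integer(1)) == 0L))
})

test_that("contour points interpolate their level within grid tolerance", {
  g <- full_design()
  set.seed(5)
  g$nmb <- 12000 - 15 * g$cost + 6000 * g$aa_sens +
    3000 * sin(g$cost / 150) * g$aa_sens
  surf <- suppressWarnings(
    fit_nmb_surface(g, grid_n = 2700, conditioning = list(crc_sens = 0.92)))
  cs <- extract_contours(surf, levels = c(7000, 10000))
  n_checked <- 0L
  for (iv in names(cs)) for (pl in cs[[iv]]) {
    vals <- interp_surface(surf, as.numeric(iv), pl$x, pl$y)
    # marching squares interpolates linearly along cell edges
    expect_lt(max(abs(vals - pl$level)), 50)
    n_checked <- n_checked + length(vals)
  }
  expect_gt(n_checked, 0L)
  # regions above a level are nested as the level rises
  above <- vapply(c(7000, 10000, 13000), function(lv)
    sum(surf$grid$nmb_smooth >= lv), integer(1))
  expect_true(all(diff(above) <= 0))
})

test_that("surface preserves monotonicity of a cost-monotone table", {
  g <- full_design()
  g$nmb <- 16000 - 25 * g$cost - 0.01 * g$cost^2 / 10 + 4000 * g$aa_sens
  surf <- suppressWarnings(
    fit_nmb_surface(g, grid_n = 1200, conditioning = list(crc_sens = 0.92)))
  sub <- surf$grid[surf$grid$interval == 1, ]
  for (aa in unique(sub$aa_sens)[c(1, 10, 20)]) {
    line <- sub$nmb_smooth[sub$aa_sens == aa][order(sub$cost[sub$aa_sens == aa])]
    expect_true(all(diff(line) < 1e-6))
  }
})
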