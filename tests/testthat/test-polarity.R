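test_that("point-to-polyline distance: vertices, feet, and dense oracle", {
  seg <- rbind(c(-1, 0), c(1, 0))
  expect_equal(point_to_polyline_distance(c(-1, 0), seg), 0)
  expect_equal(point_to_polyline_distance(c(0, 1), seg), 1)
  # beyond an endpoint the nearest point is the vertex, not the infinite line
  expect_equal(point_to_polyline_distance(c(2, 1), seg), sqrt(2))

  set.seed(51)
  for (rep in 1:5) {
    line <- cbind(cumsum(runif(20, 0.2, 1)), rnorm(20))
    p <- c(runif(1, 0, 10), runif(1, -3, 3))
    expect_equal(point_to_polyline_distance(p, line),
                 polyline_distance_dense(p, line), tolerance = 1e-4)
  }
})

test_that("proximity ratio anchors: 1 on the apical surface, 0 on the basal", {
  cell <- straight_cell(width = 10, height = 8)
  on_apical <- proximity_ratio(c(4, 8), cell)
  expect_equal(on_apical$ratio, 1)
  expect_equal(on_apical$d_apical, 0)
  on_basal <- proximity_ratio(c(4, 0), cell)
  expect_equal(on_basal$ratio, 0)
  midway <- proximity_ratio(c(5, 4), cell)
  expect_equal(midway$ratio, 0.5)
  degenerate <- cell_outline(rbind(c(0, 0), c(1, 0)), rbind(c(0, 0), c(1, 0)),
                             rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_error(proximity_ratio(c(0.5, 0), degenerate), "degenerate")
})

test_that("proximity ratio is invariant under rigid motion and scaling", {
  set.seed(61)
  cell <- straight_cell()
  transform <- function(m, theta, shift, scale) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    sweep(scale * (m %*% t(R)), 2L, shift, "+")
  }
  for (rep in 1:10) {
    p <- c(runif(1, 1, 9), runif(1, 0.5, 7.5))
    r0 <- proximity_ratio(p, cell)$ratio
    theta <- runif(1, 0, 2 * pi); shift <- rnorm(2, 0, 20)
    scale <- runif(1, 0.1, 10)
    cell2 <- cell_outline(transform(cell$apical, theta, shift, scale),
                          transform(cell$basal, theta, shift, scale),
                          transform(cell$region, theta, shift, scale))
    p2 <- as.numeric(transform(matrix(p, 1), theta, shift, scale))
    expect_equal(proximity_ratio(p2, cell2)$ratio, r0, tolerance = 1e-10)
  }
})

test_that("ratio decreases monotonically from apical to basal in a convex cell", {
  cell <- straight_cell(width = 12, height = 9)
  path_y <- seq(9, 0, length.out = 40)
  ratios <- vapply(path_y, function(y)
    proximity_ratio(c(6, y), cell)$ratio, numeric(1L))
  expect_true(all(diff(ratios) < 0))
})

test_that("morphometrics: counts, mean area, and percent occupancy", {
  cells <- list(c1 = straight_cell(10, 10), # 100 um^2
                c2 = straight_cell(20, 10, id = "c2"), # 200
                c3 = straight_cell(10, 10, id = "c3")) # 100
  empty <- morphometrics(cells, numeric(0))
  expect_equal(empty$count, 0)
  expect_equal(empty$occupancy, 0)
  one <- morphometrics(cells["c1"], 50)
  expect_equal(one$occupancy, 50)
  m <- morphometrics(cells, c(10, 20, 30)) # 60 um^2 over 400
  expect_equal(m$count, 3)
  expect_equal(m$mean_area, 20)
  expect_equal(m$occupancy, 15)
  expect_error(morphometrics(cells, c(-1, 2)), "areas")
})

test_that("polarity ECDF is a right-continuous step function reaching 1", {
  f1 <- polarity_ecdf(0.4)
  expect_equal(f1(0.39), 0)
  expect_equal(f1(0.4), 1)
  f <- polarity_ecdf(c(0.2, 0.4, 0.4, 0.8))
  expect_equal(f(0.1), 0)
  expect_equal(f(0.4), 0.75)
  expect_equal(f(0.8), 1)
  expect_equal(f(2), 1)
  expect_error(polarity_ecdf(numeric(0)), "non-empty")
})

test_that("KS statistic equals the exhaustive oracle on all small samples", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(0.1, 0.2), c(0.8, 0.9))$statistic, 1)
  d <- ks_two_sample(c(0.1, 0.5, 0.9), c(0.2, 0.6))
  expect_equal(d$statistic, ks_d_bruteforce(c(0.1, 0.5, 0.9), c(0.2, 0.6)))

  set.seed(71)
  for (na in 1:8) for (nb in 1:8) {
    a <- round(runif(na), 2); b <- round(runif(nb), 2)
    res <- ks_two_sample(a, b)
    expect_equal(res$statistic, ks_d_bruteforce(a, b),
                 label = sprintf("D for n_a=%d, n_b=%d", na, nb))
  }
})

test_that("KS asymptotic p-value agrees with the reference implementation", {
  set.seed(81)
  for (rep in 1:10) {
    a <- rnorm(40); b <- rnorm(50, mean = runif(1, 0, 1))
    ours <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("polarity_table scores every organelle and enforces referential integrity", {
  cell <- straight_cell()
  mitos <- data.frame(cell_id = "c1", x = c(2, 5), y = c(8, 4),
                      area = c(0.3, 0.4))
  pt <- polarity_table(mitos, list(c1 = cell))
  expect_equal(pt$ratio, c(1, 0.5))
  orphan <- data.frame(cell_id = "nope", x = 1, y = 1, area = 1)
  expect_error(polarity_table(orphan, list(c1 = cell)), "unknown cells")
})
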