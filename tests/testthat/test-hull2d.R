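test_that("convex hull of a square with a center point is the square", {
  sq <- make_point_cloud("square_with_center")
  h <- convex_hull(sq)
  expect_setequal(h$boundary, 1:4)
  expect_identical(h$interior, 5L)
  expect_false(h$degenerate)
})

test_that("three non-collinear points are all boundary; degenerate inputs are flagged", {
  tri <- cbind(x = c(0, 1, 0), y = c(0, 0, 1))
  h <- convex_hull(tri)
  expect_setequal(h$boundary, 1:3)
  expect_length(h$interior, 0)

  seg <- cbind(x = c(0, 1, 2), y = c(0, 1, 2))
  hd <- convex_hull(seg)
  expect_true(hd$degenerate)
  expect_setequal(hd$boundary, 1:3)
  expect_error(convex_hull(seg[0, , drop = FALSE]), "at least one point")
})

test_that("QuickHull agrees with independent oracles on random clouds", {
  withr::with_seed(2024, {
    for (rep in 1:150) {
      n <- sample(3:50, 1)
      P <- cbind(x = runif(n, 0, 30), y = runif(n, 0, 30))
      h <- convex_hull(P)
      expect_setequal(h$boundary, grDevices::chull(P))
      # orientation oracle: every point on or left of each CCW edge
      b <- h$boundary
      k <- length(b)
      ok <- TRUE
      for (e in seq_len(k)) {
        a <- P[b[e], ]; bb <- P[b[if (e == k) 1 else e + 1], ]
        cr <- (bb[1] - a[1]) * (P[, 2] - a[2]) - (bb[2] - a[2]) * (P[, 1] - a[1])
        if (any(cr < -1e-7)) { ok <- FALSE; break }
      }
      expect_true(ok)
    }
  })
})

test_that("convex hull is invariant under input point order", {
  P <- make_point_cloud("uniform_random", n = 40, seed = 11)
  h1 <- convex_hull(P)
  perm <- withr::with_seed(3, sample(nrow(P)))
  h2 <- convex_hull(P[perm, , drop = FALSE])
  expect_setequal(perm[h2$boundary], h1$boundary)
})

test_that("concave hull leaves short-edged hulls untouched and digs long edges", {
  sq <- make_point_cloud("square_with_center")
  cvx <- convex_hull(sq)
  cc <- concave_hull(sq, cvx, dist_cutoff = 5)   # all edges length 1
  expect_identical(cc$boundary, cvx$boundary)
  expect_identical(cc$interior, cvx$interior)

  cs <- make_point_cloud("C_shape")
  c15 <- concave_hull(cs, dist_cutoff = 15)
  c5 <- concave_hull(cs, dist_cutoff = 5)
  expect_gte(length(c5$boundary), length(c15$boundary))
  expect_gt(length(c5$boundary), length(convex_hull(cs)$boundary))
})

test_that("concave hull area shrinks with the cutoff and stays below the convex area", {
  for (seed in c(5, 6, 7)) {
    P <- make_point_cloud("uniform_random", n = 45, seed = seed)
    cvx <- convex_hull(P)
    a5 <- hull_area(concave_hull(P, cvx, 5))
    a15 <- hull_area(concave_hull(P, cvx, 15))
    expect_lte(a5, a15 + 1e-9)
    expect_lte(a15, hull_area(cvx) + 1e-9)
  }
})

test_that("concave hull boundary stays simple and terminates with short or final edges", {
  withr::with_seed(99, {
    for (rep in 1:40) {
      n <- sample(10:50, 1)
      P <- cbind(x = runif(n, 0, 30), y = runif(n, 0, 30))
      cutoff <- runif(1, 4, 12)
      cc <- concave_hull(P, convex_hull(P), cutoff)
      b <- cc$boundary
      k <- length(b)
      nxt <- c(b[-1], b[1])
      lens <- sqrt(rowSums((P[b, , drop = FALSE] - P[nxt, , drop = FALSE])^2))
      expect_true(all(lens <= cutoff | cc$edge_final))
      expect_false(polygon_self_intersects(P, b))
      # partition invariant
      expect_setequal(c(cc$boundary, cc$interior), seq_len(n))
    }
  })
})

test_that("concave hull vertex count is non-increasing in the distance cutoff", {
  P <- make_point_cloud("C_shape")
  cvx <- convex_hull(P)
  grid <- c(3, 5, 8, 12, 15, 20)
  nv <- vapply(grid, function(d) length(concave_hull(P, cvx, d)$boundary), 1L)
  expect_true(all(diff(nv) <= 0))
})

test_that("concave shell matches a brute-force distance check and is monotone", {
  withr::with_seed(123, {
    for (rep in 1:30) {
      n <- sample(8:50, 1)
      P <- cbind(x = runif(n, 0, 30), y = runif(n, 0, 30))
      hh <- concave_hull(P, convex_hull(P), 8)
      r1 <- runif(1, 0, 6); r2 <- r1 + runif(1, 0, 6)
      B <- P[hh$boundary, , drop = FALSE]
      brute <- function(r) {
        near <- which(vapply(seq_len(n), function(i)
          min(sqrt((B[, 1] - P[i, 1])^2 + (B[, 2] - P[i, 2])^2)) <= r, TRUE))
        sort(union(near, hh$boundary))
      }
      s1 <- concave_shell(P, hh, r1)
      s2 <- concave_shell(P, hh, r2)
      expect_identical(s1$shell, brute(r1))
      expect_identical(s2$shell, brute(r2))
      expect_true(all(s1$shell %in% s2$shell))
    }
  })
})

test_that("shell radius 0 returns the boundary; a huge radius returns everything", {
  P <- make_point_cloud("uniform_random", n = 25, seed = 4)
  hh <- concave_hull(P, convex_hull(P), 10)
  s0 <- concave_shell(P, hh, 0)
  expect_setequal(s0$shell, hh$boundary)
  sall <- concave_shell(P, hh, 1000)
  expect_setequal(sall$shell, seq_len(nrow(P)))
})

test_that("hull operations are deterministic", {
  P <- make_point_cloud("uniform_random", n = 35, seed = 8)
  a <- concave_hull(P, convex_hull(P), 7)
  b <- concave_hull(P, convex_hull(P), 7)
  expect_identical(a, b)
  expect_identical(concave_shell(P, a, 5), concave_shell(P, b, 5))
})
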