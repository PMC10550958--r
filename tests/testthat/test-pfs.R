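plane_of <- function(mu, y_min = 0, y_max = 255) {
  structure(list(mu = mu, y_min = y_min, y_max = y_max),
            class = "membership_plane")
}

test_that("fuzzification maps the gray range onto [0, 1] with stored anchors", {
  x <- matrix(c(40, 120, 200, 200), 2, 2)
  f <- fuzzify(x)
  expect_equal(f$y_min, 40)
  expect_equal(f$y_max, 200)
  expect_equal(f$mu, (x - 40) / 160)
  expect_equal(f$mu[2, 1], 0.5)  # midpoint of the range
})

test_that("constant images fuzzify to 0.5 and round-trip through defuzzify", {
  x <- matrix(77, 4, 4)
  f <- fuzzify(x)
  expect_true(all(f$mu == 0.5))
  expect_equal(f$y_min, f$y_max)
  expect_equal(defuzzify(f), x)
})

test_that("defuzzify inverts fuzzify and hits its endpoints", {
  set.seed(5)
  x <- random_image(16)
  expect_equal(defuzzify(fuzzify(x)), x, tolerance = 1e-12)
  expect_equal(defuzzify(matrix(0, 2, 2), 40, 200), matrix(40, 2, 2))
  expect_equal(defuzzify(matrix(1, 2, 2), 40, 200), matrix(200, 2, 2))
  expect_equal(defuzzify(matrix(0.25, 2, 2), 40, 200), matrix(80, 2, 2))
  expect_error(defuzzify(matrix(0.5, 2, 2), 10, 5), "y_min")
})

test_that("negation endpoints and hand-computed values", {
  for (a in c(0.1, 0.42, 0.5, 0.74, 1)) {
    expect_identical(pfs_negation(0, a), 1)
    expect_identical(pfs_negation(1, a), 0)
  }
  expect_equal(pfs_negation(0.5, 1), 0.5)
  expect_equal(pfs_negation(0.5, 0.5), 0.2)  # 0.25*0.5 / (0.25*0.5 + 0.5)
  expect_error(pfs_negation(1.2, 0.5), "\\[0, 1\\]")
  expect_error(pfs_negation(0.5, 0), "positive")
})

test_that("negation is strictly decreasing and bounded by the standard negation", {
  set.seed(9)
  for (i in 1:25) {
    a <- runif(1, 0.01, 1)
    x <- sort(runif(50))
    n <- pfs_negation(x, a)
    expect_true(all(diff(n) < 0))
    expect_true(all(n <= 1 - x + 1e-12))
  }
})

test_that("PFI planes satisfy the Pythagorean constraints", {
  set.seed(21)
  for (i in 1:20) {
    a <- runif(1, 0.01, 1)
    pl <- plane_of(matrix(runif(64), 8, 8))
    p <- build_pfi(pl, a)
    expect_true(all(p$mu_pfs >= 0 & p$mu_pfs <= 1))
    expect_true(all(p$nu_pfs >= 0 & p$nu_pfs <= 1))
    expect_true(all(p$mu_pfs^2 + p$nu_pfs^2 <= 1 + 1e-12))
    expect_equal(max(abs(p$mu_pfs^2 + p$nu_pfs^2 + p$pi_pfs^2 - 1)), 0,
                 tolerance = 1e-9)
  }
})

test_that("PFI endpoints and the alpha = 1 standard-negation limit", {
  pl <- plane_of(matrix(c(0, 1, 0.5, 0.5), 2, 2))
  p <- build_pfi(pl, 1)
  expect_equal(p$mu_pfs[1, 1], 0)
  expect_equal(p$nu_pfs[1, 1], 1)
  expect_equal(p$pi_pfs[1, 1], 0)
  expect_equal(p$mu_pfs[2, 1], 1)
  expect_equal(p$nu_pfs[2, 1], 0)
  expect_equal(p$pi_pfs[2, 1], 0)
  expect_equal(p$mu_pfs[1, 2], 0.5)
  expect_equal(p$nu_pfs[1, 2], 0.5)
  expect_equal(p$pi_pfs[1, 2], sqrt(0.5))

  set.seed(2)
  mu <- matrix(runif(25), 5, 5)
  p1 <- build_pfi(plane_of(mu), 1)
  expect_equal(p1$mu_pfs, mu, tolerance = 1e-12)
  expect_equal(p1$nu_pfs, 1 - mu, tolerance = 1e-12)

  expect_error(build_pfi(plane_of(mu), 0), "\\(0, 1\\]")
})

test_that("entropy is 1 when membership equals non-membership and 0 at total membership", {
  sz <- c(4, 4)
  mu_eq <- matrix(0.3, 4, 4)
  pfi_eq <- structure(list(mu_pfs = mu_eq, nu_pfs = mu_eq,
                           pi_pfs = sqrt(1 - 2 * mu_eq^2),
                           alpha = 0.5, y_min = 0, y_max = 255), class = "pfi")
  expect_equal(pfe(pfi_eq), 1)

  pfi_one <- structure(list(mu_pfs = matrix(1, 4, 4), nu_pfs = matrix(0, 4, 4),
                            pi_pfs = matrix(0, 4, 4),
                            alpha = 0.5, y_min = 0, y_max = 255), class = "pfi")
  expect_equal(pfe(pfi_one), 0)

  set.seed(31)
  for (i in 1:20) {
    p <- build_pfi(plane_of(matrix(runif(64), 8, 8)), runif(1, 0.01, 1))
    e <- pfe(p)
    expect_gte(e, 0)
    expect_lte(e, 1)
  }
})

test_that("alpha optimization matches the brute-force maximizer", {
  set.seed(17)
  grid <- seq(0.05, 1, by = 0.05)
  for (i in 1:20) {
    pl <- plane_of(matrix(runif(256), 16, 16))
    got <- optimize_alpha(pl, grid)
    expect_equal(got$alpha_opt, oracle_alpha_opt(pl$mu, grid))
    expect_equal(nrow(got$curve), length(grid))
    expect_equal(got$curve$pfe,
                 vapply(grid, function(a) oracle_pfe(pl$mu, a), numeric(1)))
  }
})

test_that("alpha ties break to the smallest grid value", {
  # mu == 0 gives mu_pfs = 0, nu_pfs = 1 for every alpha: a flat entropy curve
  pl <- plane_of(matrix(0, 4, 4))
  got <- optimize_alpha(pl, seq(0.1, 1, by = 0.1))
  expect_equal(got$alpha_opt, 0.1)
  expect_equal(optimize_alpha(pl, 0.7)$alpha_opt, 0.7)
  expect_error(optimize_alpha(pl, numeric(0)), "nonempty")
  expect_error(optimize_alpha(pl, c(0.5, 0.2)), "increasing")
})

test_that("constant planes reduce alpha selection to a scalar problem", {
  pl <- plane_of(matrix(0.5, 8, 8))
  grid <- seq(0.01, 1, by = 0.01)
  got <- optimize_alpha(pl, grid)
  scalar_pfe <- vapply(grid, function(a) oracle_pfe(matrix(0.5, 1, 1), a), numeric(1))
  expect_equal(got$alpha_opt, grid[which.max(scalar_pfe)])
})

test_that("hedge + INT enhancement has the right fixed points and values", {
  mk <- function(v) structure(list(mu_pfs = matrix(v, 2, 2),
                                   nu_pfs = matrix(0, 2, 2),
                                   pi_pfs = matrix(0, 2, 2),
                                   alpha = 1, y_min = 0, y_max = 255),
                              class = "pfi")
  for (lam in c(1, 2, 3.5)) {
    expect_equal(enhance(mk(0), lam)$mu, matrix(0, 2, 2))
    expect_equal(enhance(mk(1), lam)$mu, matrix(1, 2, 2))
  }
  expect_equal(enhance(mk(0.5), 1)$mu[1, 1], 0.5)
  expect_equal(enhance(mk(0.8), 2)$mu[1, 1], 0.7408)  # 0.64 > 0.5 branch
  expect_error(enhance(mk(0.5), 0.5), ">= 1")
})

test_that("enhancement is monotone in the membership plane", {
  set.seed(13)
  for (lam in c(1, 2, 4)) {
    v <- sort(runif(100))
    pfi <- structure(list(mu_pfs = matrix(v, 10, 10), nu_pfs = matrix(0, 10, 10),
                          pi_pfs = matrix(0, 10, 10), alpha = 1,
                          y_min = 0, y_max = 255), class = "pfi")
    out <- enhance(pfi, lam)$mu
    expect_true(all(diff(as.vector(out)) >= 0))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("enhancement carries defuzzification anchors forward", {
  x <- matrix(c(40, 200, 120, 80), 2, 2)
  p <- build_pfi(fuzzify(x), 0.5)
  e <- enhance(p, 2)
  expect_equal(e$y_min, 40)
  expect_equal(e$y_max, 200)
})
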