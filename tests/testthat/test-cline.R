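test_that("cline frequency matches the stated sigmoid and tail forms", {
  p0 <- list(centre = 0, width = 10)
  expect_equal(cline_frequency(0, p0), 0.5)
  expect_equal(cline_frequency(5, p0), 1 / (1 + exp(-2)))   # 0.88080
  expect_equal(cline_frequency(5, p0), 0.8808, tolerance = 1e-4)
  # symmetry of the no-tail model around the centre
  d <- seq(-40, 40, by = 0.7)
  expect_equal(cline_frequency(3 + d, list(centre = 3, width = 17)) +
                 cline_frequency(3 - d, list(centre = 3, width = 17)),
               rep(1, length(d)))
  # tails decay exponentially and join continuously
  pl <- list(centre = 0, width = 10, deltaL = 5, tauL = 0.4)
  xl <- -5
  expect_equal(cline_frequency(xl - 1e-9, pl, "left"),
               cline_frequency(xl + 1e-9, pl, "left"), tolerance = 1e-6)
  expect_equal(cline_frequency(-15, pl, "left"),
               cline_frequency(-5, pl, "left") * exp(4 * 0.4 * (-10) / 10))
  # mirror ties both tails
  pm <- list(centre = 0, width = 10, delta = 5, tau = 0.4)
  expect_equal(cline_frequency(-12, pm, "mirror") +
                 cline_frequency(12, pm, "mirror"), 1, tolerance = 1e-12)
  # monotone non-decreasing on a dense grid for all variants
  grid <- seq(-60, 60, length.out = 2000)
  pars <- list(none = p0, left = pl,
               right = list(centre = 0, width = 10, deltaR = 3, tauR = 0.2),
               mirror = pm,
               both = list(centre = 0, width = 10, deltaL = 5, tauL = 0.4,
                           deltaR = 3, tauR = 0.2))
  for (v in names(pars)) {
    expect_true(all(diff(cline_frequency(grid, pars[[v]], v)) >= -1e-12),
                info = v)
  }
  # parameter validation
  expect_error(cline_frequency(0, list(centre = 0, width = -1)), "width")
  expect_error(cline_frequency(0, list(centre = 0, width = 1, deltaL = 1,
                                       tauL = 1.4), "left"), "tau")
  expect_error(cline_frequency(0, list(centre = 0, width = 1, deltaL = -2,
                                       tauL = 0.5), "left"), "delta")
})

test_that("the internal fast path agrees with the public cline frequency", {
  x <- seq(-50, 50, length.out = 101)
  cases <- list(
    none = c(centre = 2, width = 12),
    left = c(centre = 2, width = 12, deltaL = 4, tauL = 0.3),
    right = c(centre = 2, width = 12, deltaR = 6, tauR = 0.7),
    mirror = c(centre = 2, width = 12, delta = 4, tau = 0.3),
    both = c(centre = 2, width = 12, deltaL = 4, tauL = 0.3, deltaR = 6, tauR = 0.7)
  )
  for (v in names(cases)) {
    expect_equal(hzfootprint:::cline_p_fast(x, unname(cases[[v]]), v),
                 cline_frequency(x, as.list(cases[[v]]), v), info = v)
  }
})

test_that("binomial negative log-likelihood follows the stated formula", {
  d1 <- tibble::tibble(distance = 0, h = 0.5, n = 10)
  expect_equal(cline_negloglik(d1, list(centre = 0, width = 5)), 10 * log(2))
  # doubling n doubles the value
  d2 <- d1; d2$n <- 20
  expect_equal(cline_negloglik(d2, list(centre = 0, width = 5)), 20 * log(2))
  # fitted p = h minimizes the per-locality term
  d3 <- tibble::tibble(distance = c(-3, 4), h = c(0.3, 0.8), n = c(7, 9))
  base <- cline_negloglik(d3, list(centre = 0.5, width = 10))
  probe <- function(eps) {
    p <- cline_frequency(d3$distance, list(centre = 0.5, width = 10)) + eps
    -sum(d3$n * (d3$h * log(p) + (1 - d3$h) * log(1 - p)))
  }
  h_exact <- -sum(d3$n * (d3$h * log(d3$h) + (1 - d3$h) * log(1 - d3$h)))
  expect_lte(h_exact, base)  # entropy bound: p = h is the unconstrained optimum
  expect_error(cline_negloglik(tibble::tibble(distance = 1, h = 2, n = 1),
                               list(centre = 0, width = 1)), "h must")
})

test_that("no-tail MLE matches the closed-form logit solution for one free point", {
  # with fixed width, a single locality is fitted exactly: the centre solves
  # h = logistic(4(x - c)/w) => c = x - w/4 * logit(h)
  d <- tibble::tibble(distance = c(10, -200, 220), h = c(0.73, 1e-12, 1 - 1e-12),
                      n = c(50, 1, 1))
  fit <- fit_cline(d, "none", restarts = 30, seed = 2)
  # the two extreme pseudo-points pin the asymptotes; the middle point drives c
  pred <- cline_frequency(10, as.list(fit$par))
  expect_equal(pred, 0.73, tolerance = 1e-3)
})

test_that("parameter recovery and equivariance on exact no-tail data", {
  set.seed(3)
  x <- seq(-150, 150, by = 5)   # 61 localities
  truth <- list(centre = 0, width = 30)
  h <- vapply(cline_frequency(x, truth), function(p) rbinom(1, 1000, p) / 1000, 0)
  d <- tibble::tibble(distance = x, h = h, n = 1000)
  fit <- fit_cline(d, "none", restarts = 10, seed = 4)
  expect_equal(unname(fit$par["centre"]), 0, tolerance = 1)     # +-1 km
  expect_equal(unname(fit$par["width"]), 30, tolerance = 2)     # +-2 km
  # translation equivariance
  d10 <- d; d10$distance <- d$distance + 10
  fit10 <- fit_cline(d10, "none", restarts = 10, seed = 4)
  expect_equal(unname(fit10$par["centre"]), unname(fit$par["centre"]) + 10,
               tolerance = 0.2)
  expect_equal(unname(fit10$par["width"]), unname(fit$par["width"]),
               tolerance = 0.5)
  expect_error(fit_cline(d[1:2, ], "none"), "more localities")
})

test_that("AICc selection penalizes complexity and detects true tails", {
  # hand-checked AICc: logLik -100, K = 2, n = 30 -> 204 + 12/27
  f <- structure(list(variant = "none", par = c(centre = 0, width = 1),
                      logLik = -100, K = 2L, n_loc = 30L,
                      AICc = 2 * 2 + 200 + 2 * 2 * 3 / 27), class = "cline_fit")
  expect_equal(f$AICc, 204 + 12 / 27)
  set.seed(6)
  x <- seq(-150, 150, by = 5)
  # strongly right-tailed truth, large n
  truth <- list(centre = 0, width = 20, deltaR = 10, tauR = 0.12)
  p <- cline_frequency(x, truth, "right")
  h <- rbinom(length(x), 800, p) / 800
  d <- tibble::tibble(distance = x, h = h, n = 800)
  sel <- select_model_aicc(d, restarts = 12, seed = 7)
  expect_equal(sel$best$variant, "right")
  expect_setequal(sel$table$variant, c("none", "left", "right", "mirror", "both"))
  # exact-sigmoid data: no-tail wins on the penalty
  p0 <- cline_frequency(x, list(centre = 0, width = 30))
  h0 <- rbinom(length(x), 500, p0) / 500
  sel0 <- select_model_aicc(tibble::tibble(distance = x, h = h0, n = 500),
                            restarts = 12, seed = 8)
  expect_equal(sel0$best$variant, "none")
  # when all variants tie in logLik the smallest K wins by construction
  expect_true(all(diff(sel0$table$AICc) >= 0))
  expect_error(select_model_aicc(d[1:5, ]), "at least 6")
})

test_that("profile support limits bracket the MLE and shrink with information", {
  set.seed(9)
  x <- seq(-100, 100, by = 10)
  p <- cline_frequency(x, list(centre = 0, width = 30))
  make <- function(n) {
    h <- rbinom(length(x), n, p) / n
    fit_cline(tibble::tibble(distance = x, h = h, n = n), "none",
              restarts = 8, seed = 10)
  }
  fit <- make(100)
  sl <- support_limits(fit, "centre")
  expect_lt(sl$lower, fit$par[["centre"]])
  expect_gt(sl$upper, fit$par[["centre"]])
  # bisection agrees with a brute-force grid profile of the same likelihood
  grid <- seq(sl$lower - 3, sl$upper + 3, length.out = 61)
  prof <- vapply(grid, function(cc) {
    o <- optim(fit$par["width"],
               function(w) cline_negloglik(fit$data,
                                           list(centre = cc, width = w), "none"),
               method = "L-BFGS-B", lower = 1e-3, upper = 1000)
    -o$value
  }, 0)
  ok <- grid[prof >= fit$logLik - 2]
  expect_equal(sl$lower, min(ok), tolerance = 0.5)
  expect_equal(sl$upper, max(ok), tolerance = 0.5)
  # quadrupling n roughly halves the interval width
  fit4 <- make(400)
  sl4 <- support_limits(fit4, "centre")
  ratio <- (sl4$upper - sl4$lower) / (sl$upper - sl$lower)
  expect_equal(ratio, 0.5, tolerance = 0.2)
})
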