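test_that("leverage reproduces hat-matrix arithmetic", {
  X <- cbind(1, c(1, 2, 3))
  expect_equal(leverage(c(1, 2), X), 1 / 3)
  # mean training point of a design with intercept has leverage 1/n
  set.seed(8)
  Xc <- cbind(1, matrix(rnorm(60), nrow = 20))
  xbar <- colMeans(Xc)
  expect_equal(leverage(xbar, Xc), 1 / 20, tolerance = 1e-10)
  # training leverages sum to the number of parameters (trace of H)
  lev <- vapply(seq_len(nrow(Xc)), function(i) leverage(Xc[i, ], Xc),
                numeric(1))
  expect_equal(sum(lev), ncol(Xc), tolerance = 1e-10)
  expect_true(all(lev > 0 & lev <= 1))
  expect_error(leverage(c(1, 2, 3), X), "dimension mismatch")
})

test_that("leverage falls back to a pseudo-inverse on singular designs", {
  X <- cbind(1, c(1, 2, 3), c(2, 4, 6))  # collinear
  expect_true(is.finite(leverage(c(1, 2, 4), X)))
})

test_that("chemical similarity score behaves as a nearest-neighbour mean", {
  X <- rbind(c(1, 0, 2), c(0, 1, 0), c(2, 0, 2))
  expect_equal(css(c(1, 0, 2), X, k = 1), 1)
  expect_equal(css(c(0, 5, 0), rbind(c(1, 0, 2), c(2, 0, 1)), k = 2), 0)
  # k = 2: mean of the two largest hand-computed Tanimoto similarities
  q <- c(1, 1, 1)
  tani <- function(y) sum(q * y) / (sum(q^2) + sum(y^2) - sum(q * y))
  sims <- sort(apply(X, 1, tani), decreasing = TRUE)
  expect_equal(css(q, X, k = 2), mean(sims[1:2]))
  expect_error(css(c(1, 2), X[0, , drop = FALSE]), "empty")
  expect_error(css(c(1, 2), X), "dimension mismatch")
})

test_that("cosine similarity is selectable and agrees on exact matches", {
  X <- rbind(c(1, 0, 2), c(0, 3, 0))
  expect_equal(css(c(2, 0, 4), X, k = 1, method = "cosine"), 1)
  expect_lt(css(c(2, 0, 4), X, k = 1, method = "tanimoto"), 1)
})

test_that("uncertainty levels follow the published semantics", {
  set.seed(21)
  train <- matrix(rpois(200, 1), nrow = 40)
  ctx <- ad_context(train, known_substructures = c("C", "O", "N"))
  in_row <- train[1, ]
  lev_in <- 0.5 * ctx$leverage_warn
  css_in <- 0.95

  expect_equal(assign_ul(lev_in, css_in, ctx, in_row, "C"), 0L)
  # intercept-only prediction
  expect_equal(assign_ul(lev_in, css_in, ctx, rep(0, 5), "C"), 4L)
  # unseen substructure dominates everything else
  expect_equal(assign_ul(lev_in, css_in, ctx, in_row, c("C", "Si")), 5L)
  expect_equal(assign_ul(10, 0, ctx, rep(0, 5), c("C", "Si")), 5L)
  # leverage ladder
  expect_equal(assign_ul(ctx$leverage_egregious * 1.1, 0.9, ctx,
                         in_row, "C"), 3L)
  expect_equal(assign_ul(ctx$leverage_out * 1.1, 0.9, ctx, in_row,
                         "C"), 2L)
  expect_equal(assign_ul(ctx$leverage_warn * 1.1, 0.9, ctx, in_row,
                         "C"), 1L)
  # similarity warnings alone
  expect_equal(assign_ul(0, 0.3, ctx, in_row, "C"), 1L)
  expect_equal(assign_ul(0, 0.2, ctx, in_row, "C"), 2L)
})

test_that("worsening leverage never lowers the uncertainty level", {
  set.seed(22)
  ctx <- ad_context(matrix(rpois(100, 1), nrow = 20),
                    known_substructures = "C")
  levs <- seq(0, 12 * ncol(ctx$training_design) /
                nrow(ctx$training_design), length.out = 40)
  uls <- vapply(levs, function(h)
    assign_ul(h, 0.9, ctx, c(1, 0, 0, 0, 0), "C"), integer(1))
  expect_true(all(diff(uls) >= 0))
})

test_that("meta aggregation follows propagation of uncertainty", {
  expect_equal(round2(aggregate_meta(c(0L, 0L), c(0.17, 0.16))$rmsep),
               0.23)
  expect_equal(round2(aggregate_meta(c(0L, 0L), c(0.60, 0.15))$rmsep),
               0.62)
  one <- aggregate_meta(2L, 0.4)
  expect_equal(one$ul, 2L)
  expect_equal(one$rmsep, 0.4)
  # permutation invariant and at least the largest component
  a <- aggregate_meta(c(1L, 3L, 0L), c(0.1, 0.5, 0.2))
  b <- aggregate_meta(c(3L, 0L, 1L), c(0.5, 0.2, 0.1))
  expect_equal(a, b)
  expect_gte(a$rmsep, 0.5)
  expect_equal(a$ul, 3L)
  # UL 4 remapping for endpoints whose intercept is in-domain
  expect_equal(aggregate_meta(c(4L, 1L), c(0.1, 0.1))$ul, 4L)
  expect_equal(aggregate_meta(c(4L, 1L), c(0.1, 0.1), ul4_as = 0L)$ul,
               1L)
  expect_error(aggregate_meta(integer(), numeric()), "non-empty")
})

test_that("prediction intervals apply the adjustment ladder exactly", {
  off <- pi_adjustments(1, 1, 1, 1)
  pi0 <- prediction_interval(0, 1, "KOW_wet", ul = 0L,
                             state = "liquid", factors = off)
  expect_equal(c(pi0$pi_low, pi0$pi_high), c(-1.96, 1.96))

  def <- prediction_interval(0, 1, "KOW_wet", ul = 0L, state = "liquid")
  expect_equal(def$pi_high, 1.96 * 1.25)

  vp_solid <- prediction_interval(0, 1, "VP_liquid", ul = 0L,
                                  state = "solid")
  expect_equal(vp_solid$rmsep_adj, 1.25 * 1.67)
  sw_solid <- prediction_interval(0, 1, "SW_liquid", ul = 0L,
                                  state = "maybe_solid")
  expect_equal(sw_solid$rmsep_adj, 1.25 * 1.25)
  vp_ul <- prediction_interval(0, 1, "VP_liquid", ul = 3L,
                               state = "liquid")
  expect_equal(vp_ul$rmsep_adj, 1.25 * 1.25)
  vp_both <- prediction_interval(0, 1, "VP_liquid", ul = 5L,
                                 state = "solid")
  expect_equal(vp_both$rmsep_adj, 1.25 * 1.67 * 1.25)

  degen <- prediction_interval(2.5, 0, "KAW")
  expect_equal(degen$pi_low, 2.5)
  expect_equal(degen$pi_high, 2.5)
  expect_error(prediction_interval(0, -0.1), "rmsep")
  expect_error(pi_adjustments(global = 0.9), ">= 1")
})

test_that("interval width scales linearly and adjustments only widen", {
  w <- function(r, ...) {
    p <- prediction_interval(0, r, ...)
    p$pi_high - p$pi_low
  }
  expect_equal(w(2, "KAW"), 2 * w(1, "KAW"))
  expect_gte(w(1, "VP_liquid", ul = 2L, state = "solid"),
             w(1, "VP_liquid", ul = 0L, state = "liquid"))
  expect_gte(w(1, "KAW"), 2 * 1.96)
})
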