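eps0 <- plb_weight_config(area_epsilon = 0)

test_that("mean_area is the arithmetic mean and rejects empty input", {
  expect_equal(mean_area(c(100, 300)), 200)
  expect_equal(mean_area(50), 50)
  expect_equal(mean_area(c(100, 200, 600)), 300)
  expect_error(mean_area(numeric(0)), "no boxes contribute")
  expect_error(mean_area(c(100, -1)), "positive")
})

test_that("PLB weights reproduce the printed worked examples", {
  expect_equal(plb_weights(c(100, 100), eps0)$weight, c(1, 1))
  expect_equal(plb_weights(123.4, eps0)$weight, 1)
  expect_equal(plb_weights(c(100, 300), eps0)$weight, c(4 / 3, 4 / 5))
  # epsilon guard: two zero-area boxes become equal unit areas
  expect_equal(plb_weights(c(0, 0), plb_weight_config(area_epsilon = 1))$weight,
               c(1, 1))
  expect_error(plb_weights(numeric(0), eps0), "no boxes")
  expect_error(plb_weights(c(10, -5), eps0), "non-negative")
  expect_error(plb_weight_config(area_epsilon = -1), "non-negative")
})

test_that("a box of exactly mean area always gets weight 1", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(2:20, 1)
    areas <- 10^runif(n, -1, 5)
    # appending the current mean leaves the batch mean unchanged, so the
    # appended box has exactly mean area
    areas <- c(areas, mean(areas))
    w <- plb_weights(areas, eps0)$weight
    expect_equal(w[n + 1], 1, tolerance = 1e-12)
  }
})

test_that("weights shrink to 2/(n+1) for a dominating box and rise to 2 for a vanishing one", {
  # vanishing box: weight tends to 2
  others <- c(50, 80, 120)
  w_seq <- vapply(10^(-(1:12)), function(a) {
    plb_weights(c(a, others), eps0)$weight[1]
  }, numeric(1))
  expect_true(all(diff(w_seq) > 0))
  expect_equal(w_seq[12], 2, tolerance = 1e-6)
  # dominating box among n boxes, the rest near zero: weight tends to 2/(n+1)
  for (n in 2:10) {
    areas <- c(rep(1e-12, n - 1), 1000)
    w <- plb_weights(areas, eps0)$weight
    expect_equal(w[n], 2 / (n + 1), tolerance = 1e-6)
  }
})

test_that("weights stay inside (2/(n+1), 2) over randomized batches", {
  set.seed(7)
  for (rep in 1:2000) {
    n <- sample(1:50, 1)
    areas <- 10^runif(n, -2, 6)
    w <- plb_weights(areas, eps0)$weight
    expect_true(all(w < 2))
    if (n == 1) {
      expect_equal(w, 1)
    } else {
      expect_true(all(w > 2 / (n + 1)))
    }
  }
})

test_that("weights are invariant to a common rescaling of all areas", {
  set.seed(8)
  for (rep in 1:100) {
    n <- sample(2:30, 1)
    areas <- 10^runif(n, -1, 5)
    c0 <- 10^runif(1, -3, 3)
    expect_equal(plb_weights(areas * c0, eps0)$weight,
                 plb_weights(areas, eps0)$weight, tolerance = 1e-12)
  }
})

test_that("a box's weight strictly decreases as its own area grows", {
  set.seed(9)
  for (rep in 1:100) {
    n <- sample(2:20, 1)
    areas <- 10^runif(n, 0, 4)
    i <- sample(n, 1)
    delta <- areas[i] * 0.05
    bumped <- areas
    bumped[i] <- bumped[i] + delta
    # finite-difference oracle: recompute the full weight (including the
    # feedback of area_i into the batch mean) at the perturbed area
    w0 <- plb_weights(areas, eps0)$weight[i]
    w1 <- plb_weights(bumped, eps0)$weight[i]
    expect_lt(w1, w0)
  }
})
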