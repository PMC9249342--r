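test_that("weighted cross-entropy matches closed forms and is linear in weights", {
  s1 <- cls_samples(matrix(0, 1, 3), 1L, FALSE)
  expect_equal(weighted_cross_entropy(s1, 1), log(3))
  expect_equal(weighted_cross_entropy(s1, 2), 2 * log(3))
  # identity weights equal the unweighted mean
  set.seed(5)
  s <- random_cls_set(8)
  expect_equal(weighted_cross_entropy(s, rep(1, 8)),
               mean(cross_entropy(s$logits, s$label)))
  expect_error(weighted_cross_entropy(s, rep(1, 3)), "mismatch")
})

test_that("weighted smooth-L1 matches closed forms", {
  mk <- function(pred) reg_samples(matrix(pred, 1), matrix(0, 1, 4),
                                   matrix(c(0, 0, 5, 5), 1))
  expect_equal(weighted_smooth_l1(mk(rep(0.5, 4)), 1), 0.5)
  expect_equal(weighted_smooth_l1(mk(c(2, 0, 0, 0)), 1), 1.5)
  expect_equal(weighted_smooth_l1(mk(c(2, 0.5, 0, 0)), 0), 0)
  expect_error(weighted_smooth_l1(mk(rep(1, 4)), c(1, 1)), "mismatch")
})

test_that("switches-off total equals an independent unweighted reference", {
  set.seed(17)
  for (rep in 1:100) {
    rpn_cls <- random_cls_set(sample(0:12, 1), k = 2)
    rpn_reg <- random_reg_set(sample(0:6, 1))
    roi_cls <- random_cls_set(sample(0:12, 1), k = 4)
    roi_reg <- random_reg_set(sample(0:6, 1))
    lam <- runif(1, 0.5, 2)
    got <- total_loss(rpn_cls, rpn_reg, roi_cls, roi_reg,
                      plb_loss_config(lambda_balance = lam))
    ref <- oracle_baseline_loss(rpn_cls, rpn_reg, roi_cls, roi_reg, lam)
    for (comp in c("cls_rpn", "reg_rpn", "cls_roi", "reg_roi", "total")) {
      expect_equal(got[[comp]], ref[[comp]], tolerance = 1e-6)
    }
  }
})

test_that("the breakdown total is the lambda-weighted component sum", {
  set.seed(19)
  b <- total_loss(random_cls_set(6, 2), random_reg_set(3),
                  random_cls_set(6, 4), random_reg_set(3),
                  plb_loss_config(plb1c = TRUE, plb2b = TRUE, lambda_balance = 1.5))
  expect_equal(b$total,
               b$cls_rpn + 1.5 * b$reg_rpn + b$cls_roi + 1.5 * b$reg_roi)
})

test_that("enabling one switch changes only its own component", {
  set.seed(23)
  rpn_cls <- random_cls_set(10, 2)
  rpn_reg <- random_reg_set(5)
  roi_cls <- random_cls_set(10, 4)
  roi_reg <- random_reg_set(5)
  base <- total_loss(rpn_cls, rpn_reg, roi_cls, roi_reg, plb_loss_config())
  switches <- list(
    plb1c = "cls_rpn", plb1b = "reg_rpn", plb2c = "cls_roi", plb2b = "reg_roi"
  )
  for (sw in names(switches)) {
    args <- stats::setNames(list(TRUE), sw)
    cfg <- do.call(plb_loss_config, args)
    got <- total_loss(rpn_cls, rpn_reg, roi_cls, roi_reg, cfg)
    for (comp in c("cls_rpn", "reg_rpn", "cls_roi", "reg_roi")) {
      if (comp == switches[[sw]]) {
        expect_false(isTRUE(all.equal(got[[comp]], base[[comp]])))
      } else {
        expect_identical(got[[comp]], base[[comp]])
      }
    }
  }
})

test_that("equal-area boxes make every PLB weight 1, reproducing the baseline", {
  set.seed(29)
  n <- 8
  b <- cbind(rep(0, n), 0, 10, 10) + runif(n, 0, 50) # translated equal boxes
  b[, 3] <- b[, 1] + 10
  b[, 4] <- b[, 2] + 10
  roi_cls <- cls_samples(matrix(rnorm(n * 4), n, 4),
                         sample.int(4, n, TRUE), rep(TRUE, n), b)
  roi_reg <- random_reg_set(0)
  on <- total_loss(random_cls_set(0, 2), random_reg_set(0), roi_cls, roi_reg,
                   plb_loss_config(plb2c = TRUE,
                                   weight_config = plb_weight_config(area_epsilon = 0)))
  off <- total_loss(random_cls_set(0, 2), random_reg_set(0), roi_cls, roi_reg,
                    plb_loss_config())
  expect_equal(on$cls_roi, off$cls_roi, tolerance = 1e-12)
})

test_that("the smaller of two otherwise-identical boxes contributes more", {
  logits <- rbind(c(1, 0, 2), c(1, 0, 2))
  boxes <- rbind(c(0, 0, 5, 5), c(0, 0, 30, 30))
  s <- cls_samples(logits, c(3L, 3L), c(TRUE, TRUE), boxes)
  cfg <- plb_loss_config(plb2c = TRUE,
                         weight_config = plb_weight_config(area_epsilon = 0))
  b <- total_loss(random_cls_set(0, 2), random_reg_set(0), s, random_reg_set(0), cfg)
  w <- attr(b, "weights")$cls_roi
  ce <- cross_entropy(logits, c(3L, 3L))
  expect_gt(w[1] * ce[1], w[2] * ce[2])
  expect_gt(w[1], 1)
  expect_lt(w[2], 1)
})

test_that("an enabled switch with no contributing boxes zeroes that component with a warning", {
  s <- cls_samples(matrix(rnorm(6), 3, 2), c(1L, 1L, 1L), rep(FALSE, 3))
  expect_warning(
    b <- total_loss(s, random_reg_set(0), random_cls_set(0, 4), random_reg_set(0),
                    plb_loss_config(plb1c = TRUE)),
    "no boxes contribute"
  )
  expect_equal(b$cls_rpn, 0)
})
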