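fake_scores <- function(g, i) {
  structure(list(
    genuine = data.frame(subject = paste0("s", seq_along(g)), visit_a = "v1",
                         visit_b = "v2", d = -g, s = g),
    imposter = data.frame(subject_a = "a", subject_b = "b", d = -i, s = i),
    normalizer = fit_normalizer(c(0, 1))), class = "score_set")
}

test_that("pair enumeration covers same-subject visits and first-visit imposters", {
  man <- data.frame(subject_id = rep(c("A", "B", "C"), each = 2),
                    visit_id = rep(c("v1", "v2"), 3))
  pr <- cohort_pairs(man)
  expect_identical(nrow(pr$genuine), 3L)
  expect_identical(nrow(pr$imposter), 3L)
  expect_true(all(pr$genuine$visit_a != pr$genuine$visit_b))
  expect_true(all(pr$imposter$subject_a != pr$imposter$subject_b))
  # all-visits mode: 2 visits x 2 visits x 3 subject pairs
  expect_identical(nrow(cohort_pairs(man, "all")$imposter), 12L)
  expect_error(cohort_pairs(data.frame(subject_id = c("A", "A"),
                                       visit_id = c("v1", "v2"))),
               "imposter")
  expect_error(cohort_pairs(data.frame(subject_id = c("A", "B"),
                                       visit_id = c("v1", "v1"))),
               "genuine")
})

test_that("rate table implements accept-on-tie FAR/FRR/TAR", {
  sc <- fake_scores(c(80, 90), c(40, 60))
  rt <- rate_table(sc, c(0, 70, 95, 101))
  expect_equal(rt$frr, c(0, 0, 1, 1))
  expect_equal(rt$far, c(1, 0, 0, 0))
  expect_equal(rt$tar, 1 - rt$far)
  # tie: imposter at the threshold is accepted
  rt2 <- rate_table(fake_scores(c(80), c(60)), 60)
  expect_equal(rt2$far, 1)
  # monotonicity over a sweep
  sc3 <- fake_scores(rnorm(50, 80, 5), rnorm(50, 55, 8))
  rt3 <- rate_table(sc3, seq(0, 100, by = 1))
  expect_true(all(diff(rt3$far) <= 0))
  expect_true(all(diff(rt3$frr) >= 0))
})

test_that("EER endpoints: separation gives 0, identical lists give 0.5", {
  expect_equal(equal_error_rate(c(80, 85, 95), c(20, 40, 55)), 0)
  x <- c(10, 30, 50, 70, 90)
  expect_equal(equal_error_rate(x, x), 0.5)
})

test_that("EER matches the analytic two-Gaussian crossing", {
  set.seed(33)
  g <- rnorm(500, 85, 3)
  i <- rnorm(500, 58, 5)
  # closed-form crossing of the two error curves
  cross <- uniroot(function(t) pnorm(t, 85, 3) - (1 - pnorm(t, 58, 5)),
                   c(58, 85))$root
  eer_true <- pnorm(cross, 85, 3)
  expect_equal(equal_error_rate(g, i), eer_true, tolerance = 0.01)
})

test_that("EER is invariant under strictly increasing score transforms", {
  set.seed(34)
  g <- rnorm(200, 75, 6)
  i <- rnorm(200, 60, 6)
  e0 <- equal_error_rate(g, i)
  expect_equal(equal_error_rate(2 * g + 5, 2 * i + 5), e0, tolerance = 1e-12)
  expect_equal(equal_error_rate(exp(g / 20), exp(i / 20)), e0,
               tolerance = 1e-12)
})

test_that("intensity baseline is maximal for identical volumes and degrades with gain", {
  cfg <- tiny_config(seed = 23)
  tr <- generate_subject(cfg, 51)
  vis <- generate_visit(tr, 52, motion = rep(0, 6), gain = 1)
  v <- vis$volume
  expect_equal(intensity_baseline_score(v, v, diag(4)), 0)

  # global rescaling hurts the intensity score but not the chamfer score
  v15 <- brain_volume(v$data * 1.5, v$spacing, v$affine)
  expect_lt(intensity_baseline_score(v15, v, diag(4)), -100)
  b <- gm_mask((v$data > 40 & v$data < 70) + 0L, 0.5, v$spacing, v$affine)
  b15 <- gm_mask((v15$data > 60 & v15$data < 105) + 0L, 0.5, v$spacing,
                 v$affine)
  expect_lt(chamfer_distance(b15, b) / sum(b15$mask), 0.5)
})

test_that("report writes deterministic CSVs and a summary", {
  dir <- withr::local_tempdir()
  set.seed(35)
  sc <- fake_scores(rnorm(20, 85, 4), rnorm(30, 55, 7))
  rt <- rate_table(sc, seq(0, 100, 5))
  eer <- equal_error_rate(sc)
  out1 <- file.path(dir, "r1"); out2 <- file.path(dir, "r2")
  f1 <- report(sc, rt, eer, out1)
  f2 <- report(sc, rt, eer, out2)
  expect_true(all(file.exists(f1)))
  expect_identical(readLines(file.path(out1, "scores.csv")),
                   readLines(file.path(out2, "scores.csv")))
  expect_identical(readLines(file.path(out1, "rates.csv")),
                   readLines(file.path(out2, "rates.csv")))
  expect_identical(nrow(utils::read.csv(file.path(out1, "rates.csv"))),
                   nrow(rt))
  js <- jsonlite::read_json(file.path(out1, "summary.json"))
  expect_equal(js$eer, eer, tolerance = 1e-12)

  empty <- sc; empty$imposter <- empty$imposter[0, ]
  expect_error(report(empty, rt, eer, file.path(dir, "r3")), "empty")
})
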