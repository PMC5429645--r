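sig <- function(f, d = seq_along(f) - 1) {
  tibble::tibble(depth_mm = d, force_N = f)
}

test_that("signal comparison reproduces the hand-computed examples", {
  a <- sig(c(0.7, 0.7))
  b <- sig(c(0, 0.7))
  cmp <- compare_signals(a, b)
  expect_equal(cmp$rmse, 0.7 / sqrt(2))
  expect_equal(cmp$mae, 0.7)
  expect_equal(cmp$pct_identical, 50)

  ident <- compare_signals(a, a)
  expect_equal(unlist(ident[, 1:3]),
               c(rmse = 0, mae = 0, pct_identical = 100))

  shifted <- compare_signals(sig(rep(1, 5)), sig(rep(1.3, 5)))
  expect_equal(shifted$rmse, 0.3)
  expect_equal(shifted$mae, 0.3)
  expect_equal(shifted$pct_identical, 0)

  expect_error(compare_signals(a, sig(c(0, 0.7), d = c(0, 2))),
               "different depth grids")
  expect_error(compare_signals(a, sig(c(0, 0.7, 0.7))), "sample counts")
})

test_that("comparison metrics are symmetric and rmse never exceeds the maximum error", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(5:50, 1)
      a <- sig(runif(n, 0, 3))
      b <- sig(runif(n, 0, 3))
      ab <- compare_signals(a, b)
      ba <- compare_signals(b, a)
      expect_equal(ab, ba)
      expect_lte(ab$rmse, ab$mae + 1e-12)
    }
  })
})

test_that("border crossings list entry depths per structure, including re-entries", {
  tc <- tissue_codes()
  stack <- stack_volume(data.frame(
    code = c(tc[["air"]], tc[["skin"]], tc[["soft"]], tc[["fascia"]],
             tc[["soft"]], tc[["fascia"]], tc[["liver"]]),
    thickness_mm = c(5, 2.7, 10, 2.7, 9, 2.7, 40)
  ))
  cr <- border_crossings(stack_path(stack), stack$values |>
                           volume3d(stack$spacing, stack$origin))
  fascia_cr <- cr$depth_mm[cr$code == tc[["fascia"]]]
  expect_equal(length(fascia_cr), 2L)  # two fascial layers, two crossings
  expect_equal(fascia_cr[1], 17.7, tolerance = 0.5)
  expect_equal(fascia_cr[2], 29.4, tolerance = 0.6)
  expect_equal(sum(cr$code == tc[["vessel"]]), 0L)  # absent structure
})

test_that("surface-distance metrics match constructed offsets and pool correctly", {
  ref <- tibble::tibble(code = c(1L, 2L, 3L), depth_mm = c(0, 5, 10))
  test <- tibble::tibble(code = c(1L, 2L, 3L), depth_mm = c(0, 7, 10))
  out <- msd_hsd(ref, test)
  expect_equal(out$per_structure$msd_mm[out$per_structure$code == 2L], 2)
  expect_equal(out$per_structure$hsd_mm[out$per_structure$code == 2L], 2)
  expect_equal(out$pooled$msd_mm, 2 / 3)
  expect_equal(out$pooled$hsd_mm, 2)
  expect_lte(out$pooled$msd_mm, out$pooled$hsd_mm)

  # identical crossings: zero everywhere
  same <- msd_hsd(ref, ref)
  expect_equal(same$pooled$msd_mm, 0)
  expect_equal(same$pooled$hsd_mm, 0)

  # unmatched crossings are counted, not silently paired
  test2 <- tibble::tibble(code = c(1L, 2L, 2L, 3L),
                          depth_mm = c(0, 5, 8, 10))
  out2 <- msd_hsd(ref, test2)
  expect_equal(out2$pooled$n_unmatched, 1L)
  expect_equal(out2$pooled$msd_mm, 0)

  # msd <= hsd on random crossing sets
  withr::with_seed(13, {
    for (rep in 1:20) {
      n <- sample(2:6, 1)
      r <- tibble::tibble(code = sample(1:3, n, TRUE), depth_mm = runif(n, 0, 90))
      t <- tibble::tibble(code = sample(1:3, n, TRUE), depth_mm = runif(n, 0, 90))
      o <- msd_hsd(r, t)
      if (!is.na(o$pooled$msd_mm)) {
        expect_lte(o$pooled$msd_mm, o$pooled$hsd_mm + 1e-12)
      }
    }
  })
})

test_that("Weber fraction and threshold are exact inverses with the published values", {
  expect_equal(round(jnd_threshold(0.8, 18.1), 3), 0.145)
  expect_equal(weber_jnd(0.8, 0), 0)
  expect_equal(round(weber_jnd(28, 3), 2), 10.71)
  withr::with_seed(5, {
    S <- runif(20, 0.1, 30)
    p <- runif(20, 1, 40)
    expect_equal(weber_jnd(S, jnd_threshold(S, p)), p)
  })
  expect_error(weber_jnd(0, 1), "positive")
  expect_error(jnd_threshold(-1, 10), "positive")
})

test_that("top-outlier accounting is one-sided above mean + factor sigma", {
  expect_equal(outlier_stats(rep(2, 10))$outlier_pct, 0)
  x <- c(rep(0, 99), 10)
  os <- outlier_stats(x)
  expect_equal(os$mean, 0.1)
  expect_equal(os$sd, 1, tolerance = 1e-12)
  expect_equal(os$outlier_pct, 1)
  expect_equal(os$outliers[[1]], 100L)
  # factor -> infinity flags nothing
  expect_equal(outlier_stats(x, factor = 1e9)$outlier_pct, 0)
  # one-sided: a low outlier is not flagged
  expect_equal(outlier_stats(c(rep(10, 99), 0))$outlier_pct, 0)
})

test_that("cohort summaries weight pooled identical forces by sample count", {
  report <- structure(
    tibble::tibble(
      path_id = 1:2, rmse = c(0.1, 0.3), mae = c(0.5, 0.7),
      pct_identical = c(50, 100), n_samples = c(10L, 40L),
      msd_mm = c(1, 3), hsd_mm = c(2, 4), n_unmatched = c(0L, 0L),
      outlier = c(FALSE, FALSE)
    ),
    class = c("path_error_report", class(tibble::tibble()))
  )
  sm <- summarize_report(report)
  expect_equal(sm$rmse_mean, 0.2)
  # sample-weighted, not path-averaged: (50*10 + 100*40) / 50 = 90
  expect_equal(sm$pct_identical_pooled, 90)
  expect_equal(sm$msd_mean_mm, 2)
  expect_equal(sm$hsd_max_mm, 4)

  single <- structure(report[1, ],
                      class = c("path_error_report", class(tibble::tibble())))
  sm1 <- summarize_report(single)
  expect_equal(sm1$rmse_mean, single$rmse)
  expect_equal(sm1$pct_identical_pooled, single$pct_identical)
})
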