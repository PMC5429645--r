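tc <- tissue_codes()

make_labels <- function(arr, spacing = c(0.9, 0.9, 0.9)) {
  volume3d(arr, spacing = spacing)
}

test_that("centerline extraction recovers tube axes and collapses blobs", {
  # 1-voxel straight tube maps to itself
  arr <- array(0L, c(20, 9, 9))
  arr[3:18, 5, 5] <- 1L
  cl <- extract_centerline(make_labels(arr))
  expect_equal(nrow(cl), 16L)
  expect_true(all(cl[, "y"] == 4L & cl[, "z"] == 4L))
  expect_equal(sort(cl[, "x"]), 2:17)

  # 3-voxel-thick straight tube reduces to its axis voxels
  arr2 <- array(0L, c(20, 9, 9))
  arr2[3:18, 4:6, 4:6] <- 1L
  cl2 <- extract_centerline(make_labels(arr2))
  expect_true(all(cl2[, "y"] == 4L & cl2[, "z"] == 4L))
  expect_true(all(cl2[, "x"] %in% 2:17))
  expect_gte(nrow(cl2), 14L)

  # a sphere is point-like
  arr3 <- array(0L, c(15, 15, 15))
  ctr <- c(8, 8, 8)
  for (x in 1:15) for (y in 1:15) for (z in 1:15) {
    if (sum((c(x, y, z) - ctr)^2) <= 16) arr3[x, y, z] <- 1L
  }
  cl3 <- extract_centerline(make_labels(arr3))
  expect_lte(nrow(cl3), 3L)

  expect_error(extract_centerline(make_labels(array(0L, c(4, 4, 4)))),
               "empty")
})

test_that("ray casting reports ordered crossings and Euclidean length", {
  arr <- array(tc[["air"]], c(30, 10, 10))
  arr[10:12, , ] <- tc[["bone_sensitive"]]
  lab <- make_labels(arr)
  ray <- cast_ray(c(0, 5, 5), c(25, 5, 5), lab)
  expect_equal(ray$length_mm, 25 * 0.9)
  expect_equal(ray$crossings$label,
               c(tc[["air"]], tc[["bone_sensitive"]], tc[["air"]]))
  # air-only ray: a single crossing entry
  ray2 <- cast_ray(c(0, 1, 1), c(25, 1, 1), make_labels(array(tc[["air"]],
                                                              c(30, 10, 10))))
  expect_equal(nrow(ray2$crossings), 1L)
})

test_that("path scores combine hard and soft constraints as a weighted sum", {
  cfg <- planner_config()
  free <- tibble::tibble(label = tc[["soft"]], depth_mm = 0)
  # fully clear, saturated soft criteria
  s <- score_path(free, 50, cfg, min_risk_dist = 15, n_target_voxels = 12)
  expect_equal(s$Q, 1.0)
  # blocked by bone: dismissed with infinite score
  blocked <- tibble::tibble(label = c(tc[["soft"]], tc[["bone_sensitive"]],
                                      tc[["bile"]]),
                            depth_mm = c(0, 10, 20))
  expect_equal(score_path(blocked, 50, cfg)$Q, Inf)
  # risk crossed after the target does not block
  behind <- tibble::tibble(label = c(tc[["soft"]], tc[["bile"]],
                                     tc[["vessel"]]),
                           depth_mm = c(0, 10, 20))
  expect_lt(score_path(behind, 50, cfg)$Q, Inf)
  # over-length fails C2
  expect_equal(score_path(free, 95, cfg)$Q, Inf)
  # below the quality threshold: Q = 0.3
  s3 <- score_path(free, 50, cfg, min_risk_dist = 3, n_target_voxels = 3)
  expect_equal(s3$Q, 0.5 * (0.3 + 0.3))
  # Q is monotone in clearance and target hits
  s4 <- score_path(free, 50, cfg, min_risk_dist = 6, n_target_voxels = 3)
  expect_gt(s4$Q, s3$Q)
})

test_that("accepted plans satisfy the hard constraints under an independent oracle", {
  ph <- layered_phantom(small_spec())
  m <- phantom_models(ph)
  plan <- plan_all(m$ref, n_samples = 200L)
  expect_gt(nrow(plan), 0L)
  expect_true(all(plan$length_mm <= 90))
  expect_true(all(is.finite(plan$Q) & plan$Q >= 0.4))

  labels <- ph$gold
  risk_codes <- m$ref$table$code[m$ref$table$role == "risk"]
  # independent voxel-walk: dense sampling with plain R nearest lookup
  check_path <- function(row) {
    entry <- c(row$entry_x_mm, row$entry_y_mm, row$entry_z_mm)
    dir <- c(row$dir_x, row$dir_y, row$dir_z)
    dd <- seq(0, row$length_mm, by = 0.2)
    labs <- vapply(dd, function(d) {
      idx <- round((entry + d * dir) / labels$spacing)
      labels$values[idx[1] + 1, idx[2] + 1, idx[3] + 1]
    }, integer(1))
    hit <- match(tc[["bile"]], labs)
    c(hits = !is.na(hit),
      clear = !any(labs[seq_len(max(hit - 1, 1))] %in% risk_codes,
                   na.rm = TRUE))
  }
  idx <- seq(1, nrow(plan), length.out = min(40, nrow(plan)))
  for (i in unique(round(idx))) {
    chk <- check_path(plan[i, ])
    expect_true(all(chk == 1), info = paste("path", i))
  }
})

test_that("the planner is invariant under role-preserving relabeling and ties are deterministic", {
  ph <- layered_phantom(small_spec())
  labels <- ph$gold
  tbl <- default_tissue_table()
  plan1 <- plan_all(patient_model(labels = labels, table = tbl),
                    n_samples = 100L)

  # permute all codes by +10 and relabel the volume accordingly
  perm <- function(code) code + 10L
  tbl2 <- tbl
  tbl2$code <- perm(tbl2$code)
  labels2 <- volume3d(array(perm(labels$values), vol_dim(labels)),
                      labels$spacing, labels$origin)
  plan2 <- plan_all(patient_model(labels = labels2, table = tbl2),
                    n_samples = 100L)
  expect_equal(tibble::as_tibble(plan1), tibble::as_tibble(plan2))

  # rerun determinism
  plan3 <- plan_all(patient_model(labels = labels, table = tbl),
                    n_samples = 100L)
  expect_identical(tibble::as_tibble(plan1), tibble::as_tibble(plan3))
})

test_that("a target sealed inside bone yields an empty accepted set", {
  arr <- array(tc[["air"]], c(20, 20, 30))
  arr[, , 8:9] <- tc[["skin"]]
  arr[, , 10:29] <- tc[["soft"]]
  arr[8:12, 8:12, 18:22] <- tc[["bone_sensitive"]]
  arr[10, 10, 20] <- tc[["bile"]]
  lab <- make_labels(arr)
  expect_warning(plan <- plan_all(patient_model(labels = lab)), "no feasible")
  expect_equal(nrow(plan), 0L)
})
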