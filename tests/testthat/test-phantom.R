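test_that("phantom generation is seeded and bit-identical across runs", {
  a <- layered_phantom(small_spec(seed = 9))
  b <- layered_phantom(small_spec(seed = 9))
  expect_identical(a$gold$values, b$gold$values)
  expect_identical(a$partial$values, b$partial$values)
  expect_identical(a$intensity$values, b$intensity$values)
  c <- layered_phantom(small_spec(seed = 10))
  expect_false(identical(a$intensity$values, c$intensity$values))
})

test_that("the partial model labels only key structures", {
  ph <- layered_phantom(small_spec())
  tc <- tissue_codes()
  key <- tc[c("fascia", "liver", "vessel", "bile")]
  present <- unique(as.integer(ph$partial$values))
  expect_true(all(present %in% c(0L, key)))
  # gold is fully labelled
  expect_false(any(ph$gold$values == 0L))
  # where key structures sit, partial equals gold
  mask <- ph$gold$values %in% key
  expect_identical(ph$partial$values[mask], ph$gold$values[mask])
})

test_that("transfer-function classification of the partial model reproduces the gold labels", {
  ph <- layered_phantom(small_spec(intensity_sd = 1e-6))
  m <- phantom_models(ph)
  for (x0 in c(6.3, 10.8, 15.3)) {
    tr <- trajectory(c(x0, 10.8, 0), c(0, 0, 1), 80, n_samples = 500)
    gold_seq <- suppressWarnings(sample_labels_along(tr, ph$gold))$label
    ref_sig <- suppressWarnings(
      render_insertion(tr, m$ref, engine_config(n_samples = 500L)))
    test_sig <- suppressWarnings(
      render_insertion(tr, m$test, engine_config(n_samples = 500L)))
    expect_identical(test_sig$code, gold_seq)
    expect_identical(ref_sig$force_N, test_sig$force_N)
  }
})

test_that("unperturbed phantoms render identical forces from both models", {
  ph <- layered_phantom(small_spec())
  m <- phantom_models(ph)
  tr <- centre_path()
  cmp <- compare_signals(render_insertion(tr, m$ref),
                         render_insertion(tr, m$test))
  expect_equal(cmp$pct_identical, 100)
  expect_equal(cmp$rmse, 0)
})

test_that("surface offsets are local and show up as border lag", {
  sp0 <- small_spec()
  sp2 <- small_spec(offsets = c(skin = 2))
  ph0 <- layered_phantom(sp0)
  ph2 <- layered_phantom(sp2)
  # gold untouched by perturbations
  expect_identical(ph0$gold$values, ph2$gold$values)
  # the only differing voxels lie in the offset band at the skin entry
  diff_idx <- which(ph0$intensity$values != ph2$intensity$values,
                    arr.ind = TRUE)
  z_mm <- (diff_idx[, 3] - 1) * 0.9
  expect_true(all(z_mm >= 5 - 0.9 & z_mm < 7 + 0.9))

  # a perpendicular path sees the skin 2 voxels (1.8 mm) later
  m0 <- phantom_models(ph0)
  m2 <- phantom_models(ph2)
  tr <- centre_path()
  cr <- msd_hsd(
    border_crossings(render_insertion(tr, m0$ref)),
    border_crossings(render_insertion(tr, m2$test))
  )
  skin_row <- cr$per_structure[cr$per_structure$code ==
                                 tissue_codes()[["skin"]], ]
  # crossing depths are quantised to the sample grid; allow one step
  expect_equal(skin_row$msd_mm, 1.8, tolerance = traj_spacing(tr) / 1.8)
  expect_equal(skin_row$hsd_mm, 1.8, tolerance = traj_spacing(tr) / 1.8)
})

test_that("misclassified bands sit proximal to the structure and change the rendered sustain", {
  tc <- tissue_codes()
  ph <- layered_phantom(small_spec(
    misclassify = list(structure = "fascia", thickness_mm = 1,
                       as_tissue = "liver")
  ))
  # zero thickness is the identity
  same <- misclassify_band(ph$partial, "fascia", 0, "liver")
  expect_identical(same$values, ph$partial$values)
  # band voxels carry the substitute label right above the fascia
  m <- phantom_models(ph)
  tr <- centre_path()
  sig <- render_insertion(tr, m$test)
  fascia_first <- which(sig$code == tc[["fascia"]])[1]
  band_i <- max(which(sig$code[seq_len(fascia_first - 1)] == tc[["liver"]]))
  expect_equal(sig$force_N[band_i], 0.9)  # liver sustain in the band
  expect_error(misclassify_band(ph$partial, "vessel", 1, "liver"), NA)
  arr0 <- volume3d(array(0L, c(4, 4, 4)))
  expect_error(misclassify_band(arr0, "fascia", 1, "liver"), "not present")
})

test_that("the two-fascia phantom produces a double peak returning to the soft sustain", {
  ph <- two_fascia_phantom(small_two_fascia_spec())
  m <- phantom_models(ph)
  sig <- render_insertion(trajectory(c(10.8, 10.8, 0), c(0, 0, 1), 85), m$ref)
  peaks <- sig$depth_mm[sig$force_N == 2.5 & grepl("cut", sig$event)]
  expect_equal(length(peaks), 2L)
  between <- sig$force_N[sig$depth_mm > peaks[1] + 6 &
                           sig$depth_mm < peaks[2] - 3]
  expect_true(all(between == 0.7))  # back to the soft-tissue sustain level
  expect_error(two_fascia_phantom(small_spec()), "second_fascia_depth")
  expect_error(phantom_spec(second_fascia_depth = 26), "overlap")
})
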