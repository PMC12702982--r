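test_that("generated phantoms hit the target bone volume fraction", {
  ph <- small_phantom(32, seed = 1)
  expect_equal(mean(bone_mask(ph)), 0.131, tolerance = 0.011)
  expect_true(all(ph$mineral[bone_mask(ph)] == 1))
  expect_true(all(ph$osteoid[!bone_mask(ph)] == 0))
  # across seeds the mean BV/TV stays within half a percentage point
  fracs <- vapply(1:6, function(s)
    mean(bone_mask(generate_phantom(phantom_spec(dims = 32, seed = s)))),
    numeric(1))
  expect_lt(abs(mean(fracs) - 0.131), 0.005)
})

test_that("phantoms are deterministic and span the loading axis", {
  a <- generate_phantom(phantom_spec(dims = 32, seed = 11))
  b <- generate_phantom(phantom_spec(dims = 32, seed = 11))
  expect_identical(a, b)
  bone <- bone_mask(a)
  expect_true(osteosim:::spans_loading_axis(bone))
  # single 26-connected component
  lab <- osteosim:::cpp_label26(as.logical(bone), dim(bone))
  expect_equal(max(lab), 1L)
})

test_that("infeasible targets raise informative errors", {
  expect_error(phantom_spec(target_bvtv = 1.0), "strictly between")
  expect_error(phantom_spec(dims = 8), "at least 16")
  expect_error(generate_phantom(phantom_spec(dims = 32, target_bvtv = 0.95,
                                           archetype_mix = 1)),
               "feasible range")
})

test_that("rod archetype has higher SMI than plate archetype at equal BV/TV", {
  rod <- small_phantom(48, seed = 2, target_bvtv = 0.15, archetype_mix = 1)
  plate <- small_phantom(48, seed = 2, target_bvtv = 0.15, archetype_mix = 0)
  expect_gt(static_morphometry(rod)$SMI, static_morphometry(plate)$SMI)
})

test_that("image stacks round-trip voxel-identically in all formats", {
  ph <- small_phantom(32)
  tmp <- withr::local_tempdir()
  for (ext in c("nii.gz", "tif", "raw")) {
    path <- file.path(tmp, paste0("phantom.", ext))
    write_image_stack(ph, path)
    rt <- load_image_stack(path, spacing = ph$spacing, threshold = 0.5)
    expect_identical(bone_mask(rt), bone_mask(ph))
    expect_equal(rt$spacing, ph$spacing)
  }
})

test_that("thresholds above the image maximum yield an empty-bone error", {
  ph <- small_phantom(32)
  tmp <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(ph, tmp)
  expect_error(load_image_stack(tmp, spacing = 14, threshold = 2),
               "empty bone")
})

test_that("full-scale dims are accepted by the spec validator", {
  # dims-only validation of the full biopsy format (not simulated here)
  sp <- phantom_spec(dims = c(282, 282, 264), spacing = 14)
  expect_s3_class(sp, "phantom_spec")
})

test_that("state snapshots preserve continuous fields", {
  ph <- small_phantom(32)
  ph$osteoid[5, 5, 5] <- 0.25
  ph$mineral[5, 5, 5] <- 0.1
  tmp <- withr::local_tempdir()
  save_state_snapshot(ph, tmp, "t0", time_days = 12)
  rt <- load_state_snapshot(tmp, "t0")
  expect_equal(rt$mineral, ph$mineral, tolerance = 1e-6)
  expect_equal(rt$osteoid, ph$osteoid, tolerance = 1e-6)
})
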