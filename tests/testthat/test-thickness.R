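test_that("opposing candidates require a strictly negative normal dot product", {
  n <- rbind(c(0, 0, 1),    # face 1
             c(0, 0, -1),   # antiparallel: candidate
             c(0, 0, 1),    # parallel same side: not
             c(1, 0, 0))    # perpendicular (dot = 0): not
  expect_equal(opposing_candidates(n, 1), 2L)
  expect_equal(opposing_candidates(n, 4), integer(0))
})

test_that("parallel plates recover the separation exactly on every face", {
  mesh <- make_parallel_plates(separation = 2, extent = 10, n = 6)
  ft <- face_thickness(mesh)
  expect_false(any(ft$missing))
  expect_equal(ft$thickness_mm, rep(2, nrow(mesh$faces)))
  # mirror-matched pairing: face k pairs with its image on the other plate
  half <- nrow(mesh$faces) / 2
  expect_equal(ft$pair_id[seq_len(half)], seq_len(half) + half)
})

test_that("an open sheet with parallel normals has no thickness anywhere", {
  sheet <- flat_plate_mesh(extent = 4, n = 3)
  ft <- face_thickness(sheet)
  expect_true(all(ft$missing))
})

test_that("thickness is invariant under rigid motion of the mesh", {
  mesh <- make_parallel_plates(separation = 1.3, extent = 5, n = 4)
  R <- rotation_matrix("x", 33) %*% rotation_matrix("z", 58)
  moved <- triangle_mesh(mesh$vertices %*% t(R) +
                           matrix(c(3, 1, -7), nrow(mesh$vertices), 3,
                                  byrow = TRUE), mesh$faces)
  expect_equal(face_thickness(moved)$thickness_mm,
               face_thickness(mesh)$thickness_mm, tolerance = 1e-10)
})

test_that("accelerated search equals the exhaustive double loop exactly", {
  set.seed(17)
  for (rep in 1:6) {
    r1 <- runif(1, 1.2, 2.2)
    spec <- phantom_spec(shape = "annulus",
                         r1 = r1,
                         r2 = r1 + runif(1, 0.8, 2),
                         height = runif(1, 2, 4),
                         arc = runif(1, 120, 360), spacing = 0.5,
                         rotation = if (rep %% 3 == 0)
                           rotation_matrix("y", runif(1, 0, 90)) else NULL)
    ph <- make_annulus(spec)
    mesh <- build_surface(ph$truth$calc_mask)
    fast <- face_thickness(mesh, accelerate = TRUE)
    slow <- face_thickness(mesh, accelerate = FALSE)
    expect_identical(fast, slow)
    amesh <- build_surface(ph$artery)
    qc <- face_centroids(mesh); tc <- face_centroids(amesh)
    expect_identical(calcmorph:::.knn_grid(qc, tc, 5L),
                     calcmorph:::.knn_brute(qc, tc, 5L))
  }
})

test_that("direction weights hit the closed-form angles", {
  # artery: flat plate, all normals (0, 0, 1); calcification: one triangle
  # whose normal is tilted by a known angle
  artery <- flat_plate_mesh(extent = 4, n = 3)  # 18 faces
  tilted_tri <- function(angle_deg) {
    R <- rotation_matrix("x", angle_deg)
    v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)) %*% t(R)
    triangle_mesh(sweep(v, 2, c(2, 2, 1), "+"), matrix(c(1, 2, 3), 1))
  }
  expect_equal(direction_weights(tilted_tri(0), artery), 1)
  expect_equal(direction_weights(tilted_tri(90), artery), 0, tolerance = 1e-12)
  expect_equal(direction_weights(tilted_tri(60), artery), 0.5)
  expect_equal(direction_weights(tilted_tri(180), artery), 1)
  expect_error(direction_weights(tilted_tri(0), artery, k = 50), "smaller k")
})

test_that("weighted quantile matches its brute-force oracle and bounds", {
  # zero-weight faces are excluded
  expect_equal(weighted_quantile(c(10, 1), c(0, 1), 0.97), 1)
  expect_equal(weighted_quantile(1.3, 1, 0.97), 1.3)
  # uniform weights reduce to the ordinary linear-interpolation percentile
  x <- as.numeric(1:100)
  expect_equal(weighted_quantile(x, rep(1, 100), 0.97),
               unname(quantile(x, 0.97, type = 7)))
  expect_equal(weighted_quantile(x, rep(1, 100), 0.97),
               oracle_weighted_quantile(x, rep(1, 100), 0.97))
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(2:40, 1)
    x <- rnorm(n); w <- runif(n)
    w[sample(n, n %/% 4)] <- 0
    if (all(w == 0)) w[1] <- 0.5
    for (q in c(0, 0.25, 0.5, 0.9, 0.97, 1)) {
      got <- weighted_quantile(x, w, q)
      expect_equal(got, oracle_weighted_quantile(x, w, q), tolerance = 1e-12)
      expect_gte(got, min(x[w > 0]))
      expect_lte(got, max(x[w > 0]))
    }
  }
  expect_error(weighted_quantile(c(1, 2), c(0, 0), 0.5), "positive weight")
})

test_that("representative thickness lies within the weighted face range", {
  ph <- make_annulus(phantom_spec(shape = "annulus", r1 = 2, r2 = 3.5,
                                  height = 4, arc = 360, spacing = 0.5))
  res <- morphometry(ph$ct, ph$artery)
  used <- !res$faces$missing & res$faces$weight > 0
  expect_gte(res$summary$T_rep_mm, min(res$faces$thickness_mm[used]))
  expect_lte(res$summary$T_rep_mm, max(res$faces$thickness_mm[used]))
})

test_that("morphometry flags no-calcification and stays deterministic", {
  ph <- make_annulus(phantom_spec(shape = "annulus", r1 = 2, r2 = 3,
                                  height = 4, arc = 360, spacing = 0.5))
  ct_cold <- ph$ct
  ct_cold$data[ct_cold$data >= 130 & ct_cold$data <= 500] <- 40
  res <- morphometry(ct_cold, ph$artery)
  expect_true(res$summary$no_calcification)
  expect_equal(res$summary$S_mm2, 0)
  expect_equal(res$summary$T_rep_mm, 0)
  expect_equal(res$summary$volume_mm3, 0)

  a <- morphometry(ph$ct, ph$artery)
  b <- morphometry(ph$ct, ph$artery)
  expect_identical(a$summary, b$summary)
  expect_identical(a$faces, b$faces)
})

test_that("dilating the calcification strictly grows S and volume", {
  ph <- make_annulus(phantom_spec(shape = "annulus", r1 = 2, r2 = 3,
                                  height = 4, arc = 360, spacing = 0.5))
  grown <- make_annulus(phantom_spec(shape = "annulus", r1 = 2 - 0.5,
                                     r2 = 3 + 0.5, height = 4 + 1,
                                     arc = 360, spacing = 0.5))
  a <- morphometry(ph$ct, ph$artery)
  b <- morphometry(grown$ct, grown$artery)
  expect_gt(b$summary$S_mm2, a$summary$S_mm2)
  expect_gt(b$summary$volume_mm3, a$summary$volume_mm3)
})

test_that("bilateral pooling combines sides and reports per-side rows", {
  ph <- make_annulus(phantom_spec(shape = "annulus", r1 = 2, r2 = 3,
                                  height = 4, arc = 360, spacing = 0.5))
  out <- morphometry_bilateral(ph$ct, ph$artery, ph$artery, id = "p1")
  expect_equal(out$side, c("left", "right", "pooled"))
  expect_equal(out$S_mm2[3], out$S_mm2[1] + out$S_mm2[2])
  expect_equal(out$volume_mm3[3], out$volume_mm3[1] + out$volume_mm3[2])
  # identical sides: pooled representative T equals the per-side value
  expect_equal(out$T_rep_mm[3], out$T_rep_mm[1])
})
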