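test_that("tumor region membership and distances match brute force", {
  cells <- toy_cells(cd8 = rbind(c(50, 0)), panck = rbind(c(0, 0)))
  region <- build_tumor_region(cells, r = 20)
  d <- ctl_tumor_distance(cells, region)
  expect_equal(d$median, 30)                         # 50 - 20
  inside <- toy_cells(cd8 = rbind(c(5, 5)), panck = rbind(c(0, 0)))
  expect_equal(ctl_tumor_distance(inside, build_tumor_region(inside, 20))$median, 0)
  expect_warning(r0 <- build_tumor_region(toy_cells(cd8 = rbind(c(0, 0))), 20),
                 "no panCK")
  expect_true(is_empty_region(r0))
  expect_error(build_tumor_region(cells, r = 0), "> 0")

  with_test_seed(41, {
    for (rep in 1:5) {
      ck <- matrix(runif(40, 0, 500), 20, 2)
      pts <- matrix(runif(400, -100, 600), 200, 2)
      r <- runif(1, 5, 50)
      region <- build_tumor_region(toy_cells(cd8 = pts, panck = ck), r)
      # brute-force membership + distance oracle
      oracle <- apply(pts, 1, function(p)
        max(0, min(sqrt((ck[, 1] - p[1])^2 + (ck[, 2] - p[2])^2)) - r))
      got <- ctl_tumor_distance(toy_cells(cd8 = pts, panck = ck), region)$distances
      expect_equal(got, oracle, tolerance = 1e-9)
      expect_identical(point_in_region(region, pts[, 1], pts[, 2]), oracle == 0)
    }
  })
})

test_that("ctl_treg_distance is the nearest-neighbor distance", {
  cells <- toy_cells(cd8 = rbind(c(0, 0)), foxp3 = rbind(c(3, 4), c(10, 0)))
  expect_equal(ctl_treg_distance(cells)$median, 5)    # 3-4-5 triangle
  co <- toy_cells(cd8 = rbind(c(1, 1)), foxp3 = rbind(c(1, 1)))
  expect_equal(ctl_treg_distance(co)$median, 0)
  expect_warning(res <- ctl_treg_distance(toy_cells(cd8 = rbind(c(0, 0)))), "missing")
  expect_true(is.na(res$median))
  with_test_seed(43, {
    cd8 <- matrix(runif(60, 0, 100), 30, 2)
    trg <- matrix(runif(30, 0, 100), 15, 2)
    got <- ctl_treg_distance(toy_cells(cd8 = cd8, foxp3 = trg))$distances
    oracle <- apply(cd8, 1, function(p)
      min(sqrt((trg[, 1] - p[1])^2 + (trg[, 2] - p[2])^2)))
    expect_equal(got, oracle, tolerance = 1e-9)
  })
})

test_that("distances are invariant under rigid transforms and monotone in r", {
  with_test_seed(47, {
    ck <- matrix(runif(30, 0, 300), 15, 2)
    cd8 <- matrix(runif(40, 0, 300), 20, 2)
    trg <- matrix(runif(20, 0, 300), 10, 2)
    base_t <- ctl_tumor_distance(toy_cells(cd8 = cd8, panck = ck),
                                 build_tumor_region(toy_cells(panck = ck), 20))
    base_g <- ctl_treg_distance(toy_cells(cd8 = cd8, foxp3 = trg))
    for (i in 1:5) {
      th <- runif(1, 0, 2 * pi); dx <- runif(2, -50, 50)
      Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      tr <- function(m) sweep(m %*% Rm, 2, -dx)
      got_t <- ctl_tumor_distance(toy_cells(cd8 = tr(cd8), panck = tr(ck)),
                                  build_tumor_region(toy_cells(panck = tr(ck)), 20))
      got_g <- ctl_treg_distance(toy_cells(cd8 = tr(cd8), foxp3 = tr(trg)))
      expect_equal(got_t$distances, base_t$distances, tolerance = 1e-9)
      expect_equal(got_g$distances, base_g$distances, tolerance = 1e-9)
    }
    # median non-increasing in r
    meds <- sapply(c(5, 10, 20, 40, 80), function(r)
      ctl_tumor_distance(toy_cells(cd8 = cd8, panck = ck),
                         build_tumor_region(toy_cells(panck = ck), r))$median)
    expect_true(all(diff(meds) <= 1e-12))
  })
})

test_that("distance_shift_call directions, symmetry and degenerate input", {
  with_test_seed(53, { d0 <- runif(100, 50, 150) })
  same <- distance_shift_call(d0, d0 + 0)
  expect_identical(same$call, "no_change")
  dn <- distance_shift_call(d0, pmax(d0 - 50, 0))
  expect_identical(dn$call, "significant_decrease")
  up <- distance_shift_call(pmax(d0 - 50, 0), d0)
  expect_identical(up$call, "significant_increase")
  expect_equal(dn$p, up$p, tolerance = 1e-12)        # symmetry up to direction
  expect_error(distance_shift_call(1:2, 1:5), ">= 3")
})

test_that("count_phenotypes counts exactly and conserves rows", {
  expect_equal(count_phenotypes(toy_cells(cd8 = matrix(0, 3, 2),
                                          foxp3 = matrix(1, 2, 2)))[c("CD8", "FoxP3")],
               c(CD8 = 3L, FoxP3 = 2L))
  empty <- data.frame(x_um = numeric(), y_um = numeric(), phenotype = character())
  expect_true(all(count_phenotypes(empty) == 0))
  with_test_seed(59, {
    cells <- data.frame(x_um = runif(50), y_um = runif(50),
                        phenotype = sample(cell_phenotypes(), 50, replace = TRUE))
    expect_equal(sum(count_phenotypes(cells)), nrow(cells))
  })
  bad <- data.frame(x_um = 1, y_um = 1, phenotype = "CD3")
  expect_error(count_phenotypes(bad), "unknown phenotype")
})

test_that("synthetic responder cells home toward the nest; spatial_summary calls it", {
  coh <- generate_cohort(one_class_config("R", seed = 61))
  s <- coh[[1]]
  reg_c <- build_tumor_region(s$cells$Control, 20)
  reg_t <- build_tumor_region(s$cells$N, 20)
  d_c <- ctl_tumor_distance(s$cells$Control, reg_c)$median
  d_t <- ctl_tumor_distance(s$cells$N, reg_t)$median
  expect_lt(d_t, d_c)
  cells <- rbind(cbind(data.frame(sample_id = "S001", arm = "Control"), s$cells$Control),
                 cbind(data.frame(sample_id = "S001", arm = "N"), s$cells$N))
  spa <- spatial_summary(cells)
  expect_identical(spa$ctl_tumor_shift[spa$arm == "N"], "significant_decrease")
  expect_true(all(spa$n_panCK == 300))
})
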