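make_trace <- function(force, disp_a, disp_b = disp_a, dt = 1e-4) {
  new_impact_trace(
    time = (seq_along(force) - 1) * dt,
    disp_a = disp_a, disp_b = disp_b, force = force,
    condition = test_condition(0.5, 1)
  )
}

test_that("displacement channels are averaged element-wise", {
  s <- sin(seq(0, 1, length.out = 50))
  tr <- make_trace(force = rep(1, 50), disp_a = s, disp_b = s)
  expect_equal(average_displacement(tr), s)
  eps <- 0.01
  tr2 <- make_trace(rep(1, 50), s + eps, s - eps)
  expect_equal(average_displacement(tr2), s)
  tr3 <- make_trace(rep(1, 3), c(1, 2, 3) / 1000, c(3, 2, 1) / 1000)
  expect_equal(average_displacement(tr3), c(2, 2, 2) / 1000)
  bad <- list(disp_a_m = 1:3, disp_b_m = 1:2)
  expect_error(average_displacement(bad), "length")
})

test_that("contact window recovers a constructed ground-truth interval", {
  # 40 pre-contact samples, 100 contact samples, 30 tail samples
  f_contact <- 1000 * sin(pi * seq_len(100) / 101)
  force <- c(rep(0, 40), f_contact, rep(0, 30))
  disp <- c(seq(-0.004, 0, length.out = 40),
            seq(0, 0.012, length.out = 100),
            rep(0.012, 30))
  tr <- make_trace(force, disp)
  w <- extract_contact_window(tr, force_floor = 20)
  i0 <- 40 + which(f_contact > 20)[1]
  i1 <- 40 + max(which(f_contact >= 20))
  expect_equal(nrow(w), i1 - i0 + 1)
  expect_equal(w$force_n, force[i0:i1])
  expect_equal(w$disp_m[1], 0) # re-zeroed at window start
  expect_equal(w$disp_m, disp[i0:i1] - disp[i0])
})

test_that("contact extraction rejects flat traces and honours a zero floor", {
  flat <- make_trace(rep(0, 100), seq(0, 1, length.out = 100))
  expect_error(extract_contact_window(flat), "excursion")
  pos <- make_trace(rep(5, 50), seq(0, 1, length.out = 50))
  w <- extract_contact_window(pos, force_floor = 0)
  expect_equal(nrow(w), 50)
})

test_that("baseline offset is estimated pre-contact and removed", {
  f_contact <- 1000 * sin(pi * seq_len(100) / 101)
  force <- c(rep(12, 40), f_contact + 12, rep(12, 30)) # 12 N offset
  disp <- seq(0, 0.017, length.out = 170)
  w <- extract_contact_window(make_trace(force, disp), force_floor = 30)
  expect_equal(attr(w, "baseline"), 12)
  expect_equal(max(w$force_n), max(f_contact), tolerance = 1e-9)
})

test_that("triangular curve splits into full loading and unloading limbs", {
  disp <- c(seq(0, 0.01, length.out = 50), seq(0.01, 0, length.out = 50)[-1])
  force <- c(seq(0, 5000, length.out = 50), seq(5000, 0, length.out = 50)[-1])
  seg <- segment_curve(tibble::tibble(disp_m = disp, force_n = force))
  expect_equal(nrow(seg$loading), 50)
  expect_equal(seg$discarded_count, 0)
  expect_equal(nrow(seg$unloading), 49)
  expect_equal(seg$peak$peak_force, 5000)
  expect_equal(seg$peak$peak_displacement, 0.01)
})

test_that("creep past the force peak is discarded per the brute-force filter", {
  # displacement keeps creeping up after the force maximum
  disp <- c(seq(0, 0.010, length.out = 60),
            seq(0.0101, 0.0104, length.out = 8),
            seq(0.010, 0.002, length.out = 40))
  force <- c(seq(0, 6000, length.out = 60),
             seq(5900, 5400, length.out = 8),
             seq(5300, 0, length.out = 40))
  w <- tibble::tibble(disp_m = disp, force_n = force)
  seg <- segment_curve(w)
  x_pk <- disp[which.max(force)]
  rest <- w[(which.max(force) + 1):nrow(w), ]
  oracle <- rest[rest$disp_m <= x_pk, ]
  expect_equal(seg$unloading$disp_m, oracle$disp_m)
  expect_equal(seg$discarded_count, sum(rest$disp_m > x_pk))
  expect_equal(seg$discarded_count, 8)
})

test_that("segmentation partitions the window without losing samples", {
  set.seed(31)
  for (i in 1:5) {
    n <- 80
    disp <- cumsum(abs(rnorm(n, 1e-4, 5e-5)))
    force <- c(seq(1, 4000, length.out = n / 2),
               seq(4000, 10, length.out = n / 2)) + rnorm(n, 0, 20)
    w <- tibble::tibble(disp_m = disp, force_n = force)
    seg <- segment_curve(w)
    expect_equal(nrow(seg$loading) + nrow(seg$unloading) + seg$discarded_count,
                 nrow(w))
  }
})

test_that("loading-only curves yield an empty unloading limb", {
  w <- tibble::tibble(disp_m = seq(0, 0.01, length.out = 30),
                      force_n = seq(0, 3000, length.out = 30))
  seg <- segment_curve(w)
  expect_equal(nrow(seg$unloading), 0)
  expect_equal(seg$peak$peak_force, 3000)
})

test_that("segmented peak agrees with the simulator's internal peak", {
  sim <- simulate_drop(test_condition(0.5, 2), quiet_params())
  cyc <- attr(sim$trace, "cycle")
  w <- extract_contact_window(sim$trace)
  seg <- segment_curve(w)
  # displacement is re-zeroed at the contact window start; adding the
  # offset back recovers the simulator's peak within a sample
  expect_equal(seg$peak$peak_displacement + attr(w, "disp_offset"),
               cyc$x_peak, tolerance = 1e-4)
  expect_equal(seg$peak$peak_force, cyc$F_peak, tolerance = 0.01)
})

test_that("tidy() flattens a segmented curve with phase labels", {
  disp <- c(seq(0, 0.01, length.out = 20), seq(0.01, 0, length.out = 20)[-1])
  force <- c(seq(0, 1000, length.out = 20), seq(1000, 0, length.out = 20)[-1])
  td <- tidy(segment_curve(tibble::tibble(disp_m = disp, force_n = force)))
  expect_setequal(unique(td$phase), c("loading", "unloading"))
  expect_equal(nrow(td), 39)
})
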