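test_that("pick_peaks detects planted maxima and nothing on flat signal", {
  mz <- seq(1000, 1099, by = 1)
  expect_equal(nrow(pick_peaks(mz, rep(0, 100))$peaks), 0L)

  # single triangular peak of height 100 on a zero baseline
  inten <- rep(0, 100)
  inten[48:52] <- c(25, 50, 100, 50, 25)
  pl <- pick_peaks(mz, inten, snr_min = 4, halfwindow = 10)
  expect_equal(pl$peaks$mz, mz[50])

  expect_error(pick_peaks(mz, rep(0, 99)), "same length")
  expect_error(pick_peaks(c(1, 1, 2), c(0, 0, 0)), "strictly increasing")
})

test_that("pick_peaks recovers 10 planted Gaussians in noise within one sample spacing", {
  set.seed(7)
  mz <- seq(2000, 4000, by = 0.5)
  noise_sd <- 1
  apex <- seq(2100, 3900, length.out = 10)
  inten <- rnorm(length(mz), 0, noise_sd)
  for (a in apex)
    inten <- inten + 50 * noise_sd * exp(-((mz - a)^2) / (2 * 2^2))
  pl <- pick_peaks(mz, inten, snr_min = 4, halfwindow = 10)
  # every planted apex recovered within +-1 sample spacing
  for (a in apex)
    expect_true(min(abs(pl$peaks$mz - a)) <= 0.5 + 1e-9)
})

test_that("replicate merging matches by single linkage and averages members", {
  reps <- lapply(1:3, function(r)
    peaklist(1000.0, c(10, 20, 30)[r], isolate_id = "A",
             replicate_id = paste0("r", r)))
  cons <- merge_replicates(reps, tol = 0.5, min_presence = 0.6)
  expect_equal(cons$peaks$mz, 1000.0)
  expect_equal(cons$peaks$intensity, 20)
  expect_equal(cons$peaks$presence, 1.0)

  # a peak present in 1 of 3 replicates falls below min_presence 0.6
  reps <- list(peaklist(c(1000, 1500), c(5, 5), "A", "r1"),
               peaklist(1000, 5, "A", "r2"),
               peaklist(1000, 5, "A", "r3"))
  cons <- merge_replicates(reps, tol = 0.5, min_presence = 0.6)
  expect_equal(cons$peaks$mz, 1000)
  expect_equal(nrow(cons$peaks), 1L)

  # chained gaps 0.3 and 0.2 (each <= tol) form one cluster
  reps <- list(peaklist(999.8, 1, "A", "r1"),
               peaklist(1000.1, 1, "A", "r2"),
               peaklist(1000.3, 1, "A", "r3"))
  cons <- merge_replicates(reps, tol = 0.5, min_presence = 0.6)
  expect_equal(nrow(cons$peaks), 1L)
  expect_equal(cons$peaks$presence, 1.0)
  expect_equal(cons$peaks$mz, mean(c(999.8, 1000.1, 1000.3)))
})

test_that("replicate merging is permutation-invariant and bounds consensus mz", {
  set.seed(11)
  for (i in 1:10) {
    reps <- lapply(1:3, function(r)
      peaklist(sort(runif(20, 200, 2000)), rexp(20, 0.01), "A",
               paste0("r", r)))
    cons1 <- merge_replicates(reps, tol = 0.4)
    cons2 <- merge_replicates(rev(reps), tol = 0.4)
    expect_equal(cons1$peaks, cons2$peaks)
    expect_lte(nrow(cons1$peaks), 60L)
    all_mz <- sort(unlist(lapply(reps, function(p) p$peaks$mz)))
    expect_true(all(cons1$peaks$mz >= min(all_mz) &
                      cons1$peaks$mz <= max(all_mz)))
  }
})

test_that("replicate merging rejects bad input", {
  expect_error(merge_replicates(list(), tol = 0.5), "empty")
  reps <- list(peaklist(100, 1, "A", "r1"), peaklist(100, 1, "B", "r2"))
  expect_error(merge_replicates(reps, tol = 0.5), "mix")
})

test_that("blank subtraction removes matched peaks only", {
  mk <- function(mz) merge_replicates(list(peaklist(mz, rep(1, length(mz)),
                                                    "A", "r1")),
                                      tol = 0.1, min_presence = 1)
  cons <- mk(c(500.0, 600.0))
  blank <- mk(600.1)
  blank$isolate_id <- "blank"
  out <- subtract_blank(cons, blank, tol = 0.2)
  expect_equal(out$peaks$mz, 500.0)

  # empty blank is the identity
  empty <- mk(numeric(0))
  expect_equal(subtract_blank(cons, empty, tol = 0.2)$peaks, cons$peaks)

  # subtracting a list from itself empties it
  set.seed(3)
  self <- mk(sort(runif(50, 200, 2000)))
  expect_equal(nrow(subtract_blank(self, self, tol = 0.01)$peaks), 0L)
})

test_that("region splitting partitions peaks at the documented bounds", {
  mz <- c(150, 500, 1999.9, 2000.0, 14000, 16000)
  cons <- merge_replicates(list(peaklist(mz, rep(1, 6), "A", "r1")),
                           tol = 0.01, min_presence = 1)
  expect_message(parts <- split_regions(cons), "dropped 2")
  expect_equal(parts$np$peaks$mz, c(500, 1999.9))
  expect_equal(parts$protein$peaks$mz, c(2000.0, 14000))
  expect_equal(parts$np$region, "np")
  expect_equal(parts$protein$region, "protein")
  # partition: np + protein + dropped = input
  expect_equal(nrow(parts$np$peaks) + nrow(parts$protein$peaks) + 2,
               length(mz))

  # degenerate and protein-only inputs
  empty <- merge_replicates(list(peaklist(numeric(0), numeric(0), "A",
                                          "r1")), tol = 0.01)
  parts <- split_regions(empty)
  expect_equal(nrow(parts$np$peaks), 0L)
  expect_equal(nrow(parts$protein$peaks), 0L)

  prot <- merge_replicates(list(peaklist(c(3000, 9000), c(1, 1), "A",
                                         "r1")), tol = 0.01,
                           min_presence = 1)
  parts <- split_regions(prot)
  expect_equal(nrow(parts$np$peaks), 0L)
  expect_equal(parts$protein$peaks$mz, c(3000, 9000))
})
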