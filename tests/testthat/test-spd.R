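# Naive complete-linkage agglomeration: repeatedly merge the two clusters
# with the smallest maximal pairwise age difference, while that diameter
# stays <= h. Independent of hclust.
brute_bins <- function(ages, h) {
  clusters <- as.list(seq_along(ages))
  repeat {
    best <- NULL; best_d <- Inf
    if (length(clusters) < 2) break
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- max(abs(outer(ages[clusters[[i]]], ages[clusters[[j]]], "-")))
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  memb <- integer(length(ages))
  for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
  memb
}

test_that("same-site dates bin by complete-linkage clustering at height h", {
  d <- c14_dates(c("a", "b", "c"), c(5000, 5050, 5900), 40, "s1")
  b <- bin_dates(d, h = 200)
  expect_equal(b$bin_id[1], b$bin_id[2])
  expect_false(b$bin_id[3] == b$bin_id[1])

  single <- bin_dates(c14_dates("x", 4000, 30, "s9"))
  expect_equal(nrow(single), 1)

  # dates at different sites never share a bin, whatever the ages
  two <- c14_dates(c("p", "q"), c(5000, 5000), 40, c("s1", "s2"))
  expect_length(unique(bin_dates(two)$bin_id), 2)
})

test_that("cluster binning agrees with a brute-force agglomeration oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    ages <- round(runif(10, 5000, 6000))
    d <- c14_dates(sprintf("L%d", 1:10), ages, 40, "s1")
    got <- as.integer(factor(bin_dates(d, h = 200)$bin_id))
    want <- brute_bins(ages, 200)
    # same partition up to relabelling
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})

test_that("fixed-width binning groups by h-year intervals of 14C age", {
  d <- c14_dates(c("a", "b", "c"), c(5010, 5190, 5210), 40, "s1")
  b <- bin_dates(d, h = 200, method = "fixed")
  expect_equal(b$bin_id[1], b$bin_id[2])
  expect_false(b$bin_id[3] == b$bin_id[1])
})

test_that("binned summation averages within bins and sums across them", {
  cv <- toy_curve()
  d <- c14_dates(c("a", "b", "c", "d"), c(6000, 6000, 6000, 6000), 40,
                 c("s1", "s1", "s2", "s3"))
  dens <- calibrate_dates(d, cv, normalise = TRUE, trim_tail = 0)
  # a and b share one bin -> their average = the single-date density
  bins2 <- data.frame(lab_id = c("a", "b"), bin_id = c("s1_1", "s1_1"))
  spd2 <- sum_probabilities(dens[c("a", "b")], bins2, window = c(2000, 12000))
  single <- sum_probabilities(dens["a"], window = c(2000, 12000))
  expect_same_spd(spd2, single)
  # c and d are separate sites -> twice the single-date density
  spd_cd <- sum_probabilities(dens[c("c", "d")], window = c(2000, 12000))
  expect_equal(spd_cd$value, 2 * single$value, tolerance = 1e-12)
})

test_that("summation equals a naive per-date loop oracle", {
  cv <- toy_curve()
  set.seed(3)
  n <- 50
  d <- c14_dates(sprintf("L%02d", 1:n), round(runif(n, 3500, 11000)),
                 round(runif(n, 30, 120)), sprintf("s%d", sample(1:8, n, TRUE)))
  dens <- calibrate_dates(d, cv, normalise = TRUE)
  bins <- bin_dates(d, 200)
  spd <- sum_probabilities(dens, bins, window = c(2000, 12000))

  grid <- seq(2000, 12000, by = 1)
  want <- numeric(length(grid))
  size <- table(bins$bin_id)
  for (k in seq_len(nrow(bins))) {
    dd <- dens[[bins$lab_id[k]]]
    w <- 1 / size[[bins$bin_id[k]]]
    for (j in seq_along(dd$calbp)) {
      pos <- dd$calbp[j] - grid[1] + 1
      if (pos >= 1 && pos <= length(grid)) {
        want[pos] <- want[pos] + dd$mass[j] * w
      }
    }
  }
  expect_equal(spd$value, want, tolerance = 1e-12)
})

test_that("SPD mass equals the number of bins for untrimmed normalised input", {
  cv <- toy_curve()
  set.seed(4)
  n <- 30
  d <- c14_dates(sprintf("L%02d", 1:n), round(runif(n, 4000, 9000)),
                 round(runif(n, 30, 100)), sprintf("s%d", sample(1:6, n, TRUE)))
  dens <- calibrate_dates(d, cv, normalise = TRUE, trim_tail = 0)
  bins <- bin_dates(d, 200)
  spd <- sum_probabilities(dens, bins, window = c(0, 15000))
  expect_true(spd$normalised_input)
  expect_equal(sum(spd$value), spd$n_bins, tolerance = 1e-6)
})

test_that("SPD is invariant to input order", {
  cv <- toy_curve()
  set.seed(5)
  n <- 20
  d <- c14_dates(sprintf("L%02d", 1:n), round(runif(n, 4000, 9000)),
                 round(runif(n, 30, 100)), sprintf("s%d", sample(1:5, n, TRUE)))
  dens <- calibrate_dates(d, cv, normalise = TRUE)
  bins <- bin_dates(d, 200)
  a <- sum_probabilities(dens, bins)
  perm <- sample(n)
  b <- sum_probabilities(dens[perm], bins[perm, ])
  expect_identical(a$value, b$value)
})

test_that("densities on mismatched grid steps refuse to sum", {
  cv <- toy_curve()
  d1 <- calibrate(5000, 40, cv, step = 1, lab_id = "a")
  d5 <- calibrate(6000, 40, cv, step = 5, lab_id = "b")
  expect_error(sum_probabilities(list(a = d1, b = d5)), "mismatched")
})

test_that("rolling mean is the centred windowed average with edge truncation", {
  const <- paleodem:::spd_from_values(seq(2000, 4000, 5), rep(2.5, 401))
  expect_equal(rolling_mean(const, 100)$value, rep(2.5, 401))

  imp_v <- numeric(1001); imp_v[501] <- 1
  imp <- paleodem:::spd_from_values(seq(5000, 6000, 1), imp_v)
  sm <- rolling_mean(imp, 100)$value
  expect_equal(sm[501], 1 / 101)           # 2*floor(100/2)+1 cells
  expect_equal(sm[460], 1 / 101)
  expect_equal(sm[560], 0)

  set.seed(6)
  x <- runif(300)
  spd <- paleodem:::spd_from_values(seq(3000, by = 5, length.out = 300), x)
  got <- rolling_mean(spd, 100)$value
  h <- floor(round(100 / 5) / 2)
  want <- vapply(seq_along(x), function(i) {
    e <- min(h, i - 1, length(x) - i)
    mean(x[(i - e):(i + e)])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)

  # totals preserved away from the edges
  mid <- (h + 1):(length(x) - h)
  expect_equal(sum(got[mid]), sum(vapply(mid, function(i)
    mean(x[(i - h):(i + h)]), numeric(1))))
})
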