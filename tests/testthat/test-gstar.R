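chain_weights <- function(n, ids = paste0("L", seq_len(n))) {
  D <- matrix(1e9, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) D[i, i + 1] <- D[i + 1, i] <- 5000
  diag(D) <- 0
  build_weights(D, 6000)
}

test_that("distance-band weights include self and flag isolates", {
  # three collinear receivers 5 km apart: middle W* = 3, ends W* = 2
  W <- chain_weights(3)
  expect_equal(unname(W$wstar), c(2, 3, 2))
  expect_equal(diag(W$w), c(L1 = 1, L2 = 1, L3 = 1))

  # isolated receiver: W* = 1, flagged
  D <- matrix(c(0, 99999, 99999, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  W <- build_weights(D, 6000)
  expect_equal(unname(W$wstar), c(1, 1))
  expect_equal(W$isolated, c("A", "B"))

  # d = Inf -> everything is a neighbour
  W <- build_weights(D, Inf)
  expect_true(all(W$w == 1))

  expect_error(build_weights(D, 0), "positive")
})

test_that("G* scores match a direct evaluation of the standardized formula", {
  # n = 5 spike on a chain vs the plain-loop oracle
  W <- chain_weights(5)
  x <- c(10, 0, 0, 0, 0)
  got <- getis_gstar(stats::setNames(x, paste0("L", 1:5)), W)
  expect_equal(got$gstar, oracle_gstar(x, W$w), tolerance = 1e-12)

  # random instances: random sizes, random symmetric binary weights
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2) < 0.3
    w <- w + t(w); diag(w) <- 1
    ids <- paste0("L", seq_len(n))
    dimnames(w) <- list(ids, ids)
    W <- structure(list(w = w, wstar = rowSums(w),
                        isolated = ids[rowSums(w) == 1], d = NA),
                   class = "spatial_weights")
    x <- rnorm(n)
    got <- getis_gstar(stats::setNames(x, ids), W)
    expect_equal(got$gstar, oracle_gstar(x, w), tolerance = 1e-9)
  }
})

test_that("an isolated location's G* collapses to its ordinary z-score", {
  D <- matrix(1e9, 4, 4, dimnames = list(paste0("L", 1:4), paste0("L", 1:4)))
  D[1, 2] <- D[2, 1] <- 5000
  diag(D) <- 0
  W <- build_weights(D, 6000)   # L3, L4 isolated
  x <- c(L1 = 3, L2 = 1, L3 = 8, L4 = 0)
  got <- getis_gstar(x, W)
  s <- sqrt(mean(x^2) - mean(x)^2)
  expect_equal(got$gstar[3], (8 - mean(x)) / s)
  expect_true(got$isolated[3])
})

test_that("G* is affine invariant and equivariant under relabeling", {
  set.seed(88)
  n <- 12
  ids <- paste0("L", 1:n)
  D <- as.matrix(dist(cbind(runif(n, 0, 20000), runif(n, 0, 20000))))
  dimnames(D) <- list(ids, ids)
  W <- build_weights(D, 6000)
  x <- stats::setNames(rexp(n), ids)
  z0 <- getis_gstar(x, W)$gstar

  # affine invariance: a x + b leaves every score unchanged
  expect_equal(getis_gstar(3.7 * x + 11, W)$gstar, z0, tolerance = 1e-12)

  # equivariance: permuting labels together with the weight matrix permutes
  # the scores
  p <- sample(n)
  Wp <- build_weights(D[p, p], 6000)
  zp <- getis_gstar(x[p], Wp)$gstar
  expect_equal(zp, z0[p], tolerance = 1e-12)

  # spiking one location weakly increases its own and neighbours' scores
  i <- which(W$wstar > 1)[1]
  x2 <- x; x2[i] <- x2[i] + 10
  z2 <- getis_gstar(x2, W)$gstar
  nbrs <- which(W$w[i, ] == 1)
  expect_true(all(z2[nbrs] >= z0[nbrs] - 1e-12))

  expect_error(getis_gstar(stats::setNames(rep(2, n), ids), W), "degenerate")
})

test_that("conditional permutation p-values are deterministic and calibrated", {
  W <- chain_weights(6)
  x <- stats::setNames(c(5, 1, 0, 2, 8, 3), paste0("L", 1:6))
  p1 <- permutation_pvalues(x, W, n_perm = 199, seed = 9)
  p2 <- permutation_pvalues(x, W, n_perm = 199, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$p_value > 0 & p1$p_value <= 1, na.rm = TRUE))

  # exhaustive enumeration at n = 4 agrees with large-n_perm Monte-Carlo
  W4 <- chain_weights(4)
  x4 <- stats::setNames(c(4, 0, 1, 7), paste0("L", 1:4))
  ex <- permutation_pvalues(x4, W4, method = "exhaustive")
  mc <- permutation_pvalues(x4, W4, n_perm = 4000, seed = 2)
  ok <- !is.na(ex$p_value)
  expect_true(any(ok))
  expect_equal(mc$p_value[ok], ex$p_value[ok], tolerance = 0.03)
})

test_that("isolated locations get no permutation p-value", {
  D <- matrix(1e9, 3, 3, dimnames = list(paste0("L", 1:3), paste0("L", 1:3)))
  D[1, 2] <- D[2, 1] <- 4000
  diag(D) <- 0
  W <- build_weights(D, 6000)
  p <- permutation_pvalues(stats::setNames(c(1, 5, 9), paste0("L", 1:3)), W,
                           n_perm = 99, seed = 1)
  expect_true(is.na(p$p_value[3]))
  expect_false(is.na(p$p_value[1]))
})

test_that("duration standardization scales by deployment overlap and window", {
  dep_full <- data.frame(
    receiver_id = c("R1", "R2"),
    deploy_start = as.POSIXct("2019-01-01", tz = "UTC"),
    deploy_end = as.POSIXct("2020-01-01", tz = "UTC")
  )
  breakup <- as.Date("2019-06-19")
  # full-season deployment: scaling factor 1 -> value = duration / window
  ev <- evt("F1", "R1", 0, 2, epoch = "2019-07-01 00:00:00")
  ret <- c(F1 = as.Date("2019-07-19"))   # 30-day window
  sd1 <- standardize_durations(ev, dep_full, breakup, ret, c("R1", "R2"))
  expect_equal(sd1$value[sd1$receiver_id == "R1"], 7200 / 30)
  expect_equal(sd1$value[sd1$receiver_id == "R2"], 0)

  # half-window deployment counts double per unit time
  dep_half <- dep_full
  dep_half$deploy_start[1] <- as.POSIXct("2019-07-04 00:00:00", tz = "UTC")
  sd2 <- standardize_durations(ev, dep_half, breakup, ret, c("R1", "R2"))
  expect_equal(sd2$value[sd2$receiver_id == "R1"], 2 * 7200 / 30)

  # two identical fish, one with a window twice as long and durations twice
  # as large -> identical standardized values
  ev2 <- rbind(evt("F1", "R1", 0, 2, epoch = "2019-07-01 00:00:00"),
               evt("F2", "R1", 0, 4, epoch = "2019-07-01 00:00:00"))
  ret2 <- c(F1 = as.Date("2019-07-19"), F2 = as.Date("2019-08-18"))
  sd3 <- standardize_durations(ev2, dep_full, breakup, ret2, "R1")
  expect_equal(sd3$value[sd3$tag_id == "F1"], sd3$value[sd3$tag_id == "F2"])

  # three-fish fixture vs hand-computed values
  ev3 <- rbind(evt("F1", "R1", 0, 1, epoch = "2019-07-01 00:00:00"),
               evt("F2", "R1", 0, 2, epoch = "2019-07-01 00:00:00"),
               evt("F3", "R2", 0, 1, n = 1, epoch = "2019-07-01 00:00:00"))
  ret3 <- c(F1 = as.Date("2019-07-19"), F2 = as.Date("2019-07-19"),
            F3 = as.Date("2019-07-19"))
  sd4 <- standardize_durations(ev3, dep_full, breakup, ret3, c("R1", "R2"))
  hand <- c(F1.R1 = 3600 / 30, F1.R2 = 0,
            F2.R1 = 7200 / 30, F2.R2 = 0,
            F3.R1 = 0, F3.R2 = 90 / 30)
  got <- stats::setNames(sd4$value, paste(sd4$tag_id, sd4$receiver_id, sep = "."))
  expect_equal(got[names(hand)], hand)

  # detections at a receiver with no deployment overlap -> inconsistency
  dep_none <- dep_full
  dep_none$deploy_end[1] <- as.POSIXct("2019-05-01", tz = "UTC")
  expect_error(standardize_durations(ev, dep_none, breakup, ret, c("R1", "R2")),
               "outside its deployment")
})

test_that("absence attribution assigns gap days to flanking receivers", {
  breakup <- as.Date("2019-06-19")
  # events at A (day 1) and B (day 5) of a 10-day window: days 2-4 undetected
  ev <- rbind(evt("F1", "A", 24, 26, epoch = "2019-06-19 00:00:00"),
              evt("F1", "B", 120, 122, epoch = "2019-06-19 00:00:00"))
  ret <- c(F1 = as.Date("2019-06-29"))
  ab <- attribute_absences(ev, breakup, ret, c("A", "B", "C"))
  got <- stats::setNames(ab$value, ab$receiver_id)
  # day 0 is a leading run (before the first event) -> attributed forward to A
  expect_equal(got[["A"]], (1 + 3) / 10)
  expect_equal(got[["B"]], (3 + 4) / 10)  # days 6-9 trail after B
  expect_equal(got[["C"]], 0)

  # no undetected days -> all zeros
  ev2 <- evt("F1", "A", 0, 9.5 * 24, epoch = "2019-06-19 00:00:00")
  ab2 <- attribute_absences(ev2, breakup, ret, c("A", "B"))
  expect_true(all(ab2$value == 0))

  # multi-fish fixture vs a day-by-day brute-force tally
  set.seed(99)
  recvs <- c("A", "B", "C", "D")
  evs <- list(); tags <- paste0("F", 1:4)
  for (tg in tags) {
    days_on <- sort(sample(0:19, 8))
    evs[[tg]] <- do.call(rbind, lapply(days_on, function(dd)
      evt(tg, sample(recvs, 1), dd * 24 + 6, dd * 24 + 8,
          epoch = "2019-06-19 00:00:00")))
  }
  ev4 <- do.call(rbind, evs)
  ret4 <- stats::setNames(rep(as.Date("2019-07-09"), 4), tags)  # 20-day window
  ab4 <- attribute_absences(ev4, breakup, ret4, recvs)

  brute <- stats::setNames(numeric(4 * 4),
                           paste(rep(tags, each = 4), recvs, sep = "."))
  for (tg in tags) {
    e <- evs[[tg]]
    dd <- as.numeric(as.Date(e$start) - breakup)
    for (day in 0:19) {
      if (day %in% dd) next
      prev <- dd[dd < day]; nxt <- dd[dd > day]
      if (length(prev)) {
        r <- e$receiver_id[which(dd == max(prev))]
        brute[paste(tg, r, sep = ".")] <- brute[paste(tg, r, sep = ".")] + 1 / 20
      }
      if (length(nxt)) {
        r <- e$receiver_id[which(dd == min(nxt))]
        brute[paste(tg, r, sep = ".")] <- brute[paste(tg, r, sep = ".")] + 1 / 20
      }
    }
  }
  got4 <- stats::setNames(ab4$value, paste(ab4$tag_id, ab4$receiver_id, sep = "."))
  expect_equal(got4[names(brute)], brute)
})

test_that("combined ranks merge the paired receivers and use average ties", {
  strength <- c(A = 5, B = 3, "M1+M2" = 4, RIVER = 99)
  betw <- c(A = 2, B = 1, "M1+M2" = 2, RIVER = 99)
  gst <- c(A = 1.0, B = 0.5, M1 = 2.0, M2 = 1.0)

  out <- combined_rank(strength, betw, gst, merged_pair = c("M1", "M2"))
  expect_false("RIVER" %in% out$location)
  # merged pair G* = mean(2.0, 1.0) = 1.5 -> highest -> rank 1
  expect_equal(out$gstar_rank[out$location == "M1+M2"], 1)
  # ties on betweenness: A and M1+M2 share ranks 1 and 2 -> 1.5 each
  expect_equal(out$betweenness_rank[out$location == "A"], 1.5)
  expect_equal(out$betweenness_rank[out$location == "M1+M2"], 1.5)

  # a location ranked first on all three metrics gets combined rank 3
  s2 <- c(A = 9, B = 1, C = 2); b2 <- c(A = 9, B = 1, C = 2)
  g2 <- c(A = 9, B = 1, C = 2)
  out2 <- combined_rank(s2, b2, g2)
  expect_equal(out2$combined_rank[out2$location == "A"], 3)

  # six-location fixture vs hand-ranked table
  s3 <- c(A = 10, B = 8, C = 6, D = 4, E = 2, F = 0)
  b3 <- c(A = 0, B = 2, C = 4, D = 6, E = 8, F = 10)
  g3 <- c(A = 1, B = 2, C = 3, D = 3, E = 2, F = 1)
  out3 <- combined_rank(s3, b3, g3)
  hand <- c(A = 1 + 6 + 5.5, B = 2 + 5 + 3.5, C = 3 + 4 + 1.5,
            D = 4 + 3 + 1.5, E = 5 + 2 + 3.5, F = 6 + 1 + 5.5)
  got <- stats::setNames(out3$combined_rank, out3$location)
  expect_equal(got[names(hand)], hand)
})
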