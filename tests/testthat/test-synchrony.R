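## independent loop-based reimplementation of the shifting rule, used as an
## O(n^2) oracle against the vectorized sync_pair
oracle_sync <- function(reference, target, dt, protect) {
  region <- function(t) (t >= protect[1]) + (t >= protect[2])
  n <- length(target)
  near <- off <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    d <- abs(target[k] - reference)
    best <- reference[d == min(d)]
    near[k] <- min(best)                       # tie -> earlier reference
    off[k] <- target[k] - near[k]
  }
  eligible <- abs(off) <= dt & region(target) == region(near)
  moved <- logical(n)
  for (r in unique(near[eligible])) {
    cand <- which(eligible & near == r)
    cand <- cand[order(abs(off[cand]), target[cand])]
    moved[cand[1]] <- TRUE                     # nearest wins, others stay
  }
  out <- target
  out[moved] <- near[moved]
  list(train = sort(out), n_shifted = sum(moved & off != 0L))
}

test_that("pulse shifting follows the nearest-reference window rule", {
  res <- sync_pair(c(100L, 120L, 140L), c(103L, 111L, 138L), dt = 4,
                   protect = c(2000, 4000))
  expect_equal(res$train, c(100L, 111L, 140L))
  expect_equal(res$n_shifted, 2L)

  ## no target pulse near any reference: unchanged
  far <- sync_pair(c(100L, 200L), c(150L, 250L), dt = 4, protect = c(2000, 4000))
  expect_equal(far$train, c(150L, 250L))
  expect_equal(far$n_shifted, 0L)

  ## identical trains: all offsets already zero
  same <- sync_pair(c(10L, 20L, 30L), c(10L, 20L, 30L), dt = 6,
                    protect = c(2000, 4000))
  expect_equal(same$train, c(10L, 20L, 30L))
  expect_equal(same$n_shifted, 0L)

  ## a pulse already on the reference blocks a farther candidate (nearest wins)
  blk <- sync_pair(c(104L), c(100L, 104L), dt = 6, protect = c(2000, 4000))
  expect_equal(blk$train, c(100L, 104L))
  expect_equal(blk$n_shifted, 0L)
})

test_that("moves never cross the protected window boundary", {
  ## target just inside, reference just outside (and vice versa): skipped
  res <- sync_pair(c(1998L), c(2001L), dt = 6, protect = c(2000, 4000))
  expect_equal(res$train, c(2001L))
  res2 <- sync_pair(c(2001L), c(1998L), dt = 6, protect = c(2000, 4000))
  expect_equal(res2$train, c(1998L))
  res3 <- sync_pair(c(4001L), c(3998L), dt = 6, protect = c(2000, 4000))
  expect_equal(res3$train, c(3998L))
  ## both on the same side: allowed
  res4 <- sync_pair(c(1995L), c(1998L), dt = 6, protect = c(2000, 4000))
  expect_equal(res4$train, c(1995L))
})

test_that("sync_pair agrees with a brute-force oracle on random trains", {
  set.seed(101)
  for (case in 1:100) {
    ref <- random_train(sample(3:25, 1), 1980, 4020)
    tgt <- random_train(sample(3:25, 1), 1980, 4020)
    dt <- sample(c(2, 4, 6), 1)
    got <- sync_pair(ref, tgt, dt, protect = c(2000, 4000))
    want <- oracle_sync(ref, tgt, dt, protect = c(2000, 4000))
    expect_identical(got$train, as.integer(want$train))
    expect_identical(got$n_shifted, as.integer(want$n_shifted))
    expect_true(all(diff(got$train) > 0))
    expect_equal(length(got$train), length(tgt))
  }
})

test_that("method schedules reproduce the published pair lists", {
  ## Method 1: chained neighbours in twitch-force order
  m1 <- schedule_for_method(1, the_pool)
  expect_true(attr(m1, "chained"))
  s_rows <- m1$reference %in% 1:8
  expect_equal(m1$reference[s_rows], 1:7)
  expect_equal(m1$target[s_rows], 2:8)
  expect_equal(m1$reference[m1$reference %in% 9:31], 9:30)
  expect_equal(m1$target[m1$target %in% 33:57], 33:57)

  ## Method 2: chained neighbours in mean-rate order (frozen published chains)
  m2 <- schedule_for_method(2, the_pool)
  expect_true(attr(m2, "chained"))
  s2 <- m2[m2$reference %in% 1:8, ]
  expect_equal(s2$reference, c(7, 1, 6, 5, 4, 2, 3))
  expect_equal(s2$target,    c(1, 6, 5, 4, 2, 3, 8))
  fr2 <- m2[m2$reference %in% 9:31, ]
  expect_equal(fr2$reference,
               c(18, 16, 24, 22, 28, 14, 12, 23, 13, 20, 31,
                 27, 29, 25, 9, 21, 30, 26, 19, 17, 11, 10))
  expect_equal(fr2$target,
               c(16, 24, 22, 28, 14, 12, 23, 13, 20, 31, 27,
                 29, 25, 9, 21, 30, 26, 19, 17, 11, 10, 15))
  ff2 <- m2[m2$reference %in% 32:57, ]
  expect_equal(ff2$reference,
               c(50, 44, 43, 49, 39, 54, 52, 55, 56, 48, 47, 53, 51,
                 37, 40, 41, 57, 45, 35, 33, 46, 32, 34, 38, 36))
  expect_equal(ff2$target,
               c(44, 43, 49, 39, 54, 52, 55, 56, 48, 47, 53, 51, 37,
                 40, 41, 57, 45, 35, 33, 46, 32, 34, 38, 36, 42))

  ## Method 3: independent groups of four with short trailing groups
  m3 <- schedule_for_method(3, the_pool)
  expect_false(attr(m3, "chained"))
  expect_equal(m3$reference[m3$reference %in% 1:8], c(1, 1, 1, 5, 5, 5))
  expect_equal(m3$target[m3$reference %in% 1:8], c(2, 3, 4, 6, 7, 8))
  expect_equal(m3[m3$reference == 29, "target"], c(30, 31))   # short FR group
  expect_equal(m3[m3$reference == 56, "target"], 57)          # short FF group
  expect_equal(sort(unique(m3$reference[m3$reference %in% 32:57])),
               c(32, 36, 40, 44, 48, 52, 56))

  ## Method 4: first-recruited unit of each type is the common reference
  m4 <- schedule_for_method(4, the_pool)
  expect_false(attr(m4, "chained"))
  expect_equal(m4$reference[m4$target %in% 2:8], rep(1, 7))
  expect_equal(m4$reference[m4$target %in% 10:31], rep(9, 22))
  expect_equal(m4$reference[m4$target %in% 33:57], rep(32, 25))
  expect_equal(nrow(m4), 7 + 22 + 25)

  expect_error(schedule_for_method(5, the_pool), "method")
})

test_that("applying a method conserves pulse counts and tags provenance", {
  fs <- ns_firings(11)
  for (m in 1:4) {
    sched <- schedule_for_method(m, the_pool)
    for (dt in c(2, 6)) {
      out <- apply_method(fs, sched, dt, the_pool)
      expect_identical(lengths(out$trains), lengths(fs$trains))
      expect_identical(steady_count(out), steady_count(fs))
      expect_equal(out$provenance, sprintf("method%d/dt%d", m, dt))
      for (tr in out$trains) expect_true(all(diff(tr) > 0))
    }
  }
})

test_that("an empty schedule leaves the firing set unchanged", {
  fs <- ns_firings(11)
  empty <- structure(data.frame(reference = integer(0), target = integer(0)),
                     class = c("sync_schedule", "data.frame"),
                     method = 4, chained = FALSE)
  out <- apply_method(fs, empty, 6, the_pool)
  expect_identical(out$trains, fs$trains)
})

test_that("wider windows shift more pulses", {
  fs <- ns_firings(12)
  for (m in 1:4) {
    sched <- schedule_for_method(m, the_pool)
    tot <- sapply(c(2, 4, 6), function(dt) {
      sum(apply_method(fs, sched, dt, the_pool)$shift_log$n_shifted)
    })
    expect_true(all(diff(tot) > 0))
  }
})

test_that("non-chained methods are idempotent", {
  fs <- ns_firings(13)
  for (m in c(3, 4)) {
    sched <- schedule_for_method(m, the_pool)
    once <- apply_method(fs, sched, 6, the_pool)
    twice <- apply_method(once, sched, 6, the_pool)
    expect_identical(twice$trains, once$trains)
    expect_equal(sum(twice$shift_log$n_shifted), 0)
  }
})

test_that("the reference-shift fraction matches the coincidence expectation", {
  ## Method 4 FR block: window of 2*6+1 = 13 ms against the reference
  ## unit's ~17 ms mean IPI predicts that most target pulses move
  fs <- ns_firings(14)
  out <- apply_method(fs, schedule_for_method(4, the_pool), 6, the_pool)
  sl <- out$shift_log
  fr <- sl$reference == 9
  n_target <- sum(lengths(fs$trains[the_pool$label[10:31]]))
  frac <- sum(sl$n_shifted[fr]) / n_target
  expect_gt(frac, 0.55)
  expect_lt(frac, 0.85)
})

test_that("mean CISI grows with the synchronization window", {
  ## statistical monotonicity over 10 seeds, every method
  means <- array(0, c(4, 3))
  for (seed in 1:10) {
    fs <- ns_firings(seed + 100)
    for (m in 1:4) {
      sched <- schedule_for_method(m, the_pool)
      for (w in 1:3) {
        out <- apply_method(fs, sched, c(2, 4, 6)[w], the_pool)
        s <- summarize_sync(out, the_pool)
        means[m, w] <- means[m, w] +
          s$cisi_summary$mean[s$cisi_summary$group == "all"] / 10
      }
    }
  }
  for (m in 1:4) expect_true(all(diff(means[m, ]) > 0))
})
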