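# independent readout oracle: naive triple loop over the raw array
triple_loop_readout <- function(mem, what = NULL, when = NULL, where = NULL) {
  d <- dim(mem)
  v <- unclass(mem)
  ii <- if (is.null(what)) 1:d[1] else what + 1L
  jj <- if (is.null(when)) 1:d[2] else when + 1L
  kk <- if (is.null(where)) 1:d[3] else where + 1L
  out <- array(NA_real_, dim = c(length(ii), length(jj), length(kk)))
  for (a in seq_along(ii))
    for (b in seq_along(jj))
      for (c in seq_along(kk))
        out[a, b, c] <- v[ii[a], jj[b], kk[c]]
  as.vector(out)
}

test_that("make_memory builds zero arrays of the stated shapes", {
  for (dims in list(c(2, 3, 64), c(3, 6, 144), c(1, 1, 1))) {
    mem <- make_memory(dims[1], dims[2], dims[3])
    expect_identical(dim(mem), as.integer(dims))
    expect_true(all(unclass(mem) == 0))
  }
  expect_error(make_memory(0, 3, 64), "positive")
  expect_error(make_memory(2, -1, 64), "positive")
  expect_error(make_memory(2, 3, 64, width = 8, height = 9), "n_where")
})

test_that("query matches the triple-loop readout on random memories", {
  set.seed(11)
  for (rep in 1:20) {
    d <- c(sample(1:3, 1), sample(1:4, 1), sample(c(4, 9, 16), 1))
    mem <- make_memory(d[1], d[2], d[3])
    mem[] <- round(stats::rnorm(prod(d)), 3)
    sel <- list(what = sample(c(list(NULL), as.list(0:(d[1] - 1))), 1)[[1]],
                when = sample(c(list(NULL), as.list(0:(d[2] - 1))), 1)[[1]],
                where = sample(c(list(NULL), as.list(0:(d[3] - 1))), 1)[[1]])
    got <- query(mem, sel$what, sel$when, sel$where)
    expect_equal(as.vector(got),
                 triple_loop_readout(mem, sel$what, sel$when, sel$where))
  }
})

test_that("query slices are snapshots and support single-entry lookups", {
  mem <- make_memory(2, 3, 64, what_names = c("crab", "shrimp"))
  mem <- delta_update(mem, 0, 1, 5, r = 4, alpha = 0.1)
  v <- query(mem, what = 0, when = 1)
  expect_length(as.vector(v), 64)
  expect_equal(as.vector(v)[6], 0.4)
  expect_equal(sum(as.vector(v) != 0), 1)
  expect_equal(as.numeric(query(mem, 0, 1, 5)), 0.4)
  # fresh slice of an untouched (what, when) is all zero
  expect_true(all(as.vector(query(mem, what = "shrimp", when = 2)) == 0))
  # snapshot: further updates leave the old slice alone
  mem2 <- delta_update(mem, 0, 1, 5, r = 4, alpha = 0.1)
  expect_equal(as.vector(v)[6], 0.4)
  expect_error(query(mem, what = 5), "out of bounds")
  expect_error(query(mem, when = 3), "out of bounds")
})

test_that("delta_update follows the learning rule and is local", {
  mem <- make_memory(2, 3, 64)
  m1 <- delta_update(mem, 1, 2, 42, r = 4, alpha = 0.10)
  expect_equal(as.numeric(query(m1, 1, 2, 42)), 0.4)  # 0 + 0.1 * (4 - 0)
  expect_equal(sum(unclass(m1) != unclass(mem)), 1)    # exactly one entry
  # second update continues the recursion
  m2 <- delta_update(m1, 1, 2, 42, r = 4, alpha = 0.3)
  expect_equal(as.numeric(query(m2, 1, 2, 42)), 0.4 + 0.3 * (4 - 0.4))
  # fixed point: old value equal to the reward is unchanged
  m3 <- m1
  m3[2, 3, 43] <- 4
  m3 <- delta_update(m3, 1, 2, 42, r = 4, alpha = 0.5)
  expect_equal(as.numeric(query(m3, 1, 2, 42)), 4)
  expect_error(delta_update(mem, 0, 0, 0, r = 1, alpha = 0), "alpha")
  expect_error(delta_update(mem, 0, 0, 0, r = 1, alpha = 1.2), "alpha")
})

test_that("n repeated updates from 0 equal the closed-form geometric sum", {
  # oracle: iterate the recursion explicitly, compare to r * (1 - (1-a)^n)
  for (case in list(list(r = 4, a = 0.10, n = 25),
                    list(r = -8, a = 0.37, n = 40),
                    list(r = 1, a = 1.0, n = 3))) {
    v <- 0
    mem <- make_memory(1, 1, 1)
    for (i in seq_len(case$n)) {
      v <- v + case$a * (case$r - v)
      mem <- delta_update(mem, 0, 0, 0, r = case$r, alpha = case$a)
    }
    closed <- case$r * (1 - (1 - case$a)^case$n)
    expect_equal(v, closed, tolerance = 1e-12)
    expect_equal(as.numeric(query(mem, 0, 0, 0)), closed, tolerance = 1e-12)
  }
})

test_that("values stay bounded by the extreme rewards under any sequence", {
  set.seed(7)
  rewards <- c(-8, 0, 1, 4)
  mem <- make_memory(1, 1, 4)
  for (i in 1:500) {
    mem <- delta_update(mem, 0, 0, sample(0:3, 1),
                        r = sample(rewards, 1),
                        alpha = stats::runif(1, 0.01, 1))
  }
  expect_true(all(unclass(mem) >= -8 & unclass(mem) <= 4))
})

test_that("softmax probabilities match closed forms and stay normalized", {
  expect_equal(softmax_probs(c(1, 1), beta = 1), c(0.5, 0.5))
  expect_equal(softmax_probs(c(0, log(3)), beta = 1), c(0.25, 0.75))
  expect_equal(softmax_probs(c(-3, 12, 0.4), beta = 0), rep(1 / 3, 3))
  set.seed(3)
  for (i in 1:25) {
    v <- stats::rnorm(sample(2:6, 1), sd = 5)
    p <- softmax_probs(v, beta = stats::runif(1, 0, 3))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # max-subtraction: huge summed values must not overflow
  expect_equal(softmax_probs(c(1000, 1000)), c(0.5, 0.5))
  expect_error(softmax_probs(numeric(0)), "empty")
  expect_error(softmax_probs(c(1, Inf)), "finite")
})

test_that("empirical softmax choice frequencies match analytic probabilities", {
  set.seed(123)
  v <- c(0, log(3))
  n <- 100000
  draws <- vapply(seq_len(n), function(i) softmax_choice(v, beta = 1),
                  integer(1))
  p_hat <- mean(draws == 2L)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(p_hat - 0.75), 3 * se)
})

test_that("argmax_cell returns the smallest flat index attaining the max", {
  mem <- make_memory(2, 3, 64)
  expect_identical(argmax_cell(mem, 0, 0), 0L)          # all-zero tie-break
  mem[1, 1, 43] <- 2.5                                   # cell 42
  # linear-scan oracle
  expect_identical(argmax_cell(mem, 0, 0),
                   as.integer(which(unclass(mem)[1, 1, ] ==
                                      max(unclass(mem)[1, 1, ]))[1] - 1))
  expect_identical(argmax_cell(mem, 0, 0), 42L)
  mem[1, 1, 8] <- 2.5; mem[1, 1, 10] <- 2.5              # ties at 7 and 9
  mem[1, 1, 43] <- 0
  expect_identical(argmax_cell(mem, 0, 0), 7L)
})

test_that("summed_value is a signed loop-sum over the selected cells", {
  mem <- make_memory(2, 3, 64)
  expect_identical(summed_value(mem, 0, 0, 0:63), 0)
  expect_identical(summed_value(mem, 0, 0, integer(0)), 0)
  mem[1, 1, 6] <- 0.4; mem[1, 1, 10] <- 1.0
  cells <- c(1, 5, 9, 13)
  oracle <- 0
  for (cc in cells) oracle <- oracle + unclass(mem)[1, 1, cc + 1]
  expect_equal(summed_value(mem, 0, 0, cells), oracle)
  expect_equal(summed_value(mem, 0, 0, cells), 1.4)
  expect_equal(summed_value(mem, 0, 0, c(2, 3)), 0)     # excludes nonzeros
  mem[1, 1, 11] <- -8
  expect_equal(summed_value(mem, 0, 0, c(5, 9, 10)), 0.4 + 1 - 8)
})

test_that("landscape enumerates nonzero entries with coordinates", {
  mem <- make_memory(2, 6, 144, what_names = c("crab", "shrimp"),
                     width = 12, height = 12)
  expect_identical(nrow(landscape(mem)), 0L)
  mem <- delta_update(mem, "shrimp", 3, 42, r = 4, alpha = 0.1)
  ls1 <- landscape(mem)
  expect_identical(nrow(ls1), 1L)
  expect_equal(ls1$what, "shrimp")
  expect_equal(ls1$when, 3)
  expect_equal(ls1$cell, 42)
  expect_equal(ls1$x, 42 %% 12)
  expect_equal(ls1$y, 42 %/% 12)
  mem[1, 1, 1] <- -8
  ls2 <- landscape(mem)
  expect_equal(ls2$magnitude[ls2$value == -8], 8)
  # sorted by (when, what, cell)
  expect_false(is.unsorted(ls2$when))
})
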