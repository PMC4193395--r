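qp_of <- function(p, d) {
  structure(list(p = p, d = d, qp = 100 * sqrt(p * d),
                 n_events = 10, n_movements = 5, combine = "geometric"),
            class = "qp_result")
}

test_that("trees group leaves by module with deterministic order", {
  tree <- build_tree(list(
    "kinematic.y" = qp_of(0.9, 0.8),
    "eeg.C3" = qp_of(0.8, 0.9),
    "kinematic.x" = qp_of(0.5, 0.5),
    "coherence.C3xbiceps.01" = qp_of(0.3, 0.2)
  ))
  expect_s3_class(tree, "probability_tree")
  expect_equal(tree$module, c("coherence", "eeg", "kinematic", "kinematic"))
  expect_equal(tree$source[tree$module == "kinematic"], c("x", "y"))

  single <- build_tree(list("eeg.CZ" = qp_of(1, 1)))
  expect_equal(nrow(single), 1)

  expect_error(build_tree(list("eeg.C3" = qp_of(1, 1),
                               "eeg.C3" = qp_of(0.5, 1))),
               "duplicate")
})

test_that("combining a predictor with itself is idempotent", {
  mov <- tibble::tibble(extended_start = c(5000, 15000),
                        start = c(5000, 15000), end = c(7000, 17000))
  ev <- c(3500, 14200, 20000)
  for (mode in c("union", "intersection")) {
    res <- combine_predictors(list(ev, ev), mov, mode = mode)
    expect_equal(tidy(res), tidy(combine_predictors(list(ev), mov,
                                                    mode = mode)))
  }
  expect_error(combine_predictors(list(), mov), "at least one")
})

test_that("union with a spurious predictor dilutes precision", {
  mov <- tibble::tibble(extended_start = c(5000, 15000),
                        start = c(5000, 15000), end = c(7000, 17000))
  perfect <- c(3500, 14200)            # both in pre-windows
  spurious <- c(8000, 9000, 20000)     # none in any span
  alone <- combine_predictors(list(perfect), mov)
  both <- combine_predictors(list(perfect, spurious), mov)
  expect_equal(alone$qp, 100)
  expect_lt(both$p, alone$p)
  expect_equal(both$d, alone$d)
  expect_lt(both$qp, alone$qp)
})

test_that("union never decreases d; intersection never increases it", {
  set.seed(55)
  mov <- tibble::tibble(extended_start = (1:5) * 9000,
                        start = (1:5) * 9000, end = (1:5) * 9000 + 2000)
  for (rep in 1:200) {
    a <- sort(runif(sample(1:8, 1), 0, 50000))
    b <- sort(runif(sample(1:8, 1), 0, 50000))
    da <- combine_predictors(list(a), mov)$d
    db <- combine_predictors(list(b), mov)$d
    du <- combine_predictors(list(a, b), mov, mode = "union")$d
    # at zero tolerance intersection events are a subset of every stream,
    # so d cannot grow (a nonzero tolerance can move the kept event time
    # across a span edge)
    di <- combine_predictors(list(a, b), mov, mode = "intersection",
                             tol_ms = 0)$d
    expect_gte(du, max(da, db) - 1e-12)
    expect_lte(di, min(da, db) + 1e-12)
  }
})

test_that("two-predictor unions match leaf-by-leaf recomputation", {
  set.seed(56)
  mov <- tibble::tibble(extended_start = (1:4) * 9000,
                        start = (1:4) * 9000, end = (1:4) * 9000 + 2000)
  pre <- premovement_window(mov$start)
  sets <- replicate(4, sort(runif(5, 0, 40000)), simplify = FALSE)
  for (i in 1:3) for (j in (i + 1):4) {
    res <- combine_predictors(sets[c(i, j)], mov, mode = "union",
                              dedup_ms = 0)
    merged <- sort(c(sets[[i]], sets[[j]]))
    tp <- sum(vapply(merged, function(t) {
      any(t >= pre$pre_start & t < pre$pre_end)
    }, logical(1)))
    expect_equal(res$p, tp / length(merged))
  }
})

test_that("ranking is a stable total order with documented tie-breaks", {
  tree <- build_tree(tibble::tibble(
    module = c("eeg", "kinematic", "fusion"),
    source = c("C3", "y", "C3+y"),
    p = c(0.8, 0.7, 0.75), d = c(0.8, 0.7, 0.75),
    qp = c(80, 70, 75)
  ))
  r <- rank_tree(tree)
  expect_equal(r$qp, c(80, 75, 70))
  expect_equal(r$rank, 1:3)
  expect_equal(r$set_size, c(1, 2, 1))

  # ties break by smaller set, then lexicographic source
  tied <- build_tree(tibble::tibble(
    module = c("a", "a", "a"), source = c("q+r", "b", "a"),
    p = 0.5, d = 0.5, qp = c(70, 70, 70)))
  rt <- rank_tree(tied)
  expect_equal(rt$source, c("a", "b", "q+r"))
  expect_identical(rank_tree(tied), rank_tree(tied))

  top1 <- rank_tree(tree, top_k = 1)
  expect_equal(nrow(top1), 1)
  expect_equal(top1$qp, 80)
})

test_that("a dominating single axis outranks its combination on fixtures", {
  mov <- tibble::tibble(extended_start = c(5000, 15000, 25000),
                        start = c(5000, 15000, 25000),
                        end = c(5000, 15000, 25000) + 2000)
  ev_y <- c(3500, 14200, 24100)        # perfect
  ev_x <- c(3600, 8000, 20000)         # one TP, two FP
  qp_y <- combine_predictors(list(ev_y), mov)
  qp_xy <- combine_predictors(list(ev_y, ev_x), mov)
  tree <- build_tree(tibble::tibble(
    module = c("kinematic", "kinematic"),
    source = c("y", "x+y"),
    p = c(qp_y$p, qp_xy$p), d = c(qp_y$d, qp_xy$d),
    qp = c(qp_y$qp, qp_xy$qp)))
  r <- rank_tree(tree)
  expect_equal(r$source[1], "y")
})
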