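test_that("neighbourhood schedule follows the linear shrink rule", {
  expect_equal(neighbourhood_size(0, 2, 10), 3)
  expect_equal(neighbourhood_size(5, 2, 10), 2)
  expect_equal(neighbourhood_size(10, 2, 10), 1)
  expect_equal(neighbourhood_size(7, 3.5, 7), 1)
  expect_error(neighbourhood_size(11, 2, 10), "\\[0, n\\]")
  expect_error(neighbourhood_size(-1, 2, 10), "\\[0, n\\]")
})

test_that("PCA initialization spans the leading principal plane", {
  # data exactly in a 2D plane: every initial node lies in that plane
  set.seed(4)
  basis <- qr.Q(qr(matrix(rnorm(16), 4)))[, 1:2]
  coords <- matrix(rnorm(60, sd = c(8, 3)), ncol = 2, byrow = TRUE)
  st <- score_table(100 + coords %*% t(basis), sprintf("a%d", 1:30),
                    default_tasks())
  W <- initialize_weights(st, som_config())
  centered <- sweep(W, 2L, colMeans(st$scores))
  resid <- centered - centered %*% basis %*% t(basis)
  expect_lt(max(abs(resid)), 1e-9)

  # corner nodes sit at mean +/- 2 sqrt(lambda) u along each component
  st2 <- random_table(40, seed = 7, tasks = default_tasks())
  cfg <- som_config()
  W2 <- initialize_weights(st2, cfg)
  eg <- eigen(cov(st2$scores), symmetric = TRUE)
  u1 <- eg$vectors[, 1]; u1 <- u1 * sign(u1[which.max(abs(u1))])
  u2 <- eg$vectors[, 2]; u2 <- u2 * sign(u2[which.max(abs(u2))])
  mu <- colMeans(st2$scores)
  corner_11 <- mu - 2 * sqrt(eg$values[1]) * u1 - 2 * sqrt(eg$values[2]) * u2
  corner_88 <- mu + 2 * sqrt(eg$values[1]) * u1 + 2 * sqrt(eg$values[2]) * u2
  expect_equal(unname(W2[1, ]), unname(corner_11))
  expect_equal(unname(W2[64, ]), unname(corner_88))

  # zero-variance data: mean plus tiny jitter fallback
  flat <- score_table(matrix(100, 10, 4), sprintf("b%d", 1:10), default_tasks())
  expect_warning(W3 <- initialize_weights(flat, som_config()), "rank")
  expect_lt(max(abs(W3 - 100)), 1e-2)
})

test_that("best_matching_unit equals the brute-force argmin with tie rule", {
  set.seed(12)
  W <- matrix(rnorm(64 * 4, 100, 15), 64)
  expect_identical(best_matching_unit(W[7, ], W), 7L)

  # tie: two nodes equidistant -> lower row-major index
  W2 <- rbind(c(10, 10), c(2, 0), c(0, 2), c(5, 5))
  expect_identical(best_matching_unit(c(1, 1), W2), 2L)

  for (i in 1:100) {
    W <- matrix(rnorm(16 * 3), 16)
    x <- rnorm(3)
    expect_identical(best_matching_unit(x, W), bmu_brute(x, W))
  }
  expect_error(best_matching_unit(c(1, 2), matrix(0, 4, 3)), "dimension")
})

test_that("batch training collapses onto the data in degenerate cases", {
  # identical rows: quantization error exactly 0
  st <- score_table(matrix(rep(c(90, 110, 95, 100), each = 8), 8),
                    sprintf("p%d", 1:8), default_tasks())
  expect_warning(m <- batch_train(st, som_config(grid_rows = 2, grid_cols = 2,
                                                 ordering_steps = 2,
                                                 fine_tune_steps = 1)),
                 "rank")
  expect_equal(m$quantization_error, 0)

  # 2x2 grid, four well-separated points (distinct x/y spans so the PCA
  # init lands each node nearest its own point), fine-tuning only:
  # each node converges exactly to its point, QE 0
  pts <- rbind(c(0, 0), c(0, 60), c(200, 0), c(200, 60))
  st2 <- score_table(pts, sprintf("q%d", 1:4), c("t1", "t2"))
  m2 <- batch_train(st2, som_config(grid_rows = 2, grid_cols = 2,
                                    ordering_steps = 0, fine_tune_steps = 5))
  expect_equal(m2$quantization_error, 0, tolerance = 1e-12)
  ordm <- order(m2$weights[, 1], m2$weights[, 2])
  ordp <- order(pts[, 1], pts[, 2])
  expect_equal(unname(m2$weights[ordm, ]), pts[ordp, ], tolerance = 1e-12)
})

test_that("one batch cycle equals the explicit-loop reimplementation", {
  for (i in 1:100) {
    set.seed(900 + i)
    cfg <- som_config(grid_rows = sample(2:4, 1), grid_cols = sample(2:4, 1))
    n_nodes <- cfg$grid_rows * cfg$grid_cols
    W <- matrix(rnorm(n_nodes * 3, 100, 15), n_nodes)
    X <- matrix(rnorm(12 * 3, 100, 15), 12)
    gdist <- cogsom:::grid_distance_matrix(cfg)
    r <- sample(c(0, 1, 2), 1)
    expect_equal(cogsom:::batch_cycle(X, W, gdist, r),
                 batch_cycle_brute(X, W, gdist, r), tolerance = 1e-12)
  }
})

test_that("quantization error equals the direct per-row average", {
  st <- random_table(25, seed = 31, tasks = default_tasks())
  m <- batch_train(st, som_config(grid_rows = 4, grid_cols = 4))
  expect_equal(quantization_error(m, st),
               quantization_error_brute(m$weights, st$scores),
               tolerance = 1e-6)
  # single input at distance 5 from its BMU
  mdl <- model_from_weights(outer(c(0, 10, 20, 30), rep(1, 4)), 2, 2,
                            tasks = default_tasks())
  one <- score_table(matrix(c(5, 0, 0, 0), 1), "z", default_tasks())
  expect_equal(quantization_error(mdl, one), 5)
})

test_that("component planes are exactly the weight columns", {
  W <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 4, 2)
  m <- model_from_weights(W, 2, 2, tasks = c("u", "v"))
  planes <- component_planes(m)
  expect_named(planes, c("u", "v"))
  expect_equal(planes$u, c(1, 2, 3, 4))
  expect_equal(planes$v, c(10, 20, 30, 40))
  expect_equal(do.call(cbind, planes), unname(m$weights), ignore_attr = TRUE)
})

test_that("training is deterministic and JSON serialization is bit-exact", {
  st <- random_table(80, seed = 42, tasks = default_tasks())
  m1 <- batch_train(st, som_config())
  m2 <- batch_train(st, som_config())
  expect_identical(m1$weights, m2$weights)

  path <- withr::local_tempfile(fileext = ".json")
  write_som(m1, path)
  back <- read_som(path)
  expect_identical(unname(back$weights), unname(m1$weights))
  expect_identical(back$task_names, m1$task_names)
  expect_identical(back$quantization_error, m1$quantization_error)
  expect_identical(unclass(back$config), unclass(m1$config))
})

test_that("training reduces quantization error below the initialization", {
  for (s in 1:5) {
    st <- simulate_baseline_cohort(default_baseline_spec(n_participants = 150,
                                                         seed = 60 + s))
    cfg <- som_config()
    m <- batch_train(st, cfg)
    init <- model_from_weights(initialize_weights(st, cfg), 8, 8,
                               tasks = st$task_names)
    expect_lt(m$quantization_error, quantization_error(init, st))
    expect_true(all(is.finite(m$weights)))
  }
})

test_that("well-separated profiles occupy disjoint connected lattice regions", {
  set.seed(77)
  n <- 120
  grp <- rep(1:2, each = n / 2)
  centers <- rbind(c(70, 70, 70, 70), c(130, 130, 130, 130))
  st <- score_table(centers[grp, ] + matrix(rnorm(n * 4, 0, 3), n),
                    sprintf("s%d", 1:n), default_tasks())
  m <- batch_train(st, som_config())
  bmu <- map_to_bmus(m, st)
  nodes1 <- unique(bmu[grp == 1]); nodes2 <- unique(bmu[grp == 2])
  expect_length(intersect(nodes1, nodes2), 0)

  # connectivity under Chebyshev (8-neighbour) adjacency
  connected <- function(nodes, cfg) {
    gd <- cogsom:::grid_distance_matrix(cfg)
    seen <- nodes[1]; frontier <- nodes[1]
    while (length(frontier)) {
      nb <- nodes[apply(gd[frontier, nodes, drop = FALSE] <= 1, 2, any)]
      frontier <- setdiff(nb, seen)
      seen <- union(seen, frontier)
    }
    setequal(seen, nodes)
  }
  expect_true(connected(nodes1, m$config))
  expect_true(connected(nodes2, m$config))
})
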