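test_that("consistent matrices yield their generating weights and lambda = n", {
  m <- pcm(rbind(c(1, 2, 4), c(1/2, 1, 2), c(1/4, 1/2, 1)))
  res <- ahp_weights(m)
  expect_equal(res$weights, c(4, 2, 1) / 7, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$lambda_max, 3, tolerance = 1e-9)

  ones <- pcm(matrix(1, 5, 5))
  res5 <- ahp_weights(ones)
  expect_equal(res5$weights, rep(1/5, 5), ignore_attr = TRUE)
  expect_equal(res5$lambda_max, 5, tolerance = 1e-9)
})

test_that("published domain weight vector is recovered from its consistent matrix", {
  w <- c(safety = 0.3855, effectiveness = 0.2885, economics = 0.0965,
         innovation = 0.0824, accessibility = 0.0784, applicability = 0.0688)
  m <- consistent_pcm(w / sum(w))
  res <- ahp_weights(m)
  expect_equal(res$weights, w / sum(w), tolerance = 1e-8)
  expect_equal(names(which.max(res$weights)), "safety")
})

test_that("eigenvector recovery holds for random weight vectors up to n = 10", {
  set.seed(11)
  for (n in c(3, 5, 8, 10)) {
    for (rep in 1:10) {
      w <- exp(pmin(1, pmax(-1, rnorm(n, 0, 0.7)))); w <- w / sum(w)
      res <- ahp_weights(consistent_pcm(w))
      expect_equal(res$weights, w, tolerance = 1e-8, ignore_attr = TRUE)
      # geometric-mean route agrees on consistent matrices
      expect_equal(ahp_weights(consistent_pcm(w), method = "geometric")$weights,
                   w, tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("consistent row/column rescaling leaves weights unchanged", {
  w <- c(0.4, 0.35, 0.15, 0.1)
  m <- unclass(consistent_pcm(w))
  # doubling element 2's weight: scale its row by 2 and column by 1/2
  m2 <- m; m2[2, ] <- m2[2, ] * 2; m2[, 2] <- m2[, 2] / 2; diag(m2) <- 1
  w2 <- ahp_weights(pcm(m2, permissive = TRUE))$weights
  expected <- c(0.4, 0.7, 0.15, 0.1); expected <- expected / sum(expected)
  expect_equal(w2, expected, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("power-iteration lambda_max matches a dense eigensolver", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    p <- random_pcm(n)
    res <- ahp_weights(p)
    orc <- oracle_eigen(unclass(p))
    expect_equal(res$lambda_max, orc$lambda, tolerance = 1e-8)
    expect_equal(res$weights, orc$weights, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("consistency report implements CI/CR with the random-index table", {
  m <- pcm(rbind(c(1, 2, 4), c(1/2, 1, 2), c(1/4, 1/2, 1)))
  rep <- ahp_consistency(m)
  expect_equal(rep$consistency_index, 0, tolerance = 1e-9)
  expect_equal(rep$consistency_ratio, 0, tolerance = 1e-9)
  expect_true(rep$acceptable)

  # inconsistent example checked against the characteristic-polynomial oracle
  m2 <- pcm(rbind(c(1, 2, 1/2), c(1/2, 1, 4), c(2, 1/4, 1)))
  rep2 <- ahp_consistency(m2)
  lam <- oracle_lambda_3x3(unclass(m2))
  expect_equal(rep2$lambda_max, lam, tolerance = 1e-8)
  expect_equal(rep2$consistency_ratio, (lam - 3) / 2 / 0.58, tolerance = 1e-8)

  # reciprocal 2x2 matrices are consistent by construction
  rep22 <- ahp_consistency(pcm(rbind(c(1, 5), c(1/5, 1))))
  expect_equal(rep22$consistency_ratio, 0)
  expect_true(rep22$acceptable)

  expect_error(ahp_consistency(pcm(matrix(1, 16, 16))), "random index")
})

test_that("CR grows monotonically with a single off-diagonal perturbation", {
  for (n in 3:6) {
    w <- seq(n, 1) / sum(seq(n, 1))
    crs <- vapply(c(1.5, 2.5, 4), function(phi) {
      m <- unclass(consistent_pcm(w))
      m[1, 2] <- m[1, 2] * phi
      m[2, 1] <- 1 / m[1, 2]
      ahp_consistency(pcm(m, permissive = TRUE))$consistency_ratio
    }, numeric(1))
    expect_equal(ahp_consistency(consistent_pcm(w))$consistency_ratio, 0,
                 tolerance = 1e-9)
    expect_true(all(diff(crs) > 0))
  }
})

test_that("group aggregation is the (weighted) geometric mean and idempotent", {
  base <- pcm(rbind(c(1, 2), c(1/2, 1)))
  expect_equal(unclass(aggregate_judgments(list(base, base, base))),
               unclass(base), tolerance = 1e-12)

  m2 <- pcm(rbind(c(1, 2), c(1/2, 1)))
  m8 <- pcm(rbind(c(1, 8), c(1/8, 1)))
  expect_equal(aggregate_judgments(list(m2, m8))[1, 2], 4)
  # u = (0.9, 0.3) normalizes to (0.75, 0.25): 2^0.75 * 8^0.25 = 2^1.5
  weighted <- aggregate_judgments(list(m2, m8), expert_weights = c(0.9, 0.3))
  expect_equal(weighted[1, 2], 2^1.5, tolerance = 1e-12)

  expect_error(aggregate_judgments(list()), "non-empty")
  expect_error(aggregate_judgments(list(m2, pcm(matrix(1, 3, 3)))),
               "same order")
})

test_that("authority coefficients are the Ca/Cs mean with panel flagging", {
  expect_equal(authority_coefficient(0.9, 0.8), 0.85)
  expect_equal(authority_coefficient(1, 1), 1)
  expect_error(authority_coefficient(1.2, 0.5), "\\[0, 1\\]")

  roster <- data.frame(expert_id = paste0("E", 1:3),
                       ca = c(0.9, 0.95, 0.85), cs = c(0.9, 0.8, 0.9))
  out <- panel_authority(roster)
  expect_true(all(out$cr > 0.8))
  expect_true(attr(out, "authoritative"))
  roster$cs[1] <- 0.5
  expect_false(attr(panel_authority(roster), "authoritative"))
})
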