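test_that("majority vote takes the mode and defaults on abstain/tie", {
  L <- rbind(c(1L, 1L, 0L),    # mode 1
             c(-1L, -1L, -1L), # all abstain -> default
             c(1L, 0L, -1L),   # tie -> default
             c(0L, 0L, 1L))
  expect_equal(majority_vote(L, default_class = 0L), c(1L, 0L, 0L, 0L))
  expect_equal(majority_vote(L, default_class = 1L)[2:3], c(1L, 1L))
})

test_that("pairwise moments match their definition and flag sparse pairs", {
  B <- cbind(c(1, 1, -1, 1), c(1, 1, -1, 1))        # identical
  expect_equal(pairwise_moments(B, 1)$M[1, 2], 1)
  B2 <- cbind(c(1, -1, 1), c(-1, 1, -1))            # always opposite
  expect_equal(pairwise_moments(B2, 1)$M[1, 2], -1)
  B3 <- cbind(c(1, 0, 0), c(0, 1, 0))               # zero overlap
  mom <- pairwise_moments(B3, 1)
  expect_true(is.nan(mom$M[1, 2]))
  expect_false(mom$reliable[1, 2])
})

test_that("empirical moments equal accuracy products (Monte Carlo)", {
  # accuracies 0.9, 0.8 on the probability scale are 0.8, 0.6 on +/-1;
  # the co-vote moment converges to their product 0.48
  g <- generate_label_matrix(50000, c(0.9, 0.8, 0.7), rep(0, 3), seed = 99)
  B <- weakner:::binarize_class(g$L, 1L)
  mom <- pairwise_moments(B)
  expect_equal(mom$M[1, 2], 0.48, tolerance = 0.02 / 0.48)
  expect_equal(mom$M[1, 3], 0.8 * 0.4, tolerance = 0.1)
  expect_equal(mom$M[2, 3], 0.6 * 0.4, tolerance = 0.1)
})

test_that("triplet estimates recover accuracies from moments", {
  # identical columns -> accuracies clamp at the ceiling
  B <- cbind(rep(c(1, -1), 25), rep(c(1, -1), 25), rep(c(1, -1), 25))
  a <- triplet_accuracies(pairwise_moments(B))
  expect_equal(as.numeric(a), rep(0.98, 3))
  # simulated accuracies 0.9/0.8/0.7 prob scale = 0.8/0.6/0.4 on +/-1
  g <- generate_label_matrix(50000, c(0.9, 0.8, 0.7), rep(0, 3), seed = 1)
  a2 <- triplet_accuracies(pairwise_moments(weakner:::binarize_class(g$L, 1L)))
  expect_equal(as.numeric(a2), c(0.8, 0.6, 0.4), tolerance = 0.05 / 0.4)
  # near-zero denominator triplets are skipped
  M <- diag(3); M[1, 2] <- M[2, 1] <- 0.5; M[1, 3] <- M[3, 1] <- 0.5
  M[2, 3] <- M[3, 2] <- 0.001
  mom <- list(M = M, reliable = matrix(TRUE, 3, 3))
  a3 <- triplet_accuracies(mom, prior_acc = 0.7)
  expect_equal(attr(a3, "n_triplets")[1], 0L)   # only the degenerate triplet
  expect_equal(as.numeric(a3)[1], 0.4)          # falls back to the prior
})

test_that("fit_label_model recovers simulated accuracies within 0.05", {
  set.seed(21)
  acc <- runif(10, 0.55, 0.95)
  g <- generate_label_matrix(10000, acc, rep(0.3, 10), seed = 22)
  fit <- fit_label_model(g$L, k = 1)
  expect_lt(max(abs(fit$acc[, "1"] - acc)), 0.05)
  # all LFs identical: posterior saturates toward their votes
  L <- matrix(rep(g$L[, 1], 3), ncol = 3)
  fit2 <- fit_label_model(L, k = 1)
  post <- posterior_probs(fit2, L)
  voted1 <- L[, 1] == 1L
  expect_true(all(post$probs[voted1, "1"] > 0.95))
  # refinement disabled reproduces the closed-form triplet estimates
  fit3 <- fit_label_model(g$L, k = 1, config = list(refine = FALSE))
  B <- weakner:::binarize_class(g$L, 1L)
  a <- triplet_accuracies(pairwise_moments(B))
  expect_equal(unname(fit3$acc[, "1"]), (1 + as.numeric(a)) / 2)
  # < 3 LFs falls back to the uniform prior with a warning
  expect_warning(fit4 <- fit_label_model(g$L[, 1:2], k = 1), "fewer than 3")
  expect_true(all(fit4$acc == 0.7))
})

test_that("posterior matches the closed-form Bayes oracle", {
  # three sources at 0.9, all voting class 1, uniform prior
  m <- label_model(c(0.9, 0.9, 0.9), k = 1)
  p <- posterior_probs(m, matrix(c(1L, 1L, 1L), 1))$probs
  expect_equal(unname(p[1, "1"]), 0.9^3 / (0.9^3 + 0.1^3), tolerance = 1e-9)
  # votes (1, 1, 0) at accuracy 0.8 -> 0.128 / 0.160 = 0.8
  m2 <- label_model(c(0.8, 0.8, 0.8), k = 1)
  p2 <- posterior_probs(m2, matrix(c(1L, 1L, 0L), 1))$probs
  expect_equal(unname(p2[1, "1"]), 0.8, tolerance = 1e-9)
  # all abstain -> class prior
  m3 <- label_model(c(0.8, 0.8), k = 1, class_prior = c(0.7, 0.3))
  p3 <- posterior_probs(m3, matrix(c(-1L, -1L), 1))
  expect_equal(unname(p3$probs[1, ]), c(0.7, 0.3))
  expect_false(p3$covered[1])
})

test_that("posterior equals brute-force enumeration on all 3-source multiclass configs", {
  acc <- c(0.85, 0.7, 0.6)
  prior <- c(0.5, 0.3, 0.2)
  prop <- c(0.8, 0.9, 0.7)
  model <- label_model(acc, k = 2, class_prior = prior)
  votes <- as.matrix(expand.grid(-1:2, -1:2, -1:2))
  storage.mode(votes) <- "integer"
  post <- posterior_probs(model, votes)$probs
  for (r in seq_len(nrow(votes))) {
    expect_equal(unname(post[r, ]),
                 brute_force_posterior(votes[r, ], acc, prior, prop),
                 tolerance = 1e-9)
  }
})

test_that("posterior rows normalize and predict ignores column order", {
  g <- generate_label_matrix(500, c(0.9, 0.7, 0.6, 0.8), rep(0.3, 4),
                             class_balance = c(0.4, 0.3, 0.3), seed = 5)
  fit <- fit_label_model(g$L, k = 2)
  post <- posterior_probs(fit, g$L)
  expect_true(all(abs(rowSums(post$probs) - 1) < 1e-9))
  pred <- predict(fit, g$L)
  perm <- c(3, 1, 4, 2)
  fitp <- fit_label_model(g$L[, perm], k = 2)
  expect_equal(predict(fitp, g$L[, perm]), pred)
})

test_that("estimated accuracy responds monotonically to true accuracy", {
  grid <- seq(0.55, 0.95, by = 0.1)
  est <- vapply(seq_along(grid), function(i) {
    g <- generate_label_matrix(8000, c(grid[i], 0.8, 0.75, 0.7),
                               rep(0.2, 4), seed = 300 + i)
    fit_label_model(g$L, k = 1)$acc[1, "1"]
  }, numeric(1))
  # trend: increasing over the grid beyond simulation noise
  expect_gt(stats::cor(grid, est, method = "spearman"), 0.9)
  expect_gt(est[length(est)], est[1])
})

test_that("probabilistic labels survive a JSONL round trip", {
  g <- generate_label_matrix(12, c(0.9, 0.8, 0.7), rep(0.2, 3), seed = 8)
  fit <- fit_label_model(g$L, k = 1)
  post <- posterior_probs(fit, g$L)
  index <- data.frame(doc_id = rep(c("a", "b"), each = 6),
                      sent_index = rep(c(1L, 2L), each = 3),
                      token_index = rep(1:3, 4))
  tmp <- tempfile(fileext = ".jsonl")
  write_problabels(post, index, tmp)
  back <- read_problabels(tmp)
  expect_equal(unname(back$probs), unname(post$probs), tolerance = 1e-12)
  expect_equal(back$covered, post$covered)
})
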