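test_that("pair loss evaluates the mean binary cross-entropy", {
  expect_lt(pair_loss(1, 1 - 1e-7), 1e-6)
  expect_equal(pair_loss(1, 0.5), log(2), tolerance = 1e-9)
  # scalar-loop oracle
  labels <- c(1, 0); probs <- c(0.9, 0.1)
  want <- mean(c(-log(0.9), -log(1 - 0.1)))
  expect_equal(pair_loss(labels, probs), want, tolerance = 1e-9)
  expect_error(pair_loss(c(1, 0), 0.5), "same length")
  # clipping keeps extreme probabilities finite
  expect_true(is.finite(pair_loss(c(1, 0), c(0, 1))))
})

test_that("residue loss averages per sample over unmasked positions only", {
  # hand case: one sample, mask (1,1,0), labels (1,0,.), probs (0.5,0.5,.)
  lab <- matrix(c(1, 0, 0), 1)
  pr <- matrix(c(0.5, 0.5, 0.123), 1)
  m <- matrix(c(1, 1, 0), 1)
  expect_equal(residue_loss(lab, pr, m), log(2), tolerance = 1e-9)

  # perfect predictions give ~0
  eps <- 1e-7
  lab2 <- matrix(c(1, 0, 1, 0), 2)
  pr2 <- matrix(c(1 - eps, eps, 1 - eps, eps), 2)
  m2 <- matrix(1, 2, 2)
  expect_lt(residue_loss(lab2, pr2, m2), 1e-5)

  # masked positions are inert: arbitrary labels and probs there change nothing
  set.seed(2)
  for (r in 1:100) {
    n <- sample(1:4, 1); L <- sample(3:8, 1)
    lab <- matrix(rbinom(n * L, 1, 0.4), n, L)
    pr <- matrix(runif(n * L), n, L)
    m <- matrix(rbinom(n * L, 1, 0.6), n, L)
    base <- residue_loss(lab, pr, m)
    lab2 <- lab; pr2 <- pr
    masked <- which(m == 0)
    if (length(masked)) {
      lab2[masked] <- rbinom(length(masked), 1, 0.5)
      pr2[masked] <- runif(length(masked))
    }
    expect_equal(residue_loss(lab2, pr2, m), base, tolerance = 1e-12)
  }

  # a sample with no unmasked position contributes zero
  m3 <- rbind(c(1, 1), c(0, 0))
  lab3 <- rbind(c(1, 0), c(1, 1))
  pr3 <- rbind(c(0.5, 0.5), c(0.9, 0.9))
  expect_equal(residue_loss(lab3, pr3, m3), log(2) / 2, tolerance = 1e-9)
})

test_that("total loss decomposes linearly in lambda", {
  expect_equal(total_loss(0.7, 0.3, 0), 0.7)
  expect_equal(total_loss(1, 1, 1), 2)
  set.seed(3)
  for (r in 1:20) {
    lp <- runif(1, 0, 3); lr <- runif(1, 0, 3); lam <- runif(1, 0, 2)
    expect_equal(total_loss(lp, lr, lam), lp + lam * lr, tolerance = 1e-12)
  }
  expect_error(total_loss(1, 1, -0.1), "non-negative")
})

test_that("classification threshold is inclusive at 0.5 for both tasks", {
  expect_identical(classify_pair(0.5), 1L)
  expect_identical(classify_pair(0.4999), 0L)
  expect_identical(classify_pair(1.0), 1L)
  expect_identical(classify_residue(c(0.5, 0.2, 0.8)), c(1L, 0L, 1L))
  expect_error(classify_pair(1.2), "in \\[0, 1\\]")
})

test_that("backpropagation matches finite-difference gradients on a micro model", {
  arch <- tiny_arch()
  fx <- tiny_profiles()
  params <- pepnet_params(arch, seed = 3)
  lambda <- 0.3
  y <- 1
  blab <- c(1, 0, 0, 1, 0, 1, 0, rep(0, 3))
  mask <- fx$pep$mask

  to_params <- function(flat, skel) {
    out <- utils::relist(flat, skeleton = unclass(skel))
    class(out) <- "pepnet_params"
    out
  }
  loss_fn <- function(par) {
    out <- pepnet:::forward_cached(fx$pep, fx$pro, par, arch)
    total_loss(pair_loss(y, out$pair_prob),
               residue_loss(matrix(blab, 1), matrix(out$residue_prob, 1),
                            matrix(mask, 1)),
               lambda)
  }

  cache <- pepnet:::forward_cached(fx$pep, fx$pro, params, arch)
  dres <- lambda * (cache$residue_prob - blab) * mask / sum(mask)
  g <- pepnet:::backward_pair(cache, fx$pep, fx$pro, params, arch,
                              dlogit_pair = cache$pair_prob - y,
                              dres_logit = dres)

  flat <- unlist(unclass(params))
  gflat <- unlist(unclass(g))
  expect_length(gflat, length(flat))

  h <- 1e-5
  set.seed(1)
  samp <- sample(length(flat), 200)
  for (i in samp) {
    fp <- flat; fp[i] <- fp[i] + h
    fm <- flat; fm[i] <- fm[i] - h
    num <- (loss_fn(to_params(fp, params)) - loss_fn(to_params(fm, params))) / (2 * h)
    ana <- gflat[i]
    denom <- max(abs(num), abs(ana))
    if (denom > 1e-6) {
      expect_lt(abs(num - ana) / denom, 1e-4)
    } else {
      expect_lt(abs(num - ana), 1e-8)
    }
  }
})

test_that("training is seeded, reproducible, and respects the loss decomposition", {
  sim <- tiny_dataset(seed = 3, n_pos = 8)
  ctl <- pepnet_control(epochs = 3, seed = 11, batch_size = 8)
  arch <- pepnet_architecture(embed_dim = 3, conv_filters = c(4, 4, 4),
                              conv_kernels = c(3, 3, 3), attention_dim = 3,
                              fc_sizes = c(8, 4), dropout = 0.1, pro_pad = 70)
  f1 <- pepnet(sim$table, arch, ctl)
  f2 <- pepnet(sim$table, arch, ctl)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)

  # loss decomposition holds at every logged epoch
  expect_equal(f1$history$loss_total,
               f1$history$loss_pair + ctl$lambda * f1$history$loss_pep,
               tolerance = 1e-9)

  # a different seed changes the weights
  f3 <- pepnet(sim$table, arch, pepnet_control(epochs = 3, seed = 12, batch_size = 8))
  expect_false(identical(f1$params, f3$params))
})

test_that("with lambda = 0 the residue head receives no gradient", {
  sim <- tiny_dataset(seed = 5, n_pos = 6)
  arch <- pepnet_architecture(embed_dim = 3, conv_filters = c(4, 4, 4),
                              conv_kernels = c(3, 3, 3), attention_dim = 3,
                              fc_sizes = c(8, 4), dropout = 0, pro_pad = 70)
  ctl <- pepnet_control(epochs = 1, seed = 2, lambda = 0, batch_size = 4)
  fit <- pepnet(sim$table, arch, ctl)
  init <- pepnet_params(arch, seed = ctl$seed)
  expect_identical(fit$params$res, init$res)
  # while the pair head did move
  expect_false(identical(fit$params$fc, init$fc))
})

test_that("pairs without residue labels are masked out of the residue loss", {
  sim <- tiny_dataset(seed = 6, n_pos = 6)
  tab <- sim$table
  # strip all binding vectors: residue loss must log as zero
  tab$pairs$bind <- NA_character_
  arch <- pepnet_architecture(embed_dim = 3, conv_filters = c(4, 4, 4),
                              conv_kernels = c(3, 3, 3), attention_dim = 3,
                              fc_sizes = c(8, 4), dropout = 0, pro_pad = 70)
  fit <- pepnet(tab, arch, pepnet_control(epochs = 1, seed = 2, batch_size = 4))
  expect_equal(fit$history$loss_pep, 0)
  # and the residue head stays at initialization despite lambda > 0
  init <- pepnet_params(arch, seed = 2)
  expect_identical(fit$params$res, init$res)
})

test_that("with lambda > 0 held-out residue AUC beats chance across seeds", {
  aucs <- vapply(1:5, function(s) {
    sim <- simulate_interactions(synthetic_config(
      n_positives = 60, ratio = 2, pep_len = c(8L, 20L), pro_len = c(51L, 120L),
      n_families = 3L, n_proteins = 20L, seed = s))
    plan <- make_folds(sim$table, "random", k = 5, seed = s)
    train <- subset_pairs(sim$table, plan$folds[[1]]$train)
    test <- subset_pairs(sim$table, plan$folds[[1]]$test)
    arch <- pepnet_architecture(embed_dim = 4, conv_filters = c(8, 8, 16),
                                conv_kernels = c(7, 5, 3), attention_dim = 8,
                                fc_sizes = c(32, 16), dropout = 0.1,
                                pro_pad = 120)
    fit <- pepnet(train, arch, pepnet_control(epochs = 30, seed = s))
    evaluate_predictions(test, predict(fit, test))$mean_residue_auc
  }, numeric(1))
  pval <- stats::t.test(aucs, mu = 0.5, alternative = "greater")$p.value
  expect_lt(pval, 0.05)
})
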