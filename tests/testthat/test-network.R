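test_that("channel embedding concatenates lookups and zeroes padded rows", {
  arch <- tiny_arch()
  fx <- tiny_profiles()
  params <- pepnet_params(arch, seed = 2)

  U <- channel_embed(fx$pep, params, "peptide")
  expect_equal(dim(U), c(10, 4 * arch$embed_dim))
  expect_true(all(U[8:10, ] == 0))        # 7-residue peptide padded to 10

  # hand-set tables: identity-like rows reproduce the code pattern
  p2 <- params
  d <- arch$embed_dim
  p2$pep$embed$aa <- cbind(0:21, matrix(0, 22, d - 1))
  U2 <- channel_embed(fx$pep, p2, "peptide")
  expect_equal(U2[1:7, 1], fx$pep$aa[1:7])

  # manual concatenation oracle for one row
  i <- 3
  E <- params$pep$embed
  row <- c(E$aa[fx$pep$aa[i] + 1, ], E$ss[fx$pep$ss[i] + 1, ],
           E$polhyd[fx$pep$polhyd[i] + 1, ],
           as.vector(fx$pep$numeric[i, ] %*% E$num$W) + E$num$b)
  expect_equal(U[i, ], row, tolerance = 1e-12)

  # profiles differing only at masked positions embed identically
  pep_b <- fx$pep
  pep_b$aa[9] <- 5L
  pep_b$numeric[9, ] <- 0.7
  expect_equal(channel_embed(pep_b, params, "peptide"), U, tolerance = 1e-12)

  # all-padding-like profile: zero codes and numeric -> zero matrix
  pep_z <- fx$pep
  pep_z$aa[] <- 0L; pep_z$ss[] <- 0L; pep_z$polhyd[] <- 0L
  pep_z$numeric[] <- 0; pep_z$mask[] <- 0L
  expect_true(all(channel_embed(pep_z, params, "peptide") == 0))

  expect_error({
    bad <- fx$pep; bad$aa[1] <- 99L
    channel_embed(bad, params, "peptide")
  }, "out of embedding-table range")
})

test_that("convolution stack matches the sliding-window oracle", {
  set.seed(4)
  L <- 12; D <- 5; C <- 3; k <- 3
  X <- matrix(rnorm(L * D), L, D)
  mask <- rep(1, L)
  layer <- list(W = matrix(rnorm(k * D * C), k * D, C), b = rnorm(C))

  got <- conv_features(X, list(layer), kernels = k, mask = mask)
  want <- pmax(oracle_conv1d(X, layer$W, layer$b, k), 0)
  expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)

  # kernel width 1 with identity filter: ReLU(input)
  id_layer <- list(W = diag(D), b = numeric(D))
  expect_equal(conv_features(X, list(id_layer), kernels = 1, mask = mask),
               pmax(X, 0), tolerance = 1e-12, ignore_attr = TRUE)

  # zero input, zero bias -> zero output through the full stack
  z_layers <- list(layer, list(W = matrix(rnorm(k * C * C), k * C, C), b = numeric(C)))
  z_layers[[1]]$b <- numeric(C)
  expect_true(all(conv_features(matrix(0, L, D), z_layers, c(k, k), mask) == 0))

  expect_error(conv_features(X[1:2, ], list(layer), kernels = k, mask = mask[1:2]),
               "shorter than the widest kernel")

  # repeated oracle equivalence on random instances
  for (r in 1:50) {
    L <- sample(5:15, 1); D <- sample(2:5, 1); C <- sample(2:4, 1)
    k <- sample(c(1, 3, 5), 1)
    if (L < k) L <- k
    X <- matrix(rnorm(L * D), L, D)
    layer <- list(W = matrix(rnorm(k * D * C), k * D, C), b = rnorm(C))
    got <- conv_features(X, list(layer), k, rep(1, L))
    expect_equal(got, pmax(oracle_conv1d(X, layer$W, layer$b, k), 0),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("masked max pooling ignores padded rows", {
  H <- matrix(c(1, 5, 3,
                2, 0, 9), nrow = 2, byrow = TRUE)
  expect_equal(as.numeric(masked_max_pool(H, c(1, 1))), c(2, 5, 9))
  expect_equal(as.numeric(masked_max_pool(H[1, , drop = FALSE], 1)), c(1, 5, 3))

  # large values at masked rows change nothing
  H2 <- rbind(H, c(100, 100, 100))
  expect_equal(as.numeric(masked_max_pool(H2, c(1, 1, 0))),
               as.numeric(masked_max_pool(H, c(1, 1))))
  expect_error(masked_max_pool(H, c(0, 0)), "no unmasked")

  set.seed(8)
  for (r in 1:20) {
    L <- sample(3:12, 1); C <- sample(2:6, 1)
    H <- matrix(rnorm(L * C), L, C)
    mask <- rbinom(L, 1, 0.7)
    if (sum(mask) == 0) mask[1] <- 1
    want <- apply(H[mask == 1, , drop = FALSE], 2, max)
    expect_equal(as.numeric(masked_max_pool(H, mask)), want, tolerance = 1e-12)
  }
})

test_that("self-attention matches the brute-force weighted-sum oracle", {
  set.seed(5)
  # single position: g = v
  U1 <- matrix(rnorm(4), 1, 4)
  w <- list(Wq = matrix(rnorm(12), 3, 4), Wk = matrix(rnorm(12), 3, 4),
            Wv = matrix(rnorm(12), 3, 4))
  G1 <- attend(U1, w, mask = 1)
  expect_equal(as.numeric(G1), as.numeric(w$Wv %*% U1[1, ]), tolerance = 1e-12)

  # zero queries -> uniform weights -> masked mean of v_j
  N <- 6
  U <- matrix(rnorm(N * 4), N, 4)
  mask <- c(1, 1, 1, 1, 0, 0)
  w0 <- w; w0$Wq <- matrix(0, 3, 4)
  G0 <- attend(U, w0, mask)
  vbar <- colMeans(t(w$Wv %*% t(U[1:4, ])))
  expect_equal(G0[1, ], vbar, tolerance = 1e-12)

  # attention rows are probability distributions over unmasked positions
  G <- attend(U, w, mask)
  A <- attr(G, "weights")
  expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-9)
  expect_true(all(G[5:6, ] == 0))

  # 100 random small instances against the double-loop oracle
  for (r in 1:100) {
    N <- sample(2:7, 1); d <- sample(2:5, 1); dk <- sample(2:4, 1)
    U <- matrix(rnorm(N * d), N, d)
    w <- list(Wq = matrix(rnorm(dk * d), dk, d),
              Wk = matrix(rnorm(dk * d), dk, d),
              Wv = matrix(rnorm(dk * d), dk, d))
    mask <- rbinom(N, 1, 0.8)
    if (sum(mask) == 0) mask[1] <- 1
    expect_equal(attend(U, w, mask),
                 oracle_attend(U, w$Wq, w$Wk, w$Wv, mask),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_error(attend(U, w, rep(0, N)), "masked")
})

test_that("attention pooling is the masked mean", {
  G <- rbind(c(1, 2), c(3, 4), c(100, 100))
  expect_equal(attention_pool(G, c(1, 1, 0)), c(2, 3))
  expect_equal(attention_pool(G[1, , drop = FALSE], 1), c(1, 2))
  # identical rows pool to that row
  G2 <- rbind(c(5, 6), c(5, 6))
  expect_equal(attention_pool(G2, c(1, 1)), c(5, 6))
  expect_error(attention_pool(G, c(0, 0, 0)), "no unmasked")
})

test_that("binary head composes affine + ReLU + sigmoid as hand-computed", {
  arch <- tiny_arch()
  params <- pepnet_params(arch, seed = 1)
  in_dim <- nrow(params$fc[[1]]$W)

  # zero weights -> sigma(0) = 0.5
  pz <- params
  pz$fc <- lapply(pz$fc, function(l) list(W = l$W * 0, b = l$b * 0))
  expect_equal(binary_head(numeric(5), numeric(5), numeric(3), numeric(3), pz),
               0.5)

  # eval mode is deterministic
  z <- rnorm(in_dim)
  split_z <- function(z) list(z[1:5], z[6:10], z[11:13], z[14:16])
  s <- split_z(z)
  p1 <- binary_head(s[[1]], s[[2]], s[[3]], s[[4]], params)
  p2 <- binary_head(s[[1]], s[[2]], s[[3]], s[[4]], params)
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 < 1)

  # hand-set single-unit layers
  ph <- params
  ph$fc <- list(
    list(W = matrix(1, in_dim, 1), b = 0.5),
    list(W = matrix(2, 1, 1), b = -1),
    list(W = matrix(3, 1, 1), b = 0.25)
  )
  a1 <- max(0, sum(z) + 0.5)
  a2 <- max(0, 2 * a1 - 1)
  want <- 1 / (1 + exp(-(3 * a2 + 0.25)))
  expect_equal(binary_head(s[[1]], s[[2]], s[[3]], s[[4]], ph), want,
               tolerance = 1e-12)

  expect_error(binary_head(numeric(2), numeric(2), numeric(2), numeric(2), params),
               "does not match FC input dimension")
})

test_that("residue scores apply the per-position sigmoid head", {
  set.seed(6)
  H <- matrix(rnorm(8 * 5), 8, 5)
  w <- list(W = matrix(rnorm(5), 5, 1), b = 0.3)
  got <- residue_scores(H, w)
  want <- vapply(1:8, function(j) 1 / (1 + exp(-(sum(H[j, ] * w$W) + 0.3))),
                 numeric(1))
  expect_equal(got, want, tolerance = 1e-6)

  # zero head -> all 0.5
  expect_equal(residue_scores(H, list(W = matrix(0, 5, 1), b = 0)), rep(0.5, 8))

  # the aligned hot position scores strictly largest
  H1 <- matrix(0, 8, 5); H1[4, ] <- 1
  w1 <- list(W = matrix(1, 5, 1), b = 0)
  sc <- residue_scores(H1, w1)
  expect_identical(which.max(sc), 4L)
})

test_that("forward pass is deterministic, mask-invariant, and padding-invariant", {
  arch <- tiny_arch()
  fx <- tiny_profiles()
  params <- pepnet_params(arch, seed = 9)

  o1 <- forward_pair(fx$pep, fx$pro, params, arch)
  o2 <- forward_pair(fx$pep, fx$pro, params, arch)
  expect_identical(o1, o2)
  expect_true(o1$pair_prob > 0 && o1$pair_prob < 1)
  expect_true(all(o1$residue_prob > 0 & o1$residue_prob < 1))

  # composition equals the chained component oracles
  U_pep <- channel_embed(fx$pep, params, "peptide")
  U_pro <- channel_embed(fx$pro, params, "protein")
  H_pep <- conv_features(U_pep, params$pep$conv, arch$conv_kernels, fx$pep$mask)
  H_pro <- conv_features(U_pro, params$pro$conv, arch$conv_kernels, fx$pro$mask)
  want_pair <- binary_head(
    as.numeric(masked_max_pool(H_pep, fx$pep$mask)),
    as.numeric(masked_max_pool(H_pro, fx$pro$mask)),
    attention_pool(oracle_attend(U_pep, params$pep$att$Wq, params$pep$att$Wk,
                                 params$pep$att$Wv, fx$pep$mask), fx$pep$mask),
    attention_pool(oracle_attend(U_pro, params$pro$att$Wq, params$pro$att$Wk,
                                 params$pro$att$Wv, fx$pro$mask), fx$pro$mask),
    params)
  expect_equal(o1$pair_prob, want_pair, tolerance = 1e-6)
  expect_equal(o1$residue_prob, residue_scores(H_pep, params$res),
               tolerance = 1e-6)

  # padding invariance: same peptide padded wider gives identical outputs
  prov <- fx$prov
  pep_wide <- build_profile(sequence_record("p1", "peptide", "ACDEFGH"), prov, 16)
  o_wide <- forward_pair(pep_wide, fx$pro, params, arch)
  expect_equal(o_wide$pair_prob, o1$pair_prob, tolerance = 1e-12)
  expect_equal(o_wide$residue_prob[1:7], o1$residue_prob[1:7], tolerance = 1e-12)
})
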