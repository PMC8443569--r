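# Forward computation: channel embedding, length-preserving convolution
# stacks, masked pooling, single-head scaled dot-product self-attention, and
# the two prediction heads. Every operation zeroes padded positions so outputs
# are invariant to the amount of trailing padding.

#' Embed a feature profile into the per-position representation
#'
#' Concatenates the three categorical embedding lookups (amino acid, combined
#' secondary structure, polarity/hydropathy) with an affine map of the numeric
#' tracks. Rows at padded positions are all-zero: the padding code indexes the
#' frozen zero row of each table and the whole row is masked after the affine
#' map.
#'
#' @param profile a `pepnet_profile`.
#' @param params a `pepnet_params` tree.
#' @param role `"peptide"` or `"protein"`.
#' @return L x D real matrix, D = 4 * embed_dim.
#' @export
channel_embed <- function(profile, params, role = profile$role) {
  br <- if (role == "peptide") params$pep else params$pro
  E <- br$embed
  max_code <- function(tab) nrow(tab) - 1L
  for (ch in c("aa", "ss", "polhyd")) {
    if (any(profile[[ch]] > max_code(E[[ch]]) | profile[[ch]] < 0)) {
      stop("categorical code out of embedding-table range in channel '", ch, "'",
           call. = FALSE)
    }
  }
  U <- cbind(
    E$aa[profile$aa + 1L, , drop = FALSE],
    E$ss[profile$ss + 1L, , drop = FALSE],
    E$polhyd[profile$polhyd + 1L, , drop = FALSE],
    sweep(profile$numeric %*% E$num$W, 2, E$num$b, "+")
  )
  U * profile$mask
}

# im2col for 'same' 1-D convolution: returns the L x (k*D) design matrix whose
# row l stacks the k window rows centred at l (zeros beyond the ends).
im2col <- function(X, k) {
  L <- nrow(X); D <- ncol(X); pad <- (k - 1L) %/% 2L
  Xp <- rbind(matrix(0, pad, D), X, matrix(0, pad, D))
  out <- matrix(0, L, k * D)
  for (j in seq_len(k)) {
    out[, ((j - 1L) * D + 1L):(j * D)] <- Xp[j:(j + L - 1L), , drop = FALSE]
  }
  out
}

# Adjoint of im2col: scatter-adds window-stacked gradients back to positions.
col2im_back <- function(dXc, k, L, D) {
  pad <- (k - 1L) %/% 2L
  dXp <- matrix(0, L + 2L * pad, D)
  for (j in seq_len(k)) {
    rows <- j:(j + L - 1L)
    dXp[rows, ] <- dXp[rows, ] + dXc[, ((j - 1L) * D + 1L):(j * D), drop = FALSE]
  }
  dXp[(pad + 1L):(pad + L), , drop = FALSE]
}

# One conv layer forward with caches for backprop.
conv_layer_forward <- function(X, layer, k, mask) {
  Xc <- im2col(X, k)
  pre <- Xc %*% layer$W
  pre <- pre + rep(layer$b, each = nrow(pre))
  pos <- pre > 0
  H <- (pre * pos) * mask
  list(Xc = Xc, pos = pos, H = H)
}

#' Convolution stack features
#'
#' Applies the three-layer 'same'-padded 1-D convolution stack with ReLU
#' activations. Activations at padded positions are zeroed after every layer,
#' which keeps the output invariant to the amount of trailing padding and lets
#' the residue head read per-position features directly.
#'
#' @param U L x D input matrix (embedding output).
#' @param stack list of 3 layers, each `list(W, b)` with `W` of shape
#'   `(k * D_in) x C`.
#' @param kernels integer vector of kernel widths, one per layer.
#' @param mask 0/1 validity vector of length L.
#' @return L x C matrix of non-negative per-position features.
#' @export
conv_features <- function(U, stack, kernels, mask) {
  if (nrow(U) < max(kernels)) {
    stop("input shorter than the widest kernel", call. = FALSE)
  }
  X <- U
  for (l in seq_along(stack)) {
    X <- conv_layer_forward(X, stack[[l]], kernels[l], mask)$H
  }
  X
}

#' Masked column-wise max pooling
#'
#' Reduces per-position features to one vector by taking, per feature, the
#' maximum over real (unmasked) positions only.
#'
#' @param H L x C feature matrix.
#' @param mask 0/1 vector of length L with at least one 1.
#' @return numeric vector of length C.
#' @export
masked_max_pool <- function(H, mask) {
  idx <- which(mask == 1)
  if (length(idx) == 0) stop("mask has no unmasked position", call. = FALSE)
  Hs <- H[idx, , drop = FALSE]
  am <- max.col(t(Hs), ties.method = "first")
  list_val <- Hs[cbind(am, seq_len(ncol(Hs)))]
  structure(list_val, argmax = idx[am])
}

#' Single-head scaled dot-product self-attention
#'
#' Computes, for every position i, the attended vector
#' `g_i = sum_j softmax_j(q_i . k_j / sqrt(d_k)) v_j`, with query/key/value
#' projections of the input rows and the softmax restricted to unmasked
#' positions (padded keys receive zero weight; padded query rows are returned
#' as zeros). Each attention-weight row is a probability distribution over the
#' unmasked positions.
#'
#' @param U N x D input matrix.
#' @param w attention weights: `list(Wq, Wk, Wv)`, each `d_k x D`.
#' @param mask 0/1 vector of length N with at least one 1.
#' @return N x d_k matrix; attribute `"weights"` holds the attention matrix
#'   over unmasked positions (rows sum to 1) and `"idx"` their positions.
#' @export
attend <- function(U, w, mask) {
  idx <- which(mask == 1)
  if (length(idx) == 0) stop("all positions are masked", call. = FALSE)
  Us <- U[idx, , drop = FALSE]
  dk <- nrow(w$Wq)
  Q <- Us %*% t(w$Wq)
  K <- Us %*% t(w$Wk)
  V <- Us %*% t(w$Wv)
  S <- (Q %*% t(K)) / sqrt(dk)
  rmax <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  A <- exp(S - rmax)                 # row-wise stabilized softmax
  A <- A / rowSums(A)
  G0 <- A %*% V
  G <- matrix(0, nrow(U), dk)
  G[idx, ] <- G0
  structure(G, weights = A, idx = idx, Q = Q, K = K, V = V)
}

#' Masked mean pooling of attention outputs
#'
#' @param G N x d_k matrix (attention output).
#' @param mask 0/1 vector of length N with at least one 1.
#' @return numeric vector of length d_k: the mean of rows at unmasked
#'   positions.
#' @export
attention_pool <- function(G, mask) {
  idx <- which(mask == 1)
  if (length(idx) == 0) stop("mask has no unmasked position", call. = FALSE)
  colMeans(G[idx, , drop = FALSE])
}

# FC head forward with caches; dropout masks are drawn from the current RNG
# stream when active (inverted dropout, scale 1/(1-p)).
binary_head_forward <- function(z, fc, dropout, dropout_active) {
  pre1 <- as.vector(z %*% fc[[1]]$W) + fc[[1]]$b
  a1 <- relu(pre1)
  d1 <- NULL
  if (dropout_active && dropout > 0) {
    d1 <- (stats::runif(length(a1)) >= dropout) / (1 - dropout)
    a1 <- a1 * d1
  }
  pre2 <- as.vector(a1 %*% fc[[2]]$W) + fc[[2]]$b
  a2 <- relu(pre2)
  d2 <- NULL
  if (dropout_active && dropout > 0) {
    d2 <- (stats::runif(length(a2)) >= dropout) / (1 - dropout)
    a2 <- a2 * d2
  }
  logit <- sum(a2 * fc[[3]]$W) + fc[[3]]$b
  list(z = z, pre1 = pre1, a1 = a1, d1 = d1, pre2 = pre2, a2 = a2, d2 = d2,
       logit = logit, prob = sigmoid(logit))
}

#' Pair-classification head
#'
#' Concatenates the four pooled vectors (peptide CNN, protein CNN, peptide
#' attention, protein attention) and passes them through three fully connected
#' layers (ReLU after the first two, each followed by dropout in training
#' mode) and a sigmoid.
#'
#' @param pep_cnn,pro_cnn,pep_att,pro_att pooled feature vectors.
#' @param params `pepnet_params`.
#' @param dropout dropout rate.
#' @param dropout_active logical; draw and apply dropout masks (training mode).
#' @return interaction probability strictly in (0, 1).
#' @export
binary_head <- function(pep_cnn, pro_cnn, pep_att, pro_att, params,
                        dropout = 0, dropout_active = FALSE) {
  z <- c(pep_cnn, pro_cnn, pep_att, pro_att)
  if (length(z) != nrow(params$fc[[1]]$W)) {
    stop("concatenated feature length ", length(z),
         " does not match FC input dimension ", nrow(params$fc[[1]]$W),
         call. = FALSE)
  }
  binary_head_forward(z, params$fc, dropout, dropout_active)$prob
}

#' Per-residue binding scores
#'
#' Applies the single-layer residue head `b_j = sigmoid(W . h_j + c)` to every
#' row of the peptide's pre-pooling convolution features. Padded positions are
#' scored too but carry no information; downstream consumers mask them.
#'
#' @param H L x C peptide feature matrix (pre-pooling CNN output).
#' @param w residue head weights: `list(W, b)` with `W` a C x 1 matrix and `b`
#'   a single shared bias.
#' @return numeric vector of length L with values in (0, 1).
#' @export
residue_scores <- function(H, w) {
  as.vector(sigmoid(H %*% w$W + w$b))
}

# Full forward pass for one (peptide profile, protein profile) pair with all
# caches needed by the backward pass. Because every channel is zero at padded
# positions, the convolution stack is evaluated on the leading
# max(true_length, widest kernel) rows only; the remaining rows are zero.
forward_cached <- function(pep, pro, params, arch, dropout_active = FALSE) {
  U_pep <- channel_embed(pep, params, "peptide")
  U_pro <- channel_embed(pro, params, "protein")
  kmax <- max(arch$conv_kernels)

  branch_conv <- function(U, profile, stack) {
    sl <- min(nrow(U), max(profile$true_length, kmax))
    m <- profile$mask[seq_len(sl)]
    caches <- vector("list", length(stack))
    X <- U[seq_len(sl), , drop = FALSE]
    for (l in seq_along(stack)) {
      caches[[l]] <- conv_layer_forward(X, stack[[l]], arch$conv_kernels[l], m)
      caches[[l]]$X_in <- X
      X <- caches[[l]]$H
    }
    list(caches = caches, H = X, sl = sl, mask = m)
  }
  cv_pep <- branch_conv(U_pep, pep, params$pep$conv)
  cv_pro <- branch_conv(U_pro, pro, params$pro$conv)

  pool_pep <- masked_max_pool(cv_pep$H, cv_pep$mask)
  pool_pro <- masked_max_pool(cv_pro$H, cv_pro$mask)

  G_pep <- attend(U_pep, params$pep$att, pep$mask)
  G_pro <- attend(U_pro, params$pro$att, pro$mask)
  att_pep <- attention_pool(G_pep, pep$mask)
  att_pro <- attention_pool(G_pro, pro$mask)

  head <- binary_head_forward(
    c(as.numeric(pool_pep), as.numeric(pool_pro), att_pep, att_pro),
    params$fc, arch$dropout, dropout_active)

  # padded rows have zero features, so their logit is just the shared bias
  res_logit <- rep(params$res$b, nrow(U_pep))
  res_logit[seq_len(cv_pep$sl)] <- as.vector(cv_pep$H %*% params$res$W) +
    params$res$b

  list(
    pair_prob = head$prob,
    residue_prob = sigmoid(res_logit),
    U_pep = U_pep, U_pro = U_pro,
    cv_pep = cv_pep, cv_pro = cv_pro,
    pool_pep = pool_pep, pool_pro = pool_pro,
    G_pep = G_pep, G_pro = G_pro,
    head = head, res_logit = res_logit
  )
}

#' Forward pass for one peptide-protein pair
#'
#' Composes the whole network: channel embedding, convolution stack with
#' masked max pooling, self-attention with masked mean pooling, the
#' pair-classification head over the four concatenated vectors, and the
#' residue head over the peptide's pre-pooling convolution features.
#'
#' @param pep,pro `pepnet_profile` objects for the peptide and the protein.
#' @param params `pepnet_params`.
#' @param arch `pepnet_architecture`.
#' @param mode `"eval"` (deterministic, default) or `"train"` (dropout
#'   active, consumes the RNG stream).
#' @return list with `pair_prob` (scalar in (0,1)) and `residue_prob`
#'   (length `pep_pad` vector; positions beyond the peptide's true length are
#'   meaningless and should be masked).
#' @export
forward_pair <- function(pep, pro, params, arch, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  out <- forward_cached(pep, pro, params, arch, dropout_active = mode == "train")
  list(pair_prob = out$pair_prob, residue_prob = out$residue_prob)
}
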