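# Backpropagation through the full network. Gradients mirror the
# `pepnet_params` tree exactly; correctness is pinned down by the
# finite-difference test suite.

# Backward through one conv stack. dH3 is the gradient w.r.t. the (masked)
# output of the last layer. Returns per-layer W/b gradients and dU.
conv_stack_backward <- function(caches, stack, kernels, mask, dH) {
  grads <- vector("list", length(stack))
  for (l in rev(seq_along(stack))) {
    cc <- caches[[l]]
    k <- kernels[l]
    dpre <- (dH * mask) * cc$pos
    grads[[l]] <- list(W = crossprod(cc$Xc, dpre), b = colSums(dpre))
    dXc <- dpre %*% t(stack[[l]]$W)
    dH <- col2im_back(dXc, k, nrow(cc$X_in), ncol(cc$X_in))
  }
  list(layers = grads, dU = dH)
}

# Backward through attention + masked mean pooling for one branch.
# `datt` is the gradient w.r.t. the pooled d_k vector.
attention_backward <- function(U, G, w, mask, datt) {
  idx <- attr(G, "idx")
  A <- attr(G, "weights")
  n <- length(idx)
  dk <- nrow(w$Wq)
  Us <- U[idx, , drop = FALSE]
  Q <- attr(G, "Q")
  K <- attr(G, "K")
  V <- attr(G, "V")

  dG0 <- matrix(rep(datt / n, each = n), nrow = n)   # mean-pool backward
  dV <- crossprod(A, dG0)
  dA <- dG0 %*% t(V)
  dS <- A * (dA - rowSums(dA * A))                   # softmax rows backward
  dQ <- (dS %*% K) / sqrt(dk)
  dK <- (crossprod(dS, Q)) / sqrt(dk)

  dUs <- dQ %*% w$Wq + dK %*% w$Wk + dV %*% w$Wv
  dU <- matrix(0, nrow(U), ncol(U))
  dU[idx, ] <- dUs
  list(
    att = list(Wq = crossprod(dQ, Us), Wk = crossprod(dK, Us),
               Wv = crossprod(dV, Us)),
    dU = dU
  )
}

# Backward through the channel embedding for one branch; dU must already be
# masked. Row 1 of each table (padding code 0) stays frozen at zero.
embed_backward <- function(profile, embed, dU) {
  d <- ncol(embed$aa)
  block <- function(i) dU[, ((i - 1L) * d + 1L):(i * d), drop = FALSE]
  table_grad <- function(tab, codes, dblock) {
    g <- matrix(0, nrow(tab), ncol(tab))
    rs <- rowsum(dblock, group = codes)
    g[as.integer(rownames(rs)) + 1L, ] <- rs
    g[1, ] <- 0
    g
  }
  dnum_block <- block(4L)
  list(
    aa = table_grad(embed$aa, profile$aa, block(1L)),
    ss = table_grad(embed$ss, profile$ss, block(2L)),
    polhyd = table_grad(embed$polhyd, profile$polhyd, block(3L)),
    num = list(W = crossprod(profile$numeric, dnum_block),
               b = colSums(dnum_block))
  )
}

# Full backward pass for one pair. `dlogit_pair` is dLoss/d(pair logit) and
# `dres_logit` dLoss/d(residue logits) (length pep_pad, zero wherever the
# residue loss is masked). Returns a gradient tree congruent with `params`.
backward_pair <- function(cache, pep, pro, params, arch,
                          dlogit_pair, dres_logit) {
  C3 <- arch$conv_filters[3]
  dk <- arch$attention_dim
  head <- cache$head
  sl_pep <- cache$cv_pep$sl
  sl_pro <- cache$cv_pro$sl

  # residue head (gradients only flow through the sliced conv rows; residue
  # logits beyond the slice are the constant bias and dres_logit is zero
  # there by masking)
  H_pep <- cache$cv_pep$H
  dres_s <- dres_logit[seq_len(sl_pep)]
  g_res <- list(W = crossprod(H_pep, dres_s), b = sum(dres_logit))
  dH_pep_res <- dres_s %o% as.vector(params$res$W)

  # FC head backward
  da2 <- dlogit_pair * as.vector(params$fc[[3]]$W)
  g_fc3 <- list(W = matrix(head$a2 * dlogit_pair, ncol = 1),
                b = dlogit_pair)
  if (!is.null(head$d2)) da2 <- da2 * head$d2
  dpre2 <- da2 * (head$pre2 > 0)
  g_fc2 <- list(W = head$a1 %o% dpre2, b = dpre2)
  da1 <- as.vector(params$fc[[2]]$W %*% dpre2)
  if (!is.null(head$d1)) da1 <- da1 * head$d1
  dpre1 <- da1 * (head$pre1 > 0)
  g_fc1 <- list(W = head$z %o% dpre1, b = dpre1)
  dz <- as.vector(params$fc[[1]]$W %*% dpre1)

  d_pool_pep <- dz[1:C3]
  d_pool_pro <- dz[(C3 + 1):(2 * C3)]
  d_att_pep <- dz[(2 * C3 + 1):(2 * C3 + dk)]
  d_att_pro <- dz[(2 * C3 + dk + 1):(2 * C3 + 2 * dk)]

  pool_back <- function(pool, dpool, L, C) {
    dH <- matrix(0, L, C)
    dH[cbind(attr(pool, "argmax"), seq_len(C))] <- dpool
    dH
  }
  dH_pep <- pool_back(cache$pool_pep, d_pool_pep, sl_pep, C3) + dH_pep_res
  dH_pro <- pool_back(cache$pool_pro, d_pool_pro, sl_pro, C3)

  cv_pep <- conv_stack_backward(cache$cv_pep$caches, params$pep$conv,
                                arch$conv_kernels, cache$cv_pep$mask, dH_pep)
  cv_pro <- conv_stack_backward(cache$cv_pro$caches, params$pro$conv,
                                arch$conv_kernels, cache$cv_pro$mask, dH_pro)

  at_pep <- attention_backward(cache$U_pep, cache$G_pep, params$pep$att,
                               pep$mask, d_att_pep)
  at_pro <- attention_backward(cache$U_pro, cache$G_pro, params$pro$att,
                               pro$mask, d_att_pro)

  dU_pep <- at_pep$dU
  dU_pep[seq_len(sl_pep), ] <- dU_pep[seq_len(sl_pep), , drop = FALSE] + cv_pep$dU
  dU_pro <- at_pro$dU
  dU_pro[seq_len(sl_pro), ] <- dU_pro[seq_len(sl_pro), , drop = FALSE] + cv_pro$dU
  dU_pep <- dU_pep * pep$mask
  dU_pro <- dU_pro * pro$mask

  structure(list(
    pep = list(embed = embed_backward(pep, params$pep$embed, dU_pep),
               conv = cv_pep$layers, att = at_pep$att),
    pro = list(embed = embed_backward(pro, params$pro$embed, dU_pro),
               conv = cv_pro$layers, att = at_pro$att),
    fc = list(g_fc1, g_fc2, g_fc3),
    res = g_res
  ), class = "pepnet_params")
}
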