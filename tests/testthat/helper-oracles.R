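# Independent brute-force oracles. These deliberately re-derive each quantity
# from first principles (loops, dynamic programming, exhaustive counting) and
# share no code with the implementation they check.

# per-letter alphabet lookup
oracle_encode <- function(seq) {
  symbols <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
  out <- integer(nchar(seq))
  for (i in seq_len(nchar(seq))) {
    ch <- toupper(substr(seq, i, i))
    hit <- which(symbols == ch)
    out[i] <- if (length(hit)) hit else 21L
  }
  out
}

# naive 'same' 1-D convolution: out[l, c] = sum_{j,d} X[l+j-center, d] * W[j,d,c]
oracle_conv1d <- function(X, W, b, k) {
  L <- nrow(X); D <- ncol(X); C <- ncol(W)
  pad <- (k - 1) / 2
  out <- matrix(0, L, C)
  for (l in 1:L) for (cc in 1:C) {
    acc <- b[cc]
    for (j in 1:k) {
      src <- l + j - 1 - pad
      if (src >= 1 && src <= L) {
        for (d in 1:D) acc <- acc + X[src, d] * W[(j - 1) * D + d, cc]
      }
    }
    out[l, cc] <- acc
  }
  out
}

# double-loop scaled dot-product attention over unmasked positions
oracle_attend <- function(U, Wq, Wk, Wv, mask) {
  idx <- which(mask == 1)
  dk <- nrow(Wq)
  G <- matrix(0, nrow(U), dk)
  for (i in idx) {
    qi <- as.vector(Wq %*% U[i, ])
    logits <- vapply(idx, function(j) {
      sum(qi * as.vector(Wk %*% U[j, ])) / sqrt(dk)
    }, numeric(1))
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    gi <- numeric(dk)
    for (a in seq_along(idx)) {
      gi <- gi + w[a] * as.vector(Wv %*% U[idx[a], ])
    }
    G[i, ] <- gi
  }
  G
}

# textbook affine-gap local alignment (gap of length L costs open + L * ext),
# matching the Biostrings penalty convention
oracle_sw <- function(a, b, sub, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- sub[A[i - 1], B[j - 1]]
    M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                   Iy[i - 1, j - 1] + s)
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext,
                    Iy[i - 1, j] - open - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext,
                    Ix[i, j - 1] - open - ext)
    if (M[i, j] > best) best <- M[i, j]
  }
  best
}

oracle_norm_sw <- function(a, b, sub) {
  oracle_sw(a, b, sub) / sqrt(oracle_sw(a, a, sub) * oracle_sw(b, b, sub))
}

# union-find connected components over an explicit edge list
oracle_components <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(ids, find, character(1))
  # canonical label: smallest member id per component
  canon <- vapply(split(ids, roots), min, character(1))
  stats::setNames(canon[roots], ids)
}

# AUC by exhaustive concordance counting over all (positive, negative) pairs
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# average precision by a direct loop over distinct thresholds
oracle_aupr <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  np <- sum(labels == 1)
  out <- 0
  for (th in ths) {
    sel <- scores >= th
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / np
    out <- out + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  out
}

# shared tiny fixtures ------------------------------------------------------

tiny_arch <- function(...) {
  pepnet_architecture(embed_dim = 3, conv_filters = c(4, 4, 5),
                      conv_kernels = c(3, 3, 3), attention_dim = 3,
                      fc_sizes = c(6, 4), dropout = 0, pep_pad = 10,
                      pro_pad = 60, ...)
}

tiny_profiles <- function(seed = 7) {
  prov <- stub_feature_providers(seed)
  list(
    pep = build_profile(sequence_record("p1", "peptide", "ACDEFGH"), prov, 10),
    pro = build_profile(sequence_record("q1", "protein",
                                        paste(rep("ACDEFGHIKLM", 5), collapse = "")),
                        prov, 60),
    prov = prov
  )
}

random_aa_string <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# a small labelled dataset (few pairs, short proteins) for fast training tests
tiny_dataset <- function(seed = 3, n_pos = 10) {
  simulate_interactions(synthetic_config(
    n_positives = n_pos, ratio = 2, pep_len = c(6L, 12L), pro_len = c(51L, 70L),
    n_families = 2L, n_proteins = 8L, seed = seed))
}
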