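#' Training configuration
#'
#' @param learning_rate RMSProp step size (default 2e-3).
#' @param epochs number of passes over the training pairs (default 30).
#' @param batch_size minibatch size (default 32).
#' @param lambda non-negative weight of the residue loss in the combined
#'   objective (default 0.5: the pair task stays primary, but the auxiliary
#'   residue head needs a comparable gradient share to train within a few
#'   dozen epochs).
#' @param rmsprop_decay decay of the squared-gradient running average
#'   (default 0.9).
#' @param rmsprop_eps denominator stabilizer (default 1e-7).
#' @param seed integer seed fixing all stochasticity: initialization,
#'   shuffling, and dropout.
#' @return list of class `pepnet_control`.
#' @export
pepnet_control <- function(learning_rate = 2e-3, epochs = 30L, batch_size = 32L,
                           lambda = 0.5, rmsprop_decay = 0.9,
                           rmsprop_eps = 1e-7, seed = 1L) {
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lambda = lambda,
                 rmsprop_decay = rmsprop_decay, rmsprop_eps = rmsprop_eps,
                 seed = as.integer(seed)),
            class = "pepnet_control")
}

# One RMSProp step over the whole parameter tree.
rmsprop_step <- function(p, g, v, lr, rho, eps) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- rmsprop_step(p[[i]], g[[i]], v[[i]], lr, rho, eps)
      p[[i]] <- r$p
      v[[i]] <- r$v
    }
    list(p = p, v = v)
  } else {
    v <- rho * v + (1 - rho) * g * g
    list(p = p - lr * g / (sqrt(v) + eps), v = v)
  }
}

# Build profiles for every unique peptide/protein id in a pair table.
build_profile_sets <- function(data, arch, providers, polhyd) {
  pro_pad <- min(arch$pro_pad, max(nchar(data$proteins)))
  pep_profiles <- lapply(names(data$peptides), function(id) {
    build_profile(sequence_record(id, "peptide", data$peptides[[id]]),
                  providers, arch$pep_pad, polhyd)
  })
  names(pep_profiles) <- names(data$peptides)
  pro_profiles <- lapply(names(data$proteins), function(id) {
    build_profile(sequence_record(id, "protein", data$proteins[[id]]),
                  providers, pro_pad, polhyd)
  })
  names(pro_profiles) <- names(data$proteins)
  list(pep = pep_profiles, pro = pro_profiles, pro_pad = pro_pad)
}

#' Fit the peptide-protein interaction network
#'
#' Trains the two-task network on a labelled pair table: a shared sequence
#' encoder per role (multi-channel embedding, three-layer CNN, single-head
#' self-attention), a pair-classification head over the four pooled vectors,
#' and a per-residue binding head over the peptide's convolution features. The
#' combined objective is `loss_pair + lambda * loss_pep`, where the residue
#' term is a masked cross-entropy restricted to real peptide positions of
#' pairs that carry residue labels; gradients are computed by backpropagation
#' and applied with RMSProp. Training is fully seeded: the same data, control
#' and architecture reproduce identical weights.
#'
#' @param data a [pair_table()] with sequence maps, at least one positive and
#'   one negative pair.
#' @param arch a [pepnet_architecture()].
#' @param control a [pepnet_control()].
#' @param providers feature providers; defaults to the deterministic stub
#'   providers seeded from `control$seed`.
#' @param polhyd polarity/hydropathy classification table.
#' @param verbose print per-epoch losses.
#' @return an object of class `pepnet`: the fitted parameters, architecture,
#'   control, per-epoch loss history (`history`), and everything needed by
#'   [predict.pepnet()].
#' @seealso [predict.pepnet()], [simulate_interactions()], [make_folds()]
#' @export
pepnet <- function(data, arch = pepnet_architecture(), control = pepnet_control(),
                   providers = NULL, polhyd = default_polhyd_table(),
                   verbose = FALSE) {
  stopifnot(inherits(data, "pair_table"))
  if (is.null(data$peptides) || is.null(data$proteins)) {
    stop("`data` must carry peptide and protein sequences", call. = FALSE)
  }
  labels <- data$pairs$label
  if (length(labels) == 0 || !any(labels == 1L) || !any(labels == 0L)) {
    stop("training data needs at least one positive and one negative pair",
         call. = FALSE)
  }
  if (is.null(providers)) providers <- stub_feature_providers(control$seed)

  profs <- build_profile_sets(data, arch, providers, polhyd)
  n <- nrow(data$pairs)
  pep_of <- match(data$pairs$peptide_id, names(profs$pep))
  pro_of <- match(data$pairs$protein_id, names(profs$pro))

  # residue supervision: labels padded to pep_pad; mask = profile mask for
  # labelled pairs, all-zero otherwise (those pairs train the pair head only)
  L <- arch$pep_pad
  res_labels <- matrix(0, n, L)
  res_masks <- matrix(0, n, L)
  for (i in seq_len(n)) {
    v <- parse_bind(data$pairs$bind[i])
    if (!is.null(v)) {
      tl <- profs$pep[[pep_of[i]]]$true_length
      if (length(v) != tl) {
        stop("binding vector length mismatch for pair ", i, call. = FALSE)
      }
      res_labels[i, seq_len(tl)] <- v
      res_masks[i, ] <- profs$pep[[pep_of[i]]]$mask
    }
  }

  params <- pepnet_params(arch, seed = control$seed)
  vstate <- tree_zeros_like(params)
  lambda <- control$lambda
  history <- data.frame(epoch = integer(), loss_pair = numeric(),
                        loss_pep = numeric(), loss_total = numeric())

  set.seed(control$seed)
  for (epoch in seq_len(control$epochs)) {
    ord <- sample.int(n)
    sum_pair <- 0
    sum_pep <- 0
    b0 <- 1L
    while (b0 <= n) {
      idx <- ord[b0:min(b0 + control$batch_size - 1L, n)]
      B <- length(idx)
      g_acc <- NULL
      for (i in idx) {
        pep <- profs$pep[[pep_of[i]]]
        pro <- profs$pro[[pro_of[i]]]
        cache <- forward_cached(pep, pro, params, arch, dropout_active = TRUE)
        y <- labels[i]
        p <- clip_prob(cache$pair_prob)
        sum_pair <- sum_pair - (y * log(p) + (1 - y) * log(1 - p))
        m <- res_masks[i, ]
        Mi <- sum(m)
        dres <- numeric(L)
        if (Mi > 0) {
          bl <- res_labels[i, ]
          pr <- clip_prob(cache$residue_prob)
          sum_pep <- sum_pep - sum((bl * log(pr) + (1 - bl) * log(1 - pr)) * m) / Mi
          dres <- lambda * (cache$residue_prob - bl) * m / (Mi * B)
        }
        g <- backward_pair(cache, pep, pro, params, arch,
                           dlogit_pair = (cache$pair_prob - y) / B,
                           dres_logit = dres)
        g_acc <- if (is.null(g_acc)) g else tree_map(`+`, g_acc, g)
      }
      st <- rmsprop_step(params, g_acc, vstate, control$learning_rate,
                         control$rmsprop_decay, control$rmsprop_eps)
      params <- st$p
      vstate <- st$v
      b0 <- b0 + control$batch_size
    }
    lp <- sum_pair / n
    lr_ <- sum_pep / n
    lt <- total_loss(lp, lr_, lambda)
    if (!is.finite(lt)) {
      stop("non-finite loss at epoch ", epoch,
           " (loss_pair = ", lp, ", loss_pep = ", lr_, "); try a lower learning rate",
           call. = FALSE)
    }
    history <- rbind(history, data.frame(epoch = epoch, loss_pair = lp,
                                         loss_pep = lr_, loss_total = lt))
    if (verbose) {
      message(sprintf("epoch %3d  loss_pair %.4f  loss_pep %.4f  loss_total %.4f",
                      epoch, lp, lr_, lt))
    }
  }

  structure(list(
    params = params, arch = arch, control = control,
    history = history, providers = providers, polhyd = polhyd,
    pro_pad = profs$pro_pad,
    n_train = n, n_positive = sum(labels == 1L),
    call = match.call()
  ), class = "pepnet")
}

#' Predict interactions for new peptide-protein pairs
#'
#' Runs the fitted network in deterministic evaluation mode. Each requested
#' pair gets an interaction probability, a binary call at the 0.5 threshold,
#' and per-residue binding scores over the peptide's true length. A pair whose
#' peptide fails validation (e.g. longer than 50 residues) yields an `NA` row
#' with the error recorded in the `note` column; the rest of the batch is
#' unaffected.
#'
#' @param object fitted `pepnet` model.
#' @param newdata a [pair_table()], or a data.frame with columns `peptide_id`,
#'   `protein_id`.
#' @param peptides,proteins named sequence vectors (taken from `newdata` when
#'   it is a `pair_table` carrying them).
#' @param providers feature providers; defaults to the ones used at fit time.
#' @param ... unused.
#' @return data.frame with columns `peptide_id`, `protein_id`, `prob`, `pred`,
#'   `residue_scores` (list column of numeric vectors, one score per peptide
#'   residue) and `note`.
#' @export
predict.pepnet <- function(object, newdata, peptides = NULL, proteins = NULL,
                           providers = NULL, ...) {
  if (inherits(newdata, "pair_table")) {
    peptides <- peptides %||% newdata$peptides
    proteins <- proteins %||% newdata$proteins
    pairs <- newdata$pairs
  } else {
    pairs <- as.data.frame(newdata)
  }
  if (is.null(peptides) || is.null(proteins)) {
    stop("`peptides` and `proteins` sequence maps are required", call. = FALSE)
  }
  bad_pep <- setdiff(pairs$peptide_id, names(peptides))
  bad_pro <- setdiff(pairs$protein_id, names(proteins))
  if (length(bad_pep) || length(bad_pro)) {
    stop("unknown ids: ", paste(utils::head(c(bad_pep, bad_pro), 5), collapse = ", "),
         call. = FALSE)
  }
  providers <- providers %||% object$providers
  arch <- object$arch

  prof_or_error <- function(id, role, pad) {
    tryCatch(
      build_profile(sequence_record(id, role, if (role == "peptide") peptides[[id]]
                                    else proteins[[id]]),
                    providers, pad, object$polhyd),
      error = function(e) structure(conditionMessage(e), class = "pepnet_prof_error"))
  }
  pep_profiles <- lapply(unique(pairs$peptide_id), prof_or_error,
                         role = "peptide", pad = arch$pep_pad)
  names(pep_profiles) <- unique(pairs$peptide_id)
  pro_pad <- min(arch$pro_pad, max(nchar(proteins[unique(pairs$protein_id)])))
  pro_pad <- max(pro_pad, object$pro_pad)
  pro_profiles <- lapply(unique(pairs$protein_id), prof_or_error,
                         role = "protein", pad = pro_pad)
  names(pro_profiles) <- unique(pairs$protein_id)

  n <- nrow(pairs)
  prob <- rep(NA_real_, n)
  note <- rep(NA_character_, n)
  residue_scores <- vector("list", n)
  for (i in seq_len(n)) {
    pep <- pep_profiles[[pairs$peptide_id[i]]]
    pro <- pro_profiles[[pairs$protein_id[i]]]
    if (inherits(pep, "pepnet_prof_error")) { note[i] <- as.character(pep); next }
    if (inherits(pro, "pepnet_prof_error")) { note[i] <- as.character(pro); next }
    out <- forward_pair(pep, pro, object$params, arch, mode = "eval")
    prob[i] <- out$pair_prob
    residue_scores[[i]] <- out$residue_prob[seq_len(pep$true_length)]
  }
  data.frame(
    peptide_id = pairs$peptide_id,
    protein_id = pairs$protein_id,
    prob = prob,
    pred = ifelse(is.na(prob), NA_integer_, as.integer(prob >= 0.5)),
    residue_scores = I(residue_scores),
    note = note,
    stringsAsFactors = FALSE
  )
}

#' @export
print.pepnet <- function(x, ...) {
  cat("Multi-level peptide-protein interaction model (pepnet)\n")
  cat(sprintf("  trained on %d pairs (%d positive) for %d epochs\n",
              x$n_train, x$n_positive, nrow(x$history)))
  cat(sprintf("  architecture: embed %d/channel, conv %s (kernels %s), d_k %d, FC %s\n",
              x$arch$embed_dim, paste(x$arch$conv_filters, collapse = "/"),
              paste(x$arch$conv_kernels, collapse = "/"), x$arch$attention_dim,
              paste(c(x$arch$fc_sizes, 1), collapse = "/")))
  cat(sprintf("  parameters: %d, lambda = %g, seed = %d\n",
              n_parameters(x$params), x$control$lambda, x$control$seed))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  final losses: pair %.4f, residue %.4f, total %.4f\n",
              h$loss_pair, h$loss_pep, h$loss_total))
  invisible(x)
}

#' @export
#' @method summary pepnet
summary.pepnet <- function(object, ...) {
  structure(list(model = object), class = "summary.pepnet")
}

#' @export
print.summary.pepnet <- function(x, ...) {
  print(x$model)
  cat("\nLoss history (first/last epochs):\n")
  h <- x$model$history
  show <- unique(c(1, nrow(h)))
  print(h[show, ], row.names = FALSE)
  invisible(x)
}

#' @export
#' @method coef pepnet
coef.pepnet <- function(object, ...) object$params

#' Plot the training loss history
#'
#' @param x fitted `pepnet` model.
#' @param ... passed to [graphics::matplot()].
#' @export
#' @method plot pepnet
plot.pepnet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss_pair, h$loss_pep, h$loss_total),
                    type = "l", lty = 1, col = c("steelblue", "tomato", "black"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("pair", "residue", "total"), lty = 1,
                   col = c("steelblue", "tomato", "black"), bty = "n")
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' A checkpoint is a single-file container with the architecture, control,
#' and all weight arrays; saving and re-loading round-trips bit-exactly.
#'
#' @param object fitted `pepnet` model.
#' @param path checkpoint file path.
#' @return `load_pepnet` returns the model; `save_pepnet` the path, invisibly.
#' @export
save_pepnet <- function(object, path) {
  stopifnot(inherits(object, "pepnet"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_pepnet
#' @export
load_pepnet <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "pepnet")) stop("not a pepnet checkpoint: ", path, call. = FALSE)
  obj
}
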