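#' Network architecture configuration
#'
#' Hyperparameters of the two-branch network: per-channel embedding dimension,
#' the three-layer convolution stacks, the single-head attention dimension, and
#' the three fully connected layers of the pair-classification head. Defaults
#' are a compact configuration suitable for CPU training; all values are
#' configurable.
#'
#' Each branch embeds three categorical channels (amino acid, combined
#' secondary structure, polarity/hydropathy) at `embed_dim` each plus an affine
#' map of the numeric tracks to `embed_dim`, giving a per-position width of
#' `4 * embed_dim` entering the convolution stack and the attention module.
#'
#' @param embed_dim embedding dimension per channel (default 16).
#' @param conv_filters integer vector of 3 filter counts (default 64, 64, 128).
#' @param conv_kernels integer vector of 3 odd kernel widths (default 7, 5, 3).
#' @param attention_dim dimension of the query/key/value projections
#'   (default 32).
#' @param fc_sizes sizes of the first two fully connected layers (default
#'   256, 128); the third layer always has one output unit.
#' @param dropout dropout rate applied after the first two FC layers during
#'   training (default 0.2).
#' @param pep_pad peptide padded length (default 50).
#' @param pro_pad protein padded length cap; longer proteins are truncated
#'   (default 800).
#' @param polhyd_levels number of polarity/hydropathy categories; defaults to
#'   the shipped table's category count.
#' @return list of class `pepnet_architecture`.
#' @export
pepnet_architecture <- function(embed_dim = 16L,
                                conv_filters = c(64L, 64L, 128L),
                                conv_kernels = c(7L, 5L, 3L),
                                attention_dim = 32L,
                                fc_sizes = c(256L, 128L),
                                dropout = 0.2,
                                pep_pad = 50L,
                                pro_pad = 800L,
                                polhyd_levels = NULL) {
  if (length(conv_filters) != 3L || length(conv_kernels) != 3L) {
    stop("the convolution stack has exactly three layers", call. = FALSE)
  }
  if (any(conv_kernels %% 2L == 0L)) {
    stop("kernel widths must be odd (length-preserving 'same' convolution)",
         call. = FALSE)
  }
  if (length(fc_sizes) != 2L) {
    stop("`fc_sizes` gives the two hidden FC layers; the output layer is fixed",
         call. = FALSE)
  }
  if (embed_dim < 1L || attention_dim < 1L || any(conv_filters < 1L) ||
      any(fc_sizes < 1L)) {
    stop("all dimensions must be positive", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
  if (is.null(polhyd_levels)) {
    polhyd_levels <- nrow(polhyd_codebook(default_polhyd_table()))
  }
  structure(list(
    embed_dim = as.integer(embed_dim),
    conv_filters = as.integer(conv_filters),
    conv_kernels = as.integer(conv_kernels),
    attention_dim = as.integer(attention_dim),
    fc_sizes = as.integer(fc_sizes),
    dropout = dropout,
    pep_pad = as.integer(pep_pad),
    pro_pad = as.integer(pro_pad),
    vocab = list(aa = 21L, ss = 63L, polhyd = as.integer(polhyd_levels)),
    numeric_dim = list(peptide = 3L, protein = 23L)
  ), class = "pepnet_architecture")
}

# Glorot-style normal initialization for a fan_in x fan_out matrix.
glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nrow = nr, ncol = nc)
}

# One embedding table with `levels` code rows plus a frozen all-zero row for
# the padding code 0 (stored as row 1; code c lives at row c + 1).
embed_table <- function(levels, dim) {
  tab <- rbind(numeric(dim), glorot(levels, dim))
  tab[1, ] <- 0
  tab
}

branch_params <- function(arch, role) {
  d <- arch$embed_dim
  D <- 4L * d
  num_d <- arch$numeric_dim[[role]]
  conv <- vector("list", 3L)
  in_dim <- D
  for (l in 1:3) {
    k <- arch$conv_kernels[l]
    out_dim <- arch$conv_filters[l]
    conv[[l]] <- list(W = glorot(k * in_dim, out_dim), b = numeric(out_dim))
    in_dim <- out_dim
  }
  list(
    embed = list(
      aa = embed_table(arch$vocab$aa, d),
      ss = embed_table(arch$vocab$ss, d),
      polhyd = embed_table(arch$vocab$polhyd, d),
      num = list(W = glorot(num_d, d), b = numeric(d))
    ),
    conv = conv,
    att = list(
      Wq = glorot(arch$attention_dim, D),
      Wk = glorot(arch$attention_dim, D),
      Wv = glorot(arch$attention_dim, D)
    )
  )
}

#' Initialize model parameters
#'
#' Draws all learnable weights for a given architecture: the two branch
#' parameter sets (embedding tables with a frozen zero row for the padding
#' code, convolution stacks, attention projections), the three FC layers of
#' the pair head, and the single-layer residue head. The parameter count is a
#' deterministic function of the architecture.
#'
#' @param arch a [pepnet_architecture()].
#' @param seed integer RNG seed.
#' @return nested list of class `pepnet_params`.
#' @export
pepnet_params <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "pepnet_architecture"))
  with_seed(seed, {
    C3 <- arch$conv_filters[3]
    dk <- arch$attention_dim
    in_dim <- 2L * C3 + 2L * dk
    fc <- list(
      list(W = glorot(in_dim, arch$fc_sizes[1]), b = numeric(arch$fc_sizes[1])),
      list(W = glorot(arch$fc_sizes[1], arch$fc_sizes[2]),
           b = numeric(arch$fc_sizes[2])),
      list(W = glorot(arch$fc_sizes[2], 1L), b = numeric(1L))
    )
    structure(list(
      pep = branch_params(arch, "peptide"),
      pro = branch_params(arch, "protein"),
      fc = fc,
      res = list(W = glorot(C3, 1L), b = numeric(1L))
    ), class = "pepnet_params")
  })
}

#' Count learnable parameters
#'
#' @param params a `pepnet_params` tree.
#' @return integer total number of scalar parameters.
#' @export
n_parameters <- function(params) {
  length(unlist(params, use.names = FALSE))
}
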