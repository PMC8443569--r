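#' Sequence record
#'
#' A validated (id, role, sequence) triple. Peptides are 1..50 residues;
#' proteins are longer than 50. Sequences are uppercased.
#'
#' @param id character id.
#' @param role `"peptide"` or `"protein"`.
#' @param sequence residue string.
#' @return list of class `pepnet_record` with fields `id`, `role`, `sequence`,
#'   `length`.
#' @export
sequence_record <- function(id, role = c("peptide", "protein"), sequence) {
  role <- match.arg(role)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (role == "peptide" && n > 50L) {
    stop("peptide '", id, "' has length ", n, "; peptides must be <= 50 residues",
         call. = FALSE)
  }
  if (role == "protein" && n <= 50L) {
    stop("protein '", id, "' has length ", n, "; proteins must be > 50 residues",
         call. = FALSE)
  }
  structure(list(id = as.character(id), role = role, sequence = sequence,
                 length = n),
            class = "pepnet_record")
}

#' Build a padded multi-channel feature profile for one sequence
#'
#' Encodes a sequence into the fixed-length representation consumed by the
#' network: three categorical code tracks (amino acid, secondary-structure
#' combined code, polarity/hydropathy code), a numeric matrix (peptides: the 3
#' disorder tracks; proteins: 20 normalized PSSM columns plus the 3 disorder
#' tracks), and a 0/1 validity mask. Positions beyond the true length are
#' zero in every channel. Proteins longer than `pad_len` are tail-truncated
#' (N-terminus kept) with a warning; peptides longer than `pad_len` are an
#' error.
#'
#' Numeric provider outputs must already lie in [0, 1]; the file-backed PSSM
#' reader squashes raw log-odds through the logistic function before they
#' reach this point.
#'
#' @param record a [sequence_record()].
#' @param providers feature providers ([stub_feature_providers()] or
#'   [file_feature_providers()]).
#' @param pad_len padded length (default 50 for peptides, 800 for proteins).
#' @param polhyd polarity/hydropathy classification table.
#' @return list of class `pepnet_profile` with fields `aa`, `ss`, `polhyd`
#'   (integer vectors length `pad_len`), `numeric` (`pad_len` x d matrix),
#'   `mask`, `true_length`, `role`, `id`.
#' @export
build_profile <- function(record, providers = stub_feature_providers(),
                          pad_len = if (record$role == "peptide") 50L else 800L,
                          polhyd = default_polhyd_table()) {
  stopifnot(inherits(record, "pepnet_record"))
  pad_len <- as.integer(pad_len)
  seq <- record$sequence
  n <- record$length
  if (record$role == "peptide" && n > pad_len) {
    stop("peptide '", record$id, "' longer than pad length ", pad_len, call. = FALSE)
  }
  if (n > pad_len) {
    warning("protein '", record$id, "' truncated from ", n, " to ", pad_len,
            " residues (N-terminus kept)", call. = FALSE)
    seq <- substr(seq, 1L, pad_len)
    n <- pad_len
  }

  ss_str <- providers$ss(seq)
  if (nchar(ss_str) != n) {
    stop("secondary-structure provider returned length ", nchar(ss_str),
         " for sequence of length ", n, call. = FALSE)
  }
  dis <- providers$disorder(seq)
  if (!is.matrix(dis) || nrow(dis) != n || ncol(dis) != 3) {
    stop("disorder provider must return an n x 3 matrix", call. = FALSE)
  }

  aa <- encode_residues(seq)
  ssc <- combine_ss_codes(seq, ss_str)
  ph <- combine_polhyd_codes(seq, polhyd)

  if (record$role == "protein") {
    pssm <- providers$pssm(seq)
    if (!is.matrix(pssm) || nrow(pssm) != n || ncol(pssm) != 20) {
      stop("PSSM provider must return an n x 20 matrix", call. = FALSE)
    }
    if (any(pssm < 0) || any(pssm > 1)) {
      stop("PSSM provider must return values in [0, 1] (normalize log-odds first)",
           call. = FALSE)
    }
    num <- cbind(pssm, dis)
  } else {
    num <- dis
  }

  pad_vec <- function(v) c(v, integer(pad_len - n))
  numeric_mat <- matrix(0, nrow = pad_len, ncol = ncol(num))
  numeric_mat[seq_len(n), ] <- num
  structure(list(
    aa = pad_vec(aa),
    ss = pad_vec(ssc),
    polhyd = pad_vec(ph),
    numeric = numeric_mat,
    mask = c(rep(1L, n), rep(0L, pad_len - n)),
    true_length = n,
    role = record$role,
    id = record$id
  ), class = "pepnet_profile")
}

#' @export
print.pepnet_profile <- function(x, ...) {
  cat(sprintf("<pepnet_profile> %s '%s': %d residues padded to %d, %d numeric tracks\n",
              x$role, x$id, x$true_length, length(x$mask), ncol(x$numeric)))
  invisible(x)
}
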