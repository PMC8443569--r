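#' Interaction pair table
#'
#' The central data container: a data frame of (peptide_id, protein_id, label)
#' rows with an optional per-residue binding vector per pair, plus id-to-
#' sequence maps for the two roles. Sequence maps may be omitted for purely
#' combinatorial operations (e.g. negative sampling over ids).
#'
#' @param pairs data.frame with columns `peptide_id`, `protein_id`, `label`
#'   (0/1) and optionally `bind` (comma-separated 0/1 string over the
#'   peptide's residues, `NA` or `"-"` when absent).
#' @param peptides named character vector mapping peptide id to sequence, or
#'   `NULL`.
#' @param proteins named character vector mapping protein id to sequence, or
#'   `NULL`.
#' @return list of class `pair_table` with elements `pairs`, `peptides`,
#'   `proteins`.
#' @export
pair_table <- function(pairs, peptides = NULL, proteins = NULL) {
  need <- c("peptide_id", "protein_id", "label")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs))) {
    stop("`pairs` must be a data.frame with columns peptide_id, protein_id, label",
         call. = FALSE)
  }
  pairs$peptide_id <- as.character(pairs$peptide_id)
  pairs$protein_id <- as.character(pairs$protein_id)
  pairs$label <- as.integer(pairs$label)
  if (!all(pairs$label %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  if (!"bind" %in% names(pairs)) pairs$bind <- NA_character_
  pairs$bind <- as.character(pairs$bind)
  pairs$bind[pairs$bind %in% c("-", "")] <- NA_character_
  key <- paste(pairs$peptide_id, pairs$protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (peptide_id, protein_id) rows in pair table", call. = FALSE)
  }
  rownames(pairs) <- NULL

  if (!is.null(peptides)) {
    bad <- setdiff(pairs$peptide_id, names(peptides))
    if (length(bad)) stop("unresolvable peptide ids: ",
                          paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(proteins)) {
    bad <- setdiff(pairs$protein_id, names(proteins))
    if (length(bad)) stop("unresolvable protein ids: ",
                          paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  has_bind <- !is.na(pairs$bind)
  if (!is.null(peptides) && any(has_bind)) {
    for (i in which(has_bind)) {
      v <- parse_bind(pairs$bind[i])
      plen <- nchar(peptides[[pairs$peptide_id[i]]])
      if (length(v) != plen) {
        stop("binding vector length ", length(v), " does not match peptide '",
             pairs$peptide_id[i], "' length ", plen, call. = FALSE)
      }
    }
  }
  structure(list(pairs = pairs, peptides = peptides, proteins = proteins),
            class = "pair_table")
}

# "1,0,0,1" -> integer vector; NA -> NULL
parse_bind <- function(s) {
  if (is.na(s)) return(NULL)
  v <- as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  if (anyNA(v) || !all(v %in% c(0L, 1L))) {
    stop("binding vectors must be comma-separated 0/1", call. = FALSE)
  }
  v
}

format_bind <- function(v) {
  if (is.null(v)) NA_character_ else paste(v, collapse = ",")
}

#' @export
print.pair_table <- function(x, ...) {
  n <- nrow(x$pairs)
  npos <- sum(x$pairs$label == 1L)
  cat(sprintf("<pair_table> %d pairs (%d positive, %d negative), %d with residue labels\n",
              n, npos, n - npos, sum(!is.na(x$pairs$bind))))
  cat(sprintf("  peptides: %s, proteins: %s\n",
              if (is.null(x$peptides)) "ids only" else length(x$peptides),
              if (is.null(x$proteins)) "ids only" else length(x$proteins)))
  invisible(x)
}

#' Subset a pair table by row indices
#'
#' @param x a `pair_table`.
#' @param i integer row indices into `x$pairs`.
#' @return a `pair_table` with the selected rows (sequence maps untouched).
#' @export
subset_pairs <- function(x, i) {
  stopifnot(inherits(x, "pair_table"))
  pair_table(x$pairs[i, , drop = FALSE], x$peptides, x$proteins)
}
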