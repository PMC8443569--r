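#' Residue alphabet
#'
#' The 21-letter residue alphabet used throughout the package: the 20 canonical
#' amino acids plus `X` for unknown or non-standard residues. Letters are coded
#' as integers 1..21; code 0 is reserved for padding positions and never
#' represents a residue.
#'
#' @return A list with `symbols` (ordered character vector of length 21) and
#'   `codes` (named integer vector mapping letter to code).
#' @examples
#' ab <- residue_alphabet()
#' ab$codes[["A"]]
#' @export
residue_alphabet <- function() {
  symbols <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
  codes <- stats::setNames(seq_along(symbols), symbols)
  list(symbols = symbols, codes = codes)
}

#' Encode a residue string as integer codes
#'
#' Each letter maps to its code in [residue_alphabet()]; any letter outside the
#' 20 canonical amino acids maps to the code of `X` (21). Input is uppercased.
#'
#' @param seq a single non-empty residue string.
#' @param alphabet alphabet as returned by [residue_alphabet()].
#' @return integer vector of the same length as the sequence, values in 1..21.
#' @examples
#' encode_residues("ACDX")
#' encode_residues("acdB")  # lowercase accepted; B -> code of X
#' @export
encode_residues <- function(seq, alphabet = residue_alphabet()) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop("`seq` must be a single non-empty residue string", call. = FALSE)
  }
  letters <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- unname(alphabet$codes[letters])
  codes[is.na(codes)] <- alphabet$codes[["X"]]
  as.integer(codes)
}

#' Combine amino-acid and secondary-structure classes into one categorical code
#'
#' Each residue position gets a single code for the (amino acid, secondary
#' structure) pair via the bijection `(aa_code - 1) * 3 + ss_code`, with
#' secondary-structure classes coded H = 1, E = 2, C = 3. Codes therefore range
#' over 1..63 and are distinct for all 21 x 3 combinations.
#'
#' @param seq residue string.
#' @param ss secondary-structure string over the 3-class alphabet `{H, E, C}`,
#'   same length as `seq`.
#' @param alphabet residue alphabet.
#' @return integer vector, values in 1..63.
#' @examples
#' combine_ss_codes("AC", "HC")
#' @export
combine_ss_codes <- function(seq, ss, alphabet = residue_alphabet()) {
  aa <- encode_residues(seq, alphabet)
  if (!is.character(ss) || length(ss) != 1L || nchar(ss) != length(aa)) {
    stop("`ss` must be a string of the same length as `seq`", call. = FALSE)
  }
  ss_letters <- strsplit(toupper(ss), "", fixed = TRUE)[[1]]
  ss_code <- match(ss_letters, c("H", "E", "C"))
  if (anyNA(ss_code)) {
    stop("secondary-structure letters must be in {H, E, C}", call. = FALSE)
  }
  as.integer((aa - 1L) * 3L + ss_code)
}

#' Default polarity/hydropathy classification table
#'
#' Residue classes used by the polarity/hydropathy categorical channel:
#' polarity in \{nonpolar, polar, charged\} by side-chain chemistry, hydropathy
#' in \{hydrophobic, neutral, hydrophilic\} by banding the Kyte-Doolittle index
#' (>= 2 hydrophobic, <= -2 hydrophilic, else neutral). `X` carries its own
#' `unknown/unknown` category. The table ships as an editable TSV
#' (`system.file("extdata", "polarity_hydropathy.tsv", package = "pepnet")`).
#'
#' @return data.frame with columns `residue`, `polarity`, `hydropathy`.
#' @export
default_polhyd_table <- function() {
  path <- system.file("extdata", "polarity_hydropathy.tsv", package = "pepnet")
  if (!nzchar(path)) stop("bundled polarity/hydropathy table not found", call. = FALSE)
  read_polhyd_table(path)
}

#' Read a polarity/hydropathy table from TSV
#'
#' @param path TSV with columns `residue`, `polarity`, `hydropathy` covering
#'   all 21 alphabet letters.
#' @return data.frame as in [default_polhyd_table()].
#' @export
read_polhyd_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "polarity", "hydropathy")
  if (!all(need %in% names(tab))) {
    stop("polarity/hydropathy table must have columns residue, polarity, hydropathy",
         call. = FALSE)
  }
  tab$residue <- toupper(tab$residue)
  missing <- setdiff(residue_alphabet()$symbols, tab$residue)
  if (length(missing) > 0) {
    stop("polarity/hydropathy table is missing letters: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Codebook for polarity/hydropathy category codes
#'
#' Enumerates the distinct (polarity, hydropathy) class pairs present in a
#' classification table, in lexicographic order, and assigns codes 1..n.
#'
#' @param table a table as returned by [default_polhyd_table()].
#' @return data.frame with columns `polarity`, `hydropathy`, `code`.
#' @export
polhyd_codebook <- function(table = default_polhyd_table()) {
  pairs <- unique(table[, c("polarity", "hydropathy")])
  pairs <- pairs[order(pairs$polarity, pairs$hydropathy), , drop = FALSE]
  pairs$code <- seq_len(nrow(pairs))
  rownames(pairs) <- NULL
  pairs
}

#' Combine polarity and hydropathy classes into one categorical code
#'
#' Residues sharing both the polarity class and the hydropathy class share a
#' code; codes index the cross-product categories enumerated by
#' [polhyd_codebook()].
#'
#' @param seq residue string.
#' @param table classification table covering all 21 letters.
#' @return integer vector of per-position category codes.
#' @examples
#' combine_polhyd_codes("VL")  # both nonpolar/hydrophobic -> equal codes
#' @export
combine_polhyd_codes <- function(seq, table = default_polhyd_table()) {
  letters <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(letters) == 0L) stop("`seq` must be non-empty", call. = FALSE)
  letters[!letters %in% residue_alphabet()$symbols] <- "X"
  idx <- match(letters, table$residue)
  if (anyNA(idx)) {
    stop("polarity/hydropathy table is missing letters present in `seq`",
         call. = FALSE)
  }
  book <- polhyd_codebook(table)
  key_seq <- paste(table$polarity[idx], table$hydropathy[idx], sep = "\r")
  key_book <- paste(book$polarity, book$hydropathy, sep = "\r")
  as.integer(book$code[match(key_seq, key_book)])
}
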